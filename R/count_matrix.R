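#' Construct a UMI count matrix
#'
#' The core container of the package: an integer genes x cells matrix of UMI
#' counts with gene identifiers as row names, droplet barcodes as column
#' names, a sample label, and a per-gene mitochondrial flag. The orientation
#' is always genes x cells internally, whatever the on-disk convention.
#'
#' @param counts Non-negative integer matrix, genes in rows, cells in
#'   columns. A sparse `Matrix` is accepted and densified.
#' @param gene_ids Character vector of unique gene identifiers, one per row.
#'   Defaults to `rownames(counts)`.
#' @param barcodes Character vector of unique cell barcodes, one per column.
#'   Defaults to `colnames(counts)`.
#' @param sample_label Single string naming the sample.
#' @param mito_flags Logical vector, one per gene, marking mitochondrial
#'   genes. If `NULL`, derived from `mito_prefix`.
#' @param mito_prefix Gene-id prefix identifying mitochondrial genes when
#'   `mito_flags` is not given. Default `"Q0"`, the systematic-name prefix of
#'   the yeast mitochondrial genome.
#' @return An object of class `count_matrix` with elements `counts`,
#'   `sample_label` and `mito_flags`; `gene_ids()` and `barcodes()` read the
#'   dimnames.
#' @export
count_matrix <- function(counts, gene_ids = rownames(counts),
                         barcodes = colnames(counts),
                         sample_label = "sample",
                         mito_flags = NULL, mito_prefix = "Q0") {
  if (inherits(counts, "Matrix")) counts <- as.matrix(counts)
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  storage_ok <- is.numeric(counts)
  if (!storage_ok) stop("counts must be numeric")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integral")
  mode(counts) <- "integer"
  if (is.null(gene_ids) || is.null(barcodes))
    stop("gene_ids and barcodes are required")
  gene_ids <- as.character(gene_ids)
  barcodes <- as.character(barcodes)
  if (length(gene_ids) != nrow(counts))
    stop("gene_ids length does not match number of rows")
  if (length(barcodes) != ncol(counts))
    stop("barcodes length does not match number of columns")
  if (anyDuplicated(gene_ids)) stop("duplicate gene_ids")
  if (anyDuplicated(barcodes)) stop("duplicate barcodes")
  if (is.null(mito_flags)) {
    mito_flags <- startsWith(gene_ids, mito_prefix)
  }
  if (length(mito_flags) != length(gene_ids))
    stop("mito_flags must have one entry per gene")
  dimnames(counts) <- list(gene_ids, barcodes)
  structure(list(counts = counts,
                 sample_label = as.character(sample_label)[1],
                 mito_flags = as.logical(mito_flags)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d cells (sample '%s')\n",
              nrow(x$counts), ncol(x$counts), x$sample_label))
  cat(sprintf("  total UMIs: %.0f; mitochondrial genes: %d\n",
              sum(x$counts), sum(x$mito_flags)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Gene identifiers and barcodes of a count matrix
#' @param cm A `count_matrix`.
#' @return Character vector of gene ids / barcodes.
#' @export
gene_ids <- function(cm) rownames(cm$counts)

#' @rdname gene_ids
#' @export
barcodes <- function(cm) colnames(cm$counts)

#' Subset a count matrix by gene and/or cell
#'
#' @param x A `count_matrix`.
#' @param i,j Gene and cell indices (any form `[` accepts).
#' @param ... Unused.
#' @return A `count_matrix` over the selected genes and cells.
#' @export
`[.count_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  keep_genes <- stats::setNames(seq_len(nrow(x$counts)), rownames(x$counts))
  keep_cells <- stats::setNames(seq_len(ncol(x$counts)), colnames(x$counts))
  gi <- keep_genes[i]
  cj <- keep_cells[j]
  gid <- names(gi); if (is.null(gid)) gid <- character(0)
  bc <- names(cj); if (is.null(bc)) bc <- character(0)
  # ids passed explicitly: zero-extent subsets drop dimnames in base R
  count_matrix(x$counts[gi, cj, drop = FALSE],
               gene_ids = gid, barcodes = bc,
               sample_label = x$sample_label,
               mito_flags = x$mito_flags[gi])
}

#' Construct a bulk expression profile
#'
#' @param gene_ids Unique gene identifiers.
#' @param fpkm Non-negative expression values (fragments per kilobase per
#'   million mapped reads), one per gene.
#' @return An object of class `bulk_profile`.
#' @export
bulk_profile <- function(gene_ids, fpkm) {
  gene_ids <- as.character(gene_ids)
  fpkm <- as.numeric(fpkm)
  if (length(gene_ids) != length(fpkm))
    stop("gene_ids and fpkm lengths differ")
  if (anyDuplicated(gene_ids)) stop("duplicate gene_ids in bulk profile")
  if (anyNA(fpkm) || any(fpkm < 0)) stop("fpkm must be non-negative")
  structure(list(gene_ids = gene_ids, fpkm = stats::setNames(fpkm, gene_ids)),
            class = "bulk_profile")
}

#' @export
print.bulk_profile <- function(x, ...) {
  cat(sprintf("bulk_profile: %d genes, %d detected (fpkm > 0)\n",
              length(x$gene_ids), sum(x$fpkm > 0)))
  invisible(x)
}
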
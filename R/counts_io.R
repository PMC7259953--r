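#' Read a 10x-style Matrix Market triplet directory
#'
#' Reads a UMI count matrix stored as `matrix.mtx` (Matrix Market coordinate
#' format, 1-based indices) together with `barcodes.tsv` (one barcode per
#' line) and `features.tsv` (1-3 tab-separated columns; the first column is
#' the gene id). On disk the matrix is genes x cells, as written by the 10x
#' pipeline; the result is genes x cells too.
#'
#' @param matrix_path Path to the `.mtx` file.
#' @param barcodes_path Path to the barcode file.
#' @param features_path Path to the feature/gene file.
#' @param sample_label Sample name recorded on the result.
#' @param mito_prefix Gene-id prefix flagging mitochondrial genes.
#' @return A [count_matrix()].
#' @export
read_mtx_counts <- function(matrix_path, barcodes_path, features_path,
                            sample_label = "sample", mito_prefix = "Q0") {
  m <- Matrix::readMM(matrix_path)
  m <- as.matrix(m)
  if (any(m < 0) || any(m != round(m)))
    stop("matrix file contains negative or non-integer entries")
  feats <- utils::read.delim(features_path, header = FALSE,
                             colClasses = "character")
  genes <- feats[[1]]
  bcs <- utils::read.delim(barcodes_path, header = FALSE,
                           colClasses = "character")[[1]]
  if (nrow(m) != length(genes))
    stop(sprintf("feature file has %d entries but matrix has %d rows",
                 length(genes), nrow(m)))
  if (ncol(m) != length(bcs))
    stop(sprintf("barcode file has %d entries but matrix has %d columns",
                 length(bcs), ncol(m)))
  count_matrix(m, gene_ids = genes, barcodes = bcs,
               sample_label = sample_label, mito_prefix = mito_prefix)
}

#' Write a count matrix as a Matrix Market triplet directory
#'
#' Emits `matrix.mtx` in the "coordinate integer general" dialect with
#' 1-based indices, plus `barcodes.tsv` and `features.tsv`, readable back by
#' [read_mtx_counts()].
#'
#' @param cm A [count_matrix()].
#' @param out_dir Directory to write into; created if absent.
#' @return Invisibly, the paths of the three files written.
#' @export
write_mtx_counts <- function(cm, out_dir) {
  stopifnot(inherits(cm, "count_matrix"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  mtx <- file.path(out_dir, "matrix.mtx")
  nz <- which(cm$counts != 0, arr.ind = TRUE)
  con <- file(mtx, "w")
  on.exit(close(con))
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               sprintf("%d %d %d", nrow(cm$counts), ncol(cm$counts),
                       nrow(nz))), con)
  if (nrow(nz) > 0) {
    writeLines(sprintf("%d %d %d", nz[, 1], nz[, 2],
                       cm$counts[nz]), con)
  }
  bc <- file.path(out_dir, "barcodes.tsv")
  writeLines(barcodes(cm), bc)
  ft <- file.path(out_dir, "features.tsv")
  writeLines(gene_ids(cm), ft)
  invisible(c(matrix = mtx, barcodes = bc, features = ft))
}

#' Read a two-column bulk expression table
#'
#' Expects tab-separated `gene id <TAB> fpkm` rows. A header line is
#' auto-detected: if the second field of the first row is not numeric the
#' row is treated as a header and skipped.
#'
#' @param path Path to the TSV file.
#' @return A [bulk_profile()].
#' @export
read_bulk_table <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, colClasses = "character")
  if (ncol(tab) < 2) stop("bulk table must have two columns")
  if (nrow(tab) > 0 && is.na(suppressWarnings(as.numeric(tab[1, 2])))) {
    tab <- tab[-1, , drop = FALSE]
  }
  fpkm <- suppressWarnings(as.numeric(tab[[2]]))
  if (anyNA(fpkm)) stop("non-numeric fpkm value in bulk table")
  if (any(fpkm < 0)) stop("negative fpkm value in bulk table")
  if (anyDuplicated(tab[[1]])) stop("duplicated gene id in bulk table")
  bulk_profile(tab[[1]], fpkm)
}
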
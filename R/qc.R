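#' Per-cell quality-control statistics
#'
#' @param cm A [count_matrix()].
#' @return A data.frame with one row per cell: `barcode`, `genes_detected`
#'   (genes with count > 0), `total_umi` (column sum) and `mito_pct`
#'   (percent of UMIs from mitochondrial genes; 0 for cells with no UMIs).
#' @export
cell_stats <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  total <- colSums(cm$counts)
  mito <- if (any(cm$mito_flags)) {
    colSums(cm$counts[cm$mito_flags, , drop = FALSE])
  } else {
    rep(0, ncol(cm$counts))
  }
  pct <- ifelse(total > 0, 100 * mito / total, 0)
  data.frame(barcode = barcodes(cm),
             genes_detected = colSums(cm$counts > 0),
             total_umi = as.numeric(total),
             mito_pct = as.numeric(pct),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Quality-control thresholds
#'
#' Maxima on detected genes (doublet proxy) and mitochondrial-read
#' percentage (damaged-cell proxy). Both are strict upper bounds: cells at
#' exactly the threshold are kept. The study set `max_genes_detected` to
#' 2000 for glucose-grown and mixed samples and 1500 for lag-phase samples,
#' and `max_mito_pct` to 0.2, 0.5 and 1.5 depending on the sample.
#'
#' @param max_genes_detected Positive integer; cells with more detected
#'   genes are removed.
#' @param max_mito_pct Maximum mitochondrial-read percentage in 0-100.
#' @param mito_scale `"percent"` (default) interprets `max_mito_pct` on the
#'   0-100 scale; `"fraction"` interprets it as a 0-1 fraction (so 0.2 means
#'   20%), for the alternative reading of thresholds quoted without units.
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(max_genes_detected = 2000, max_mito_pct = 0.2,
                          mito_scale = c("percent", "fraction")) {
  mito_scale <- match.arg(mito_scale)
  if (max_genes_detected <= 0) stop("max_genes_detected must be positive")
  if (max_mito_pct < 0) stop("max_mito_pct must be non-negative")
  lim <- if (mito_scale == "fraction") max_mito_pct * 100 else max_mito_pct
  if (lim > 100) stop("mito threshold exceeds 100%")
  structure(list(max_genes_detected = max_genes_detected,
                 max_mito_pct = max_mito_pct, mito_scale = mito_scale,
                 mito_pct_limit = lim),
            class = "qc_thresholds")
}

#' Filter cells by QC thresholds
#'
#' Removes cells whose detected-gene count or mitochondrial percentage
#' strictly exceeds its threshold. The gene set is unchanged; no lower bound
#' is applied (empty-droplet removal is the barcode caller's job, upstream).
#'
#' @param cm A [count_matrix()].
#' @param thresholds A [qc_thresholds()].
#' @return A list with `filtered` (the surviving `count_matrix`) and
#'   `report` (class `qc_report`): kept/removed barcodes with removal
#'   reasons and the per-cell stats table.
#' @export
apply_qc <- function(cm, thresholds) {
  stopifnot(inherits(cm, "count_matrix"), inherits(thresholds, "qc_thresholds"))
  st <- cell_stats(cm)
  too_many_genes <- st$genes_detected > thresholds$max_genes_detected
  too_mito <- st$mito_pct > thresholds$mito_pct_limit
  keep <- !(too_many_genes | too_mito)
  reason <- character(sum(!keep))
  reason <- ifelse(too_many_genes[!keep] & too_mito[!keep],
                   "genes_detected;mito_pct",
                   ifelse(too_many_genes[!keep], "genes_detected", "mito_pct"))
  report <- structure(list(
    kept_barcodes = st$barcode[keep],
    removed_barcodes = stats::setNames(reason, st$barcode[!keep]),
    per_cell_stats = st,
    thresholds = thresholds), class = "qc_report")
  list(filtered = cm[, keep], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d cells kept, %d removed\n",
              length(x$kept_barcodes), length(x$removed_barcodes)))
  if (length(x$removed_barcodes) > 0) {
    tab <- table(x$removed_barcodes)
    for (r in names(tab)) cat(sprintf("  %s: %d\n", r, tab[[r]]))
  }
  invisible(x)
}

#' Write a QC report as TSV
#'
#' One row per input cell with its stats, kept flag and removal reason.
#'
#' @param report A `qc_report` from [apply_qc()].
#' @param path Output file path.
#' @return Invisibly, the data.frame written.
#' @export
write_qc_report <- function(report, path) {
  st <- report$per_cell_stats
  st$kept <- st$barcode %in% report$kept_barcodes
  st$reason <- ifelse(st$kept, "",
                      report$removed_barcodes[st$barcode])
  utils::write.table(st, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(st)
}
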
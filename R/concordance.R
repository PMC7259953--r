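#' Pseudobulk gene totals
#'
#' Sums UMI counts per gene across all cells, mimicking a bulk measurement.
#'
#' @param cm A [count_matrix()].
#' @return Named numeric vector of per-gene total UMIs.
#' @export
pseudobulk <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  rowSums(cm$counts)
}

#' Pseudobulk vs bulk concordance
#'
#' Compares log-transformed pseudobulk UMI totals against a bulk fpkm
#' profile over the union of gene ids (exact string match). Both axes get
#' the same pseudo-count before the log. Genes detected in bulk but not in
#' the single-cell data are excluded from the fit (the headline rule of the
#' comparison); genes detected only in single-cell are kept. "Detected"
#' means strictly positive raw value.
#'
#' @param sc_totals Named numeric vector of per-gene single-cell UMI totals
#'   (e.g. from [pseudobulk()]).
#' @param bulk A [bulk_profile()].
#' @param pseudo_count Positive value added before the log (default 0.1, so
#'   an undetected gene maps to `log10(0.1) = -1`).
#' @param log_base Log base for both axes (default 10; Pearson R^2 is
#'   base-invariant).
#' @param exclude_bulk_only Apply the bulk-only exclusion rule (default
#'   `TRUE`). Set `FALSE` to fit over every gene.
#' @return An object of class `concordance_result`: `r_squared` (squared
#'   Pearson correlation over the included genes), `n_common_detected`,
#'   `n_sc_only`, `n_bulk_only`, the per-gene table (`genes`), and the
#'   parameters used.
#' @export
concordance_r2 <- function(sc_totals, bulk, pseudo_count = 0.1,
                           log_base = 10, exclude_bulk_only = TRUE) {
  stopifnot(inherits(bulk, "bulk_profile"))
  if (is.null(names(sc_totals))) stop("sc_totals must be named by gene id")
  if (pseudo_count <= 0) stop("pseudo_count must be positive")
  universe <- union(names(sc_totals), bulk$gene_ids)
  sc <- stats::setNames(rep(0, length(universe)), universe)
  sc[names(sc_totals)] <- sc_totals
  fp <- stats::setNames(rep(0, length(universe)), universe)
  fp[bulk$gene_ids] <- bulk$fpkm
  sc_det <- sc > 0
  bulk_det <- fp > 0
  bulk_only <- bulk_det & !sc_det
  sc_only <- sc_det & !bulk_det
  included <- if (exclude_bulk_only) !bulk_only else rep(TRUE, length(universe))
  x <- log(sc + pseudo_count, base = log_base)
  y <- log(fp + pseudo_count, base = log_base)
  if (sum(included) < 3)
    stop("fewer than 3 genes in the included set")
  if (stats::sd(x[included]) == 0 || stats::sd(y[included]) == 0)
    stop("zero variance on one axis; correlation undefined")
  r2 <- stats::cor(x[included], y[included])^2
  genes <- data.frame(gene_id = universe, sc_total = as.numeric(sc),
                      fpkm = as.numeric(fp),
                      log_sc = as.numeric(x), log_bulk = as.numeric(y),
                      included = as.logical(included),
                      status = ifelse(bulk_only, "bulk_only",
                               ifelse(sc_only, "sc_only",
                               ifelse(sc_det, "both", "neither"))),
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(r_squared = r2,
                 n_common_detected = sum(sc_det & bulk_det),
                 n_sc_only = sum(sc_only),
                 n_bulk_only = sum(bulk_only),
                 pseudo_count = pseudo_count, log_base = log_base,
                 exclude_bulk_only = exclude_bulk_only,
                 genes = genes),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("concordance_result: R^2 = %.3f over %d genes\n",
              x$r_squared, sum(x$genes$included)))
  cat(sprintf("  detected in both: %d; sc-only: %d; bulk-only: %d (%s)\n",
              x$n_common_detected, x$n_sc_only, x$n_bulk_only,
              if (x$exclude_bulk_only) "excluded from fit" else "included"))
  invisible(x)
}
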
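#' Depth-normalize and log-transform UMI counts
#'
#' Standard per-cell library-size normalization:
#' `value(g, c) = ln(1 + scale_factor * count(g, c) / total_umi(c))`.
#' Cells with zero total UMIs are retained with all-zero columns (QC is a
#' separate concern). For every cell with nonzero total,
#' `sum(expm1(values))` equals `scale_factor` exactly.
#'
#' @param cm A [count_matrix()].
#' @param scale_factor Positive scalar pseudo library size (default 10000).
#' @return An object of class `normalized_matrix`: `values` (genes x cells,
#'   natural-log units), `scale_factor`, and `source` (the input
#'   `count_matrix`).
#' @export
log_normalize <- function(cm, scale_factor = 10000) {
  stopifnot(inherits(cm, "count_matrix"))
  if (!is.numeric(scale_factor) || scale_factor <= 0)
    stop("scale_factor must be positive")
  total <- colSums(cm$counts)
  denom <- ifelse(total > 0, total, 1)
  vals <- log1p(sweep(cm$counts, 2, scale_factor / denom, `*`))
  vals[, total == 0] <- 0
  dimnames(vals) <- dimnames(cm$counts)
  structure(list(values = vals, scale_factor = scale_factor, source = cm),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf(
    "normalized_matrix: %d genes x %d cells, ln(1 + %g * count/total)\n",
    nrow(x$values), ncol(x$values), x$scale_factor))
  invisible(x)
}

#' @export
dim.normalized_matrix <- function(x) dim(x$values)
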
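#' Differential-expression parameters
#'
#' Thresholds for the two-group rank-sum comparison: a Benjamini-Hochberg
#' false-discovery-rate gate of 0.05 and a minimum absolute log2 fold change
#' of 0.25, the gates used to contrast the two lag-phase subpopulations.
#'
#' @param fdr_threshold FDR gate in (0, 1] (default 0.05).
#' @param min_abs_log2fc Minimum |log2 fold change| (default 0.25).
#' @param fc_pseudo Pseudo value added to de-logged group means before the
#'   fold-change ratio (default 0.01).
#' @param min_expressing_fraction Pre-filter: only genes expressed (count >
#'   0) in at least this fraction of cells in one of the groups are tested
#'   (default 0.1; set 0 to test every gene).
#' @return An object of class `de_params`.
#' @export
de_params <- function(fdr_threshold = 0.05, min_abs_log2fc = 0.25,
                      fc_pseudo = 0.01, min_expressing_fraction = 0.1) {
  if (fdr_threshold <= 0 || fdr_threshold > 1)
    stop("fdr_threshold must be in (0, 1]")
  if (min_abs_log2fc < 0) stop("min_abs_log2fc must be non-negative")
  if (fc_pseudo <= 0) stop("fc_pseudo must be positive")
  if (min_expressing_fraction < 0 || min_expressing_fraction > 1)
    stop("min_expressing_fraction must be in [0, 1]")
  structure(list(fdr_threshold = fdr_threshold,
                 min_abs_log2fc = min_abs_log2fc,
                 fc_pseudo = fc_pseudo,
                 min_expressing_fraction = min_expressing_fraction),
            class = "de_params")
}

#' Two-group differential expression
#'
#' Per-gene Mann-Whitney rank-sum test on normalized expression between two
#' cell groups, with BH adjustment over the tested genes and the fold-change
#' gate of [de_params()]. Group means are taken on the de-logged scale
#' (`expm1(values)`), and
#' `log2fc = log2((mean_a + fc_pseudo) / (mean_b + fc_pseudo))`, so positive
#' values mean higher expression in group A.
#'
#' @param nm A [log_normalize()] result.
#' @param labels Named character vector (barcode -> label) covering the
#'   cells of `nm`, e.g. from [classify_by_markers()] or [kmeans_cells()].
#' @param group_a,group_b The two labels to contrast.
#' @param params A [de_params()].
#' @return A `de_table`: data.frame with one row per tested gene (`gene_id`,
#'   `mean_a`, `mean_b`, `log2fc`, `pct_a`, `pct_b`, `p_value`,
#'   `p_adjusted`, `significant`, `direction`), ordered by `p_adjusted`.
#' @export
differential_expression <- function(nm, labels, group_a, group_b,
                                    params = de_params()) {
  stopifnot(inherits(nm, "normalized_matrix"), inherits(params, "de_params"))
  bcs <- colnames(nm$values)
  if (!all(bcs %in% names(labels)))
    stop("labels must cover every cell of the matrix")
  lab <- labels[bcs]
  if (!group_a %in% lab) stop("no cell carries label: ", group_a)
  if (!group_b %in% lab) stop("no cell carries label: ", group_b)
  a <- nm$values[, lab == group_a, drop = FALSE]
  b <- nm$values[, lab == group_b, drop = FALSE]
  expr_a <- rowMeans(a > 0)
  expr_b <- rowMeans(b > 0)
  tested <- expr_a >= params$min_expressing_fraction |
    expr_b >= params$min_expressing_fraction
  genes <- rownames(nm$values)[tested]
  if (length(genes) == 0) {
    tab <- data.frame(gene_id = character(0), mean_a = numeric(0),
                      mean_b = numeric(0), log2fc = numeric(0),
                      pct_a = numeric(0), pct_b = numeric(0),
                      p_value = numeric(0), p_adjusted = numeric(0),
                      significant = logical(0), direction = character(0))
    return(structure(tab, class = c("de_table", "data.frame"),
                     params = params, groups = c(group_a, group_b)))
  }
  mean_a <- rowMeans(expm1(a[tested, , drop = FALSE]))
  mean_b <- rowMeans(expm1(b[tested, , drop = FALSE]))
  l2fc <- log2((mean_a + params$fc_pseudo) / (mean_b + params$fc_pseudo))
  pv <- vapply(genes, function(g) {
    rank_sum_test(a[g, ], b[g, ])$p_value
  }, numeric(1))
  padj <- stats::p.adjust(pv, method = "BH")
  sig <- padj <= params$fdr_threshold & abs(l2fc) >= params$min_abs_log2fc
  tab <- data.frame(gene_id = genes,
                    mean_a = mean_a, mean_b = mean_b, log2fc = l2fc,
                    pct_a = expr_a[tested], pct_b = expr_b[tested],
                    p_value = pv, p_adjusted = padj,
                    significant = sig,
                    direction = ifelse(l2fc > 0, "up_in_a",
                                ifelse(l2fc < 0, "up_in_b", "none")),
                    row.names = NULL, stringsAsFactors = FALSE)
  tab <- tab[order(tab$p_adjusted, tab$p_value), ]
  rownames(tab) <- NULL
  structure(tab, class = c("de_table", "data.frame"),
            params = params, groups = c(group_a, group_b))
}

#' @export
print.de_table <- function(x, ...) {
  g <- attr(x, "groups")
  cat(sprintf("de_table: %s vs %s, %d genes tested, %d significant\n",
              g[1], g[2], nrow(x), sum(x$significant)))
  if (nrow(x) > 0) print.data.frame(utils::head(x, 10), digits = 3)
  invisible(x)
}

#' @export
summary.de_table <- function(object, ...) {
  list(n_tested = nrow(object),
       n_significant = sum(object$significant),
       n_up_in_a = sum(object$significant & object$direction == "up_in_a"),
       n_up_in_b = sum(object$significant & object$direction == "up_in_b"))
}

#' Write a differential-expression table as TSV
#'
#' @param de A `de_table`.
#' @param path Output file path.
#' @return Invisibly, `de`.
#' @export
write_de_table <- function(de, path) {
  utils::write.table(as.data.frame(de), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(de)
}
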
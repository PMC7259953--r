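#' Co-expression network parameters
#'
#' Filters and clustering settings for the co-expression analysis: genes
#' need at least 10 total UMIs across the population; an edge requires an
#' absolute Pearson correlation of at least 0.1 with a Bonferroni-adjusted
#' p-value at most 0.05; genes correlated with fewer than seven others are
#' dropped; retained genes are grouped into six modules.
#'
#' @param min_total_umi Minimum raw UMI total per gene (default 10).
#' @param min_partners Minimum number of significant partners per gene
#'   (default 7).
#' @param min_abs_r Minimum absolute Pearson coefficient for an edge
#'   (default 0.1).
#' @param alpha Family-wise (Bonferroni) significance level for edges
#'   (default 0.05). The family is all unordered pairs among genes passing
#'   the UMI filter.
#' @param n_modules Number of modules to cut (default 6).
#' @param linkage Agglomeration for hierarchical clustering: `"average"`
#'   (default), `"complete"` or `"ward"`.
#' @param pruning `"single_pass"` (default): degrees are computed once on
#'   the pre-prune gene set; `"iterative"`: recompute until a fixed point.
#' @param cluster_method `"hclust"` (default) or `"kmeans"` on the rows of
#'   the correlation matrix.
#' @param seed RNG seed used only by the k-means clustering option.
#' @return An object of class `coexpr_params`.
#' @export
coexpr_params <- function(min_total_umi = 10, min_partners = 7,
                          min_abs_r = 0.1, alpha = 0.05, n_modules = 6,
                          linkage = c("average", "complete", "ward"),
                          pruning = c("single_pass", "iterative"),
                          cluster_method = c("hclust", "kmeans"),
                          seed = 1L) {
  linkage <- match.arg(linkage)
  pruning <- match.arg(pruning)
  cluster_method <- match.arg(cluster_method)
  if (min_abs_r <= 0 || min_abs_r >= 1) stop("min_abs_r must be in (0, 1)")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (n_modules < 1) stop("n_modules must be positive")
  structure(list(min_total_umi = min_total_umi, min_partners = min_partners,
                 min_abs_r = min_abs_r, alpha = alpha, n_modules = n_modules,
                 linkage = linkage, pruning = pruning,
                 cluster_method = cluster_method, seed = as.integer(seed)),
            class = "coexpr_params")
}

#' Pairwise Pearson correlation with p-values
#'
#' Product-moment correlation of each gene pair across cells, with the
#' two-sided p-value from `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2`
#' degrees of freedom. Genes with zero variance across cells get `r = 0`,
#' `p = 1` against every partner and are flagged.
#'
#' @param nm A [log_normalize()] result.
#' @param genes Optional subset of gene ids (default: all genes).
#' @return List with `r` (correlation matrix), `p` (two-sided p-values,
#'   diagonal 0), and `zero_variance` (logical per gene).
#' @export
pairwise_pearson <- function(nm, genes = NULL) {
  stopifnot(inherits(nm, "normalized_matrix"))
  vals <- nm$values
  if (!is.null(genes)) {
    missing_genes <- setdiff(genes, rownames(vals))
    if (length(missing_genes) > 0)
      stop("unknown gene(s): ", paste(utils::head(missing_genes, 3),
                                      collapse = ", "))
    vals <- vals[genes, , drop = FALSE]
  }
  n <- ncol(vals)
  if (n < 3) stop("at least 3 cells required for correlation p-values")
  sds <- apply(vals, 1, stats::sd)
  zv <- sds == 0
  r <- matrix(0, nrow(vals), nrow(vals),
              dimnames = list(rownames(vals), rownames(vals)))
  if (any(!zv)) {
    r[!zv, !zv] <- stats::cor(t(vals[!zv, , drop = FALSE]))
  }
  diag(r) <- ifelse(zv, 0, 1)
  rc <- pmin(pmax(r, -1), 1)
  tstat <- rc * sqrt((n - 2) / pmax(1 - rc^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[abs(rc) >= 1] <- 0
  p[zv, ] <- 1
  p[, zv] <- 1
  diag(p) <- 0
  list(r = r, p = p, zero_variance = stats::setNames(zv, rownames(vals)))
}

#' Build a co-expression network
#'
#' Applies the full filter cascade: (1) drop genes below the raw-UMI total;
#' (2) correlate all remaining gene pairs; (3) Bonferroni-adjust over the
#' number of unordered pairs; (4) call an edge significant if
#' `|r| >= min_abs_r` and adjusted p <= alpha; (5) drop genes with fewer
#' significant partners than `min_partners`; (6) zero the correlation
#' diagonal; (7) cluster the retained correlation rows into modules.
#' Zero-variance genes never form edges. An empty surviving set yields an
#' empty network, not an error.
#'
#' @param nm A [log_normalize()] result.
#' @param cm The matching raw [count_matrix()] (used for the UMI filter).
#' @param params A [coexpr_params()].
#' @return An object of class `coexpression_network`: `retained_genes`,
#'   `corr` (zero diagonal), `p_adj`, `signif_edges`, `degrees` (the degree
#'   used for the pruning decision), `modules` (named integer vector in
#'   `1..n_modules`), `umi_filtered_genes`, and `params`.
#' @export
build_network <- function(nm, cm, params = coexpr_params()) {
  stopifnot(inherits(nm, "normalized_matrix"), inherits(cm, "count_matrix"),
            inherits(params, "coexpr_params"))
  if (!identical(rownames(nm$values), gene_ids(cm)))
    stop("normalized matrix and count matrix must share the gene universe")
  totals <- rowSums(cm$counts)
  pass_umi <- names(totals)[totals >= params$min_total_umi]
  umi_dropped <- setdiff(gene_ids(cm), pass_umi)
  empty <- function() structure(
    list(retained_genes = character(0),
         corr = matrix(0, 0, 0), p_adj = matrix(0, 0, 0),
         signif_edges = matrix(FALSE, 0, 0),
         degrees = integer(0), modules = integer(0),
         umi_filtered_genes = umi_dropped, params = params),
    class = "coexpression_network")
  if (length(pass_umi) < 2) {
    message("co-expression: fewer than 2 genes pass the UMI filter")
    return(empty())
  }
  pp <- pairwise_pearson(nm, genes = pass_umi)
  m <- length(pass_umi)
  n_pairs <- m * (m - 1) / 2
  p_adj <- pp$p * n_pairs
  p_adj[p_adj > 1] <- 1
  diag(p_adj) <- 0
  signif <- abs(pp$r) >= params$min_abs_r & p_adj <= params$alpha
  diag(signif) <- FALSE
  signif[pp$zero_variance, ] <- FALSE
  signif[, pp$zero_variance] <- FALSE
  if (params$pruning == "single_pass") {
    deg <- rowSums(signif)
    keep <- deg >= params$min_partners
    prune_deg <- deg[keep]
  } else {
    keep <- rep(TRUE, m)
    repeat {
      deg <- rowSums(signif[keep, keep, drop = FALSE])
      drop_now <- deg < params$min_partners
      if (!any(drop_now)) break
      keep[keep][drop_now] <- FALSE
      if (!any(keep)) break
    }
    prune_deg <- if (any(keep))
      rowSums(signif[keep, keep, drop = FALSE]) else integer(0)
  }
  retained <- pass_umi[keep]
  if (length(retained) == 0) {
    message("co-expression: no gene passes the partner filter")
    return(empty())
  }
  corr <- pp$r[retained, retained, drop = FALSE]
  diag(corr) <- 0
  edges <- signif[retained, retained, drop = FALSE]
  k <- min(params$n_modules, length(retained))
  modules <- if (length(retained) == 1) {
    stats::setNames(1L, retained)
  } else if (params$cluster_method == "hclust") {
    link <- c(average = "average", complete = "complete",
              ward = "ward.D2")[[params$linkage]]
    hc <- stats::hclust(stats::dist(corr), method = link)
    stats::cutree(hc, k = k)
  } else {
    km <- with_seed(params$seed,
                    stats::kmeans(corr, centers = k, nstart = 10,
                                  iter.max = 100))
    stats::setNames(km$cluster, retained)
  }
  structure(list(retained_genes = retained, corr = corr,
                 p_adj = p_adj[retained, retained, drop = FALSE],
                 signif_edges = edges,
                 degrees = stats::setNames(as.integer(prune_deg), retained),
                 modules = modules,
                 umi_filtered_genes = umi_dropped, params = params),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf(
    "coexpression_network: %d retained genes, %d significant edges\n",
    length(x$retained_genes), sum(x$signif_edges) / 2))
  if (length(x$modules) > 0) {
    tab <- table(x$modules)
    cat("  module sizes:", paste(sprintf("%s:%d", names(tab), tab),
                                 collapse = " "), "\n")
  }
  invisible(x)
}

#' Export a network edge list and module table
#'
#' Writes a TSV edge list (gene1, gene2, r, p_adj, significant) over all
#' retained-gene pairs plus a two-column module assignment TSV.
#'
#' @param net A `coexpression_network`.
#' @param edges_path,modules_path Output paths.
#' @return Invisibly, the edge data.frame.
#' @export
write_network <- function(net, edges_path, modules_path) {
  g <- net$retained_genes
  if (length(g) >= 2) {
    idx <- utils::combn(length(g), 2)
    ed <- data.frame(gene1 = g[idx[1, ]], gene2 = g[idx[2, ]],
                     r = net$corr[t(idx)],
                     p_adj = net$p_adj[t(idx)],
                     significant = net$signif_edges[t(idx)],
                     stringsAsFactors = FALSE)
  } else {
    ed <- data.frame(gene1 = character(0), gene2 = character(0),
                     r = numeric(0), p_adj = numeric(0),
                     significant = logical(0))
  }
  utils::write.table(ed, edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(gene_id = names(net$modules), module = net$modules),
    modules_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(ed)
}
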
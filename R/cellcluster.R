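#' PCA embedding of cells
#'
#' Projects cells into principal-component space of the normalized
#' expression matrix. Genes are centered and unit-scaled (zero-variance
#' genes are left unscaled rather than producing NaN) before the singular
#' value decomposition; components are ordered by decreasing explained
#' variance.
#'
#' @param nm A [log_normalize()] result.
#' @param n_components Number of components to keep (default 10); silently
#'   reduced (with a warning) when it exceeds the data rank.
#' @param scale_genes Unit-scale genes before projection (default `TRUE`).
#' @param highly_variable_n Optional: restrict to the top-N variance genes
#'   before embedding (default `NULL`, use all genes).
#' @return Cells x components matrix with an `explained_variance` attribute.
#' @export
pca_embed <- function(nm, n_components = 10, scale_genes = TRUE,
                      highly_variable_n = NULL) {
  stopifnot(inherits(nm, "normalized_matrix"))
  x <- t(nm$values)                      # cells x genes
  if (nrow(x) < 2) stop("at least 2 cells required")
  if (!is.null(highly_variable_n)) {
    v <- apply(x, 2, stats::var)
    keep <- order(v, decreasing = TRUE)[seq_len(min(highly_variable_n,
                                                    ncol(x)))]
    x <- x[, sort(keep), drop = FALSE]
  }
  x <- scale(x, center = TRUE, scale = FALSE)
  if (scale_genes) {
    sds <- apply(x, 2, stats::sd)
    sds[sds == 0] <- 1
    x <- sweep(x, 2, sds, `/`)
  }
  max_rank <- min(nrow(x) - 1, ncol(x))
  if (n_components > max_rank) {
    warning(sprintf("n_components reduced from %d to rank %d",
                    n_components, max_rank))
    n_components <- max_rank
  }
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE,
                      rank. = n_components)
  emb <- pc$x[, seq_len(n_components), drop = FALSE]
  rownames(emb) <- colnames(nm$values)
  attr(emb, "explained_variance") <-
    pc$sdev[seq_len(n_components)]^2 / sum(pc$sdev^2)
  emb
}

#' k-means clustering of embedded cells
#'
#' Lloyd's algorithm with k-means++ initialization, keeping the best of
#' `n_init` seeded restarts by total within-cluster sum of squares.
#' Deterministic given the seed; the caller's RNG stream is untouched.
#'
#' @param embedding Cells x features matrix (e.g. from [pca_embed()]).
#' @param k Number of clusters.
#' @param n_init Number of restarts (default 10).
#' @param seed RNG seed (default 1).
#' @return An object of class `cluster_assignment`: `cluster` (named vector
#'   barcode -> 1..k), `centers`, `inertia`.
#' @export
kmeans_cells <- function(embedding, k, n_init = 10, seed = 1L) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  if (k < 1) stop("k must be >= 1")
  if (k > n) stop("k exceeds the number of cells")
  best <- NULL
  with_seed(seed, {
    for (i in seq_len(n_init)) {
      centers <- kmeanspp_init(embedding, k)
      km <- suppressWarnings(
        stats::kmeans(embedding, centers = centers, iter.max = 100,
                      algorithm = "Lloyd"))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
  })
  cl <- best$cluster
  names(cl) <- rownames(embedding)
  structure(list(cluster = cl, centers = best$centers,
                 inertia = best$tot.withinss, k = k, seed = seed),
            class = "cluster_assignment")
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance from the nearest chosen center
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1)
  centers[1, ] <- x[idx, ]
  if (k > 1) {
    d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
    for (j in 2:k) {
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      idx <- sample.int(n, 1, prob = prob)
      centers[j, ] <- x[idx, ]
      d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
    }
  }
  # duplicated centers break stats::kmeans; replace with distinct points
  if (anyDuplicated(centers)) {
    for (j in which(duplicated(centers))) {
      for (cand in sample.int(n, n)) {
        trial <- x[cand, ]
        clash <- apply(centers[-j, , drop = FALSE], 1,
                       function(cc) isTRUE(all(cc == trial)))
        if (!any(clash)) { centers[j, ] <- trial; break }
      }
    }
    if (anyDuplicated(centers))  # data has < k distinct points: jitter
      centers <- centers + stats::rnorm(length(centers), 0, 1e-8)
  }
  centers
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %d cells in %d clusters (inertia %.2f)\n",
              length(x$cluster), x$k, x$inertia))
  print(table(x$cluster))
  invisible(x)
}

#' Cluster cells from a normalized matrix
#'
#' Convenience wrapper: [pca_embed()] then [kmeans_cells()].
#'
#' @param nm A [log_normalize()] result.
#' @param k Number of clusters (the lag-phase analysis used 4).
#' @param n_components PCA components (default 10).
#' @param n_init,seed Passed to [kmeans_cells()].
#' @param highly_variable_n Passed to [pca_embed()].
#' @return A `cluster_assignment`.
#' @export
cluster_cells <- function(nm, k, n_components = 10, n_init = 10, seed = 1L,
                          highly_variable_n = NULL) {
  emb <- pca_embed(nm, n_components = n_components,
                   highly_variable_n = highly_variable_n)
  kmeans_cells(emb, k = k, n_init = n_init, seed = seed)
}
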
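# evaluate expr under a temporary RNG state; restores the caller's stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same items;
#' invariant to label permutation, 1 for identical partitions, ~0 for
#' independent ones.
#'
#' @param a,b Vectors of cluster labels of equal length.
#' @return Scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

#' Best-match Jaccard recovery of planted gene sets
#'
#' For each reference (truth) gene set, the highest Jaccard index achieved
#' by any predicted module. Used to score module recovery without caring
#' about module labels.
#'
#' @param modules Named vector: gene id -> module label (e.g. the `modules`
#'   element of a `coexpression_network`).
#' @param truth_sets List of character vectors of gene ids.
#' @return Numeric vector, one best-match Jaccard per truth set.
#' @export
best_match_jaccard <- function(modules, truth_sets) {
  pred_sets <- split(names(modules), modules)
  vapply(truth_sets, function(tr) {
    if (length(pred_sets) == 0) return(0)
    max(vapply(pred_sets, function(pr) {
      length(intersect(tr, pr)) / length(union(tr, pr))
    }, numeric(1)))
  }, numeric(1))
}
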
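#' Micro-colony lag-time table
#'
#' Single-cell lag times grouped by micro-colony (the descendants of one
#' trapped founder cell), with a right-censoring flag for cells that did not
#' resume growth within the observation window.
#'
#' @param colony_id,cell_id Character vectors; `cell_id` must be unique.
#' @param lag_time Non-negative lag durations in hours.
#' @param resumed Logical: did the cell resume growth within the window?
#' @param observation_window Length of the observation window in hours
#'   (default 24).
#' @return An object of class `colony_lag_table` (a data.frame).
#' @export
colony_lag_table <- function(colony_id, cell_id, lag_time, resumed,
                             observation_window = 24) {
  colony_id <- as.character(colony_id)
  cell_id <- as.character(cell_id)
  lag_time <- as.numeric(lag_time)
  resumed <- as.logical(resumed)
  n <- length(cell_id)
  if (length(colony_id) != n || length(lag_time) != n ||
      length(resumed) != n)
    stop("all columns must have the same length")
  if (anyDuplicated(cell_id)) stop("cell_id must be unique")
  if (any(lag_time < 0, na.rm = TRUE)) stop("lag_time must be non-negative")
  if (observation_window <= 0) stop("observation_window must be positive")
  if (any(resumed & lag_time > observation_window, na.rm = TRUE))
    stop("resumed cells cannot have lag_time beyond the observation window")
  structure(data.frame(colony_id = colony_id, cell_id = cell_id,
                       lag_time = lag_time, resumed = resumed,
                       stringsAsFactors = FALSE),
            observation_window = observation_window,
            class = c("colony_lag_table", "data.frame"))
}

#' Read a colony lag table from TSV
#'
#' Expects columns `colony_id`, `cell_id`, `lag_time`, `resumed`.
#'
#' @param path Input TSV path.
#' @param observation_window Window length in hours (default 24).
#' @return A [colony_lag_table()].
#' @export
read_colony_lag_table <- function(path, observation_window = 24) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("colony_id", "cell_id", "lag_time", "resumed")
  if (!all(need %in% names(tab)))
    stop("missing column(s): ", paste(setdiff(need, names(tab)),
                                      collapse = ", "))
  colony_lag_table(tab$colony_id, tab$cell_id, tab$lag_time,
                   tab$resumed, observation_window)
}

eligible_lags <- function(table, censoring = c("drop_censored", "window_max")) {
  censoring <- match.arg(censoring)
  win <- attr(table, "observation_window")
  if (censoring == "drop_censored") {
    tab <- table[table$resumed, , drop = FALSE]
    lags <- tab$lag_time
  } else {
    tab <- table
    lags <- ifelse(tab$resumed, tab$lag_time, win)
  }
  list(colony = tab$colony_id, lag = lags)
}

#' Within- and between-colony pairwise lag differences
#'
#' Absolute lag-time differences over all unordered cell pairs, split into
#' same-colony (within) and cross-colony (between) sets, plus the
#' per-colony mean within difference and the mean over all pairs.
#'
#' @param table A [colony_lag_table()].
#' @param censoring `"drop_censored"` (default: only cells that resumed
#'   growth enter) or `"window_max"` (non-resumers enter with the window
#'   length as a lower-bound lag).
#' @return List with `within`, `between` (numeric vectors of absolute
#'   differences), `colony_means` (named, colonies with >= 2 eligible
#'   cells), `population_mean` (mean over all pairs) and `n_eligible`.
#' @export
pairwise_lag_diffs <- function(table,
                               censoring = c("drop_censored", "window_max")) {
  el <- eligible_lags(table, censoring)
  n <- length(el$lag)
  counts <- table(el$colony)
  if (sum(counts >= 2) < 2 || n < 3)
    stop("need at least 2 colonies with >= 2 eligible cells")
  idx <- utils::combn(n, 2)
  d <- abs(el$lag[idx[1, ]] - el$lag[idx[2, ]])
  same <- el$colony[idx[1, ]] == el$colony[idx[2, ]]
  within <- d[same]
  colony_of_pair <- el$colony[idx[1, ]][same]
  colony_means <- tapply(within, colony_of_pair, mean)
  list(within = within, between = d[!same],
       colony_means = colony_means[order(names(colony_means))],
       population_mean = mean(d), n_eligible = n)
}

#' Test whether related cells have more similar lag times
#'
#' Compares lag-time differences of genealogically related cells (same
#' micro-colony) against the population at large. Two variants:
#' `pairs_two_sample` (default) is a one-sided Mann-Whitney rank-sum test of
#' within-colony versus cross-colony pair differences;
#' `colony_means_one_sample` is a one-sided Wilcoxon signed-rank test of the
#' per-colony mean differences against the population mean pairwise
#' difference (the dots-versus-line reading of the comparison). Pair
#' differences sharing a cell are not independent; `p_value` is computed
#' over these non-independent pairs and flagged as such.
#'
#' @param table A [colony_lag_table()].
#' @param method `"pairs_two_sample"` or `"colony_means_one_sample"`.
#' @param censoring See [pairwise_lag_diffs()].
#' @return An object of class `lag_relatedness`: the pair-difference sets,
#'   colony means, population mean, `statistic`, `p_value`, `method`,
#'   `censoring` and `nonindependent_pairs = TRUE`.
#' @export
relatedness_test <- function(table,
                             method = c("pairs_two_sample",
                                        "colony_means_one_sample"),
                             censoring = c("drop_censored", "window_max")) {
  method <- match.arg(method)
  censoring <- match.arg(censoring)
  pd <- pairwise_lag_diffs(table, censoring)
  if (method == "pairs_two_sample") {
    ts <- rank_sum_test(pd$within, pd$between, alternative = "less")
    statistic <- ts$statistic
    p <- ts$p_value
  } else {
    w <- suppressWarnings(
      stats::wilcox.test(as.numeric(pd$colony_means),
                         mu = pd$population_mean, alternative = "less"))
    statistic <- unname(w$statistic)
    p <- w$p.value
  }
  structure(list(within_pair_diffs = pd$within,
                 between_pair_diffs = pd$between,
                 colony_mean_diffs = pd$colony_means,
                 population_mean_pairwise_diff = pd$population_mean,
                 n_eligible = pd$n_eligible,
                 statistic = statistic,
                 p_value = max(p, .Machine$double.xmin),
                 method = method, censoring = censoring,
                 nonindependent_pairs = TRUE),
            class = "lag_relatedness")
}

#' @export
print.lag_relatedness <- function(x, ...) {
  cat(sprintf("lag_relatedness (%s, %s):\n", x$method, x$censoring))
  cat(sprintf("  %d eligible cells, %d within pairs, %d between pairs\n",
              x$n_eligible, length(x$within_pair_diffs),
              length(x$between_pair_diffs)))
  cat(sprintf("  mean within diff %.3f h vs population mean %.3f h\n",
              mean(x$within_pair_diffs), x$population_mean_pairwise_diff))
  cat(sprintf("  one-sided p = %.3g (non-independent pairs)\n", x$p_value))
  invisible(x)
}
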
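test_that("a two-cell colony's mean pairwise difference is forced", {
  tab <- colony_lag_table(c("A", "A", "B", "B", "B"),
                          sprintf("c%d", 1:5),
                          c(5, 7, 10, 11, 12), rep(TRUE, 5))
  pd <- pairwise_lag_diffs(tab)
  expect_equal(unname(pd$colony_means["A"]), 2)
  expect_equal(unname(pd$colony_means["B"]), mean(c(1, 2, 1)))
})

test_that("identical lags give all-zero differences", {
  tab <- colony_lag_table(rep(c("A", "B"), each = 3), sprintf("c%d", 1:6),
                          rep(8, 6), rep(TRUE, 6))
  pd <- pairwise_lag_diffs(tab)
  expect_true(all(pd$within == 0))
  expect_true(all(pd$between == 0))
  expect_equal(pd$population_mean, 0)
})

test_that("all outputs equal a nested-loop brute force on 20 cells", {
  set.seed(101)
  colony <- sample(LETTERS[1:6], 20, replace = TRUE)
  lag <- round(runif(20, 2, 20), 2)
  tab <- colony_lag_table(colony, sprintf("c%02d", 1:20), lag,
                          rep(TRUE, 20))
  pd <- pairwise_lag_diffs(tab)
  w <- c(); b <- c()
  for (i in 1:19) for (j in (i + 1):20) {
    d <- abs(lag[i] - lag[j])
    if (colony[i] == colony[j]) w <- c(w, d) else b <- c(b, d)
  }
  expect_equal(sort(pd$within), sort(w))
  expect_equal(sort(pd$between), sort(b))
  expect_equal(pd$population_mean, mean(c(w, b)))
  for (cc in names(pd$colony_means)) {
    idx <- which(colony == cc)
    dd <- c()
    for (i in idx) for (j in idx) if (i < j) dd <- c(dd, abs(lag[i] - lag[j]))
    expect_equal(unname(pd$colony_means[cc]), mean(dd))
  }
})

test_that("pair counts satisfy within + between = C(n, 2)", {
  for (seed in 1:6) {
    sim <- generate_colony_lags(colony_sim_config(seed = seed))
    pd <- pairwise_lag_diffs(sim$table)
    n <- pd$n_eligible
    expect_equal(length(pd$within) + length(pd$between), choose(n, 2))
  }
})

test_that("the population mean is the pair-weighted within/between mix", {
  sim <- generate_colony_lags(colony_sim_config(seed = 7))
  pd <- pairwise_lag_diffs(sim$table)
  nw <- length(pd$within); nb <- length(pd$between)
  expect_equal(pd$population_mean,
               (nw * mean(pd$within) + nb * mean(pd$between)) / (nw + nb))
})

test_that("the statistic is invariant under a global shift of lag times", {
  sim <- generate_colony_lags(colony_sim_config(seed = 8,
                                                nonresume_probability = 0))
  t1 <- sim$table
  t2 <- colony_lag_table(t1$colony_id, t1$cell_id, t1$lag_time + 3,
                         t1$resumed, observation_window = 30)
  r1 <- relatedness_test(t1)
  r2 <- relatedness_test(t2)
  expect_equal(r1$statistic, r2$statistic)
  expect_equal(r1$p_value, r2$p_value)
})

test_that("perfectly similar colonies attain the extreme one-sided p", {
  # within diffs all zero, between all positive
  tab <- colony_lag_table(rep(c("A", "B", "C"), each = 3),
                          sprintf("c%d", 1:9),
                          rep(c(5, 10, 15), each = 3), rep(TRUE, 9))
  res <- relatedness_test(tab)
  pd <- pairwise_lag_diffs(tab)
  expect_true(all(pd$within == 0))
  expect_true(all(pd$between > 0))
  # U = 0: every within diff below every between diff
  expect_equal(res$statistic, 0)
  expect_lt(res$p_value, 0.001)
})

test_that("both test variants agree on direction for a strong effect", {
  sim <- generate_colony_lags(colony_sim_config(colony_sd = 4, cell_sd = 0.5,
                                                nonresume_probability = 0,
                                                seed = 9))
  a <- relatedness_test(sim$table, method = "pairs_two_sample")
  b <- relatedness_test(sim$table, method = "colony_means_one_sample")
  expect_lt(a$p_value, 0.01)
  expect_lt(b$p_value, 0.01)
  expect_true(a$nonindependent_pairs)
})

test_that("censoring modes control who enters the comparison", {
  tab <- colony_lag_table(rep(c("A", "B"), each = 3), sprintf("c%d", 1:6),
                          c(5, 6, 23, 8, 9, 22),
                          c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE))
  drop <- pairwise_lag_diffs(tab, censoring = "drop_censored")
  expect_equal(drop$n_eligible, 4L)
  win <- pairwise_lag_diffs(tab, censoring = "window_max")
  expect_equal(win$n_eligible, 6L)
  # non-resumers carry the window as a lower-bound lag
  expect_true(any(win$within == 24 - 6 | win$within == 24 - 5))
})

test_that("no eligible colonies is an error under drop_censored", {
  sim <- generate_colony_lags(colony_sim_config(nonresume_probability = 1,
                                                seed = 10))
  expect_false(any(sim$table$resumed))
  expect_error(pairwise_lag_diffs(sim$table), "eligible")
})

test_that("lag tables round-trip through TSV", {
  sim <- generate_colony_lags(colony_sim_config(seed = 11))
  f <- withr::local_tempfile()
  write.table(sim$table, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_colony_lag_table(f)
  expect_equal(back$lag_time, sim$table$lag_time)
  expect_equal(back$colony_id, sim$table$colony_id)
})
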
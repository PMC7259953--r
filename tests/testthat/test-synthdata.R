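test_that("the generator is deterministic given its seed", {
  a <- generate_counts(synth_config(seed = 5))
  b <- generate_counts(synth_config(seed = 5))
  expect_identical(a$matrix$counts, b$matrix$counts)
  expect_identical(a$truth, b$truth)
  c <- generate_counts(synth_config(seed = 6))
  expect_false(identical(a$matrix$counts, c$matrix$counts))
})

test_that("generated matrices satisfy the count-matrix invariants", {
  sim <- generate_counts(synth_config(seed = 7))
  cm <- sim$matrix
  expect_s3_class(cm, "count_matrix")
  expect_true(all(cm$counts >= 0))
  expect_true(is.integer(cm$counts))
  expect_false(anyDuplicated(barcodes(cm)) > 0)
  expect_equal(nrow(sim$truth), ncol(cm$counts))
  expect_equal(sum(cm$mito_flags), 5L)
})

test_that("per-gene means track program x mean library factor", {
  # no ambient, doublets, modules or damage: plain NB around the program
  n_genes <- 130
  cfg <- single_pop_cfg(n_genes = n_genes, n_cells = 2000,
                        module_genes = list(), seed = 12)
  sim <- generate_counts(cfg)
  prog <- cfg$populations[[1]]$program
  mean_lib <- exp(cfg$library_size_log_mean + cfg$library_size_log_sd^2 / 2)
  expected <- prog * mean_lib
  observed <- rowMeans(sim$matrix$counts)
  # NB + lognormal-library variance Monte-Carlo SEs; with 130 genes a few
  # 3-SE excursions are expected by chance, none beyond 4.5 SE
  lib_var <- (exp(cfg$library_size_log_sd^2) - 1) * mean_lib^2
  gene_var <- expected + expected^2 / cfg$dispersion + prog^2 * lib_var
  se <- sqrt(gene_var / 2000)
  z <- abs(observed - expected) / se
  expect_gte(mean(z <= 3), 0.95)
  expect_true(all(z <= 4.5))
})

test_that("filled droplets land in the thousands, empties near 100", {
  sim <- generate_counts(synth_config(seed = 8))
  tot <- colSums(sim$matrix$counts)
  filled <- sim$truth$population != "empty"
  qs <- quantile(tot[filled], c(0.02, 0.98))
  expect_gt(qs[1], 700)
  expect_lt(qs[2], 12000)
  expect_equal(mean(tot[!filled]), 100, tolerance = 0.15)
  expect_lt(max(tot[!filled]), 700)
})

test_that("damaged cells carry a visibly boosted mitochondrial fraction", {
  sim <- generate_counts(synth_config(seed = 9, damaged_cell_fraction = 0.2))
  st <- cell_stats(sim$matrix)
  filled <- sim$truth$population != "empty"
  dmg <- sim$truth$damaged & filled
  ok <- !sim$truth$damaged & filled
  expect_gt(median(st$mito_pct[dmg]), 5 * median(st$mito_pct[ok]))
})

test_that("doublet barcodes have inflated totals and correct bookkeeping", {
  cfg <- synth_config(seed = 10, doublet_rate = 0.1)
  sim <- generate_counts(cfg)
  filled <- sim$truth$population != "empty"
  expect_equal(sum(sim$truth$doublet), floor(0.1 * sum(filled)))
  tot <- colSums(sim$matrix$counts)
  expect_gt(mean(tot[sim$truth$doublet]),
            1.5 * mean(tot[filled & !sim$truth$doublet]))
})

test_that("stage streams are isolated: doublets do not perturb the rest", {
  base <- generate_counts(synth_config(seed = 11, doublet_rate = 0))
  with_doub <- generate_counts(synth_config(seed = 11, doublet_rate = 0.05))
  hosts <- with_doub$truth$doublet
  expect_identical(base$matrix$counts[, !hosts],
                   with_doub$matrix$counts[, !hosts])
})

test_that("colony lags collapse to the mean when both sds are zero", {
  sim <- generate_colony_lags(colony_sim_config(colony_sd = 0, cell_sd = 0,
                                                nonresume_probability = 0,
                                                seed = 12))
  expect_true(all(sim$table$lag_time == 10))
  expect_true(all(sim$table$resumed))
})

test_that("colony simulations hit the requested size and structure", {
  sim <- generate_colony_lags(colony_sim_config(seed = 13))
  expect_equal(nrow(sim$table), 133L)
  sizes <- table(sim$table$colony_id)
  expect_equal(unname(median(sizes)), 3)
  expect_true(all(sizes >= 1 & sizes <= 4))
})

test_that("without colony variance, within and between diffs match in law", {
  sim <- generate_colony_lags(colony_sim_config(n_cells = 600,
                                                colony_sd = 0,
                                                nonresume_probability = 0,
                                                seed = 14))
  pd <- pairwise_lag_diffs(sim$table)
  ks <- suppressWarnings(ks.test(pd$within, pd$between))
  expect_gt(ks$p.value, 0.01)
})

test_that("a noiseless bulk pair is perfectly concordant", {
  sim <- generate_counts(synth_config(seed = 15))
  bulk <- generate_bulk_pair(sim$matrix, noise_sd = 0)
  res <- concordance_r2(pseudobulk(sim$matrix), bulk)
  expect_equal(res$r_squared, 1.0, tolerance = 1e-12)
})

test_that("zeroing genes on the bulk side shows up as sc-only detections", {
  sim <- generate_counts(synth_config(seed = 16))
  detected <- names(which(pseudobulk(sim$matrix) > 0))
  drop <- detected[1:5]
  bulk <- generate_bulk_pair(sim$matrix, noise_sd = 0,
                             genes_zero_in_bulk = drop)
  res <- concordance_r2(pseudobulk(sim$matrix), bulk)
  expect_equal(res$n_sc_only, 5L)
})

test_that("concordance degrades monotonically in bulk noise", {
  sim <- generate_counts(synth_config(seed = 17))
  sc <- pseudobulk(sim$matrix)
  r2 <- vapply(c(0, 0.3, 1.5), function(s) {
    mean(vapply(1:3, function(rep)
      concordance_r2(sc, generate_bulk_pair(sim$matrix, noise_sd = s,
                                            seed = rep))$r_squared,
      numeric(1)))
  }, numeric(1))
  expect_equal(r2[1], 1, tolerance = 1e-12)
  expect_true(all(diff(r2) < 0))
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(ambient_fraction = 1.2), "ambient_fraction")
  expect_error(synth_config(dispersion = 0), "dispersion")
  prog <- setNames(rep(1, 120), sprintf("g%03d", 1:120))
  pops <- list(list(name = "p", n_cells = 10, program = prog,
                    markers = "nope"))
  expect_error(synth_config(n_genes = 120, populations = pops,
                            modules = list(), mito_gene_ids = character(0)),
               "marker genes")
})
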
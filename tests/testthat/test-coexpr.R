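# a matrix whose first `n_block` genes are exact copies of one pattern:
# they form a clique of perfect correlations; remaining genes are noise
block_nm <- function(n_block, n_noise = 10, n_cells = 30, seed = 81) {
  set.seed(seed)
  pattern <- rpois(n_cells, 5)
  noise <- matrix(rpois(n_noise * n_cells, 5), n_noise, n_cells)
  counts <- rbind(matrix(rep(pattern, each = n_block), n_block, n_cells),
                  noise)
  cm <- count_matrix(counts,
                     c(sprintf("blk%02d", seq_len(n_block)),
                       sprintf("nse%02d", seq_len(n_noise))),
                     sprintf("c%03d", seq_len(n_cells)),
                     mito_flags = rep(FALSE, n_block + n_noise))
  list(cm = cm, nm = log_normalize(cm))
}

test_that("pairwise correlations match the closed-form t-test p", {
  fx <- single_pop_cfg(n_genes = 130, n_cells = 40, seed = 4)
  sim <- generate_counts(fx)
  nm <- log_normalize(sim$matrix)
  genes <- sprintf("g%03d", 1:8)
  pp <- pairwise_pearson(nm, genes)
  n <- ncol(nm$values)
  for (i in 1:7) for (j in (i + 1):8) {
    r_oracle <- cor(nm$values[genes[i], ], nm$values[genes[j], ])
    expect_equal(pp$r[i, j], r_oracle)
    t_or <- r_oracle * sqrt((n - 2) / (1 - r_oracle^2))
    expect_equal(pp$p[i, j], 2 * pt(abs(t_or), n - 2, lower.tail = FALSE))
  }
  expect_equal(pp$r, t(pp$r))
})

test_that("self- and affine-related genes correlate perfectly", {
  counts <- matrix(c(1L, 3L, 2L, 5L,
                     3L, 7L, 5L, 11L), 2, 4, byrow = TRUE,
                   dimnames = list(c("g1", "g2"), sprintf("c%d", 1:4)))
  cm <- count_matrix(counts)
  nm <- structure(list(values = matrix(as.numeric(counts), 2, 4,
                                       dimnames = dimnames(counts)),
                       scale_factor = 1, source = cm),
                  class = "normalized_matrix")
  pp <- pairwise_pearson(nm)
  expect_equal(pp$r["g1", "g1"], 1)      # before diagonal zeroing
  expect_equal(pp$r["g1", "g2"], 1)      # g2 = 2*g1 + 1
  expect_equal(pp$p["g1", "g2"], 0)
})

test_that("zero-variance genes get r = 0, p = 1 and form no edges", {
  set.seed(86)
  vals <- rbind(flat = rep(2, 20),
                g1 = rnorm(20, 5), g2 = rnorm(20, 5))
  colnames(vals) <- sprintf("c%02d", 1:20)
  cm <- count_matrix(matrix(1L, 3, 20, dimnames = dimnames(vals)))
  nm <- structure(list(values = vals, scale_factor = 1, source = cm),
                  class = "normalized_matrix")
  pp <- pairwise_pearson(nm)
  expect_true(pp$zero_variance["flat"])
  expect_equal(unname(pp$r["flat", "g1"]), 0)
  expect_equal(unname(pp$p["flat", "g1"]), 1)
  expect_equal(unname(pp$r["flat", "flat"]), 0)
})

test_that("genes under the UMI total are excluded before correlation", {
  fx <- block_nm(8)
  counts <- fx$cm$counts
  counts[17, ] <- 0L
  counts[17, 1:9] <- 1L                  # exactly 9 total UMIs
  counts[18, 1:10] <- 1L
  counts[18, 11:30] <- 0L                # exactly 10 total UMIs
  cm <- count_matrix(counts, gene_ids(fx$cm), barcodes(fx$cm),
                     mito_flags = rep(FALSE, nrow(counts)))
  net <- build_network(log_normalize(cm), cm, coexpr_params())
  expect_true("nse09" %in% net$umi_filtered_genes)      # 9 < 10: dropped
  expect_false("nse10" %in% net$umi_filtered_genes)     # 10 passes
})

test_that("a 7-gene clique (6 partners each) is pruned, an 8-gene kept", {
  seven <- block_nm(7, seed = 82)
  net7 <- build_network(seven$nm, seven$cm, coexpr_params())
  expect_equal(length(net7$retained_genes), 0L)
  eight <- block_nm(8, seed = 83)
  net8 <- build_network(eight$nm, eight$cm, coexpr_params())
  expect_setequal(net8$retained_genes, sprintf("blk%02d", 1:8))
  expect_true(all(net8$degrees >= 7))
})

test_that("the correlation diagonal is exactly zero and Bonferroni holds", {
  fx <- single_pop_cfg(n_genes = 130, n_cells = 200, seed = 5)
  sim <- generate_counts(fx)
  nm <- log_normalize(sim$matrix)
  net <- build_network(nm, sim$matrix, coexpr_params(n_modules = 2))
  expect_true(all(diag(net$corr) == 0))
  expect_equal(net$corr, t(net$corr), tolerance = 1e-12)
  # Bonferroni-adjusted p never below raw p and capped at 1
  pp <- pairwise_pearson(nm, net$retained_genes)
  off <- upper.tri(net$p_adj)
  expect_true(all(net$p_adj[off] >= pp$p[off] - 1e-15))
  expect_true(all(net$p_adj <= 1))
  # every significant edge meets the correlation floor
  expect_true(all(abs(net$corr[net$signif_edges]) >= 0.1))
})

test_that("tightening any filter never grows the retained set", {
  fx <- single_pop_cfg(n_genes = 130, n_cells = 250, seed = 6)
  sim <- generate_counts(fx)
  nm <- log_normalize(sim$matrix)
  base <- build_network(nm, sim$matrix, coexpr_params(n_modules = 2))
  tighter <- list(coexpr_params(min_total_umi = 50, n_modules = 2),
                  coexpr_params(min_partners = 10, n_modules = 2),
                  coexpr_params(min_abs_r = 0.3, n_modules = 2),
                  coexpr_params(alpha = 0.001, n_modules = 2))
  for (p in tighter) {
    net <- build_network(nm, sim$matrix, p)
    expect_true(all(net$retained_genes %in% base$retained_genes))
  }
})

test_that("iterative pruning reaches a fixed point within single-pass set", {
  fx <- single_pop_cfg(n_genes = 130, n_cells = 250, seed = 8)
  sim <- generate_counts(fx)
  nm <- log_normalize(sim$matrix)
  sp <- build_network(nm, sim$matrix, coexpr_params(n_modules = 2))
  it <- build_network(nm, sim$matrix,
                      coexpr_params(n_modules = 2, pruning = "iterative"))
  expect_true(all(it$retained_genes %in% sp$retained_genes))
  if (length(it$retained_genes) > 0)
    expect_true(all(it$degrees >= 7))
})

test_that("planted modules are recovered by both clustering methods", {
  cfg <- single_pop_cfg(n_genes = 130, n_cells = 300, seed = 9)
  sim <- generate_counts(cfg)
  nm <- log_normalize(sim$matrix)
  truth <- list(sprintf("g%03d", 1:15), sprintf("g%03d", 16:30))
  for (method in c("hclust", "kmeans")) {
    net <- build_network(nm, sim$matrix,
                         coexpr_params(n_modules = 2,
                                       cluster_method = method))
    expect_true(all(best_match_jaccard(net$modules, truth) >= 0.8))
  }
})

test_that("no surviving gene yields an empty network, not an error", {
  cm <- rand_cm(n_genes = 10, n_cells = 20, seed = 84)
  expect_message(
    net <- build_network(log_normalize(cm), cm,
                         coexpr_params(min_total_umi = 10000)),
    "UMI filter")
  expect_equal(length(net$retained_genes), 0L)
  expect_equal(length(net$modules), 0L)
})

test_that("edge lists and module tables export as TSV", {
  fx <- block_nm(8, seed = 85)
  net <- build_network(fx$nm, fx$cm, coexpr_params())
  d <- withr::local_tempdir()
  ed <- write_network(net, file.path(d, "e.tsv"), file.path(d, "m.tsv"))
  expect_equal(nrow(ed), choose(8, 2))
  expect_true(all(ed$significant))
  mods <- read.delim(file.path(d, "m.tsv"))
  expect_equal(nrow(mods), 8L)
})
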
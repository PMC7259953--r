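# fixture builders and independent oracles shared across test files

# small random count matrix with a couple of mitochondrial genes
rand_cm <- function(n_genes = 20, n_cells = 50, seed = 1, mean_count = 1.2,
                    sparsity = 0.6) {
  set.seed(seed)
  n <- n_genes * n_cells
  m <- matrix(as.integer(rpois(n, mean_count) * (runif(n) > sparsity)),
              n_genes, n_cells)
  genes <- c(sprintf("Q0%03d", seq_len(min(2, n_genes))),
             sprintf("YAL%03dW", seq_len(n_genes - min(2, n_genes))))
  count_matrix(m, gene_ids = genes,
               barcodes = sprintf("bc%04d", seq_len(n_cells)))
}

# one-population generator config with explicit planted modules
single_pop_cfg <- function(n_genes = 130, n_cells = 500,
                           module_genes = list(sprintf("g%03d", 1:15),
                                               sprintf("g%03d", 16:30)),
                           latent_sd = 1.2, seed = 7, ...) {
  set.seed(99)
  base <- exp(rnorm(n_genes))
  prog <- setNames(base / sum(base), sprintf("g%03d", seq_len(n_genes)))
  synth_config(
    n_genes = n_genes,
    populations = list(list(name = "pop", n_cells = n_cells,
                            program = prog, markers = character(0))),
    modules = lapply(module_genes,
                     function(g) list(genes = g, latent_sd = latent_sd)),
    mito_gene_ids = character(0), ambient_fraction = 0, doublet_rate = 0,
    n_empty_droplets = 0, damaged_cell_fraction = 0, seed = seed, ...)
}

# three clearly separated populations: 60 genes boosted 4x, 20 per population
three_pop_cfg <- function(seed = 1, n_per = 150) {
  n_genes <- 200
  set.seed(777)
  base <- exp(rnorm(n_genes))
  names(base) <- sprintf("g%03d", seq_len(n_genes))
  pops <- lapply(1:3, function(p) {
    pr <- base
    idx <- ((p - 1) * 20 + 1):(p * 20)
    pr[idx] <- pr[idx] * 4
    list(name = paste0("pop", p), n_cells = n_per,
         program = pr / sum(pr), markers = character(0))
  })
  synth_config(n_genes = n_genes, populations = pops, modules = list(),
               mito_gene_ids = character(0), ambient_fraction = 0,
               doublet_rate = 0, n_empty_droplets = 0,
               damaged_cell_fraction = 0, seed = seed)
}

# full enumeration over all C(n, n1) group assignments of the ranks;
# independent oracle for the rank-sum p-value (untied data)
enum_ranksum_p <- function(x, y, alternative = "two.sided") {
  n1 <- length(x)
  vals <- c(x, y)
  r <- rank(vals)
  obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(vals), n1)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  switch(alternative,
         less = mean(us <= obs),
         greater = mean(us >= obs),
         two.sided = min(1, 2 * min(mean(us <= obs), mean(us >= obs))))
}

# default maltose marker panel of the mixed control
maltose_panel <- function() {
  marker_panel(c("MAL11", "MAL12", "MAL31", "MAL32", "IMA1", "HXK1"),
               positive_label = "maltose", negative_label = "glucose")
}

# hand-written MTX triplet file set
write_mtx_fixture <- function(dir, header, triplets, genes, bcs) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               header, triplets), file.path(dir, "matrix.mtx"))
  writeLines(genes, file.path(dir, "features.tsv"))
  writeLines(bcs, file.path(dir, "barcodes.tsv"))
  dir
}
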
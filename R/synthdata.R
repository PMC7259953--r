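#' Synthetic droplet scRNA-seq configuration
#'
#' Describes the generative model for a synthetic UMI count matrix with the
#' structure the pipeline assumes: two or more cell populations with
#' distinct expression programs and marker genes, planted co-expression
#' modules driven by a shared per-cell latent activity, lognormal library
#' sizes placing filled droplets in the 1,000-10,000 UMI range, ambient
#' mRNA contamination, doublets, empty droplets at ~100 UMIs, and a damaged
#' subpopulation with boosted mitochondrial reads.
#'
#' With all arguments at their defaults the generator emulates the mixed
#' glucose/maltose control condition: a "glucose" and a "maltose" population
#' of 250 cells each over 200 genes, the maltose population expressing the
#' classic maltose-growth markers (MAL11, MAL12, MAL31, MAL32, IMA1 and the
#' glucose-repressed HXK1), 60 additional genes separated two- to four-fold
#' between the populations, two 15-gene co-expression modules, and five
#' mitochondrial (Q0-prefixed) genes.
#'
#' @param n_genes Number of genes (default 200).
#' @param populations List of populations, each a list with `name`,
#'   `n_cells`, `program` (per-gene positive expected-rate vector; the
#'   defaults are relative profiles summing to 1 so the library factor sets
#'   the expected total UMIs) and `markers` (character subset of gene ids).
#'   `NULL` builds the default two-population design.
#' @param modules List of planted co-expression modules, each a list with
#'   `genes` (character subset) and `latent_sd` (lognormal sd of the shared
#'   per-cell activity). `NULL` plants two 15-gene modules at `latent_sd`
#'   1.2, which puts the median within-module correlation of normalized
#'   values around 0.3-0.4 after counting noise.
#' @param library_size_log_mean,library_size_log_sd Lognormal parameters of
#'   the per-cell library factor (defaults `log(3000)` and 0.4, putting
#'   filled droplets in roughly 1,000-10,000 total UMIs).
#' @param dispersion Negative-binomial size parameter (default 1).
#' @param ambient_fraction Fraction of each cell's expected counts replaced
#'   by the ambient (population-average) profile. Default 0.002: the
#'   protocol being emulated demonstrates minimal premature lysis, and the
#'   clean marker-based separation of its mixed control implies filled
#'   droplets carry far less soup than a uniform-soup reading of the
#'   empty-droplet UMI content would suggest.
#' @param doublet_rate Fraction of barcodes that receive a second cell's
#'   transcriptome (default 0.02).
#' @param n_empty_droplets Number of appended empty droplets (default 100).
#' @param empty_umi_mean Poisson mean of empty-droplet totals (default 100).
#' @param mito_gene_ids Gene ids flagged mitochondrial (default five
#'   Q0-prefixed genes included in the default universe).
#' @param damaged_cell_fraction Fraction of cells with boosted
#'   mitochondrial expression (default 0.05).
#' @param damaged_mito_boost Multiplier on mitochondrial rates in damaged
#'   cells (default 20).
#' @param sample_label Label stored on the generated matrix.
#' @param seed Integer seed; the generator is deterministic given the
#'   config, and each generation stage consumes its own derived stream so
#'   changing, say, the doublet rate does not scramble the base counts.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_genes = 200, populations = NULL, modules = NULL,
                         library_size_log_mean = log(3000),
                         library_size_log_sd = 0.4,
                         dispersion = 1,
                         ambient_fraction = 0.002, doublet_rate = 0.02,
                         n_empty_droplets = 100, empty_umi_mean = 100,
                         mito_gene_ids = NULL,
                         damaged_cell_fraction = 0.05,
                         damaged_mito_boost = 20,
                         sample_label = "synthetic", seed = 1L) {
  if (is.null(populations)) {
    def <- default_populations(n_genes, seed)
    populations <- def$populations
    if (is.null(mito_gene_ids)) mito_gene_ids <- def$mito_gene_ids
    if (is.null(modules)) modules <- def$modules
  }
  gene_universe <- names(populations[[1]]$program)
  if (is.null(gene_universe))
    stop("population programs must be named by gene id")
  if (length(gene_universe) != n_genes)
    stop("program length disagrees with n_genes")
  if (is.null(mito_gene_ids)) mito_gene_ids <- character(0)
  if (is.null(modules)) modules <- list()
  for (p in populations) {
    if (!identical(names(p$program), gene_universe))
      stop("all population programs must share one gene universe")
    if (any(p$program <= 0)) stop("program rates must be strictly positive")
    if (!all(p$markers %in% gene_universe))
      stop("marker genes must be in the gene universe")
  }
  for (m in modules) {
    if (!all(m$genes %in% gene_universe))
      stop("module genes must be in the gene universe")
    if (m$latent_sd <= 0) stop("latent_sd must be positive")
  }
  if (!all(mito_gene_ids %in% gene_universe))
    stop("mito_gene_ids must be in the gene universe")
  if (ambient_fraction < 0 || ambient_fraction >= 1)
    stop("ambient_fraction must be in [0, 1)")
  if (doublet_rate < 0 || doublet_rate >= 1)
    stop("doublet_rate must be in [0, 1)")
  if (dispersion <= 0) stop("dispersion must be positive")
  structure(list(n_genes = n_genes, gene_universe = gene_universe,
                 populations = populations, modules = modules,
                 library_size_log_mean = library_size_log_mean,
                 library_size_log_sd = library_size_log_sd,
                 dispersion = dispersion,
                 ambient_fraction = ambient_fraction,
                 doublet_rate = doublet_rate,
                 n_empty_droplets = n_empty_droplets,
                 empty_umi_mean = empty_umi_mean,
                 mito_gene_ids = mito_gene_ids,
                 damaged_cell_fraction = damaged_cell_fraction,
                 damaged_mito_boost = damaged_mito_boost,
                 sample_label = sample_label, seed = as.integer(seed)),
            class = "synth_config")
}

# default two-population design: maltose markers, 60 separated genes,
# two 15-gene co-expression modules, five mitochondrial genes
default_populations <- function(n_genes, seed) {
  if (n_genes < 120) stop("default design needs at least 120 genes")
  markers <- c("MAL11", "MAL12", "MAL31", "MAL32", "IMA1", "HXK1")
  mito <- c("Q0045", "Q0085", "Q0105", "Q0130", "Q0250")
  n_other <- n_genes - length(markers) - length(mito)
  genes <- c(markers, mito, sprintf("gene%03d", seq_len(n_other)))
  base <- with_seed(seed * 7 + 11, stats::rlnorm(n_genes, 0, 1))
  names(base) <- genes
  base[markers] <- mean(base)          # markers at a typical gene's level
  base[mito] <- 0.0002 * sum(base)     # ~0.1% together: healthy cells sit
                                       # below the 0.2% QC ceiling
  glucose <- base
  glucose[markers] <- base[markers] * 2e-4    # tight catabolite repression
  maltose <- base                             # induced on maltose
  sep_genes <- sprintf("gene%03d", seq_len(60))
  fold <- with_seed(seed * 7 + 12, stats::runif(60, 2, 4))
  up_in_glucose <- seq_len(60) %% 2 == 0
  glucose[sep_genes[up_in_glucose]] <-
    glucose[sep_genes[up_in_glucose]] * fold[up_in_glucose]
  maltose[sep_genes[!up_in_glucose]] <-
    maltose[sep_genes[!up_in_glucose]] * fold[!up_in_glucose]
  modules <- list(
    list(genes = sprintf("gene%03d", 61:75), latent_sd = 1.2),
    list(genes = sprintf("gene%03d", 76:90), latent_sd = 1.2))
  list(populations = list(
         list(name = "glucose", n_cells = 250,
              program = glucose / sum(glucose), markers = character(0)),
         list(name = "maltose", n_cells = 250,
              program = maltose / sum(maltose), markers = markers)),
       modules = modules, mito_gene_ids = mito)
}

#' Generate a synthetic UMI count matrix with ground truth
#'
#' Per cell `c` of population `p`, the expected count of gene `g` is
#' `program_gp * module_latents * library_factor_c`, where each planted
#' module contributes a shared per-cell lognormal activity (mean 1) to its
#' member genes. Counts are negative-binomial draws around a rate mixed
#' with the ambient profile (the library-weighted population average, the
#' soup released by prematurely lysed cells); a fraction of barcodes become
#' doublets by adding an independently simulated second cell; empty
#' droplets carrying Poisson-distributed ambient counts are appended; and a
#' damaged fraction of cells has its mitochondrial rates boosted.
#'
#' @param cfg A [synth_config()].
#' @return List with `matrix` (a [count_matrix()]) and `truth`: a
#'   data.frame (`barcode`, `population` — `"empty"` for empty droplets —
#'   `doublet`, `damaged`, `library_factor`) plus `module_latents` (cells x
#'   modules) and `module_genes`.
#' @export
generate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  genes <- cfg$gene_universe
  n_genes <- length(genes)
  pops <- cfg$populations
  pop_of_cell <- rep(vapply(pops, `[[`, "", "name"),
                     vapply(pops, function(p) p$n_cells, numeric(1)))
  n_cells <- length(pop_of_cell)
  prog <- vapply(pops, `[[`, numeric(n_genes), "program")
  colnames(prog) <- vapply(pops, `[[`, "", "name")

  lib <- with_seed(cfg$seed + 101L,
                   stats::rlnorm(n_cells, cfg$library_size_log_mean,
                                 cfg$library_size_log_sd))
  n_mod <- length(cfg$modules)
  latents <- with_seed(cfg$seed + 102L, {
    if (n_mod == 0) matrix(0, n_cells, 0) else
      vapply(cfg$modules, function(m)
        stats::rlnorm(n_cells, -m$latent_sd^2 / 2, m$latent_sd),
        numeric(n_cells))
  })
  if (n_mod > 0 && is.null(dim(latents)))
    latents <- matrix(latents, ncol = n_mod)
  damaged <- with_seed(cfg$seed + 103L,
                       stats::runif(n_cells) < cfg$damaged_cell_fraction)

  rate <- prog[, pop_of_cell, drop = FALSE]
  for (m in seq_len(n_mod)) {
    gidx <- match(cfg$modules[[m]]$genes, genes)
    rate[gidx, ] <- rate[gidx, ] * rep(latents[, m], each = length(gidx))
  }
  if (length(cfg$mito_gene_ids) > 0 && any(damaged)) {
    midx <- match(cfg$mito_gene_ids, genes)
    rate[midx, damaged] <- rate[midx, damaged] * cfg$damaged_mito_boost
  }
  rate <- sweep(rate, 2, lib, `*`)
  amb_profile <- rowSums(sweep(prog[, pop_of_cell, drop = FALSE], 2,
                               lib, `*`))
  amb_profile <- amb_profile / sum(amb_profile)
  if (cfg$ambient_fraction > 0) {
    cell_totals <- colSums(rate)
    rate <- (1 - cfg$ambient_fraction) * rate +
      cfg$ambient_fraction * outer(amb_profile, cell_totals)
  }
  counts <- with_seed(cfg$seed + 104L,
    matrix(stats::rnbinom(length(rate), mu = rate, size = cfg$dispersion),
           n_genes, n_cells))

  n_doub <- floor(cfg$doublet_rate * n_cells)
  doublet <- rep(FALSE, n_cells)
  if (n_doub > 0) {
    with_seed(cfg$seed + 105L, {
      hosts <- sample.int(n_cells, n_doub)
      donors_pop <- sample(pop_of_cell, n_doub, replace = TRUE)
      donor_lib <- stats::rlnorm(n_doub, cfg$library_size_log_mean,
                                 cfg$library_size_log_sd)
      for (i in seq_len(n_doub)) {
        donor_rate <- prog[, donors_pop[i]] * donor_lib[i]
        counts[, hosts[i]] <- counts[, hosts[i]] +
          stats::rnbinom(n_genes, mu = donor_rate, size = cfg$dispersion)
      }
      doublet[hosts] <- TRUE
    })
  }

  n_empty <- cfg$n_empty_droplets
  if (n_empty > 0) {
    empties <- with_seed(cfg$seed + 106L, {
      tot <- stats::rpois(n_empty, cfg$empty_umi_mean)
      vapply(tot, function(tt)
        as.numeric(stats::rmultinom(1, tt, amb_profile)), numeric(n_genes))
    })
  } else {
    empties <- matrix(0, n_genes, 0)
  }

  all_counts <- cbind(counts, empties)
  bcs <- c(sprintf("cell%05d", seq_len(n_cells)),
           if (n_empty > 0) sprintf("empty%05d", seq_len(n_empty)))
  cm <- count_matrix(all_counts, gene_ids = genes, barcodes = bcs,
                     sample_label = cfg$sample_label,
                     mito_flags = genes %in% cfg$mito_gene_ids)
  truth <- data.frame(
    barcode = bcs,
    population = c(pop_of_cell, rep("empty", n_empty)),
    doublet = c(doublet, rep(FALSE, n_empty)),
    damaged = c(damaged, rep(FALSE, n_empty)),
    library_factor = c(lib, rep(NA_real_, n_empty)),
    stringsAsFactors = FALSE)
  list(matrix = cm, truth = truth,
       module_latents = latents,
       module_genes = lapply(cfg$modules, `[[`, "genes"))
}

#' Colony lag-time simulation configuration
#'
#' Colony-structured lag times: `lag = lag_mean + b_colony + e_cell` with
#' `b ~ N(0, colony_sd^2)` shared within a micro-colony and independent
#' cell noise `e ~ N(0, cell_sd^2)`, truncated below at zero. Cells fail to
#' resume growth within the observation window independently with
#' `nonresume_probability` (a drawn lag beyond the window also censors the
#' cell). Defaults mirror the microscopy experiment: 133 cells in colonies
#' of two to four members (median size 3), a 10 h mean lag in the 5-20 h+
#' range, and a 24 h observation window.
#'
#' @param n_cells Total number of cells (default 133).
#' @param size_choices Possible colony sizes, sampled uniformly (default
#'   `2:4`; the last colony is trimmed to hit `n_cells` exactly).
#' @param lag_mean Mean lag in hours (default 10).
#' @param colony_sd Between-colony sd in hours (default 2).
#' @param cell_sd Within-colony sd in hours (default 1).
#' @param nonresume_probability Probability a cell never resumes (default
#'   0.1).
#' @param observation_window Hours observed (default 24).
#' @param seed Integer seed.
#' @return An object of class `colony_sim_config`.
#' @export
colony_sim_config <- function(n_cells = 133, size_choices = 2:4,
                              lag_mean = 10, colony_sd = 2, cell_sd = 1,
                              nonresume_probability = 0.1,
                              observation_window = 24, seed = 1L) {
  if (colony_sd < 0 || cell_sd < 0) stop("sds must be non-negative")
  if (nonresume_probability < 0 || nonresume_probability > 1)
    stop("nonresume_probability must be in [0, 1]")
  if (any(size_choices < 1)) stop("colony sizes must be >= 1")
  structure(list(n_cells = n_cells, size_choices = size_choices,
                 lag_mean = lag_mean, colony_sd = colony_sd,
                 cell_sd = cell_sd,
                 nonresume_probability = nonresume_probability,
                 observation_window = observation_window,
                 seed = as.integer(seed)),
            class = "colony_sim_config")
}

#' Generate colony-structured lag times
#'
#' @param cfg A [colony_sim_config()].
#' @return List with `table` (a [colony_lag_table()]) and `truth` (the
#'   per-colony effects and the sds used).
#' @export
generate_colony_lags <- function(cfg) {
  stopifnot(inherits(cfg, "colony_sim_config"))
  with_seed(cfg$seed + 201L, {
    sizes <- integer(0)
    while (sum(sizes) < cfg$n_cells) {
      sizes <- c(sizes, sample(cfg$size_choices, 1))
    }
    sizes[length(sizes)] <- sizes[length(sizes)] -
      (sum(sizes) - cfg$n_cells)
    sizes <- sizes[sizes > 0]
    n_col <- length(sizes)
    b <- stats::rnorm(n_col, 0, cfg$colony_sd)
    colony <- rep(sprintf("colony%03d", seq_len(n_col)), sizes)
    e <- stats::rnorm(cfg$n_cells, 0, cfg$cell_sd)
    lag <- pmax(0, cfg$lag_mean + rep(b, sizes) + e)
    resumed <- stats::runif(cfg$n_cells) >= cfg$nonresume_probability
    resumed <- resumed & lag <= cfg$observation_window
    tab <- colony_lag_table(colony, sprintf("cell%04d", seq_len(cfg$n_cells)),
                            lag, resumed, cfg$observation_window)
    list(table = tab,
         truth = list(colony_effects = stats::setNames(
                        b, sprintf("colony%03d", seq_len(n_col))),
                      colony_sd = cfg$colony_sd, cell_sd = cfg$cell_sd))
  })
}

#' Generate a matched bulk profile from a count matrix
#'
#' Builds an fpkm-like bulk profile proportional to the pseudobulk totals,
#' perturbed by mean-one lognormal noise, optionally zeroing a chosen gene
#' set on the bulk side to exercise the detection-exclusion bookkeeping of
#' [concordance_r2()].
#'
#' @param cm A [count_matrix()].
#' @param noise_sd Lognormal sd of the per-gene perturbation (0 gives exact
#'   proportionality and concordance R^2 of 1).
#' @param genes_zero_in_bulk Gene ids forced to zero in the bulk profile.
#' @param scale Optional total fpkm mass. The default (`NULL`) keeps the
#'   pseudobulk scale, so with zero noise the profile is exactly concordant
#'   (R^2 = 1); rescaling interacts with the fixed pseudo-count and makes
#'   the log-log relation slightly non-linear.
#' @param seed Integer seed.
#' @return A [bulk_profile()] over the genes of `cm`.
#' @export
generate_bulk_pair <- function(cm, noise_sd = 0, genes_zero_in_bulk = NULL,
                               scale = NULL, seed = 1L) {
  stopifnot(inherits(cm, "count_matrix"))
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  totals <- pseudobulk(cm)
  fpkm <- if (is.null(scale)) totals else
    totals / max(sum(totals), 1) * scale
  if (noise_sd > 0) {
    noise <- with_seed(seed + 301L,
                       stats::rlnorm(length(fpkm), -noise_sd^2 / 2, noise_sd))
    fpkm <- fpkm * noise
  }
  if (!is.null(genes_zero_in_bulk)) {
    bad <- setdiff(genes_zero_in_bulk, names(fpkm))
    if (length(bad) > 0) stop("unknown gene(s): ", paste(bad, collapse = ", "))
    fpkm[genes_zero_in_bulk] <- 0
  }
  bulk_profile(names(fpkm), unname(fpkm))
}
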
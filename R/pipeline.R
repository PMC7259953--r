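#' Pipeline configuration
#'
#' Bundles the stage parameters for [run_pipeline()]. Input is either a
#' ready [count_matrix()] or a [synth_config()] to simulate one. Stages
#' without a configuration (e.g. no marker panel, no bulk profile) are
#' skipped.
#'
#' @param out_dir Run directory; created if absent.
#' @param counts A [count_matrix()], or `NULL` to simulate from `synth`.
#' @param synth A [synth_config()] used when `counts` is `NULL`.
#' @param qc A [qc_thresholds()] (default: 2000 genes, 0.2% mito).
#' @param scale_factor Normalization scale factor (default 10000).
#' @param markers Optional [marker_panel()] for cell classification.
#' @param cluster_k Optional k for PCA + k-means subpopulation discovery.
#' @param n_components PCA components for clustering (default 10).
#' @param de Optional [de_params()]; differential expression runs between
#'   `de_groups` of the marker labeling when a panel is given, else between
#'   clusters 1 and 2 when clustering ran.
#' @param de_groups Length-2 character vector of labels to contrast
#'   (default: the panel's positive and negative labels).
#' @param coexpr Optional [coexpr_params()] for network construction.
#' @param bulk Optional [bulk_profile()] for pseudobulk concordance.
#' @param lag_table Optional [colony_lag_table()] for the relatedness test.
#' @param lineage_method,censoring Passed to [relatedness_test()].
#' @param seed Global seed for every stochastic stage.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, counts = NULL, synth = NULL,
                            qc = qc_thresholds(), scale_factor = 10000,
                            markers = NULL, cluster_k = NULL,
                            n_components = 10,
                            de = de_params(), de_groups = NULL,
                            coexpr = NULL, bulk = NULL, lag_table = NULL,
                            lineage_method = "pairs_two_sample",
                            censoring = "drop_censored", seed = 1L) {
  if (is.null(counts) && is.null(synth))
    stop("provide counts or a synth_config")
  structure(list(out_dir = out_dir, counts = counts, synth = synth,
                 qc = qc, scale_factor = scale_factor, markers = markers,
                 cluster_k = cluster_k, n_components = n_components,
                 de = de, de_groups = de_groups, coexpr = coexpr,
                 bulk = bulk, lag_table = lag_table,
                 lineage_method = lineage_method, censoring = censoring,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the analysis pipeline
#'
#' Executes qc -> normalize -> (markers | cluster) -> differential
#' expression -> co-expression, plus concordance and the lineage test when
#' their inputs are configured, writing every intermediate as a
#' standard-format file (MTX/TSV/JSON) under the run directory along with a
#' `manifest.json` recording the seed, stage outputs and cell/gene counts
#' in and out of every filter. Deterministic given (config, seed).
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of the in-memory stage results plus
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  manifest <- list(seed = config$seed,
                   package_version = as.character(
                     utils::packageVersion("yeastlag")),
                   stages = list())
  res <- list()

  cm <- config$counts
  if (is.null(cm)) {
    sim <- generate_counts(config$synth)
    cm <- sim$matrix
    write_mtx_counts(cm, out("simulated"))
    utils::write.table(sim$truth, out("truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    res$simulation <- sim
    manifest$stages$simulate <- list(
      n_genes = nrow(cm$counts), n_barcodes = ncol(cm$counts),
      outputs = c("simulated/matrix.mtx", "truth.tsv"))
  }

  qcres <- apply_qc(cm, config$qc)
  write_qc_report(qcres$report, out("qc_report.tsv"))
  write_mtx_counts(qcres$filtered, out("filtered"))
  res$qc <- qcres
  manifest$stages$qc <- list(
    cells_in = ncol(cm$counts), cells_out = ncol(qcres$filtered$counts),
    outputs = c("qc_report.tsv", "filtered/matrix.mtx"))
  cm <- qcres$filtered

  nm <- log_normalize(cm, scale_factor = config$scale_factor)
  Matrix::writeMM(Matrix::Matrix(nm$values, sparse = TRUE),
                  out("normalized.mtx"))
  res$normalized <- nm
  manifest$stages$normalize <- list(scale_factor = config$scale_factor,
                                    outputs = "normalized.mtx")

  labels <- NULL
  if (!is.null(config$markers)) {
    labels <- classify_by_markers(cm, config$markers)
    utils::write.table(
      data.frame(barcode = names(labels), label = labels),
      out("marker_labels.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    res$marker_labels <- labels
    manifest$stages$classify <- list(
      label_counts = as.list(table(labels)),
      outputs = "marker_labels.tsv")
  }
  if (!is.null(config$cluster_k)) {
    ca <- cluster_cells(nm, k = config$cluster_k,
                        n_components = config$n_components,
                        seed = config$seed)
    utils::write.table(
      data.frame(barcode = names(ca$cluster), cluster = ca$cluster),
      out("clusters.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    res$clusters <- ca
    manifest$stages$cluster <- list(
      k = config$cluster_k, inertia = ca$inertia,
      sizes = as.list(table(ca$cluster)), outputs = "clusters.tsv")
  }

  if (!is.null(config$de)) {
    de_labels <- NULL
    groups <- config$de_groups
    if (!is.null(labels)) {
      de_labels <- labels
      if (is.null(groups))
        groups <- c(config$markers$positive_label,
                    config$markers$negative_label)
    } else if (!is.null(res$clusters)) {
      de_labels <- stats::setNames(as.character(res$clusters$cluster),
                                   names(res$clusters$cluster))
      if (is.null(groups)) groups <- c("1", "2")
    }
    if (!is.null(de_labels) && all(groups %in% de_labels)) {
      de <- differential_expression(nm, de_labels, groups[1], groups[2],
                                    params = config$de)
      write_de_table(de, out("de_table.tsv"))
      res$de <- de
      manifest$stages$de <- list(
        groups = groups, n_tested = nrow(de),
        n_significant = sum(de$significant), outputs = "de_table.tsv")
    }
  }

  if (!is.null(config$coexpr)) {
    net <- build_network(nm, cm, params = config$coexpr)
    write_network(net, out("coexpr_edges.tsv"), out("coexpr_modules.tsv"))
    res$network <- net
    manifest$stages$coexpr <- list(
      genes_in = nrow(cm$counts),
      genes_retained = length(net$retained_genes),
      outputs = c("coexpr_edges.tsv", "coexpr_modules.tsv"))
  }

  if (!is.null(config$bulk)) {
    conc <- concordance_r2(pseudobulk(cm), config$bulk)
    utils::write.table(conc$genes, out("concordance_genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      conc[c("r_squared", "n_common_detected", "n_sc_only", "n_bulk_only",
             "pseudo_count", "log_base")],
      out("concordance.json"), auto_unbox = TRUE, digits = NA)
    res$concordance <- conc
    manifest$stages$concordance <- list(
      r_squared = conc$r_squared,
      outputs = c("concordance_genes.tsv", "concordance.json"))
  }

  if (!is.null(config$lag_table)) {
    lr <- relatedness_test(config$lag_table, method = config$lineage_method,
                           censoring = config$censoring)
    jsonlite::write_json(
      lr[c("population_mean_pairwise_diff", "n_eligible", "statistic",
           "p_value", "method", "censoring", "nonindependent_pairs")],
      out("lineage.json"), auto_unbox = TRUE, digits = NA)
    res$lineage <- lr
    manifest$stages$lineage <- list(p_value = lr$p_value,
                                    outputs = "lineage.json")
  }

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}
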
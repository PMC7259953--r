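#' Marker gene panel
#'
#' A panel of marker genes and a raw-transcript threshold used to split a
#' population in two, as done to separate maltose-grown from glucose-grown
#' cells via MAL11/MAL12/MAL31/MAL32/IMA1 (and the glucose-repressed HXK1).
#'
#' @param gene_ids Non-empty character vector of panel genes.
#' @param min_transcripts Minimum summed raw UMI count over the panel to
#'   call a cell positive (default 2, "at least two transcripts").
#' @param positive_label,negative_label Labels for cells above/below the
#'   threshold.
#' @param mode `"sum"` (default): threshold applies to the summed count over
#'   the panel. `"any"`: a cell is positive if any single panel gene reaches
#'   `min_transcripts` on its own.
#' @return An object of class `marker_panel`.
#' @export
marker_panel <- function(gene_ids, min_transcripts = 2,
                         positive_label = "positive",
                         negative_label = "negative",
                         mode = c("sum", "any")) {
  mode <- match.arg(mode)
  gene_ids <- unique(as.character(gene_ids))
  if (length(gene_ids) == 0) stop("panel must contain at least one gene")
  if (min_transcripts < 1) stop("min_transcripts must be >= 1")
  if (identical(positive_label, negative_label))
    stop("labels must be distinct")
  structure(list(gene_ids = gene_ids, min_transcripts = min_transcripts,
                 positive_label = positive_label,
                 negative_label = negative_label, mode = mode),
            class = "marker_panel")
}

#' Classify cells by a marker panel
#'
#' Labels each cell by thresholding its raw panel-gene UMI counts; the rule
#' never looks at normalized values. Panel genes absent from the matrix
#' contribute zero (with a warning); if none are present it is a
#' configuration error.
#'
#' @param cm A [count_matrix()].
#' @param panel A [marker_panel()].
#' @return Named character vector: barcode -> label.
#' @export
classify_by_markers <- function(cm, panel) {
  stopifnot(inherits(cm, "count_matrix"), inherits(panel, "marker_panel"))
  present <- intersect(panel$gene_ids, gene_ids(cm))
  if (length(present) == 0)
    stop("no panel gene present in the count matrix")
  if (length(present) < length(panel$gene_ids))
    warning(sprintf("%d panel gene(s) absent from the matrix",
                    length(panel$gene_ids) - length(present)))
  sub <- cm$counts[present, , drop = FALSE]
  pos <- if (panel$mode == "sum") {
    colSums(sub) >= panel$min_transcripts
  } else {
    apply(sub >= panel$min_transcripts, 2, any)
  }
  stats::setNames(ifelse(pos, panel$positive_label, panel$negative_label),
                  barcodes(cm))
}
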
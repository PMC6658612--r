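#' Whole-brain node table
#'
#' Returns the packaged 294-node parcellation used to build connectomes:
#' a cortical set of 264 nodes plus 30 subcortical additions (amygdala,
#' hippocampus, striatum). The 20 rows flagged `roi = TRUE` are the regions of
#' interest carried into the treatment-response analyses and hold real MNI
#' coordinates; the remaining rows are synthetic placeholder coordinates (the
#' original cortical coordinate set is not redistributable) — downstream code
#' consumes only node identities and counts, never the filler coordinates.
#'
#' @return A data.frame with columns `node_id`, `label`, `x`, `y`, `z`
#'   (MNI mm), `region_class`, `type` (`cortical`/`subcortical`) and `roi`.
#' @export
parcellation_table <- function() {
  path <- system.file("extdata", "nodes294_synthetic.tsv", package = "oxynet")
  tab <- read.delim(path, stringsAsFactors = FALSE)
  tab$roi <- as.logical(tab$roi)
  tab
}

#' Region-of-interest table
#'
#' The 20 nodes of interest used as candidate predictors of treatment
#' response: five insula, five anterior cingulate (ACC), six amygdala and four
#' striatal regions, with their MNI coordinates.
#'
#' @return A data.frame with columns `node_id`, `label`, `x`, `y`, `z`,
#'   `region_class`.
#' @export
roi_table <- function() {
  path <- system.file("extdata", "roi20.tsv", package = "oxynet")
  read.delim(path, stringsAsFactors = FALSE)
}
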
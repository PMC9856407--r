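#' Marker panel
#'
#' An ordered set of marker names with a per-marker scalar positivity
#' threshold on the 0-1 mean-intensity scale, and a flag for the candidate
#' biomarkers (the immunogenic-cell-death / checkpoint-blockade panel: CC3,
#' ICAM-1, CALR, Gal-3, MPO, NRP-1, PD-L1) as opposed to lineage markers.
#'
#' @param markers Character vector of unique marker names.
#' @param thresholds Numeric thresholds in (0, 1), recycled if length 1.
#' @param candidate Logical vector flagging candidate biomarkers, recycled.
#' @return A tibble of class `marker_panel` with columns `marker`,
#'   `threshold`, `candidate`.
#' @export
marker_panel <- function(markers, thresholds = 0.35, candidate = FALSE) {
  if (length(markers) == 0) stopf("marker_panel: need at least one marker")
  if (anyDuplicated(markers)) stopf("marker_panel: marker names must be unique")
  thresholds <- rep_len(thresholds, length(markers))
  candidate <- rep_len(candidate, length(markers))
  if (any(!is.finite(thresholds)) || any(thresholds <= 0) || any(thresholds >= 1))
    stopf("marker_panel: thresholds must lie strictly inside (0, 1)")
  out <- tibble::tibble(marker = as.character(markers),
                        threshold = thresholds,
                        candidate = as.logical(candidate))
  class(out) <- c("marker_panel", class(out))
  out
}

#' Read a marker panel from YAML
#'
#' Expected layout: a `markers` map of `name: {threshold: x, candidate: yes}`
#' entries (threshold/candidate optional, defaulting to 0.35 / false).
#'
#' @param path Path to a YAML file.
#' @return A [marker_panel()].
#' @export
read_marker_panel <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$markers)) stopf("marker panel YAML must have a 'markers' map")
  nm <- names(raw$markers)
  thr <- vapply(raw$markers, function(m) as.numeric(m$threshold %||% 0.35), 0)
  cand <- vapply(raw$markers, function(m) isTRUE(m$candidate), FALSE)
  marker_panel(nm, thr, cand)
}

#' Default marker panel shipped with the package
#'
#' Lineage markers used by the default gating hierarchy plus the seven
#' candidate biomarkers, all gated at an intensity threshold of 0.35.
#'
#' @return A [marker_panel()].
#' @export
default_marker_panel <- function() {
  read_marker_panel(system.file("extdata", "marker_panel.yaml",
                                package = "mimaspat", mustWork = TRUE))
}

candidate_markers <- function(panel) panel$marker[panel$candidate]

panel_threshold <- function(panel, marker) {
  i <- match(marker, panel$marker)
  if (anyNA(i)) stopf("unknown marker(s): %s", paste(marker[is.na(i)], collapse = ", "))
  panel$threshold[i]
}
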
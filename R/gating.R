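#' Read and validate a hierarchical gating tree
#'
#' A gating tree is a binary hierarchy of marker-positivity tests. Each
#' internal node is a list with `marker`, `positive` and `negative` children;
#' each leaf is a list with `cell_type`. Validation checks that every
#' referenced marker exists in the panel, that no root-to-leaf path tests the
#' same marker twice, and that every leaf carries a cell type.
#'
#' @param path Path to a YAML gating-tree file.
#' @param panel A [marker_panel()] the tree's markers must belong to.
#' @return The tree as a nested list of class `gating_tree`.
#' @export
read_gating_tree <- function(path, panel = default_marker_panel()) {
  tree <- yaml::read_yaml(path)
  as_gating_tree(tree, panel)
}

#' @rdname read_gating_tree
#' @param tree A nested list in the gating-tree layout.
#' @export
as_gating_tree <- function(tree, panel = default_marker_panel()) {
  check_gating_node(tree, panel, seen = character())
  structure(tree, class = "gating_tree")
}

check_gating_node <- function(node, panel, seen) {
  if (!is.null(node$cell_type)) {
    if (!nzchar(node$cell_type)) stopf("gating tree: empty cell_type at a leaf")
    return(invisible(NULL))
  }
  if (is.null(node$marker))
    stopf("gating tree: node without 'marker' or 'cell_type'")
  if (!node$marker %in% panel$marker)
    stopf("gating tree references unknown marker '%s'", node$marker)
  if (node$marker %in% seen)
    stopf("gating tree tests marker '%s' twice on one path", node$marker)
  if (is.null(node$positive) || is.null(node$negative))
    stopf("gating tree: node '%s' must have positive and negative children",
          node$marker)
  check_gating_node(node$positive, panel, c(seen, node$marker))
  check_gating_node(node$negative, panel, c(seen, node$marker))
  invisible(NULL)
}

#' Default gating tree shipped with the package
#' @param panel A [marker_panel()].
#' @return A `gating_tree`.
#' @export
default_gating_tree <- function(panel = default_marker_panel()) {
  read_gating_tree(system.file("extdata", "gating_tree.yaml",
                               package = "mimaspat", mustWork = TRUE), panel)
}

#' Cell types named at the leaves of a gating tree
#' @param tree A `gating_tree`.
#' @param drop_unclassified Omit the fallback type. Default TRUE.
#' @return Character vector of cell-type names in leaf order.
#' @export
gating_tree_types <- function(tree, drop_unclassified = TRUE) {
  leaves <- function(node) {
    if (!is.null(node$cell_type)) return(node$cell_type)
    c(leaves(node$positive), leaves(node$negative))
  }
  out <- unique(leaves(tree))
  if (drop_unclassified) out <- setdiff(out, "unclassified")
  out
}

#' Compute per-marker positivity flags
#'
#' A cell is positive for a marker iff its mean intensity strictly exceeds
#' the panel threshold (intensity equal to the threshold is negative).
#'
#' @param cells Cell table with one intensity column per panel marker.
#' @param panel A [marker_panel()].
#' @return `cells` with one logical `<marker>_pos` column appended (or
#'   replaced) per marker.
#' @export
compute_positivity <- function(cells, panel = default_marker_panel()) {
  miss <- setdiff(panel$marker, names(cells))
  if (length(miss))
    stopf("cell table lacks intensity column(s): %s", paste(miss, collapse = ", "))
  for (i in seq_len(nrow(panel))) {
    m <- panel$marker[i]
    cells[[flag_col(m)]] <- cells[[m]] > panel$threshold[i]
  }
  cells
}

#' Classify cells into standard cell types by hierarchical gating
#'
#' Deterministic descent of the gating tree on positivity flags; the tree's
#' gate order resolves every assignment (no probabilistic tie-breaking) and
#' cells reaching an `unclassified` leaf keep that label.
#'
#' @param cells Cell table carrying `<marker>_pos` flag columns (see
#'   [compute_positivity()]).
#' @param tree A `gating_tree`.
#' @param panel A [marker_panel()] used to validate the tree's markers.
#' @return `cells` with a `cell_type` character column.
#' @export
classify <- function(cells, tree = default_gating_tree(panel),
                     panel = default_marker_panel()) {
  tree <- as_gating_tree(unclass(tree), panel)
  used <- tree_markers(tree)
  miss <- setdiff(flag_col(used), names(cells))
  if (length(miss))
    stopf("cell table lacks flag column(s): %s (run compute_positivity first)",
          paste(miss, collapse = ", "))
  out <- rep_len("unclassified", nrow(cells))
  descend <- function(node, idx) {
    if (!length(idx)) return(invisible(NULL))
    if (!is.null(node$cell_type)) {
      out[idx] <<- node$cell_type
      return(invisible(NULL))
    }
    f <- cells[[flag_col(node$marker)]][idx]
    descend(node$positive, idx[f])
    descend(node$negative, idx[!f])
  }
  descend(tree, seq_len(nrow(cells)))
  cells$cell_type <- out
  cells
}

tree_markers <- function(node) {
  if (!is.null(node$cell_type)) return(character())
  unique(c(node$marker, tree_markers(node$positive), tree_markers(node$negative)))
}

#' Enumerate candidate-marker x cell-type combinations
#'
#' The Cartesian product of the panel's candidate biomarkers and the standard
#' cell types; each row is one (marker, cell type) query for the zonal rate
#' and enrichment analysis.
#'
#' @param panel A [marker_panel()].
#' @param cell_types Character vector of standard cell types; defaults to the
#'   default gating tree's leaf types.
#' @return Tibble with columns `marker`, `cell_type`.
#' @export
enumerate_combinations <- function(panel = default_marker_panel(),
                                   cell_types = gating_tree_types(default_gating_tree(panel))) {
  cand <- candidate_markers(panel)
  if (!length(cand) || !length(cell_types))
    stopf("need at least one candidate marker and one cell type")
  tibble::tibble(marker = rep(cand, times = length(cell_types)),
                 cell_type = rep(cell_types, each = length(cand)))
}
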
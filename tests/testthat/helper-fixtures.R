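# Shared fixtures: default config objects, a cached gated default scene per
# seed (several files need one), and small constructors for custom scenarios.

panel_default <- default_marker_panel()
tree_default <- default_gating_tree(panel_default)
scenario_default <- default_scenario()
geom_default <- device_geometry()
zones_default <- zone_config()

# generate + gate + zone the default scenario once per seed and cache
.scene_cache <- new.env(parent = emptyenv())
gated_scene <- function(seed = 1) {
  key <- paste0("s", seed)
  if (is.null(.scene_cache[[key]])) {
    scene <- generate_scene(scenario_default, seed = seed)
    cells <- assign_zones(classify(compute_positivity(scene$cells, panel_default),
                                   tree_default, panel_default))
    .scene_cache[[key]] <- list(scene = scene, cells = cells)
  }
  .scene_cache[[key]]
}

# single-type scenario with configurable marker rates (no signature markers)
single_type_scenario <- function(rate = 0, density = 2000) {
  comp <- lapply(setNames(nm = c(zones_default$names, "control")),
                 function(z) c(only_type = 1))
  rates <- list(only_type = lapply(setNames(nm = panel_default$marker),
                                   function(m) rate))
  scenario_config(comp, list(positive_params = c(12, 4),
                             negative_params = c(1.5, 20),
                             signatures = list(),
                             marker_rates = rates),
                  density_per_mm2 = density, seed = 1)
}

# canonical form of a partition label vector (first-appearance relabeling)
canon_partition <- function(v) match(v, unique(v))

# independent connected-components oracle on the strict epsilon graph
igraph_components <- function(x, y, eps) {
  D <- as.matrix(stats::dist(cbind(x, y)))
  A <- D < eps
  diag(A) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  unname(igraph::components(g)$membership)
}

# flag table row helper for classification examples
flag_row <- function(...) {
  pos <- c(...)
  row <- as.list(setNames(rep(FALSE, nrow(panel_default)),
                          flag_col(panel_default$marker)))
  for (m in pos) row[[flag_col(m)]] <- TRUE
  tibble::as_tibble(row)
}

flag_col <- function(marker) paste0(marker, "_pos")
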
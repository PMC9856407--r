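test_that("components below the minimum size dissolve to non-clustering", {
  set.seed(1)
  pts <- tibble::tibble(x_um = runif(9, 0, 30), y_um = runif(9, 0, 30))
  res <- cluster_hotspots(pts, d_max = 50, min_cells = 10)
  expect_identical(nrow(res$summary), 0L)
  expect_true(all(res$cells$cluster_id == 0L))
})

test_that("chain merging links collinear points into one cluster", {
  chain <- tibble::tibble(x_um = seq(0, by = 40, length.out = 10), y_um = 0)
  res <- cluster_hotspots(chain, d_max = 50, min_cells = 10)
  expect_identical(nrow(res$summary), 1L)
  expect_identical(res$summary$n_cells, 10L)
  expect_true(all(res$cells$cluster_id == res$cells$cluster_id[1]))
})

test_that("pairs at exactly d_max do not link (strict inequality)", {
  pts <- tibble::tibble(x_um = c(0, 50), y_um = c(0, 0))
  res <- cluster_hotspots(pts, d_max = 50, min_cells = 2)
  expect_identical(res$cells$component_id[1] == res$cells$component_id[2], FALSE)
  res2 <- cluster_hotspots(pts, d_max = 50.0001, min_cells = 2)
  expect_identical(res2$cells$component_id[1], res2$cells$component_id[2])
})

test_that("partition equals the brute-force epsilon-graph oracle", {
  set.seed(99)
  for (k in 1:30) {
    n <- sample(20:500, 1)
    x <- runif(n, 0, 1000); y <- runif(n, 0, 1000)
    eps <- sample(c(30, 50, 75), 1)
    res <- cluster_hotspots(tibble::tibble(x_um = x, y_um = y),
                            d_max = eps, min_cells = 2)
    ref <- igraph_components(x, y, eps)
    expect_identical(canon_partition(res$cells$component_id),
                     canon_partition(ref))
  }
})

test_that("empty and degenerate inputs are handled", {
  empty <- cluster_hotspots(tibble::tibble(x_um = numeric(), y_um = numeric()))
  expect_identical(nrow(empty$cells), 0L)
  expect_identical(nrow(empty$summary), 0L)
  expect_error(cluster_hotspots(tibble::tibble(x_um = c(0, NA), y_um = 0)),
               "non-finite")
  expect_error(cluster_hotspots(tibble::tibble(x_um = 1, y_um = 1), d_max = 0),
               "d_max")
  expect_error(cluster_hotspots(tibble::tibble(x_um = 1, y_um = 1), min_cells = 1),
               "min_cells")
})

test_that("membership at smaller d_max refines membership at larger d_max", {
  set.seed(5)
  pts <- tibble::tibble(x_um = runif(400, 0, 800), y_um = runif(400, 0, 800))
  small <- cluster_hotspots(pts, 30, 10)$cells$component_id
  large <- cluster_hotspots(pts, 75, 10)$cells$component_id
  for (comp in unique(small))
    expect_identical(length(unique(large[small == comp])), 1L)
})

test_that("raising min_cells never creates a new cluster", {
  set.seed(6)
  pts <- tibble::tibble(x_um = runif(300, 0, 600), y_um = runif(300, 0, 600))
  lo <- cluster_hotspots(pts, 50, 5)
  hi <- cluster_hotspots(pts, 50, 15)
  # every cluster surviving at min 15 is exactly one of the min-5 clusters
  comp_sets_lo <- split(seq_len(300), lo$cells$cluster_id)
  comp_sets_hi <- split(seq_len(300), hi$cells$cluster_id)
  comp_sets_lo[["0"]] <- NULL; comp_sets_hi[["0"]] <- NULL
  key <- function(s) paste(sort(s), collapse = ",")
  expect_true(all(vapply(comp_sets_hi, key, "") %in%
                    vapply(comp_sets_lo, key, "")))
  expect_lte(length(comp_sets_hi), length(comp_sets_lo))
})

test_that("the partition is invariant to permutation, translation and rotation", {
  set.seed(7)
  pts <- tibble::tibble(x_um = runif(250, 0, 500), y_um = runif(250, 0, 500))
  base <- cluster_hotspots(pts, 50, 8)
  perm <- sample(250)
  shuffled <- cluster_hotspots(pts[perm, ], 50, 8)
  expect_identical(canon_partition(shuffled$cells$component_id),
                   canon_partition(base$cells$component_id[perm]))
  # randomized ids differ from the partition itself: same sets either way
  sets <- function(res) {
    s <- split(res$cells$cell_ref, res$cells$cluster_id)
    s[["0"]] <- NULL
    unname(sort(vapply(s, function(v) paste(sort(v), collapse = ","), "")))
  }
  base$cells$cell_ref <- seq_len(250)
  shuffled$cells$cell_ref <- perm
  expect_identical(sets(base), sets(shuffled))
  th <- 0.7
  rot <- tibble::tibble(
    x_um = 100 + cos(th) * pts$x_um - sin(th) * pts$y_um,
    y_um = -50 + sin(th) * pts$x_um + cos(th) * pts$y_um)
  rotated <- cluster_hotspots(rot, 50, 8)
  expect_identical(canon_partition(rotated$cells$component_id),
                   canon_partition(base$cells$component_id))
})

test_that("multi-scale clustering nests and reports fragmentation", {
  set.seed(8)
  pts <- tibble::tibble(x_um = runif(500, 0, 900), y_um = runif(500, 0, 900))
  ms <- multiscale_cluster(pts, c(30, 50, 75), 10)
  small <- ms$results[["30"]]$cells
  largest <- ms$results[["75"]]$cells
  for (cl in setdiff(unique(small$cluster_id), 0L))
    expect_identical(length(unique(largest$component_id[small$cluster_id == cl])), 1L)
  expect_identical(ms$summary$d_max, c(30, 50, 75))
  expect_identical(ms$summary$fragmentation[3], 0L)  # largest scale never splits itself
  # empty input gives empty results at every scale
  ms0 <- multiscale_cluster(tibble::tibble(x_um = numeric(), y_um = numeric()))
  expect_identical(ms0$summary$n_clusters, c(0L, 0L, 0L))
  expect_error(multiscale_cluster(pts, c(50, 50)), "increasing")
})

test_that("cluster counts do not grow with the link distance on the default scene", {
  cells <- gated_scene(1)$cells
  n1 <- cells[cells$cell_type == "n1_neutrophil", ]
  ms <- multiscale_cluster(n1, c(30, 50, 75), 10)
  expect_gte(ms$summary$n_clusters[1], ms$summary$n_clusters[3])
})

test_that("neutrophil hotspots are treatment-specific; uniform populations are not", {
  cells <- gated_scene(1)$cells
  n1 <- cells[cells$cell_type == "n1_neutrophil", ]
  spec <- cluster_specificity(cluster_hotspots(n1, 50, 10))
  expect_true(spec$treatment_specific)
  expect_gte(sum(spec$zone_counts[c("proximal", "border")]), 1)
  expect_identical(unname(spec$zone_counts["remote"]), 0L)
  # a spatially uniform population (endothelium) clusters everywhere
  for (s in 1:5) {
    endo <- gated_scene(s)$cells
    endo <- endo[endo$cell_type == "endothelial_cell", ]
    u <- cluster_specificity(cluster_hotspots(endo, 50, 10))
    expect_false(u$treatment_specific)
  }
  # no clusters -> all zone counts zero
  sparse <- cells[cells$cell_type == "n1_neutrophil" & cells$zone == "remote", ]
  z <- cluster_specificity(cluster_hotspots(sparse, 50, 10))
  expect_true(all(z$zone_counts == 0L))
  expect_false(z$treatment_specific)
})
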
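test_that("zone assignment follows radial distance within the band", {
  cells <- tibble::tibble(
    cell_id = 1:6,
    x_um = c(0, 0, 0, 0, 500, 0),
    y_um = c(0, 1500, 250, 500, 500, -50))
  z <- assign_zones(cells, geom_default, zones_default)
  expect_identical(z$zone,
                   c("immediate", "remote", "proximal", "border", "other", "other"))
})

test_that("zone assignment matches a naive per-cell loop and partitions the band", {
  set.seed(21)
  cells <- tibble::tibble(x_um = runif(500, -800, 800),
                          y_um = runif(500, -200, 2400))
  z <- assign_zones(cells, geom_default, zones_default)$zone
  b <- zones_default$boundaries
  ref <- character(500)
  for (i in 1:500) {
    x <- cells$x_um[i]; y <- cells$y_um[i]
    d <- sqrt(x^2 + y^2)
    ref[i] <- if (y < 0 || abs(x) > 400 || d > max(b)) "other"
    else if (d < b[2]) "immediate" else if (d < b[3]) "proximal"
    else if (d < b[4]) "border" else if (d < b[5]) "distal" else "remote"
  }
  expect_identical(z, ref)
  expect_identical(length(z), 500L)
})

test_that("ROIs land inside their zone and membership matches brute force", {
  rois <- suppressWarnings(sample_rois("proximal", 5, seed = 4))
  expect_identical(nrow(rois), 5L)
  r <- sqrt(rois$center_x^2 + rois$center_y^2)
  expect_true(all(r - rois$diameter / 2 >= 100))
  expect_true(all(r + rois$diameter / 2 <= 400))
  expect_true(all(abs(rois$center_x) + rois$diameter / 2 <= 400))
  cells <- gated_scene(1)$cells
  for (i in 1:5) {
    roi <- rois[i, ]
    manual <- sqrt((cells$x_um - roi$center_x)^2 +
                     (cells$y_um - roi$center_y)^2) <= roi$diameter / 2
    expect_identical(cells_in_roi(cells, roi), manual)
  }
  # non-overlap holds when the zone has room (remote zone is spacious)
  far <- sample_rois("remote", 6, seed = 4)
  d2 <- as.matrix(dist(cbind(far$center_x, far$center_y)))
  mind <- outer(far$diameter / 2, far$diameter / 2, "+")
  expect_true(all(d2[upper.tri(d2)] > mind[upper.tri(mind)]))
})

test_that("ROIs in the default scenario average 200-500 cells", {
  cells <- gated_scene(1)$cells
  rois <- suppressWarnings(sample_rois("proximal", 6, seed = 8))
  counts <- vapply(seq_len(nrow(rois)),
                   function(i) sum(cells_in_roi(cells, rois[i, ])), 0)
  expect_gte(mean(counts), 200)
  expect_lte(mean(counts), 500)
})

test_that("a zone too small for the requested ROI diameter errors", {
  thin <- zone_config(c("a", "b"), c(0, 50, 2000))
  expect_error(sample_rois("a", 3, diameter_range = c(110, 220), zones = thin),
               "too small")
})

test_that("combination rates equal an independent loop and handle empty groups", {
  set.seed(33)
  n <- 400
  cells <- tibble::tibble(
    cell_id = 1:n, x_um = 0, y_um = 0,
    cell_type = sample(c("a", "b", "c"), n, TRUE),
    zone = sample(c("z1", "z2"), n, TRUE),
    M1_pos = runif(n) < 0.3, M2_pos = runif(n) < 0.05)
  combos <- tibble::tibble(marker = c("M1", "M2", NA, "M1"),
                           cell_type = c("a", "b", "c", NA))
  rt <- combination_rates(cells, combos, by = "zone")
  for (k in seq_len(nrow(rt))) {
    cnt <- 0; tot <- 0
    for (i in seq_len(n)) {
      if (cells$zone[i] != rt$zone[k]) next
      tot <- tot + 1
      ok <- TRUE
      if (!is.na(rt$cell_type[k]) && cells$cell_type[i] != rt$cell_type[k]) ok <- FALSE
      if (!is.na(rt$marker[k]) && !cells[[paste0(rt$marker[k], "_pos")]][i]) ok <- FALSE
      if (ok) cnt <- cnt + 1
    }
    expect_equal(rt$n_pos[k], cnt)
    expect_equal(rt$rate[k], cnt / tot)
  }
  # group with no matching cells -> rate 0
  no <- combination_rates(cells[cells$zone == "z1", ],
                          tibble::tibble(marker = "M1", cell_type = "missing"),
                          by = "zone")
  expect_identical(no$rate, 0)
  # type-conditional denominator
  tc <- combination_rates(cells, tibble::tibble(marker = "M1", cell_type = "a"),
                          by = "zone", denominator = "type")
  z1a <- cells$zone == "z1" & cells$cell_type == "a"
  expect_equal(tc$rate[tc$zone == "z1"], sum(cells$M1_pos & z1a) / sum(z1a))
})

test_that("border-zone CSCs recover the planted calreticulin fraction", {
  cells <- gated_scene(1)$cells
  rt <- combination_rates(cells,
                          tibble::tibble(marker = "CALR", cell_type = "cancer_stem_cell"),
                          by = "zone", denominator = "type")
  row <- rt[rt$zone == "border", ]
  se <- sqrt(0.42 * 0.58 / row$n_type)
  expect_lt(abs(row$rate - 0.42), 3 * se)
})

test_that("paired enrichment test matches its closed form and boundary rules", {
  # mean-zero differences with positive variance: t = 0, one-tailed p = 0.5
  a <- c(0.11, 0.09, 0.12, 0.08)
  b <- c(0.10, 0.10, 0.10, 0.10)
  r <- enrichment_test(a, b)
  expect_equal(r$t, 0)
  expect_equal(r$p, 0.5)
  # textbook paired t on differences [0.1, 0.12, 0.09, 0.11, 0.1]
  d <- c(0.1, 0.12, 0.09, 0.11, 0.1)
  ctrl <- c(0.02, 0.05, 0.04, 0.01, 0.03)
  r2 <- enrichment_test(ctrl + d, ctrl)
  t_ref <- mean(d) / (sd(d) / sqrt(5))
  p_ref <- stats::pt(t_ref, df = 4, lower.tail = FALSE)
  expect_equal(r2$t, t_ref)
  expect_equal(r2$df, 4)
  expect_equal(r2$p, p_ref)
  # zero-variance differences: warning and p = 1
  expect_warning(rz <- enrichment_test(c(.1, .1, .1), c(.05, .05, .05)),
                 "zero-variance")
  expect_equal(rz$p, 1)
  # fewer than 2 pairs is undefined
  expect_error(enrichment_test(0.1, 0.05), "fewer than 2")
  expect_error(enrichment_test(c(.1, .2), c(.1, .2, .3)), "equal numbers")
  # one-tailed p <= two-tailed p when the difference is in the tested direction
  r_one <- enrichment_test(ctrl + d, ctrl, tails = "one")
  r_two <- enrichment_test(ctrl + d, ctrl, tails = "two")
  expect_lte(r_one$p, r_two$p)
})

test_that("the reporting filter keeps strictly-above-threshold combinations", {
  rt <- tibble::tibble(zone = "z", marker = "M", cell_type = c("a", "b", "c"),
                       n_group = 1000L, n_type = c(9L, 10L, 11L),
                       n_pos = c(9L, 10L, 11L), rate = c(0.009, 0.01, 0.011))
  kept <- filter_reportable(rt)
  expect_identical(kept$cell_type, "c")
  # brute-force filter agreement on random rates
  set.seed(2)
  rnd <- tibble::tibble(rate = runif(200, 0, 0.03))
  expect_identical(nrow(filter_reportable(rnd)), sum(rnd$rate > 0.01))
})

test_that("zonal rates order as planted: neutrophils proximal, CSC border, PD-L1 remote", {
  combos <- tibble::tibble(marker = c(NA, NA, "PDL1"),
                           cell_type = c("n1_neutrophil", "cancer_stem_cell", NA))
  agg <- NULL
  for (s in 1:3) {
    rt <- combination_rates(gated_scene(s)$cells, combos, by = "zone")
    rt <- rt[order(rt$zone, rt$marker, rt$cell_type, na.last = TRUE), ]
    agg <- if (is.null(agg)) rt else {
      stopifnot(identical(agg$zone, rt$zone))
      agg$rate <- agg$rate + rt$rate; agg
    }
  }
  get <- function(ct, m, z) agg$rate[
    (is.na(m) & is.na(agg$marker) | !is.na(agg$marker) & agg$marker %in% m) &
    (is.na(ct) & is.na(agg$cell_type) | !is.na(agg$cell_type) & agg$cell_type %in% ct) &
    agg$zone == z]
  expect_gt(get("n1_neutrophil", NA, "proximal"), get("n1_neutrophil", NA, "remote"))
  csc <- vapply(zones_default$names, function(z) get("cancer_stem_cell", NA, z), 0)
  expect_identical(names(which.max(csc)), "border")
  pdl1 <- vapply(zones_default$names, function(z) get(NA, "PDL1", z), 0)
  expect_identical(names(which.max(pdl1)), "remote")
})

test_that("the fold-ratio of CSCs to ICAM-1+ DCs recovers the planted 13.2", {
  n_csc <- n_icam_dc <- n_border <- 0
  for (s in 1:20) {
    cells <- gated_scene(s)$cells
    b <- cells$zone == "border"
    n_border <- n_border + sum(b)
    n_csc <- n_csc + sum(b & cells$cell_type == "cancer_stem_cell")
    n_icam_dc <- n_icam_dc + sum(b & cells$cell_type == "dendritic_cell" &
                                   cells$ICAM1_pos)
  }
  expect_gte(n_border, 2000)
  expect_lt(abs(n_csc / n_icam_dc - 13.2) / 13.2, 0.10)
})
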
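#' Assign drug-source-relative zones to cells
#'
#' Each cell's Euclidean distance from the drug source is mapped to the zone
#' whose radial interval contains it, restricted to the assay band (the
#' rectangle ahead of the source along the release direction). Cells behind
#' the source, beyond the band half-width, or past the outermost boundary are
#' labeled `"other"`.
#'
#' @param cells Cell table with `x_um`, `y_um` columns.
#' @param geometry A [device_geometry()].
#' @param zones A [zone_config()].
#' @param metric `"radial"` (Euclidean distance from the source; default) or
#'   `"axial"` (distance along the release direction only).
#' @return `cells` with a `zone` character column.
#' @export
assign_zones <- function(cells, geometry = device_geometry(),
                         zones = zone_config(), metric = c("radial", "axial")) {
  metric <- match.arg(metric)
  if (any(!is.finite(cells$x_um)) || any(!is.finite(cells$y_um)))
    stopf("non-finite cell coordinates")
  bc <- band_coords(cells$x_um, cells$y_um, geometry)
  d <- if (metric == "radial") sqrt(bc$axial^2 + bc$cross^2) else bc$axial
  idx <- findInterval(d, zones$boundaries, rightmost.closed = TRUE)
  lab <- rep_len("other", nrow(cells))
  in_band <- bc$axial >= 0 & abs(bc$cross) <= geometry$assay_band_halfwidth &
    idx >= 1 & idx <= length(zones$names)
  lab[in_band] <- zones$names[idx[in_band]]
  cells$zone <- lab
  cells
}

#' Sample circular regions of interest within a zone
#'
#' ROI centers are uniform over the subset of the zone that keeps the whole
#' circle inside the zone (radially and within the band); diameters are
#' uniform over `diameter_range`, capped at the zone's radial width so a
#' valid circle exists. The `"control"` zone draws from the matched control
#' region's rectangle instead.
#'
#' @param zone Zone name (one of the `zones` names, or `"control"`).
#' @param n_rois Number of ROIs.
#' @param diameter_range Length-2 numeric, ROI diameter bounds in um.
#'   Default c(110, 220).
#' @param seed Integer RNG seed.
#' @param geometry A [device_geometry()].
#' @param zones A [zone_config()].
#' @param no_overlap Keep ROIs pairwise disjoint so replicate rates are
#'   independent (required for a calibrated paired test). When a zone is too
#'   crowded to place another disjoint circle within `max_attempts`, the last
#'   candidate is kept with a warning. Default TRUE.
#' @param max_attempts Placement attempts per ROI. Default 200.
#' @return Tibble of class `roi_set`: `roi_id`, `zone`, `center_x`,
#'   `center_y`, `diameter`.
#' @export
sample_rois <- function(zone, n_rois = 6, diameter_range = c(110, 220),
                        seed = 1, geometry = device_geometry(),
                        zones = zone_config(), no_overlap = TRUE,
                        max_attempts = 200) {
  stopifnot(length(diameter_range) == 2, diameter_range[1] <= diameter_range[2])
  hw <- geometry$assay_band_halfwidth
  is_control <- zone == "control"
  if (is_control) {
    box <- control_region_box(geometry, zones)
    dmax <- min(diameter_range[2],
                diff(box$cross_range) - 1e-6, diff(box$axial_range) - 1e-6)
    if (dmax < diameter_range[1])
      stopf("control region too small for ROI diameter >= %g", diameter_range[1])
  } else {
    zi <- match(zone, zones$names)
    if (is.na(zi)) stopf("unknown zone '%s'", zone)
    lo <- zones$boundaries[zi]; hi <- zones$boundaries[zi + 1]
    # cap the diameter so the circle fits radially and inside the band
    dmax <- min(diameter_range[2], (hi - lo) - 1e-6, 2 * hw - 1e-6)
    if (dmax < diameter_range[1])
      stopf("zone '%s' too small for ROI diameter >= %g", zone, diameter_range[1])
  }
  with_seed(seed, {
    diam <- numeric(n_rois)
    cx <- numeric(n_rois); cy <- numeric(n_rois)  # band coords: cross, axial
    crowded <- FALSE
    for (i in seq_len(n_rois)) {
      placed <- FALSE
      d <- runif(1, diameter_range[1], dmax)   # diameter fixed per ROI
      rad <- d / 2
      for (att in seq_len(max_attempts)) {
        if (is_control) {
          cross <- runif(1, box$cross_range[1] + rad, box$cross_range[2] - rad)
          axial <- runif(1, box$axial_range[1] + rad, box$axial_range[2] - rad)
        } else {
          repeat {
            r <- sqrt(runif(1, (lo + rad)^2, (hi - rad)^2))
            th <- runif(1, -pi / 2, pi / 2)  # angle from the release axis
            cross <- r * sin(th); axial <- r * cos(th)
            if (abs(cross) <= hw - rad && axial >= rad) break
          }
        }
        diam[i] <- d; cx[i] <- cross; cy[i] <- axial
        if (!no_overlap || i == 1L) { placed <- TRUE; break }
        sep2 <- (cx[seq_len(i - 1)] - cross)^2 + (cy[seq_len(i - 1)] - axial)^2
        if (all(sep2 > ((diam[seq_len(i - 1)] + d) / 2)^2)) { placed <- TRUE; break }
      }
      if (!placed) crowded <- TRUE
    }
    if (crowded)
      warning(sprintf("zone '%s': could not place %d non-overlapping ROIs; some overlap",
                      zone, n_rois))
    w <- band_to_world(cy, cx, geometry)
    out <- tibble::tibble(roi_id = seq_len(n_rois), zone = zone,
                          center_x = w$x, center_y = w$y, diameter = diam)
    class(out) <- c("roi_set", class(out))
    out
  })
}

#' Cells inside one ROI
#' @param cells Cell table with `x_um`, `y_um`.
#' @param roi One row of an `roi_set`.
#' @return Logical vector: cell center within the ROI radius (inclusive).
#' @export
cells_in_roi <- function(cells, roi) {
  (cells$x_um - roi$center_x)^2 + (cells$y_um - roi$center_y)^2 <= (roi$diameter / 2)^2
}

#' Positivity rates of marker x cell-type combinations per group
#'
#' For each combination and each group (zone by default), the rate is the
#' number of cells of the type positive for the marker over the total cell
#' count of the group (`denominator = "all"`), or over the count of cells of
#' that type (`denominator = "type"`, e.g. "fraction of CSCs that are
#' CALR-high"). A combination row with `marker = NA` counts the type alone;
#' `cell_type = NA` counts the marker alone.
#'
#' @param cells Cell table with flags, `cell_type`, and the grouping column.
#' @param combos Tibble with `marker`, `cell_type` columns (see
#'   [enumerate_combinations()]).
#' @param by Name of the grouping column. Default `"zone"`.
#' @param denominator `"all"` or `"type"`.
#' @return Tibble: group column, `marker`, `cell_type`, `n_group`, `n_type`,
#'   `n_pos`, `rate`.
#' @export
combination_rates <- function(cells, combos, by = "zone",
                              denominator = c("all", "type")) {
  denominator <- match.arg(denominator)
  if (!by %in% names(cells)) stopf("cells have no '%s' column", by)
  groups <- unique(cells[[by]])
  res <- vector("list", length(groups) * nrow(combos))
  k <- 0L
  for (g in groups) {
    gi <- cells[[by]] == g
    n_group <- sum(gi)
    for (j in seq_len(nrow(combos))) {
      m <- combos$marker[j]; ct <- combos$cell_type[j]
      sel <- gi
      if (!is.na(ct)) sel <- sel & cells$cell_type == ct
      n_type <- sum(sel)
      if (!is.na(m)) sel <- sel & cells[[flag_col(m)]]
      n_pos <- sum(sel)
      denom <- if (denominator == "type" && !is.na(ct)) n_type else n_group
      k <- k + 1L
      res[[k]] <- data.frame(group = g, marker = m, cell_type = ct,
                             n_group = n_group, n_type = n_type, n_pos = n_pos,
                             rate = if (denom > 0) n_pos / denom else 0,
                             stringsAsFactors = FALSE)
    }
  }
  out <- tibble::as_tibble(do.call(rbind, res[seq_len(k)]))
  names(out)[1] <- by
  out
}

#' Per-ROI rates of marker x cell-type combinations
#'
#' @param cells Cell table with flags and `cell_type`.
#' @param rois An `roi_set` from [sample_rois()].
#' @inheritParams combination_rates
#' @return Tibble: `roi_id`, `zone`, `marker`, `cell_type`, `n_group`,
#'   `n_type`, `n_pos`, `rate`.
#' @export
roi_rates <- function(cells, rois, combos, denominator = c("all", "type")) {
  denominator <- match.arg(denominator)
  out <- lapply(seq_len(nrow(rois)), function(i) {
    roi <- rois[i, ]
    sub <- cells[cells_in_roi(cells, roi), , drop = FALSE]
    sub$.roi <- "x"
    r <- combination_rates(sub, combos, by = ".roi", denominator = denominator)
    r$.roi <- NULL
    cbind(data.frame(roi_id = roi$roi_id, zone = roi$zone), r)
  })
  tibble::as_tibble(do.call(rbind, out))
}

#' Paired enrichment test of assay vs control ROI rates
#'
#' Paired t statistic on per-ROI rate differences (assay minus control,
#' paired by sampling order), one-tailed for enrichment (assay > control) by
#' default; two-tailed available for whole-assay comparisons. Zero-variance
#' differences yield p = 1 (no evidence) with a warning.
#'
#' @param assay_rates,control_rates Equal-length numeric vectors of per-ROI
#'   rates, paired by position; at least 2 pairs.
#' @param tails `"one"` (assay > control) or `"two"`.
#' @return List with `t`, `df`, `p`, `mean_diff`.
#' @export
enrichment_test <- function(assay_rates, control_rates, tails = c("one", "two")) {
  tails <- match.arg(tails)
  if (length(assay_rates) != length(control_rates))
    stopf("assay and control must have equal numbers of paired ROIs")
  if (length(assay_rates) < 2)
    stopf("paired t-test undefined with fewer than 2 ROI pairs")
  d <- assay_rates - control_rates
  if (sd(d) == 0) {
    warning("zero-variance rate differences; reporting p = 1 (no evidence)")
    return(list(t = NA_real_, df = length(d) - 1L, p = 1, mean_diff = mean(d)))
  }
  alt <- if (tails == "one") "greater" else "two.sided"
  ht <- stats::t.test(assay_rates, control_rates, paired = TRUE, alternative = alt)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value), mean_diff = mean(d))
}

#' Keep combinations above the clinical reporting threshold
#'
#' Drops combinations whose rate does not strictly exceed the threshold
#' (default 1%, the conventional cutoff for reporting a phenotype).
#'
#' @param rates A rate table from [combination_rates()].
#' @param threshold Reporting threshold on the rate. Default 0.01.
#' @return The filtered rate table.
#' @export
filter_reportable <- function(rates, threshold = 0.01) {
  rates[rates$rate > threshold, , drop = FALSE]
}

#' Type-I-error calibration of the paired enrichment test
#'
#' Simulates null datasets in which the assay band and the control region
#' share the control (background) composition, runs the full
#' generate - gate - classify - ROI - paired one-tailed t path on the rate of
#' non-proliferating tumor cells, and reports the rejection rate at `alpha`.
#' Simulations use a reduced field (one wide 100-600 um sampling zone,
#' outermost boundary 800 um, density 4000 cells/mm2) so non-overlapping ROIs
#' place easily and a large replicate count stays fast.
#'
#' @param n_sims Number of simulated datasets.
#' @param seed Base RNG seed; simulation i uses `seed + i`.
#' @param alpha Nominal level. Default 0.05.
#' @param n_rois ROI pairs per simulation. Default 5.
#' @return List with `rejection_rate`, `p_values`, `n_sims`.
#' @export
simulate_null_type1 <- function(n_sims = 1000, seed = 1, alpha = 0.05, n_rois = 5) {
  base <- default_scenario()
  null_comp <- lapply(setNames(nm = names(base$zone_composition)),
                      function(z) base$zone_composition$control)
  null_sc <- scenario_config(null_comp, base$expression,
                             density_per_mm2 = 4000, seed = seed)
  geom <- device_geometry(assay_band_halfwidth = 400)
  zns <- zone_config(names = c("immediate", "proximal", "border"),
                     boundaries = c(0, 100, 600, 800))
  panel <- default_marker_panel()
  tree <- default_gating_tree(panel)
  combo <- tibble::tibble(marker = NA_character_, cell_type = "nonproliferating_tumor")
  pvals <- vapply(seq_len(n_sims), function(i) {
    s <- seed + i
    scene <- generate_scene(null_sc, geom, zns, panel, seed = s)
    ctrl <- generate_control_region(null_sc, geom, zns, panel, seed = s + 500000L)
    ac <- classify(compute_positivity(scene$cells, panel), tree, panel)
    cc <- classify(compute_positivity(ctrl$cells, panel), tree, panel)
    a_roi <- sample_rois("proximal", n_rois, seed = s + 1000000L,
                         geometry = geom, zones = zns)
    c_roi <- sample_rois("control", n_rois, seed = s + 1500000L,
                         geometry = geom, zones = zns)
    a <- roi_rates(ac, a_roi, combo)$rate
    b <- roi_rates(cc, c_roi, combo)$rate
    enrichment_test(a, b, tails = "one")$p
  }, 0)
  list(rejection_rate = mean(pvals <= alpha), p_values = pvals, n_sims = n_sims)
}
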
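#' Generate a synthetic assay-area cell table
#'
#' Places cells by a homogeneous Poisson point process over the assay band
#' (the rectangle extending from the drug source along the release direction,
#' clipped to the outermost zone radius), assigns each cell a planted cell
#' type from its zone's multinomial composition, and draws one intensity per
#' marker from the positive or negative Beta population according to the
#' expression model. Everything is deterministic given the seed.
#'
#' @param scenario A [scenario_config()].
#' @param geometry A [device_geometry()].
#' @param zones A [zone_config()].
#' @param panel A [marker_panel()].
#' @param seed Integer RNG seed; defaults to `scenario$seed`.
#' @return A list of class `mima_scene` with elements `cells` (tibble:
#'   `cell_id`, `x_um`, `y_um`, one intensity column per marker) and `truth`
#'   (tibble: `cell_id`, `true_type`, `true_zone`, one `true_<marker>_pos`
#'   logical column per marker).
#' @export
generate_scene <- function(scenario, geometry = device_geometry(),
                           zones = zone_config(), panel = default_marker_panel(),
                           seed = scenario$seed) {
  errs <- validate_scenario(scenario)
  if (length(errs)) stopf("invalid scenario: %s", paste(errs, collapse = "; "))
  missing_zones <- setdiff(zones$names, names(scenario$zone_composition))
  if (length(missing_zones))
    stopf("scenario lacks composition for zone(s): %s",
          paste(missing_zones, collapse = ", "))
  if (scenario$density_per_mm2 <= 0)
    stopf("cannot generate an empty scene: density_per_mm2 is zero")

  rmax <- max(zones$boundaries)
  hw <- geometry$assay_band_halfwidth
  with_seed(seed, {
    n_box <- rpois(1, scenario$density_per_mm2 * (2 * hw * rmax) / 1e6)
    cross <- runif(n_box, -hw, hw)
    axial <- runif(n_box, 0, rmax)
    r <- sqrt(cross^2 + axial^2)
    keep <- r <= rmax
    cross <- cross[keep]; axial <- axial[keep]; r <- r[keep]
    zone_idx <- findInterval(r, zones$boundaries, rightmost.closed = TRUE)
    zone <- zones$names[zone_idx]

    type <- character(length(r))
    for (z in zones$names) {
      i <- which(zone == z)
      if (!length(i)) next
      comp <- scenario$zone_composition[[z]]
      type[i] <- sample(names(comp), length(i), replace = TRUE, prob = comp)
    }
    draws <- draw_marker_intensities(scenario, panel, type, zone)
    w <- band_to_world(axial, cross, geometry)
    assemble_scene(w$x, w$y, type, zone, draws, panel)
  })
}

#' Generate the matched control region
#'
#' Cells are placed in a rectangular region perpendicular to the release
#' direction, starting beyond the outermost zone boundary (so no control cell
#' lies in any assay zone) and sized to the assay-region area so that, at
#' equal density, total cell counts match the assay area. The planted
#' composition is the scenario's `control` (background) composition.
#'
#' @inheritParams generate_scene
#' @param n_cells Optional exact cell count (e.g. the realized assay count
#'   for exact matching); when `NULL`, drawn Poisson at the scenario density.
#' @return A `mima_scene` list; the truth `true_zone` is `"control"`.
#' @export
generate_control_region <- function(scenario, geometry = device_geometry(),
                                    zones = zone_config(),
                                    panel = default_marker_panel(),
                                    seed = scenario$seed + 1L, n_cells = NULL) {
  errs <- validate_scenario(scenario)
  if (length(errs)) stopf("invalid scenario: %s", paste(errs, collapse = "; "))
  if (is.null(scenario$zone_composition$control))
    stopf("scenario has no 'control' composition")
  box <- control_region_box(geometry, zones)
  area <- diff(box$cross_range) * diff(box$axial_range)
  if (area <= 0) stopf("control region has zero size")

  with_seed(seed, {
    n <- if (is.null(n_cells)) {
      # same expected count as the assay region at the same density
      rpois(1, scenario$density_per_mm2 * assay_region_area(geometry, zones) / 1e6)
    } else as.integer(n_cells)
    cross <- runif(n, box$cross_range[1], box$cross_range[2])
    axial <- runif(n, box$axial_range[1], box$axial_range[2])
    type <- sample(names(scenario$zone_composition$control), n, replace = TRUE,
                   prob = scenario$zone_composition$control)
    draws <- draw_marker_intensities(scenario, panel, type, rep("control", n))
    w <- band_to_world(axial, cross, geometry)
    assemble_scene(w$x, w$y, type, rep("control", n), draws, panel)
  })
}

# Draw flags and intensities for all markers given planted type and zone.
draw_marker_intensities <- function(scenario, panel, type, zone) {
  n <- length(type)
  pos_par <- unlist(scenario$expression$positive_params)
  neg_par <- unlist(scenario$expression$negative_params)
  zs <- unique(zone)
  Pz <- lapply(setNames(zs, zs), function(z) zone_rate_matrix(scenario, panel, z))
  intens <- matrix(0, nrow = n, ncol = nrow(panel),
                   dimnames = list(NULL, panel$marker))
  flags <- matrix(FALSE, nrow = n, ncol = nrow(panel),
                  dimnames = list(NULL, panel$marker))
  for (m in panel$marker) {
    p <- numeric(n)
    for (z in zs) {
      i <- zone == z
      p[i] <- Pz[[z]][type[i], m]
    }
    pos <- runif(n) < p
    x <- rbeta(n, neg_par[1], neg_par[2])
    x[pos] <- rbeta(sum(pos), pos_par[1], pos_par[2])
    intens[, m] <- x
    flags[, m] <- pos
  }
  list(intensity = intens, flags = flags)
}

assemble_scene <- function(x, y, type, zone, draws, panel) {
  n <- length(x)
  cells <- tibble::as_tibble(cbind(
    data.frame(cell_id = seq_len(n), x_um = x, y_um = y),
    as.data.frame(draws$intensity)
  ))
  truth <- tibble::as_tibble(cbind(
    data.frame(cell_id = seq_len(n), true_type = type, true_zone = zone,
               stringsAsFactors = FALSE),
    as.data.frame(draws$flags) |> stats::setNames(paste0("true_", flag_col(panel$marker)))
  ))
  structure(list(cells = cells, truth = truth), class = "mima_scene")
}

#' @export
print.mima_scene <- function(x, ...) {
  cat(sprintf("<mima_scene> %d cells, %d markers\n",
              nrow(x$cells), ncol(x$cells) - 3L))
  invisible(x)
}

#' Write a scene's cell table (and truth columns) to CSV
#'
#' @param scene A `mima_scene`.
#' @param path Output CSV path.
#' @param truth Include planted-type/flag columns. Default TRUE.
#' @export
write_cell_table <- function(scene, path, truth = TRUE) {
  out <- scene$cells
  if (truth) out <- cbind(out, scene$truth[, -1, drop = FALSE])
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
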
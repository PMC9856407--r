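#' Device geometry of a drug-releasing reservoir
#'
#' Describes the position of the intratumoral drug source (one microdevice
#' reservoir), the direction of passive drug release, and the rectangular
#' assay band over which cells are analyzed. Distances are in micrometers
#' throughout; the source sits at `source_xy` and the assay band extends from
#' the source along `release_direction`, with cross-axis half-width
#' `assay_band_halfwidth`.
#'
#' @param source_xy Numeric length-2, XY position of the drug source (um).
#' @param release_direction Numeric length-2 direction of drug release;
#'   normalized internally, must have positive norm.
#' @param reservoir_diameter Reservoir diameter (um), > 0. Default 200.
#' @param assay_band_halfwidth Half-width of the assay band perpendicular to
#'   the release direction (um). Default 400.
#' @param control_gap Gap (um) between the outermost zone boundary and the
#'   near edge of the matched control region, which is placed perpendicular
#'   to the release direction. Default 200.
#'
#' @return An object of class `device_geometry`.
#' @export
device_geometry <- function(source_xy = c(0, 0),
                            release_direction = c(0, 1),
                            reservoir_diameter = 200,
                            assay_band_halfwidth = 400,
                            control_gap = 200) {
  stopifnot(length(source_xy) == 2, is.finite(source_xy),
            length(release_direction) == 2, is.finite(release_direction))
  nrm <- sqrt(sum(release_direction^2))
  if (nrm <= 0) stopf("release_direction must have positive norm")
  if (!is.numeric(reservoir_diameter) || reservoir_diameter <= 0)
    stopf("reservoir_diameter must be > 0")
  if (assay_band_halfwidth <= 0) stopf("assay_band_halfwidth must be > 0")
  dir <- release_direction / nrm
  structure(list(
    source_xy = as.numeric(source_xy),
    release_direction = dir,
    perp_direction = c(-dir[2], dir[1]),
    reservoir_diameter = reservoir_diameter,
    assay_band_halfwidth = assay_band_halfwidth,
    control_gap = control_gap
  ), class = "device_geometry")
}

#' Zone configuration: radial distance bands from the drug source
#'
#' Zones are consecutive radial distance intervals `[boundaries[i],
#' boundaries[i+1])` from the source, restricted to the assay band. The
#' defaults place a cell ~1500 um from the source in the remote zone.
#'
#' @param names Ordered zone names.
#' @param boundaries Numeric vector of length `length(names) + 1`, strictly
#'   increasing radial boundaries in um starting at 0.
#' @return An object of class `zone_config`.
#' @export
zone_config <- function(names = c("immediate", "proximal", "border", "distal", "remote"),
                        boundaries = c(0, 100, 400, 600, 1000, 2000)) {
  if (length(boundaries) != length(names) + 1)
    stopf("zone_config: need %d boundaries for %d zones", length(names) + 1, length(names))
  if (any(diff(boundaries) <= 0))
    stopf("zone_config: boundaries must be strictly increasing")
  if (anyDuplicated(names)) stopf("zone_config: zone names must be unique")
  structure(list(names = as.character(names), boundaries = as.numeric(boundaries)),
            class = "zone_config")
}

# Band-frame coordinates: axial = distance along release direction,
# cross = signed distance perpendicular to it.
band_coords <- function(x, y, geometry) {
  dx <- x - geometry$source_xy[1]
  dy <- y - geometry$source_xy[2]
  list(
    axial = dx * geometry$release_direction[1] + dy * geometry$release_direction[2],
    cross = dx * geometry$perp_direction[1] + dy * geometry$perp_direction[2]
  )
}

band_to_world <- function(axial, cross, geometry) {
  list(
    x = geometry$source_xy[1] + axial * geometry$release_direction[1] +
      cross * geometry$perp_direction[1],
    y = geometry$source_xy[2] + axial * geometry$release_direction[2] +
      cross * geometry$perp_direction[2]
  )
}

# Area (um^2) of the assay region: the rectangle [0, rmax] x [-hw, hw] in
# band coordinates intersected with the disk of radius rmax about the source.
assay_region_area <- function(geometry, zones) {
  rmax <- max(zones$boundaries)
  hw <- min(geometry$assay_band_halfwidth, rmax)
  # integral of sqrt(rmax^2 - t^2) dt over [-hw, hw]
  hw * sqrt(rmax^2 - hw^2) + rmax^2 * asin(hw / rmax)
}

# Rectangle (in band coordinates along the perpendicular axis) holding the
# matched control region: cross-axis offset in [d0, d0 + len], axial in
# [-hw, hw]. Placed perpendicular to drug release, beyond every assay zone.
control_region_box <- function(geometry, zones) {
  rmax <- max(zones$boundaries)
  d0 <- rmax + geometry$control_gap
  len <- assay_region_area(geometry, zones) / (2 * geometry$assay_band_halfwidth)
  if (len <= 0) stopf("control region has zero size")
  if (d0 <= rmax) stopf("control region overlaps the assay zones")
  list(cross_range = c(d0, d0 + len),
       axial_range = c(-geometry$assay_band_halfwidth, geometry$assay_band_halfwidth))
}
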
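#' Render a synthetic chromogen image for a marker
#'
#' Draws each cell's nucleus as a compact disc of hematoxylin-like absorbance
#' and adds AEC-like red-brown chromogen whose absorbance is proportional to
#' the cell's marker intensity. Transmitted light follows a Beer-Lambert
#' model per RGB channel with published stain absorbance vectors
#' (hematoxylin ~ (0.65, 0.70, 0.29), AEC ~ (0.27, 0.68, 0.68)), so the
#' rendered image behaves like a brightfield chromogenic scan. Also returns
#' the true nuclear label mask for segmentation-recovery tests.
#'
#' @param cells Cell table with `x_um`, `y_um` and one intensity column per
#'   marker.
#' @param marker Name of the marker intensity column to render.
#' @param scale_um_per_px Pixel size in um. Default 0.5 (20x-scan-like).
#' @param nucleus_radius_um Nucleus radius in um. Default 4.
#' @param frame Optional list with `xlim`, `ylim` (um); defaults to the cell
#'   bounding box plus a margin.
#' @param aec_gain Absorbance of the AEC signal at marker intensity 1.
#'   Default 1.2.
#' @param aec_spread Radius of the AEC deposit relative to the nucleus
#'   radius; chromogen spreads into the perinuclear cytoplasm, which is what
#'   lets weak signals register against the nuclear counterstain. Default 1.6.
#' @param overlap_warn Warn when more than this fraction of nuclei overlap a
#'   neighbor. Default 0.2.
#' @return List of class `chromogen_render`: `rgb` (`h x w x 3` array in
#'   `[0, 1]`), `mask` (integer label matrix, labels = row numbers of
#'   `cells`), `scale_um_per_px`, `frame`.
#' @export
render_chromogen_images <- function(cells, marker, scale_um_per_px = 0.5,
                                    nucleus_radius_um = 4, frame = NULL,
                                    aec_gain = 1.2, aec_spread = 1.6,
                                    overlap_warn = 0.2) {
  if (!marker %in% names(cells)) stopf("no intensity column '%s'", marker)
  margin <- 3 * aec_spread * nucleus_radius_um
  if (is.null(frame))
    frame <- list(xlim = range(cells$x_um) + c(-margin, margin),
                  ylim = range(cells$y_um) + c(-margin, margin))
  w <- ceiling(diff(frame$xlim) / scale_um_per_px)
  h <- ceiling(diff(frame$ylim) / scale_um_per_px)
  cx <- (cells$x_um - frame$xlim[1]) / scale_um_per_px + 0.5
  cy <- (cells$y_um - frame$ylim[1]) / scale_um_per_px + 0.5
  if (any(cx < 1 | cx > w | cy < 1 | cy > h))
    stopf("cells do not fit in the image frame at %g um/px", scale_um_per_px)
  r_px <- nucleus_radius_um / scale_um_per_px

  od_h <- matrix(0, h, w)       # hematoxylin absorbance
  od_a <- matrix(0, h, w)       # AEC absorbance
  mask <- matrix(0L, h, w)
  near2 <- matrix(Inf, h, w)    # squared distance to the owning nucleus
  overlaps <- 0L
  r_aec <- aec_spread * r_px
  for (i in seq_len(nrow(cells))) {
    x0 <- max(1L, floor(cx[i] - r_aec)); x1 <- min(w, ceiling(cx[i] + r_aec))
    y0 <- max(1L, floor(cy[i] - r_aec)); y1 <- min(h, ceiling(cy[i] + r_aec))
    xs <- x0:x1; ys <- y0:y1
    d2 <- outer((ys - cy[i])^2, (xs - cx[i])^2, "+")
    inside <- d2 <= r_px^2
    # smooth-edged disc profiles; the chromogen deposit is wider than the
    # nucleus so the yellow channel stays graded against the counterstain
    od_h[ys, xs] <- od_h[ys, xs] + ifelse(inside, 0.9 * exp(-(d2 / r_px^2)^3), 0)
    od_a[ys, xs] <- od_a[ys, xs] +
      aec_gain * cells[[marker]][i] * exp(-(d2 / r_aec^2)^3)
    if (!any(inside)) next
    taken <- mask[ys, xs]
    if (any(inside & taken > 0L)) overlaps <- overlaps + 1L
    claim <- inside & d2 < near2[ys, xs]
    m <- mask[ys, xs]; m[claim] <- i
    mask[ys, xs] <- m
    n2 <- near2[ys, xs]; n2[claim] <- d2[claim]
    near2[ys, xs] <- n2
  }
  if (nrow(cells) > 0 && overlaps / nrow(cells) > overlap_warn)
    warning(sprintf("%d of %d rendered nuclei overlap a neighbor",
                    overlaps, nrow(cells)))
  hema <- c(0.650, 0.704, 0.286)
  aec <- c(0.2743, 0.6796, 0.6803)
  rgb <- array(0, c(h, w, 3))
  for (ch in 1:3)
    rgb[, , ch] <- exp(-(od_h * hema[ch] + od_a * aec[ch]))
  structure(list(rgb = rgb, mask = structure(mask, scale_um_per_px = scale_um_per_px),
                 scale_um_per_px = scale_um_per_px, frame = frame),
            class = "chromogen_render")
}

#' Write a rendered chromogen image (and its label mask) to PNG
#'
#' @param render A `chromogen_render`.
#' @param rgb_path Output path for the RGB PNG.
#' @param mask_path Optional output path for the 16-bit label-mask PNG.
#' @export
write_chromogen_png <- function(render, rgb_path, mask_path = NULL) {
  EBImage::writeImage(EBImage::Image(aperm(render$rgb, c(2, 1, 3)),
                                     colormode = "Color"), rgb_path)
  if (!is.null(mask_path))
    EBImage::writeImage(EBImage::Image(t(render$mask) / 65535), mask_path,
                        bits.per.sample = 16L)
  invisible(rgb_path)
}
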
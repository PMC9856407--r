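#' Channel image constructor
#'
#' A single-channel pixel grid with its physical scale. Matrices are in
#' standard R orientation: rows are image y, columns image x.
#'
#' @param pixels Numeric matrix of finite intensities.
#' @param scale_um_per_px Physical pixel size in um, > 0.
#' @param channel_name Channel label.
#' @return The matrix with class `channel_image` and scale/name attributes.
#' @export
channel_image <- function(pixels, scale_um_per_px = 0.5, channel_name = "channel") {
  if (!is.matrix(pixels) || any(!is.finite(pixels)))
    stopf("channel_image: pixels must be a finite numeric matrix")
  if (scale_um_per_px <= 0) stopf("channel_image: scale must be > 0")
  structure(pixels, scale_um_per_px = scale_um_per_px,
            channel_name = channel_name, class = c("channel_image", "matrix"))
}

img_scale <- function(x, default = 0.5) attr(x, "scale_um_per_px") %||% default

#' Extract the AEC chromogen signal as the CMYK yellow channel
#'
#' Standard RGB to CMYK conversion isolating the red-brown AEC chromogen in
#' the yellow component: with r, g, b in `[0, 1]`, `K = 1 - max(r, g, b)` and
#' `Y = (1 - b - K) / (1 - K)`, defined as 0 where `K = 1` (pure black).
#'
#' @param rgb_image Numeric `h x w x 3` array; 8-bit inputs (max > 1) are
#'   divided by 255.
#' @param scale_um_per_px Physical pixel size in um.
#' @return A [channel_image()] named `"AEC_yellow"` with values in `[0, 1]`.
#' @export
aec_yellow_channel <- function(rgb_image, scale_um_per_px = 0.5) {
  if (length(dim(rgb_image)) != 3 || dim(rgb_image)[3] != 3)
    stopf("aec_yellow_channel: input must be an h x w x 3 RGB array")
  if (max(rgb_image) > 1) rgb_image <- rgb_image / 255
  d <- dim(rgb_image)
  chan <- function(k) matrix(rgb_image[, , k], d[1], d[2])
  r <- chan(1); g <- chan(2); b <- chan(3)
  K <- 1 - pmax(r, pmax(g, b))
  Y <- matrix(0, nrow(r), ncol(r))
  ok <- K < 1
  Y[ok] <- (1 - b[ok] - K[ok]) / (1 - K[ok])
  Y <- pmin(pmax(Y, 0), 1)   # argument order preserves the dim attribute
  channel_image(Y, scale_um_per_px, "AEC_yellow")
}

#' Nuclear-stain channel from a chromogen RGB image
#'
#' Closed-form two-stain arithmetic for synthetic fixtures: hematoxylin
#' absorbs red strongly and blue weakly while AEC does the opposite, so the
#' hematoxylin density follows from the red and blue optical densities alone
#' (`od = -log` of transmittance) via a 2x2 solve with the stain absorbance
#' vectors. This keeps nuclei compact even where chromogen is deposited
#' around them; a full multi-stain deconvolution is unnecessary for rendered
#' fixtures.
#'
#' @inheritParams aec_yellow_channel
#' @return A [channel_image()] named `"hematoxylin"`, scaled to `[0, 1]`.
#' @export
hematoxylin_channel <- function(rgb_image, scale_um_per_px = 0.5) {
  if (length(dim(rgb_image)) != 3 || dim(rgb_image)[3] != 3)
    stopf("hematoxylin_channel: input must be an h x w x 3 RGB array")
  if (max(rgb_image) > 1) rgb_image <- rgb_image / 255
  d <- dim(rgb_image)
  od_r <- -log(pmax(matrix(rgb_image[, , 1], d[1], d[2]), 1e-6))
  od_b <- -log(pmax(matrix(rgb_image[, , 3], d[1], d[2]), 1e-6))
  # absorbance vectors: hematoxylin (0.650, -, 0.286), AEC (0.2743, -, 0.6803)
  h <- (0.6803 * od_r - 0.2743 * od_b) / (0.650 * 0.6803 - 0.2743 * 0.286)
  channel_image(pmin(pmax(h, 0), 1), scale_um_per_px, "hematoxylin")
}

#' Segment nuclei by threshold, morphological cleanup and seeded watershed
#'
#' Pipeline: global threshold (Otsu by default) on the nuclear channel,
#' morphological opening (noise removal / erosion-dilation), then a
#' distance-transform-seeded watershed to split touching nuclei; objects
#' below the minimum area are removed and labels relabeled 1..N. A blank
#' image yields an empty mask without error.
#'
#' @param nuclear A [channel_image()] (or matrix) of the nuclear stain.
#' @param threshold `"otsu"` or a numeric cutoff in (0, 1).
#' @param opening_radius Radius (px) of the disc brush for opening. Default 2.
#' @param watershed_tolerance Minimum object-height separation in the
#'   distance map for a split. Default 1.
#' @param min_area Minimum object area in px. Default 50.
#' @return An integer label matrix (0 = background) with the input's scale
#'   attribute.
#' @export
segment_nuclei <- function(nuclear, threshold = "otsu", opening_radius = 2,
                           watershed_tolerance = 1, min_area = 50) {
  px <- unclass(nuclear)
  attributes(px) <- list(dim = dim(px))
  if (diff(range(px)) == 0)
    return(structure(matrix(0L, nrow(px), ncol(px)),
                     scale_um_per_px = img_scale(nuclear)))
  img <- EBImage::Image(t(px))   # EBImage indexes [x, y]
  th <- if (identical(threshold, "otsu")) EBImage::otsu(img) else threshold
  mask <- img > th
  if (opening_radius > 0)
    mask <- EBImage::opening(mask, EBImage::makeBrush(2 * opening_radius + 1, "disc"))
  if (sum(mask) == 0)
    return(structure(matrix(0L, nrow(px), ncol(px)),
                     scale_um_per_px = img_scale(nuclear)))
  dm <- EBImage::distmap(mask)
  lab <- EBImage::watershed(dm, tolerance = watershed_tolerance, ext = 1)
  labm <- t(EBImage::imageData(lab))
  sizes <- tabulate(labm[labm > 0])
  keep <- which(sizes >= min_area)
  relab <- integer(length(sizes))
  relab[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(labm), ncol(labm))
  pos <- labm > 0
  out[pos] <- relab[labm[pos]]
  structure(out, scale_um_per_px = img_scale(nuclear))
}

#' Per-object mean intensities and centroids
#'
#' One row per labeled object; per-channel mean intensity over the object's
#' pixels (values stay in `[0, 1]` for normalized channels) and the centroid
#' converted to um via the pixel scale. Invariant to relabeling of the mask.
#'
#' @param mask Integer label matrix (0 = background).
#' @param channels Named list of [channel_image()] matrices sharing the
#'   mask's dimensions.
#' @param scale_um_per_px Pixel size; defaults to the mask's attribute.
#' @return Tibble: `cell_id`, `x_um`, `y_um`, `area_px`, one column per
#'   channel.
#' @export
measure_mean_intensity <- function(mask, channels,
                                   scale_um_per_px = img_scale(mask)) {
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    stopf("channels must be a named list")
  for (ch in channels)
    if (!all(dim(ch) == dim(mask)))
      stopf("channel dimensions do not match the mask")
  labs <- sort(unique(mask[mask > 0]))
  if (!length(labs)) {
    out <- tibble::tibble(cell_id = integer(), x_um = numeric(),
                          y_um = numeric(), area_px = integer())
    for (nm in names(channels)) out[[nm]] <- numeric()
    return(out)
  }
  pos <- which(mask > 0)
  f <- factor(mask[pos], levels = labs)
  area <- as.integer(table(f))
  rows <- (pos - 1) %% nrow(mask) + 1
  cols <- (pos - 1) %/% nrow(mask) + 1
  cx <- as.numeric(tapply(cols, f, mean))
  cy <- as.numeric(tapply(rows, f, mean))
  out <- tibble::tibble(cell_id = as.integer(labs),
                        x_um = (cx - 0.5) * scale_um_per_px,
                        y_um = (cy - 0.5) * scale_um_per_px,
                        area_px = area)
  for (nm in names(channels)) {
    v <- unclass(channels[[nm]])[pos]
    out[[nm]] <- as.numeric(tapply(v, f, mean))
  }
  out
}
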
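#' Segmentation parameters
#'
#' @param median_radius radius (pixels) of the median smoothing neighbourhood
#'   applied to each RGB channel before thresholding. Default 4.
#' @param smooth_radius radius (pixels) of the disc structuring element used
#'   for morphological contour smoothing (opening followed by closing) of the
#'   binary wing and spot masks. Default 8.
#' @param median_shape `"disc"` or `"square"` neighbourhood for the median
#'   filter. The acquisition software's choice is not knowable; disc is the
#'   default.
#' @param min_contrast minimum separation (intensity units) between the two
#'   Otsu classes' means for a segmentation to be considered genuine; guards
#'   against silently thresholding noise when the expected channel contrast
#'   (blue-dark wing on bright background; red-dark spots on red wing) is
#'   absent.
#' @return A list of class `"seg_params"`.
#' @export
seg_params <- function(median_radius = 4, smooth_radius = 8,
                       median_shape = c("disc", "square"),
                       min_contrast = 30) {
  stopifnot(median_radius >= 1, smooth_radius >= 1, min_contrast >= 0)
  structure(list(median_radius = median_radius, smooth_radius = smooth_radius,
                 median_shape = match.arg(median_shape),
                 min_contrast = min_contrast), class = "seg_params")
}

#' Median smoothing of an RGB image
#'
#' Replaces every pixel of every channel by the median over a disc (or
#' square) neighbourhood of the given radius; borders are handled by edge
#' replication.
#'
#' @param img H x W x 3 array (or a single H x W matrix) of intensities.
#' @param radius neighbourhood radius in pixels (>= 1).
#' @param shape `"disc"` (default) or `"square"`.
#' @return Smoothed array of the same shape.
#' @export
median_smooth <- function(img, radius = 4, shape = c("disc", "square")) {
  shape <- match.arg(shape)
  stopifnot(radius >= 1)
  if (is.matrix(img))
    return(median_filter_cpp(img, as.integer(radius), shape == "square"))
  stopifnot(length(dim(img)) == 3)
  out <- img
  for (ch in seq_len(dim(img)[3]))
    out[, , ch] <- median_filter_cpp(img[, , ch], as.integer(radius),
                                     shape == "square")
  out
}

#' Otsu threshold of an intensity channel
#'
#' Exhaustively maximizes the between-class variance over the 256-bin
#' histogram of (rounded) intensities in `[0, 255]`. The returned threshold
#' `t` separates the classes `<= t` and `> t`; the lowest maximizing `t` is
#' returned on ties.
#'
#' @param channel numeric matrix or vector of intensities in `[0, 255]`.
#' @return Integer threshold in `0..254`.
#' @export
otsu_threshold <- function(channel) {
  v <- round(as.numeric(channel))
  v[v < 0] <- 0; v[v > 255] <- 255
  if (length(unique(v)) < 2)
    stop("Otsu threshold undefined: channel has fewer than 2 distinct values")
  h <- tabulate(v + 1L, nbins = 256L)
  n <- sum(h)
  lv <- 0:255
  w0 <- cumsum(h)
  s0 <- cumsum(h * lv)
  mu_t <- s0[256] / n
  w1 <- n - w0
  mu0 <- s0 / pmax(w0, 1)
  mu1 <- (s0[256] - s0) / pmax(w1, 1)
  bcv <- (w0 / n) * (w1 / n) * (mu0 - mu1)^2
  bcv[w0 == 0 | w1 == 0] <- -Inf
  bcv <- bcv[1:255]  # thresholds t = 0..254
  which.max(bcv) - 1L
}

label_components <- function(mask, connectivity = 8) {
  label_components_cpp(mask, as.integer(connectivity))
}

largest_component <- function(mask, connectivity = 8) {
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0])
  lab == which.max(sizes)  # which.max resolves ties to the lowest label
}

morph_smooth <- function(mask, radius) {
  kern <- EBImage::makeBrush(2 * radius + 1, shape = "disc")
  m <- EBImage::closing(EBImage::opening(mask * 1, kern), kern)
  as.matrix(EBImage::imageData(m)) > 0.5
}

fill_holes <- function(mask) {
  as.matrix(EBImage::imageData(EBImage::fillHull(mask * 1))) > 0.5
}

#' Extract the whole-wing mask from an elytron image
#'
#' Applies Otsu's method to the blue channel (the red wing is blue-dark on
#' the bright background), keeps the below-threshold class, retains the
#' largest 8-connected component, fills interior holes, and smooths the
#' contour by morphological opening then closing with a disc of radius
#' `smooth_radius`.
#'
#' @param img H x W x 3 RGB array in `[0, 255]` (typically already median
#'   smoothed; see [median_smooth()]).
#' @param params a [seg_params()] object.
#' @return Logical H x W wing mask (one connected component, no holes).
#' @export
segment_wing <- function(img, params = seg_params()) {
  stopifnot(length(dim(img)) == 3, dim(img)[3] == 3)
  blue <- img[, , 3]
  t <- otsu_threshold(blue)
  wing <- blue <= t
  if (!any(wing)) stop("no wing found: below-threshold class is empty")
  if (mean(blue[!wing]) - mean(blue[wing]) < params$min_contrast)
    stop("no wing found: blue-channel contrast between wing and background ",
         "is below min_contrast; check channel conventions")
  wing <- largest_component(wing)
  wing <- fill_holes(wing)
  wing <- morph_smooth(wing, params$smooth_radius)
  wing <- largest_component(wing)
  wing <- fill_holes(wing)
  if (!any(wing)) stop("no wing found after morphological smoothing")
  if (sum(wing) < 0.05 * length(wing))
    stop("no wing found: largest blue-dark component covers under 5% of ",
         "the image; check channel conventions")
  border <- sum(wing[1, ]) + sum(wing[nrow(wing), ]) +
    sum(wing[, 1]) + sum(wing[, ncol(wing)])
  if (border > 0.2 * (2 * nrow(wing) + 2 * ncol(wing)))
    stop("wing mask touches the image border extensively; ",
         "check channel conventions")
  wing
}

#' Extract the raw black-spot mask within a wing
#'
#' Applies Otsu's method to the red-channel values restricted to wing pixels
#' (black spots are red-dark on the red wing), keeps the below-threshold
#' class, intersects with the wing, and smooths the contour by opening then
#' closing with a disc of radius `smooth_radius`. If the red values inside
#' the wing show no genuine bimodality (class-mean separation below
#' `min_contrast`), the wing is deemed spotless and an empty mask is
#' returned.
#'
#' @param img H x W x 3 RGB array in `[0, 255]`.
#' @param wing logical wing mask from [segment_wing()].
#' @param params a [seg_params()] object.
#' @return Logical H x W spot mask, always a subset of `wing`.
#' @export
segment_spots <- function(img, wing, params = seg_params()) {
  stopifnot(length(dim(img)) == 3, dim(img)[3] == 3,
            identical(dim(img)[1:2], dim(wing)))
  if (!any(wing)) stop("wing mask is empty")
  red <- img[, , 1]
  vals <- red[wing]
  if (length(unique(round(vals))) < 2) return(wing & FALSE)
  t <- otsu_threshold(vals)
  spots <- wing & red <= t
  if (!any(spots)) return(wing & FALSE)
  if (mean(red[wing & !spots]) - mean(red[spots]) < params$min_contrast)
    return(wing & FALSE)  # unimodal red within wing: spotless
  spots <- morph_smooth(spots, params$smooth_radius)
  spots & wing
}

#' Segment one elytron image end to end
#'
#' Convenience wrapper: median smoothing, wing extraction, spot extraction.
#'
#' @inheritParams segment_wing
#' @return A list with `wing` and `spots` logical masks and the smoothed
#'   image (`smoothed`).
#' @export
process_elytron_image <- function(img, params = seg_params()) {
  sm <- median_smooth(img, params$median_radius, params$median_shape)
  wing <- segment_wing(sm, params)
  spots <- segment_spots(sm, wing, params)
  list(wing = wing, spots = spots, smoothed = sm)
}
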
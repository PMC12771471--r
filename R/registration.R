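# Resample a raster under the rigid alignment transform by inverse mapping.
# transform: list(cx, cy, theta, flip_y) mapping source -> canonical frame
# (center source centroid at canvas center, rotate by -theta, optional y
# flip). method "nearest" keeps masks binary; "bilinear" for intensities.
apply_alignment <- function(x, transform, out_dim = dim(x)[1:2],
                            method = c("nearest", "bilinear")) {
  method <- match.arg(method)
  is_mask <- is.logical(x)
  arr <- if (length(dim(x)) == 3) x else
    array(as.numeric(x), dim = c(dim(x), 1))
  H <- out_dim[1]; W <- out_dim[2]
  co <- (W + 1) / 2; ro <- (H + 1) / 2
  X <- matrix(rep(seq_len(W), each = H), H, W)
  Y <- matrix(rep(seq_len(H), times = W), H, W)
  u <- X - co; v <- Y - ro
  if (isTRUE(transform$flip_y)) v <- -v
  xs <- transform$cx + cos(transform$theta) * u - sin(transform$theta) * v
  ys <- transform$cy + sin(transform$theta) * u + cos(transform$theta) * v
  sample_plane <- function(plane) {
    Hs <- nrow(plane); Ws <- ncol(plane)
    if (method == "nearest") {
      xi <- round(xs); yi <- round(ys)
      ok <- xi >= 1 & xi <= Ws & yi >= 1 & yi <= Hs
      out <- matrix(0, H, W)
      out[ok] <- plane[cbind(yi[ok], xi[ok])]
      out
    } else {
      x0 <- floor(xs); y0 <- floor(ys)
      fx <- xs - x0; fy <- ys - y0
      g <- function(yy, xx) {
        ok <- xx >= 1 & xx <= Ws & yy >= 1 & yy <= Hs
        out <- matrix(0, H, W)
        out[ok] <- plane[cbind(yy[ok], xx[ok])]
        out
      }
      (1 - fx) * (1 - fy) * g(y0, x0) + fx * (1 - fy) * g(y0, x0 + 1) +
        (1 - fx) * fy * g(y0 + 1, x0) + fx * fy * g(y0 + 1, x0 + 1)
    }
  }
  out <- array(0, dim = c(H, W, dim(arr)[3]))
  for (ch in seq_len(dim(arr)[3])) out[, , ch] <- sample_plane(arr[, , ch])
  if (length(dim(x)) != 3) out <- out[, , 1]
  if (is_mask) out <- out > 0.5
  out
}

#' Align a wing mask to the canonical frame
#'
#' Translates the wing-pixel centroid to the image center and rotates so the
#' first and second principal components of the wing pixel coordinates lie
#' along the X and Y axes. The two-fold rotation ambiguity is resolved by
#' requiring the third central moment (skewness) of the wing pixels along X
#' to be non-negative; if the skewness along Y is then negative the mask is
#' mirrored about the X axis, so left and right elytra land in one frame.
#' For shapes with vanishing third moments (e.g. ellipses) the rotation
#' angle is normalized to (-90, 90] degrees and no flip is applied.
#'
#' Companion rasters (spot masks, RGB images) are resampled under the same
#' transform: nearest-neighbour for logical masks, bilinear otherwise.
#'
#' @param wing logical wing mask.
#' @param companions named list of rasters sharing `wing`'s frame.
#' @param out_dim `(H, W)` of the canonical canvas (defaults to input size).
#' @return A list of class `"aligned_wing"`: `wing` (aligned mask),
#'   `companions` (aligned rasters), `transform` (source centroid `cx`, `cy`,
#'   rotation `theta` in radians, `flip_y`).
#' @export
align_wing <- function(wing, companions = list(), out_dim = dim(wing)) {
  pix <- which(wing, arr.ind = TRUE)
  if (nrow(pix) < 3) stop("wing mask is empty or degenerate")
  xy <- cbind(x = pix[, 2], y = pix[, 1])
  cx <- mean(xy[, 1]); cy <- mean(xy[, 2])
  C <- cov(xy)
  ev <- eigen(C, symmetric = TRUE)
  if (ev$values[2] <= 1e-9 * ev$values[1] || ev$values[1] <= 0)
    stop("degenerate wing pixel covariance (collinear pixels)")
  v1 <- ev$vectors[, 1]
  theta <- atan2(v1[2], v1[1])
  if (theta <= -pi / 2) theta <- theta + pi
  if (theta > pi / 2) theta <- theta - pi
  rot <- function(th) {
    xr <- cos(th) * (xy[, 1] - cx) + sin(th) * (xy[, 2] - cy)
    yr <- -sin(th) * (xy[, 1] - cx) + cos(th) * (xy[, 2] - cy)
    cbind(xr, yr)
  }
  p <- rot(theta)
  skew <- function(z) mean(z^3) / (sd(z)^3 + 1e-12)
  tol <- 1e-3
  if (skew(p[, 1]) < -tol) {
    theta <- theta + pi
    p <- rot(theta)
  }
  flip_y <- skew(p[, 2]) < -tol
  transform <- list(cx = cx, cy = cy, theta = theta, flip_y = flip_y)
  aligned <- apply_alignment(wing, transform, out_dim, "nearest")
  comp <- lapply(companions, function(z)
    apply_alignment(z, transform, out_dim,
                    if (is.logical(z)) "nearest" else "bilinear"))
  structure(list(wing = aligned, companions = comp, transform = transform),
            class = "aligned_wing")
}

mask_bbox <- function(mask) {
  pix <- which(mask, arr.ind = TRUE)
  if (nrow(pix) == 0) stop("empty mask has no bounding box")
  c(xmin = min(pix[, 2]), xmax = max(pix[, 2]),
    ymin = min(pix[, 1]), ymax = max(pix[, 1]))
}

# Endpoint-matched anisotropic bbox rescaling by nearest-neighbour inverse
# mapping: the source bbox corners map exactly onto the target rectangle, so
# every output wing bbox has exactly the target dimensions.
rescale_bbox <- function(mask, bbox, target_wh, out_dim, companions = list()) {
  Wt <- target_wh[1]; Ht <- target_wh[2]
  if (bbox["xmax"] - bbox["xmin"] < 1 || bbox["ymax"] - bbox["ymin"] < 1)
    stop("zero-extent bounding box cannot be rescaled")
  H <- out_dim[1]; W <- out_dim[2]
  xo_min <- round((W + 1) / 2 - (Wt - 1) / 2)
  yo_min <- round((H + 1) / 2 - (Ht - 1) / 2)
  X <- matrix(rep(seq_len(W), each = H), H, W)
  Y <- matrix(rep(seq_len(H), times = W), H, W)
  xs <- round(bbox["xmin"] + (X - xo_min) *
                (bbox["xmax"] - bbox["xmin"]) / (Wt - 1))
  ys <- round(bbox["ymin"] + (Y - yo_min) *
                (bbox["ymax"] - bbox["ymin"]) / (Ht - 1))
  samp <- function(m) {
    ok <- xs >= 1 & xs <= ncol(m) & ys >= 1 & ys <= nrow(m)
    out <- matrix(FALSE, H, W)
    out[ok] <- m[cbind(ys[ok], xs[ok])]
    out
  }
  list(mask = samp(mask), companions = lapply(companions, samp),
       scale = c(sx = (Wt - 1) / unname(bbox["xmax"] - bbox["xmin"]),
                 sy = (Ht - 1) / unname(bbox["ymax"] - bbox["ymin"])),
       bbox_out = c(xmin = xo_min, xmax = xo_min + Wt - 1,
                    ymin = yo_min, ymax = yo_min + Ht - 1))
}

#' Scale aligned wings to a common bounding rectangle
#'
#' Computes each wing's tight bounding rectangle and maps it onto the
#' cohort-common target rectangle (by default the median width and height
#' across wings, a robust choice) with anisotropic nearest-neighbour
#' scaling, so all specimens share identical bounding-box dimensions.
#' Companion masks (e.g. spot masks) are rescaled with their wing's
#' transform.
#'
#' @param aligned list of [align_wing()] results (each with `wing` and
#'   optional logical `companions`).
#' @param target_wh optional `(width, height)` of the target rectangle.
#' @return A list with `wings`, `companions`, per-image `scale` factors, the
#'   common `target_wh` and the common output `bbox`.
#' @export
scale_to_common_bbox <- function(aligned, target_wh = NULL) {
  stopifnot(length(aligned) >= 1)
  bbs <- lapply(aligned, function(a) mask_bbox(a$wing))
  if (is.null(target_wh))
    target_wh <- c(round(median(vapply(bbs, function(b)
                     b["xmax"] - b["xmin"] + 1, numeric(1)))),
                   round(median(vapply(bbs, function(b)
                     b["ymax"] - b["ymin"] + 1, numeric(1)))))
  out_dim <- dim(aligned[[1]]$wing)
  res <- lapply(seq_along(aligned), function(i)
    rescale_bbox(aligned[[i]]$wing, bbs[[i]], target_wh, out_dim,
                 aligned[[i]]$companions))
  list(wings = lapply(res, `[[`, "mask"),
       companions = lapply(res, `[[`, "companions"),
       scale = lapply(res, `[[`, "scale"),
       target_wh = target_wh, bbox = res[[1]]$bbox_out)
}

#' Average a stack of binary masks
#'
#' @param masks list of logical matrices of identical dimension.
#' @return Numeric matrix of per-pixel means in `[0, 1]`.
#' @export
build_average_image <- function(masks) {
  stopifnot(length(masks) >= 1)
  d <- dim(masks[[1]])
  for (m in masks)
    if (!identical(dim(m), d)) stop("masks must share the same shape")
  Reduce(`+`, lapply(masks, function(m) m * 1)) / length(masks)
}

# Greedy closest-pair matching of component centroids to reference centers;
# deterministic and stable against small centroid perturbations.
match_to_reference <- function(cx, cy, ref) {
  n <- length(cx)
  D <- outer(seq_len(n), seq_len(n), function(i, j)
    sqrt((cx[i] - ref$x[j])^2 + (cy[i] - ref$y[j])^2))
  relab <- integer(n)
  for (k in seq_len(n)) {
    ij <- arrayInd(which.min(D), dim(D))
    relab[ij[1]] <- ij[2]
    D[ij[1], ] <- Inf
    D[, ij[2]] <- Inf
  }
  relab
}

#' Derive the labeled ten-spot template from an average spot image
#'
#' Scans thresholds 0.05, 0.10, ..., 0.95 and keeps the smallest one whose
#' above-threshold 8-connected component count equals `expected_spots`
#' (favouring the largest template extent). Components are labeled 1..10 in
#' the canonical numbering (anterior to posterior, then across the wing):
#' when `reference_centers` are supplied (as [build_spot_template()] does,
#' from the package's canonical layout) each component takes the label of
#' its closest-pair reference center; otherwise components are ordered by
#' centroid x then y.
#'
#' @param avg average image in `[0, 1]` from [build_average_image()].
#' @param expected_spots required component count (default 10).
#' @param thresholds candidate thresholds.
#' @param reference_centers optional data.frame with `x`, `y` giving the
#'   expected center of each canonical spot in the frame of `avg` (row i =
#'   spot i).
#' @return A list of class `"spot_template"`: `label_map` (H x W integers
#'   0-10), `centroids` (data.frame `spot_index`, `x`, `y`),
#'   `source_threshold`.
#' @export
template_from_average <- function(avg, expected_spots = 10,
                                  thresholds = seq(0.05, 0.95, by = 0.05),
                                  reference_centers = NULL) {
  stopifnot(all(avg >= 0 & avg <= 1))
  achievable <- integer(0)
  for (t in thresholds) {
    lab <- label_components(avg >= t - 1e-9)
    n <- max(lab)
    achievable <- c(achievable, n)
    if (n == expected_spots) {
      cx <- vapply(seq_len(n), function(k)
        mean(which(lab == k, arr.ind = TRUE)[, 2]), numeric(1))
      cy <- vapply(seq_len(n), function(k)
        mean(which(lab == k, arr.ind = TRUE)[, 1]), numeric(1))
      relab <- if (!is.null(reference_centers)) {
        stopifnot(nrow(reference_centers) == n)
        match_to_reference(cx, cy, reference_centers)
      } else {
        ord <- order(cx, cy)
        match(seq_len(n), ord)  # old label -> canonical label
      }
      ord <- order(relab)  # component index of canonical label 1..n
      label_map <- matrix(0L, nrow(lab), ncol(lab))
      label_map[lab > 0] <- relab[lab[lab > 0]]
      return(structure(list(
        label_map = label_map,
        centroids = data.frame(spot_index = seq_len(n),
                               x = cx[ord], y = cy[ord]),
        source_threshold = t), class = "spot_template"))
    }
  }
  stop("no threshold separates exactly ", expected_spots, " spots; ",
       "achievable counts: ",
       paste(unique(sort(achievable)), collapse = ", "))
}
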
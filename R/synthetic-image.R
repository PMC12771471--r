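#' Canonical ten-spot layout of the elytron
#'
#' Fixed coordinates of the ten black spot positions used throughout the
#' package, expressed in wing-ellipse units: `ex`, `ey` are the spot center
#' in units of the wing semi-axes (so the wing boundary is the unit circle in
#' these coordinates), and `r_frac` is the spot radius as a fraction of the
#' semi-minor axis. Spot numbering runs anterior to posterior, then across
#' the wing, mirroring the conventional 1-10 schematic for *Harmonia
#' axyridis* elytra. The coordinates themselves are a package constant chosen
#' for reproducible fixtures (the schematic fixes numbering, not geometry).
#'
#' @return A data.frame with columns `spot_index`, `ex`, `ey`, `r_frac`.
#' @export
elytra_spot_layout <- function() {
  data.frame(
    spot_index = 1:10,
    ex = c(-0.65, -0.65, -0.20, -0.20, -0.20, 0.25, 0.25, 0.42, 0.68, 0.68),
    ey = c(-0.40, 0.40, -0.55, 0.00, 0.55, -0.45, 0.45, 0.00, -0.36, 0.36),
    r_frac = c(0.13, 0.13, 0.13, 0.14, 0.13, 0.13, 0.13, 0.12, 0.11, 0.11)
  )
}

#' Configuration for one synthetic elytron image
#'
#' Describes an elliptical red elytron on a bright background carrying up to
#' ten black spots at the canonical positions of [elytra_spot_layout()].
#' Females receive spot radii multiplied by `female_scale`, emulating the
#' larger black spots of females in the sexually dimorphic morph.
#'
#' @param image_size `(H, W)` of the rendered image in pixels.
#' @param wing_axes `(a, b)` semi-axes of the wing ellipse in pixels
#'   (a along x, b along y).
#' @param background_rgb,wing_rgb,spot_rgb RGB triples in `[0, 255]`. The
#'   conventions of the segmentation stage require the wing to be red-bright
#'   and blue-dark relative to the background, and spots red-dark relative
#'   to the wing.
#' @param sex `"female"` or `"male"`.
#' @param female_scale spot-radius multiplier (>= 1) applied when
#'   `sex = "female"`. Default 1.3, the effect size used for power analyses
#'   (disk areas then scale by 1.69).
#' @param spots data.frame with columns `spot_index`, `x`, `y`, `radius`,
#'   `eccentricity`; positions in pixels relative to the wing center, in the
#'   unrotated wing frame. Defaults to the canonical layout scaled to
#'   `wing_axes`; pass a zero-row data.frame for a spotless wing.
#' @param fusion_pairs list of length-2 integer vectors; each pair of spots
#'   is pulled together along their connecting line until the disks overlap,
#'   creating a fused blob for watershed testing.
#' @param rotation_deg global rotation of the wing in the image, degrees.
#' @param translation `(dx, dy)` displacement of the wing center from the
#'   image center, pixels.
#' @param noise_sd standard deviation of additive per-channel Gaussian noise
#'   (intensity units; clipped to `[0, 255]`).
#' @param seed integer seed, or NULL to use the current RNG stream.
#' @return An object of class `"elytron_config"`.
#' @export
synthetic_elytron_config <- function(image_size = c(320L, 480L),
                                     wing_axes = c(215, 140),
                                     background_rgb = c(245, 245, 245),
                                     wing_rgb = c(200, 40, 35),
                                     spot_rgb = c(25, 22, 20),
                                     sex = c("female", "male"),
                                     female_scale = 1.3,
                                     spots = NULL,
                                     fusion_pairs = list(),
                                     rotation_deg = 0,
                                     translation = c(0, 0),
                                     noise_sd = 5,
                                     seed = NULL) {
  sex <- match.arg(sex)
  a <- wing_axes[1]; b <- wing_axes[2]
  if (is.null(spots)) {
    lay <- elytra_spot_layout()
    spots <- data.frame(
      spot_index = lay$spot_index,
      x = lay$ex * a, y = lay$ey * b,
      radius = lay$r_frac * b,
      eccentricity = 0
    )
  }
  if (nrow(spots) > 0 && sex == "female")
    spots$radius <- spots$radius * female_scale
  cfg <- structure(list(
    image_size = as.integer(image_size), wing_axes = c(a, b),
    background_rgb = background_rgb, wing_rgb = wing_rgb, spot_rgb = spot_rgb,
    sex = sex, female_scale = female_scale, spots = spots,
    fusion_pairs = fusion_pairs, rotation_deg = rotation_deg,
    translation = translation, noise_sd = noise_sd, seed = seed
  ), class = "elytron_config")
  validate_elytron_config(cfg)
}

apply_fusion <- function(spots, fusion_pairs) {
  for (pr in fusion_pairs) {
    i <- match(pr[1], spots$spot_index); j <- match(pr[2], spots$spot_index)
    if (is.na(i) || is.na(j))
      stop("fusion pair refers to a spot index not present in the config")
    d <- sqrt((spots$x[i] - spots$x[j])^2 + (spots$y[i] - spots$y[j])^2)
    target <- 0.8 * (spots$radius[i] + spots$radius[j])
    if (d > target && d > 0) {
      shift <- (d - target) / 2 / d
      mx <- spots$x[j] - spots$x[i]; my <- spots$y[j] - spots$y[i]
      spots$x[i] <- spots$x[i] + shift * mx; spots$y[i] <- spots$y[i] + shift * my
      spots$x[j] <- spots$x[j] - shift * mx; spots$y[j] <- spots$y[j] - shift * my
    }
  }
  spots
}

validate_elytron_config <- function(cfg) {
  H <- cfg$image_size[1]; W <- cfg$image_size[2]
  a <- cfg$wing_axes[1]; b <- cfg$wing_axes[2]
  stopifnot(H >= 1, W >= 1, a > 0, b > 0, cfg$noise_sd >= 0,
            cfg$female_scale >= 1)
  th <- cfg$rotation_deg * pi / 180
  hx <- sqrt((a * cos(th))^2 + (b * sin(th))^2)
  hy <- sqrt((a * sin(th))^2 + (b * cos(th))^2)
  cx <- (W + 1) / 2 + cfg$translation[1]; cy <- (H + 1) / 2 + cfg$translation[2]
  if (cx - hx < 1 || cx + hx > W || cy - hy < 1 || cy + hy > H)
    stop("wing ellipse does not fit inside the image")
  if (cfg$wing_rgb[1] - cfg$spot_rgb[1] < 50)
    stop("spot_rgb must be clearly red-dark relative to wing_rgb")
  if (cfg$background_rgb[3] - cfg$wing_rgb[3] < 50)
    stop("wing_rgb must be clearly blue-dark relative to background_rgb")
  sp <- cfg$spots
  if (nrow(sp) > 0) {
    if (anyDuplicated(sp$spot_index))
      stop("spot_index must be unique within one elytron")
    if (any(sp$radius <= 0)) stop("spot radii must be positive")
    if (any(sp$eccentricity < 0 | sp$eccentricity >= 1))
      stop("eccentricity must lie in [0, 1)")
    sp <- apply_fusion(sp, cfg$fusion_pairs)
    out <- sqrt((sp$x / pmax(a - sp$radius, 1e-9))^2 +
                (sp$y / pmax(b - sp$radius, 1e-9))^2) > 1 | sp$radius >= b
    if (any(out))
      stop("spot(s) ", paste(sp$spot_index[out], collapse = ", "),
           " extend outside the wing ellipse")
  }
  cfg
}

#' Render a synthetic elytron image with ground truth
#'
#' Rasterizes the configured wing ellipse and spot disks, applies the global
#' rotation/translation, then adds clipped per-channel Gaussian noise. Where
#' fused spots overlap, each pixel is attributed to the spot whose center is
#' nearest in radius-normalized distance (ties to the lower spot index), so
#' the ground-truth label masks are always disjoint.
#'
#' @param config an [synthetic_elytron_config()] object.
#' @return A list with `image` (H x W x 3 array, 0-255) and `truth`, a list
#'   holding `spot_areas` (named pixel counts for spots 1-10, pre-noise),
#'   `wing_area`, `label_mask` (H x W integers 0-10), `wing_mask`,
#'   `transform` and the realized `spots` table.
#' @export
render_elytron <- function(config) {
  config <- validate_elytron_config(config)
  with_seed(config$seed, render_elytron_impl(config))
}

render_elytron_impl <- function(config) {
  H <- config$image_size[1]; W <- config$image_size[2]
  a <- config$wing_axes[1]; b <- config$wing_axes[2]
  th <- config$rotation_deg * pi / 180
  cx <- (W + 1) / 2 + config$translation[1]
  cy <- (H + 1) / 2 + config$translation[2]
  X <- matrix(rep(seq_len(W), each = H), H, W)
  Y <- matrix(rep(seq_len(H), times = W), H, W)
  # inverse transform into the unrotated wing frame
  u <- cos(th) * (X - cx) + sin(th) * (Y - cy)
  v <- -sin(th) * (X - cx) + cos(th) * (Y - cy)
  wing_mask <- (u / a)^2 + (v / b)^2 <= 1
  sp <- apply_fusion(config$spots, config$fusion_pairs)
  label <- matrix(0L, H, W)
  if (nrow(sp) > 0) {
    best <- matrix(Inf, H, W)
    for (k in order(sp$spot_index)) {
      ry <- sp$radius[k] * sqrt(1 - sp$eccentricity[k]^2)
      d <- ((u - sp$x[k]) / sp$radius[k])^2 + ((v - sp$y[k]) / ry)^2
      hit <- d <= 1 & d < best  # strict < keeps earlier (lower) label on ties
      label[hit] <- sp$spot_index[k]
      best <- pmin(best, ifelse(d <= 1, d, Inf))
    }
  }
  img <- array(0, dim = c(H, W, 3))
  for (ch in 1:3) {
    plane <- matrix(config$background_rgb[ch], H, W)
    plane[wing_mask] <- config$wing_rgb[ch]
    plane[label > 0] <- config$spot_rgb[ch]
    img[, , ch] <- plane
  }
  if (config$noise_sd > 0) {
    img <- img + array(rnorm(length(img), 0, config$noise_sd), dim = dim(img))
    img[img < 0] <- 0; img[img > 255] <- 255
  }
  spot_areas <- setNames(tabulate(label[label > 0], nbins = 10), 1:10)
  list(
    image = img,
    truth = list(
      spot_areas = spot_areas,
      wing_area = sum(wing_mask),
      label_mask = label,
      wing_mask = wing_mask,
      transform = list(rotation_deg = config$rotation_deg,
                      translation = config$translation),
      spots = sp
    )
  )
}

draw_cohort_configs <- function(n_per_sex, base, female_scale,
                                radius_jitter_sdlog, center_jitter_sd,
                                rotation_jitter_sd, translation_jitter_sd) {
  out <- list()
  idx <- 0
  for (sex in c("female", "male")) {
    for (i in seq_len(n_per_sex)) {
      idx <- idx + 1
      cfg <- base
      cfg$sex <- sex
      cfg$female_scale <- female_scale
      sp <- base$spots
      scale_sex <- if (sex == "female") female_scale else 1
      jit <- list(
        log_radius = rnorm(nrow(sp), 0, radius_jitter_sdlog),
        dx = rnorm(nrow(sp), 0, center_jitter_sd),
        dy = rnorm(nrow(sp), 0, center_jitter_sd),
        rotation = rnorm(1, 0, rotation_jitter_sd),
        translation = rnorm(2, 0, translation_jitter_sd)
      )
      sp$radius <- sp$radius * scale_sex * exp(jit$log_radius)
      sp$x <- sp$x + jit$dx; sp$y <- sp$y + jit$dy
      cfg$spots <- sp
      cfg$rotation_deg <- base$rotation_deg + jit$rotation
      cfg$translation <- base$translation + jit$translation
      cfg$seed <- NULL
      out[[idx]] <- list(config = validate_elytron_config(cfg), sex = sex,
                         individual_id = sprintf("%s_%02d",
                                                 substr(sex, 1, 1), i),
                         jitter = jit)
    }
  }
  out
}

#' Render a ground-truthed cohort of synthetic elytra
#'
#' Draws `n_per_sex` females and `n_per_sex` males from a base configuration.
#' Female spot radii are multiplied by `female_scale`; each individual then
#' receives lognormal radius jitter, isotropic Gaussian center jitter, and a
#' small random rotation/translation of the whole wing. All draws are
#' recorded in the returned ground truth.
#'
#' @param n_per_sex individuals per sex (>= 1).
#' @param base base [synthetic_elytron_config()]; its `spots` table gives the
#'   male (unscaled) geometry. `base$spots` must use the male scale, so pass
#'   a config built with `sex = "male"`.
#' @param female_scale spot-radius multiplier for females.
#' @param seed integer seed for the whole cohort.
#' @param radius_jitter_sdlog sdlog of the lognormal radius jitter
#'   (default 0.1, i.e. ~10% coefficient of variation).
#' @param center_jitter_sd sd (pixels) of the spot-center jitter.
#' @param rotation_jitter_sd sd (degrees) of the per-individual rotation.
#' @param translation_jitter_sd sd (pixels) of the per-individual translation.
#' @return A list of length `2 * n_per_sex`; each element has `image`,
#'   `truth`, `sex`, `individual_id` and the realized `config`.
#' @export
render_cohort <- function(n_per_sex, base = NULL, female_scale = 1.3,
                          seed = NULL, radius_jitter_sdlog = 0.1,
                          center_jitter_sd = 2, rotation_jitter_sd = 4,
                          translation_jitter_sd = 3) {
  stopifnot(n_per_sex >= 1)
  if (is.null(base)) base <- synthetic_elytron_config(sex = "male")
  with_seed(seed, {
    cfgs <- draw_cohort_configs(n_per_sex, base, female_scale,
                                radius_jitter_sdlog, center_jitter_sd,
                                rotation_jitter_sd, translation_jitter_sd)
    lapply(cfgs, function(e) {
      r <- render_elytron_impl(e$config)
      list(image = r$image, truth = r$truth, sex = e$sex,
           individual_id = e$individual_id, config = e$config)
    })
  })
}

#' Pixel count of a rasterized disk
#'
#' Counts integer-grid pixels inside a disk of radius `r` centered at
#' (`cx`, `cy`); the same rasterization rule used by [render_elytron()], so
#' areas returned here match rendered ground truth.
#'
#' @param cx,cy disk center (pixels, may be fractional).
#' @param r radius in pixels.
#' @return Integer pixel count.
#' @export
disk_pixel_count <- function(cx, cy, r) {
  xs <- floor(cx - r):ceiling(cx + r)
  ys <- floor(cy - r):ceiling(cy + r)
  sum(outer((ys - cy)^2, (xs - cx)^2, "+") <= r^2)
}

#' Simulate cohort ground-truth spot areas without rendering images
#'
#' Draws the same per-individual jitters as [render_cohort()] and returns the
#' rasterized (pixel-count) spot areas normalized by the wing-ellipse pixel
#' area, skipping image synthesis. Used for statistical power and type-I
#' error simulations where the imaging stage is not under test.
#'
#' @inheritParams render_cohort
#' @return A data.frame of spot-area records with columns `individual_id`,
#'   `sex`, `treatment`, `spot_index`, `normalized_area`.
#' @export
cohort_truth_areas <- function(n_per_sex, base = NULL, female_scale = 1.3,
                               seed = NULL, radius_jitter_sdlog = 0.1,
                               center_jitter_sd = 2, rotation_jitter_sd = 4,
                               translation_jitter_sd = 3) {
  stopifnot(n_per_sex >= 1)
  if (is.null(base)) base <- synthetic_elytron_config(sex = "male")
  with_seed(seed, {
    cfgs <- draw_cohort_configs(n_per_sex, base, female_scale,
                                radius_jitter_sdlog, center_jitter_sd,
                                rotation_jitter_sd, translation_jitter_sd)
    H <- base$image_size[1]; W <- base$image_size[2]
    a <- base$wing_axes[1]; b <- base$wing_axes[2]
    cx <- (W + 1) / 2; cy <- (H + 1) / 2
    X <- matrix(rep(seq_len(W), each = H), H, W)
    Y <- matrix(rep(seq_len(H), times = W), H, W)
    wing_area <- sum(((X - cx) / a)^2 + ((Y - cy) / b)^2 <= 1)
    do.call(rbind, lapply(cfgs, function(e) {
      sp <- e$config$spots
      areas <- vapply(seq_len(nrow(sp)), function(k)
        disk_pixel_count(cx + sp$x[k], cy + sp$y[k], sp$radius[k]),
        numeric(1))
      data.frame(individual_id = e$individual_id, sex = toupper(substr(e$sex, 1, 1)),
                 treatment = "GFP_RNAi", spot_index = sp$spot_index,
                 normalized_area = areas / wing_area)
    }))
  })
}
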
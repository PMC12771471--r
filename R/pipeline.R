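#' Build the average ten-spot template from a segmented cohort
#'
#' Aligns each wing (and its spot mask) to the canonical frame, rescales all
#' wings to the cohort-common bounding rectangle, averages the rescaled spot
#' masks, and thresholds the average into the labeled ten-spot template.
#'
#' @param segmented list of per-individual lists with logical `wing` and
#'   `spots` masks (e.g. from [process_elytron_image()]).
#' @param expected_spots number of spots the template must separate.
#' @return A list of class `"cohort_template"`: the `template`
#'   ([template_from_average()] result), the common `bbox` and `target_wh`
#'   in the template canvas, the `average` image and the canvas `dim`.
#' @export
build_spot_template <- function(segmented, expected_spots = 10) {
  aligned <- lapply(segmented, function(s)
    align_wing(s$wing, companions = list(spots = s$spots)))
  scaled <- scale_to_common_bbox(aligned)
  avg <- build_average_image(lapply(scaled$companions, `[[`, "spots"))
  # expected spot centers: canonical layout scaled onto the common wing bbox
  lay <- elytra_spot_layout()
  bb <- scaled$bbox
  ref <- data.frame(
    x = (bb["xmin"] + bb["xmax"]) / 2 + lay$ex * (bb["xmax"] - bb["xmin"]) / 2,
    y = (bb["ymin"] + bb["ymax"]) / 2 + lay$ey * (bb["ymax"] - bb["ymin"]) / 2)
  tpl <- template_from_average(avg, expected_spots,
                               reference_centers =
                                 if (expected_spots == nrow(lay)) ref)
  structure(list(template = tpl, bbox = scaled$bbox,
                 target_wh = scaled$target_wh, average = avg,
                 dim = dim(avg)), class = "cohort_template")
}

# Map the template label map into an individual's aligned (unscaled) frame:
# inverse of the endpoint-matched bbox scaling used for template building.
template_in_frame <- function(cohort_template, wing_bbox, out_dim) {
  tb <- cohort_template$bbox
  H <- out_dim[1]; W <- out_dim[2]
  X <- matrix(rep(seq_len(W), each = H), H, W)
  Y <- matrix(rep(seq_len(H), times = W), H, W)
  xs <- round(tb["xmin"] + (X - wing_bbox["xmin"]) *
                (tb["xmax"] - tb["xmin"]) /
                max(wing_bbox["xmax"] - wing_bbox["xmin"], 1))
  ys <- round(tb["ymin"] + (Y - wing_bbox["ymin"]) *
                (tb["ymax"] - tb["ymin"]) /
                max(wing_bbox["ymax"] - wing_bbox["ymin"], 1))
  lm <- cohort_template$template$label_map
  ok <- xs >= 1 & xs <= ncol(lm) & ys >= 1 & ys <= nrow(lm)
  out <- matrix(0L, H, W)
  out[ok] <- lm[cbind(ys[ok], xs[ok])]
  out
}

#' Quantify the ten spot areas of one segmented elytron
#'
#' Rigidly aligns the wing and spot masks to the canonical frame, projects
#' the cohort template into that frame (undoing the bounding-box scaling, so
#' areas are measured on unscaled masks), splits the spot mask with the
#' template-constrained watershed, and measures normalized areas.
#'
#' @param wing,spots logical masks for one individual.
#' @param cohort_template a [build_spot_template()] result.
#' @param min_distance peak separation for [distance_peaks()].
#' @return A list with `areas` (from [measure_areas()]), the
#'   `label_map`, aligned masks, and QC fields.
#' @export
quantify_elytron <- function(wing, spots, cohort_template, min_distance = 8) {
  al <- align_wing(wing, companions = list(spots = spots),
                   out_dim = cohort_template$dim)
  wing_a <- al$wing; spots_a <- al$companions$spots
  local_template <- template_in_frame(cohort_template, mask_bbox(wing_a),
                                      dim(wing_a))
  peaks <- distance_peaks(spots_a, min_distance)
  if (nrow(peaks) > 0) {
    lbl <- assign_peaks_to_template(peaks, local_template)
    lm <- constrained_watershed(spots_a, peaks, lbl)
  } else {
    lm <- suppressWarnings(constrained_watershed(spots_a, peaks, integer(0)))
  }
  list(areas = measure_areas(lm, wing_a), label_map = lm,
       wing = wing_a, spots = spots_a, template_local = local_template)
}

#' Quantify normalized spot areas across a cohort of elytron images
#'
#' Full image pipeline: segmentation of each image, cohort template
#' construction, constrained-watershed splitting and area measurement. The
#' output table has one row per individual and spot index, matching the raw
#' spot-morphology table consumed by [run_dimorphism_battery()].
#'
#' @param images list of H x W x 3 RGB arrays.
#' @param meta data.frame with one row per image: `individual_id`, `sex`
#'   (`"F"`/`"M"`), `treatment`.
#' @param params a [seg_params()] object.
#' @param template optionally a precomputed [build_spot_template()] result;
#'   built from this cohort when NULL.
#' @param min_distance peak separation for [distance_peaks()].
#' @return A list with `records` (data.frame: `individual_id`, `sex`,
#'   `treatment`, `spot_index`, `normalized_area`), the `template`, and
#'   per-individual `details`.
#' @export
quantify_cohort <- function(images, meta, params = seg_params(),
                            template = NULL, min_distance = 8) {
  stopifnot(length(images) == nrow(meta))
  segmented <- lapply(images, process_elytron_image, params = params)
  if (is.null(template)) template <- build_spot_template(segmented)
  details <- lapply(segmented, function(s)
    quantify_elytron(s$wing, s$spots, template, min_distance))
  records <- do.call(rbind, lapply(seq_along(details), function(i)
    data.frame(individual_id = meta$individual_id[i], sex = meta$sex[i],
               treatment = meta$treatment[i],
               spot_index = details[[i]]$areas$spot_index,
               normalized_area = details[[i]]$areas$normalized_area)))
  list(records = records, template = template, details = details)
}
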
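distance_transform <- function(mask) {
  as.matrix(EBImage::imageData(EBImage::distmap(mask * 1)))
}

shift_mat <- function(m, dr, dc, fill = -Inf) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(fill, H, W)
  rs <- max(1, 1 + dr):min(H, H + dr)
  cs <- max(1, 1 + dc):min(W, W + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Peaks of the distance transform of a spot mask
#'
#' Computes the Euclidean distance transform of the mask and returns its
#' local maxima (8-neighbourhood); plateaus of equal distance collapse to a
#' single representative (maximal distance, then lowest row, then lowest
#' column), and remaining peaks are thinned greedily (descending distance,
#' ties by row then column) so that kept peaks are at least `min_distance`
#' pixels apart.
#'
#' @param spots logical spot mask.
#' @param min_distance minimum pairwise peak separation in pixels; defaults
#'   to 8 (the contour-smoothing radius).
#' @return data.frame with columns `row`, `col`, `dist` (may have 0 rows).
#' @export
distance_peaks <- function(spots, min_distance = 8) {
  empty <- data.frame(row = integer(0), col = integer(0), dist = numeric(0))
  if (!any(spots)) return(empty)
  d <- distance_transform(spots)
  nb_max <- matrix(-Inf, nrow(d), ncol(d))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb_max <- pmax(nb_max, shift_mat(d, dr, dc))
  }
  cand <- spots & d >= nb_max
  if (!any(cand)) return(empty)
  lab <- label_components(cand)
  reps <- do.call(rbind, lapply(seq_len(max(lab)), function(k) {
    pix <- which(lab == k, arr.ind = TRUE)
    dv <- d[pix]
    sel <- order(-dv, pix[, 1], pix[, 2])[1]
    data.frame(row = pix[sel, 1], col = pix[sel, 2], dist = dv[sel])
  }))
  reps <- reps[order(-reps$dist, reps$row, reps$col), , drop = FALSE]
  keep <- logical(nrow(reps))
  for (i in seq_len(nrow(reps))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    dd <- sqrt((reps$row[keep] - reps$row[i])^2 +
               (reps$col[keep] - reps$col[i])^2)
    keep[i] <- all(dd >= min_distance)
  }
  out <- reps[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign distance-transform peaks to template spot regions
#'
#' A peak lying inside a template region takes that region's label;
#' otherwise it takes the label of the nearest template region by Euclidean
#' distance to the region's pixels, ties resolving to the lower label.
#'
#' @param peaks data.frame from [distance_peaks()].
#' @param template a [template_from_average()] object, or a bare integer
#'   label matrix.
#' @return Integer vector of template labels, one per peak.
#' @export
assign_peaks_to_template <- function(peaks, template) {
  label_map <- if (inherits(template, "spot_template")) template$label_map
               else template
  if (nrow(peaks) == 0) return(integer(0))
  labels <- sort(unique(label_map[label_map > 0]))
  if (length(labels) == 0) stop("template has no labeled regions")
  pix_by_label <- lapply(labels, function(k) which(label_map == k,
                                                  arr.ind = TRUE))
  vapply(seq_len(nrow(peaks)), function(i) {
    at <- label_map[peaks$row[i], peaks$col[i]]
    if (at > 0) return(as.integer(at))
    best <- NA_integer_; bestd <- Inf
    for (j in seq_along(labels)) {
      p <- pix_by_label[[j]]
      dmin <- min((p[, 1] - peaks$row[i])^2 + (p[, 2] - peaks$col[i])^2)
      if (dmin < bestd - 1e-9) { bestd <- dmin; best <- labels[j] }
    }
    as.integer(best)
  }, integer(1))
}

#' Template-constrained marker-based watershed of a spot mask
#'
#' Peaks sharing a template label are merged into a single marker, then a
#' marker-based watershed of the negated Euclidean distance transform is
#' flooded within the spot mask (8-connectivity). Merging markers by
#' template label suppresses the over-segmentation that multiple
#' distance-transform peaks inside one complex spot would otherwise cause;
#' output labels are template labels. Fragments not connected to any marker
#' keep label 0 and are reported in the QC field.
#'
#' @param spots logical spot mask.
#' @param peaks data.frame from [distance_peaks()].
#' @param peak_labels integer labels per peak (template labels from
#'   [assign_peaks_to_template()], or `seq_len(nrow(peaks))` for an
#'   unconstrained watershed with one basin per peak).
#' @return A list of class `"spot_label_map"`: `labels` (integer matrix),
#'   `provenance` (per-label peak coordinates), `qc` (list with
#'   `n_unlabeled_pixels`, `n_fragments`).
#' @export
constrained_watershed <- function(spots, peaks, peak_labels) {
  if (nrow(peaks) == 0) {
    warning("no peaks supplied; returning an empty label map")
    return(structure(list(labels = matrix(0L, nrow(spots), ncol(spots)),
                          provenance = list(),
                          qc = list(n_unlabeled_pixels = sum(spots),
                                    n_fragments = max(label_components(spots)))),
                     class = "spot_label_map"))
  }
  stopifnot(nrow(peaks) == length(peak_labels), all(peak_labels > 0))
  d <- distance_transform(spots)
  markers <- matrix(0L, nrow(spots), ncol(spots))
  markers[cbind(peaks$row, peaks$col)] <- as.integer(peak_labels)
  labels <- marker_watershed_cpp(d, markers, spots, 8L)
  unreached <- spots & labels == 0
  structure(list(
    labels = labels,
    provenance = split(peaks[, c("row", "col")], peak_labels),
    qc = list(n_unlabeled_pixels = sum(unreached),
              n_fragments = if (any(unreached))
                max(label_components(unreached)) else 0L)
  ), class = "spot_label_map")
}

#' Normalized per-spot areas
#'
#' For each template label 1..`n_spots`, the labeled pixel count divided by
#' the wing pixel count (the total elytral area); labels absent from the map
#' are reported with area 0.
#'
#' @param label_map a [constrained_watershed()] result or bare label matrix.
#' @param wing logical wing mask (nonempty).
#' @param n_spots number of template spots (default 10).
#' @return data.frame with `spot_index`, `pixel_area`, `normalized_area`.
#' @export
measure_areas <- function(label_map, wing, n_spots = 10) {
  labels <- if (inherits(label_map, "spot_label_map")) label_map$labels
            else label_map
  if (!any(wing)) stop("wing mask is empty")
  counts <- tabulate(labels[labels > 0], nbins = n_spots)
  data.frame(spot_index = seq_len(n_spots), pixel_area = counts,
             normalized_area = counts / sum(wing))
}
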
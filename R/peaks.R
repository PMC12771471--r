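# data.frame with 0-based half-open start/end -> GRanges (1-based closed)
intervals_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = if ("sequence_id" %in% names(df)) df$sequence_id else "seq",
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end))
}

#' Count motif hits per open-chromatin peak
#'
#' A hit belongs to a peak iff the two intervals overlap by at least 1 bp
#' (0-based half-open convention on both sides). Peaks with at least one
#' hit form class A (with Dsx motifs), the rest class B (without).
#'
#' @param hits data.frame of [scan_pssm()] hits.
#' @param peaks data.frame of peak intervals (`sequence_id`, `start`,
#'   `end`, plus metadata such as `allele`).
#' @return `peaks` with `n_motifs` and logical `has_motif` columns added.
#' @export
intersect_hits_peaks <- function(hits, peaks) {
  if (nrow(peaks) == 0) {
    peaks$n_motifs <- integer(0); peaks$has_motif <- logical(0)
    return(peaks)
  }
  if (nrow(hits) == 0) {
    peaks$n_motifs <- 0L
  } else {
    peaks$n_motifs <- GenomicRanges::countOverlaps(
      intervals_to_granges(peaks), intervals_to_granges(hits),
      minoverlap = 1L)
  }
  peaks$has_motif <- peaks$n_motifs >= 1
  peaks
}

#' With/without-motif peak ratio per allele
#'
#' For each allele, tabulates the number of peaks, total motif hits inside
#' peaks, peaks with at least one motif (A), peaks without (B), and the
#' ratio A/B reported to 3 significant figures (undefined when B = 0, in
#' which case `ratio` is NA and `ratio_defined` FALSE).
#'
#' @param annotated data.frame from [intersect_hits_peaks()] with an
#'   `allele` column.
#' @param allele_order optional ordering of the rows; alleles with no peaks
#'   are dropped with a warning.
#' @return data.frame with one row per allele: `allele`, `n_peaks`,
#'   `n_motifs_in_peaks`, `n_with_motif`, `n_without_motif`, `ratio`,
#'   `ratio_defined`.
#' @export
ratio_table <- function(annotated, allele_order = NULL) {
  stopifnot("allele" %in% names(annotated))
  if (is.null(allele_order)) allele_order <- unique(annotated$allele)
  missing <- setdiff(allele_order, unique(annotated$allele))
  if (length(missing) > 0)
    warning("allele group(s) with no peaks omitted: ",
            paste(missing, collapse = ", "))
  allele_order <- setdiff(allele_order, missing)
  out <- do.call(rbind, lapply(allele_order, function(al) {
    p <- annotated[annotated$allele == al, ]
    A <- sum(p$has_motif); B <- sum(!p$has_motif)
    data.frame(allele = al, n_peaks = nrow(p),
               n_motifs_in_peaks = sum(p$n_motifs),
               n_with_motif = A, n_without_motif = B,
               ratio = if (B > 0) signif(A / B, 3) else NA_real_,
               ratio_defined = B > 0)
  }))
  rownames(out) <- NULL
  out
}

#' Fraction of reads in peaks (FRiP)
#'
#' Fraction of read intervals overlapping any peak by at least 1 bp, with
#' the ENCODE-style quality verdict (ideal > 0.3, acceptable > 0.2).
#'
#' @param reads data.frame of read intervals (`sequence_id`, `start`,
#'   `end`; 0-based half-open).
#' @param peaks data.frame of peak intervals.
#' @return A list of class `"frip"`: `frip` in `[0, 1]`, `n_reads`,
#'   `verdict` (`"ideal"`, `"acceptable"`, or `"poor"`).
#' @export
frip <- function(reads, peaks) {
  if (nrow(reads) == 0) stop("FRiP is undefined with zero reads")
  f <- if (nrow(peaks) == 0) 0 else
    mean(GenomicRanges::countOverlaps(intervals_to_granges(reads),
                                      intervals_to_granges(peaks),
                                      minoverlap = 1L) > 0)
  structure(list(frip = f, n_reads = nrow(reads),
                 verdict = if (f > 0.3) "ideal"
                           else if (f > 0.2) "acceptable" else "poor"),
            class = "frip")
}

overlaps_any <- function(start, end, starts, ends) {
  # 0-based half-open intervals overlap iff start < other_end & end > other_start
  any(start < ends & end > starts)
}

#' Classify peaks as conserved or lineage-specific
#'
#' Using a precomputed ortholog interval map between allele scaffolds
#' (pairs of corresponding intervals), a peak is conserved iff, for every
#' other allele, some map pair links a region overlapping the peak to a
#' partner region that overlaps a peak of that allele; otherwise it is
#' lineage-specific. With `min_other_alleles` the strict all-other-alleles
#' requirement can be relaxed to a k-of-n rule.
#'
#' @param peaks data.frame of peaks across all alleles (`sequence_id`,
#'   `start`, `end`, `allele`).
#' @param ortholog_map data.frame of interval correspondences: `seq_a`,
#'   `start_a`, `end_a`, `seq_b`, `start_b`, `end_b` (0-based half-open;
#'   treated symmetrically).
#' @param min_other_alleles number of other alleles in which an orthologous
#'   peak must be found; default `NULL` means all of them (strict).
#' @return `peaks` with a `conservation` column
#'   (`"conserved"`/`"lineage_specific"`).
#' @export
classify_conservation <- function(peaks, ortholog_map,
                                  min_other_alleles = NULL) {
  stopifnot(all(c("sequence_id", "start", "end", "allele") %in% names(peaks)))
  alleles <- unique(peaks$allele)
  if (nrow(ortholog_map) == 0) {
    warning("empty ortholog map: all peaks classified lineage-specific")
    peaks$conservation <- "lineage_specific"
    return(peaks)
  }
  # symmetrize the map
  map <- rbind(
    data.frame(seq_a = ortholog_map$seq_a, start_a = ortholog_map$start_a,
               end_a = ortholog_map$end_a, seq_b = ortholog_map$seq_b,
               start_b = ortholog_map$start_b, end_b = ortholog_map$end_b),
    data.frame(seq_a = ortholog_map$seq_b, start_a = ortholog_map$start_b,
               end_a = ortholog_map$end_b, seq_b = ortholog_map$seq_a,
               start_b = ortholog_map$start_a, end_b = ortholog_map$end_a))
  seq2allele <- unique(peaks[, c("sequence_id", "allele")])
  map$allele_b <- seq2allele$allele[match(map$seq_b, seq2allele$sequence_id)]
  peaks$conservation <- vapply(seq_len(nrow(peaks)), function(i) {
    p <- peaks[i, ]
    others <- setdiff(alleles, p$allele)
    need <- if (is.null(min_other_alleles)) length(others)
            else min(min_other_alleles, length(others))
    found <- 0L
    for (al in others) {
      m <- map[map$seq_a == p$sequence_id & !is.na(map$allele_b) &
                 map$allele_b == al, , drop = FALSE]
      ok <- FALSE
      for (j in seq_len(nrow(m))) {
        if (p$start < m$end_a[j] && p$end > m$start_a[j]) {
          q <- peaks[peaks$allele == al &
                       peaks$sequence_id == m$seq_b[j], , drop = FALSE]
          if (nrow(q) > 0 &&
              overlaps_any(m$start_b[j], m$end_b[j], q$start, q$end)) {
            ok <- TRUE
            break
          }
        }
      }
      found <- found + ok
    }
    if (found >= need) "conserved" else "lineage_specific"
  }, character(1))
  peaks
}

#' Fraction of peaks shared between the sexes
#'
#' Merges the union of female and male peaks into clusters (any >= 1 bp
#' overlap joins intervals) and reports the fraction of clusters containing
#' at least one peak from each sex.
#'
#' @param peaks_f,peaks_m data.frames of peak intervals for female and male
#'   samples (`sequence_id`, `start`, `end`).
#' @return Fraction in `[0, 1]`.
#' @export
sex_shared_fraction <- function(peaks_f, peaks_m) {
  if (nrow(peaks_f) == 0 && nrow(peaks_m) == 0)
    stop("both peak sets are empty")
  if (nrow(peaks_f) == 0 || nrow(peaks_m) == 0) return(0)
  gf <- intervals_to_granges(peaks_f)
  gm <- intervals_to_granges(peaks_m)
  merged <- GenomicRanges::reduce(c(gf, gm))
  shared <- GenomicRanges::countOverlaps(merged, gf) > 0 &
    GenomicRanges::countOverlaps(merged, gm) > 0
  mean(shared)
}
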
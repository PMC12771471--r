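#' Configuration for a motif-planted synthetic genomic sequence
#'
#' @param length sequence length in bp.
#' @param gc_fraction GC content of the i.i.d. background (default 0.5).
#' @param peaks data.frame of open-chromatin intervals with 0-based
#'   half-open `start`, `end` (non-overlapping, within the sequence) and
#'   optional metadata columns (`allele`, `sex`, `name`).
#' @param planted_motifs data.frame with `position` (0-based start of the
#'   planted consensus) and `strand` (`"+"`/`"-"`); may have 0 rows.
#' @param seed integer seed.
#' @return A list of class `"genome_config"`.
#' @export
synthetic_genome_config <- function(length, gc_fraction = 0.5,
                                    peaks = data.frame(start = integer(0),
                                                       end = integer(0)),
                                    planted_motifs =
                                      data.frame(position = integer(0),
                                                 strand = character(0)),
                                    seed = NULL) {
  stopifnot(length >= 1, gc_fraction >= 0, gc_fraction <= 1)
  if (nrow(peaks) > 0) {
    stopifnot(all(peaks$start >= 0), all(peaks$end <= length),
              all(peaks$start < peaks$end))
    o <- order(peaks$start)
    if (any(peaks$end[o][-nrow(peaks)] > peaks$start[o][-1]))
      stop("peaks must be non-overlapping")
  }
  structure(list(length = length, gc_fraction = gc_fraction, peaks = peaks,
                 planted_motifs = planted_motifs, seed = seed),
            class = "genome_config")
}

#' Synthesize a genomic sequence with peaks and planted motif instances
#'
#' Draws an i.i.d. background sequence at the configured GC content and
#' overwrites each planted position with the PSSM consensus (its reverse
#' complement for minus-strand plantings). Planted motifs must not overlap
#' one another.
#'
#' @param config a [synthetic_genome_config()] object.
#' @param pssm a [pssm()] object supplying the consensus.
#' @param sequence_id name given to the sequence.
#' @return A list with `sequence` (a `Biostrings::DNAStringSet` of length
#'   1), `peaks` (the configured intervals with `sequence_id` attached) and
#'   `truth` (the planted `position`, `strand`, and consensus).
#' @export
synthesize_genome <- function(config, pssm, sequence_id = "synthetic") {
  stopifnot(inherits(config, "genome_config"), inherits(pssm, "pssm"))
  L <- pssm$length
  pm <- config$planted_motifs
  if (nrow(pm) > 0) {
    stopifnot(all(pm$position >= 0), all(pm$position + L <= config$length),
              all(pm$strand %in% c("+", "-")))
    o <- order(pm$position)
    if (any(diff(pm$position[o]) < L))
      stop("planted motifs must not overlap")
  }
  gc <- config$gc_fraction
  bases <- with_seed(config$seed,
    sample(BASES, config$length, replace = TRUE,
           prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)))
  cons <- strsplit(pssm_consensus(pssm), "")[[1]]
  rc <- rev(c(A = "T", C = "G", G = "C", T = "A")[cons])
  for (i in seq_len(nrow(pm))) {
    ins <- if (pm$strand[i] == "+") cons else rc
    bases[pm$position[i] + seq_len(L)] <- ins
  }
  peaks <- config$peaks
  if (nrow(peaks) > 0) peaks$sequence_id <- sequence_id
  truth <- pm
  if (nrow(truth) > 0) {
    truth$sequence_id <- sequence_id
    truth$consensus <- pssm_consensus(pssm)
  }
  seqs <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
  names(seqs) <- sequence_id
  list(sequence = seqs, peaks = peaks, truth = truth)
}

#' Lay out non-overlapping peaks and plant a designed motif count
#'
#' Convenience builder for allele fixtures: creates `n_with + n_without`
#' peaks of equal width separated by fixed gaps, and plants `motif_total`
#' consensus copies inside the first `n_with` peaks (at least one each,
#' extras distributed round-robin), leaving the remaining peaks motif-free.
#'
#' @param n_with,n_without numbers of peaks with and without planted motifs.
#' @param motif_total total planted motif copies (>= `n_with`).
#' @param pssm a [pssm()] object.
#' @param allele label attached to the peaks.
#' @param peak_width,gap peak width and inter-peak gap in bp.
#' @param margin flanking sequence before the first and after the last peak.
#' @param seed integer seed for the background sequence.
#' @return A [synthesize_genome()] result whose `peaks` carry `allele`.
#' @export
plant_allele_fixture <- function(n_with, n_without, motif_total, pssm,
                                 allele = "allele", peak_width = 120,
                                 gap = 90, margin = 200, seed = NULL) {
  stopifnot(motif_total >= n_with)
  n <- n_with + n_without
  starts <- margin + (seq_len(n) - 1) * (peak_width + gap)
  peaks <- data.frame(start = starts, end = starts + peak_width,
                      allele = allele,
                      name = sprintf("%s_peak%02d", allele, seq_len(n)))
  L <- pssm$length
  per_peak <- rep(0L, n_with)
  for (i in seq_len(motif_total))
    per_peak[(i - 1) %% n_with + 1] <- per_peak[(i - 1) %% n_with + 1] + 1L
  max_fit <- floor((peak_width - 6) / (L + 4))
  if (any(per_peak > max_fit))
    stop("peak_width too small for the requested motif density")
  planted <- do.call(rbind, lapply(seq_len(n_with), function(i) {
    k <- per_peak[i]
    if (k == 0) return(NULL)
    data.frame(position = peaks$start[i] + 3 + (seq_len(k) - 1) * (L + 4),
               strand = rep(c("+", "-"), length.out = k))
  }))
  if (is.null(planted))
    planted <- data.frame(position = integer(0), strand = character(0))
  total_len <- margin * 2 + n * peak_width + (n - 1) * gap
  cfg <- synthetic_genome_config(total_len, gc_fraction = 0.5, peaks = peaks,
                                 planted_motifs = planted, seed = seed)
  synthesize_genome(cfg, pssm, sequence_id = allele)
}
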
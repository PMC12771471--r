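BASES <- c("A", "C", "G", "T")

#' Position-specific scoring matrix
#'
#' Builds a PSSM from a 4 x L count (or frequency) matrix. Probabilities are
#' `(count + pseudocount) / (column total + 4 * pseudocount)` and the
#' log-likelihood-ratio score matrix is `log(p / background)` in natural
#' log (the score scale on which the detection threshold of 5 is applied).
#'
#' @param counts numeric 4 x L matrix with rows A, C, G, T.
#' @param background base frequencies (default uniform 0.25).
#' @param pseudocount added to every cell (default 0.01).
#' @param motif_id identifier carried through to hits.
#' @return A list of class `"pssm"`: `counts`, `probs`, `log_odds`,
#'   `background`, `pseudocount`, `motif_id`, `length`.
#' @export
pssm <- function(counts, background = c(A = 0.25, C = 0.25, G = 0.25,
                                        T = 0.25),
                 pseudocount = 0.01, motif_id = "motif") {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 4, ncol(counts) >= 1, all(counts >= 0),
            pseudocount > 0, length(background) == 4,
            abs(sum(background) - 1) < 1e-6)
  rownames(counts) <- BASES
  probs <- sweep(counts + pseudocount, 2,
                 colSums(counts) + 4 * pseudocount, "/")
  structure(list(counts = counts, probs = probs,
                 log_odds = log(probs / background),
                 background = background, pseudocount = pseudocount,
                 motif_id = motif_id, length = ncol(counts)),
            class = "pssm")
}

#' Read a JASPAR-format count matrix
#'
#' Parses the plain-text JASPAR pfm layout: a `>ID name` header line
#' followed by four rows `A [ 1 2 3 ]` (brackets optional).
#'
#' @param path file path.
#' @inheritParams pssm
#' @return A [pssm()] object.
#' @export
read_jaspar <- function(path, background = c(A = 0.25, C = 0.25, G = 0.25,
                                             T = 0.25),
                        pseudocount = 0.01) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  header <- grep("^>", lines)
  if (length(header) != 1) stop("expected exactly one '>' header line")
  id <- strsplit(sub("^>", "", lines[header]), "\\s+")[[1]][1]
  rows <- lines[-header]
  if (length(rows) != 4) stop("expected 4 base rows after the header")
  mat <- t(vapply(rows, function(l) {
    l <- gsub("[][]", " ", l)
    parts <- strsplit(trimws(l), "\\s+")[[1]]
    as.numeric(parts[-1])
  }, numeric(length(strsplit(gsub("[][]", " ",
                                  trimws(rows[1])), "\\s+")[[1]]) - 1)))
  base_order <- toupper(substr(trimws(rows), 1, 1))
  if (!setequal(base_order, BASES)) stop("rows must be labelled A, C, G, T")
  mat <- mat[match(BASES, base_order), , drop = FALSE]
  pssm(mat, background = background, pseudocount = pseudocount,
       motif_id = id)
}

#' Consensus sequence of a PSSM
#'
#' @param x a [pssm()] object.
#' @return Character string of the per-column maximal bases (ties to the
#'   earlier base in A, C, G, T order).
#' @export
pssm_consensus <- function(x) {
  stopifnot(inherits(x, "pssm"))
  paste(BASES[apply(x$probs, 2, which.max)], collapse = "")
}

#' Maximal attainable PSSM score
#'
#' @param x a [pssm()] object.
#' @return Sum of the per-column maxima of the log-odds matrix.
#' @export
pssm_max_score <- function(x) sum(apply(x$log_odds, 2, max))

revcomp_pssm_matrix <- function(M) M[4:1, ncol(M):1, drop = FALSE]

encode_dna <- function(seq) {
  if (inherits(seq, "DNAString") || inherits(seq, "DNAStringSet"))
    seq <- as.character(seq)[1]
  match(strsplit(toupper(seq), "")[[1]], BASES)  # N and others -> NA
}

score_windows <- function(code, M) {
  L <- ncol(M); n <- length(code)
  nw <- n - L + 1
  if (nw < 1) return(numeric(0))
  s <- numeric(nw)
  for (i in seq_len(L)) {
    idx <- code[i:(i + nw - 1)]
    s <- s + M[cbind(idx, i)]  # NA (ambiguous base) propagates
  }
  s
}

#' Scan a sequence for PSSM hits above a log-likelihood threshold
#'
#' Scores every length-L window on the forward strand (and, by default, the
#' reverse strand via the reverse-complemented matrix) as the sum of
#' per-position log-likelihood ratios `log(p_i(base)/background(base))`,
#' and reports windows scoring at least `threshold` (default 5, the
#' detection threshold for Dsx-binding sites). Windows containing ambiguous
#' bases are skipped; minus-strand hits are reported in forward coordinates.
#'
#' @param seq character string, `DNAString`, or named element of a
#'   `DNAStringSet`.
#' @param pssm a [pssm()] object.
#' @param threshold minimum log-likelihood-ratio score (natural log).
#' @param both_strands scan the reverse strand too (default TRUE).
#' @param sequence_id identifier recorded in the hit table.
#' @return data.frame of hits: `sequence_id`, `start`, `end` (0-based
#'   half-open), `strand`, `score`, `motif_id`, sorted by `start` then
#'   strand.
#' @export
scan_pssm <- function(seq, pssm, threshold = 5, both_strands = TRUE,
                      sequence_id = "seq") {
  stopifnot(inherits(pssm, "pssm"))
  code <- encode_dna(seq)
  L <- pssm$length
  empty <- data.frame(sequence_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      score = numeric(0), motif_id = character(0))
  if (length(code) < L) return(empty)
  hit_frame <- function(scores, strand) {
    ok <- which(!is.na(scores) & scores >= threshold)
    if (length(ok) == 0) return(NULL)
    data.frame(sequence_id = sequence_id, start = ok - 1L,
               end = ok - 1L + L, strand = strand, score = scores[ok],
               motif_id = pssm$motif_id)
  }
  out <- list(hit_frame(score_windows(code, pssm$log_odds), "+"))
  if (both_strands)
    out <- c(out, list(hit_frame(
      score_windows(code, revcomp_pssm_matrix(pssm$log_odds)), "-")))
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Synthetic Dsx-like binding motif
#'
#' Loads the package's bundled 13-bp position count matrix, a synthetic
#' stand-in with a DM-domain-like CAATGT core (consensus GCAACAATGTAAC).
#' It emulates the shape of a JASPAR Dsx matrix for fixtures and
#' simulations but is deliberately non-palindromic, so a planted site
#' scores above the detection threshold on one strand only and planted
#' motif counts are unambiguous; it is not a measured binding profile.
#'
#' @inheritParams pssm
#' @return A [pssm()] object.
#' @export
dsx_motif_synthetic <- function(background = c(A = 0.25, C = 0.25, G = 0.25,
                                               T = 0.25),
                                pseudocount = 0.01) {
  read_jaspar(system.file("extdata", "dsx_motif_synthetic.jaspar",
                          package = "elytramorph", mustWork = TRUE),
              background = background, pseudocount = pseudocount)
}
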
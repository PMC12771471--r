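#' Read an RGB image file
#'
#' @param path PNG/TIFF/JPEG file.
#' @return H x W x 3 numeric array with intensities in `[0, 255]`.
#' @export
read_rgb_image <- function(path) {
  img <- EBImage::readImage(path)
  d <- EBImage::imageData(img)  # EBImage stores x (columns) first
  if (length(dim(d)) == 2) d <- array(rep(d, 3), dim = c(dim(d), 3))
  if (dim(d)[3] > 3) d <- d[, , 1:3]
  aperm(d, c(2, 1, 3)) * 255
}

#' Write an RGB image or mask as 8-bit PNG
#'
#' Masks (logical matrices) are written as 0/255 grayscale; label maps
#' (integer matrices) as 16-bit grayscale; RGB arrays as 8-bit color.
#'
#' @param x H x W x 3 array in `[0, 255]`, logical mask, or integer label
#'   matrix.
#' @param path output path.
#' @export
write_image_png <- function(x, path) {
  if (is.logical(x)) {
    EBImage::writeImage(EBImage::Image(t(x) * 1), path, type = "png")
  } else if (is.matrix(x)) {
    EBImage::writeImage(EBImage::Image(t(x) / 65535), path, type = "png",
                        bits.per.sample = 16L)
  } else {
    EBImage::writeImage(EBImage::Image(aperm(x, c(2, 1, 3)) / 255,
                                       colormode = "Color"),
                        path, type = "png")
  }
  invisible(path)
}

#' Read intervals from a BED file
#'
#' @param path BED file (BED3-BED6).
#' @return data.frame with `sequence_id`, `start`, `end` (0-based
#'   half-open) and, when present, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.frame(sequence_id = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr))
  md <- as.data.frame(S4Vectors::mcols(gr))
  if ("name" %in% names(md)) out$name <- md$name
  if ("score" %in% names(md)) out$score <- md$score
  st <- as.character(GenomicRanges::strand(gr))
  if (any(st != "*")) out$strand <- st
  out
}

#' Write intervals to a BED6 file
#'
#' @param df data.frame with `sequence_id`, `start`, `end` (0-based
#'   half-open) and optional `name`, `score`, `strand`.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  gr <- intervals_to_granges(df)
  if ("name" %in% names(df)) names(gr) <- df$name
  if ("score" %in% names(df)) gr$score <- df$score
  if ("strand" %in% names(df))
    GenomicRanges::strand(gr) <- ifelse(df$strand %in% c("+", "-"),
                                        df$strand, "*")
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write a FASTA file
#'
#' @param seqs a `Biostrings::DNAStringSet`.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a FASTA file
#'
#' @param path FASTA file.
#' @return A `Biostrings::DNAStringSet`.
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' Write a data.frame as TSV
#'
#' @param df data.frame.
#' @param path output path.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv <- function(path) read.delim(path, check.names = FALSE)
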
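test_that("the PSSM scanner equals an exhaustive per-window scorer", {
  mot <- dsx_motif_synthetic()
  set.seed(81)
  for (rep in 1:3) {
    s <- random_dna(500)
    # use a permissive threshold so background windows appear in both outputs
    for (thr in c(-20, 5)) {
      got <- scan_pssm(s, mot, threshold = thr)
      oracle <- brute_scan(s, mot$log_odds, thr)
      expect_identical(nrow(got), nrow(oracle))
      expect_equal(got$start, oracle$start)
      expect_identical(got$strand, oracle$strand)
      expect_equal(got$score, oracle$score, tolerance = 1e-12)
    }
  }
})

test_that("scanning respects strand symmetry and skips N windows", {
  mot <- dsx_motif_synthetic()
  set.seed(82)
  s <- random_dna(300)
  h_fwd <- scan_pssm(s, mot, threshold = -15)
  h_rc <- scan_pssm(revcomp_chr(s), mot, threshold = -15)
  # mirrored coordinates, flipped strands, same score multiset
  expect_identical(nrow(h_fwd), nrow(h_rc))
  mirrored <- data.frame(start = nchar(s) - h_rc$end,
                         strand = ifelse(h_rc$strand == "+", "-", "+"),
                         score = h_rc$score)
  mirrored <- mirrored[order(mirrored$start, mirrored$strand), ]
  expect_equal(h_fwd$start, mirrored$start)
  expect_identical(h_fwd$strand, mirrored$strand)
  expect_equal(h_fwd$score, mirrored$score, tolerance = 1e-12)

  sN <- paste0(substr(s, 1, 100), "N", substr(s, 102, 300))
  hN <- scan_pssm(sN, mot, threshold = -1e6)
  expect_false(any(hN$start <= 100 & hN$end > 100))

  expect_identical(nrow(scan_pssm("ACGT", mot)), 0L)
})

test_that("hit-peak intersection follows half-open overlap and partitions", {
  peaks <- data.frame(sequence_id = "s", start = c(0, 100, 200),
                      end = c(50, 150, 260), allele = "x")
  hits <- data.frame(sequence_id = "s", start = c(50, 140, 210, 220),
                     end = c(63, 153, 223, 233), strand = "+", score = 9)
  ann <- intersect_hits_peaks(hits, peaks)
  # a hit starting exactly at a peak's end does not overlap it
  expect_identical(ann$n_motifs, c(0L, 1L, 2L))
  expect_identical(ann$has_motif, c(FALSE, TRUE, TRUE))
  expect_identical(sum(ann$has_motif) + sum(!ann$has_motif), nrow(peaks))

  # all-pairs oracle on random intervals
  set.seed(83)
  p2 <- data.frame(sequence_id = "s", start = sort(sample(0:900, 20)) * 1)
  p2$end <- p2$start + sample(10:80, 20, TRUE)
  h2 <- data.frame(sequence_id = "s", start = sample(0:950, 40, TRUE))
  h2$end <- h2$start + 13
  p2$allele <- "x"
  got <- intersect_hits_peaks(h2, p2)$n_motifs
  oracle <- vapply(seq_len(nrow(p2)), function(i)
    sum(h2$start < p2$end[i] & h2$end > p2$start[i]), integer(1))
  expect_identical(got, oracle)
})

test_that("ratio table reproduces worked A/B examples to 3 significant figures", {
  mk <- function(allele, A, B) data.frame(
    sequence_id = allele, start = seq_len(A + B) * 100,
    end = seq_len(A + B) * 100 + 50, allele = allele,
    n_motifs = rep(c(1L, 0L), c(A, B)), has_motif = rep(c(TRUE, FALSE), c(A, B)))
  ann <- rbind(mk("Red-nSpots", 5, 3), mk("Black-2Spots", 11, 10),
               mk("Even", 7, 7), mk("NoB", 4, 0))
  rt <- ratio_table(ann)
  expect_equal(rt$ratio[rt$allele == "Red-nSpots"], 1.67)
  expect_equal(rt$ratio[rt$allele == "Black-2Spots"], 1.10)
  expect_equal(rt$ratio[rt$allele == "Even"], 1.00)
  expect_true(is.na(rt$ratio[rt$allele == "NoB"]))
  expect_false(rt$ratio_defined[rt$allele == "NoB"])
  expect_true(all(rt$n_with_motif + rt$n_without_motif == rt$n_peaks))
  expect_warning(ratio_table(ann, allele_order = c("Red-nSpots", "ghost")),
                 "omitted")
})

test_that("FRiP matches all-pairs counting with the documented verdicts", {
  peaks <- data.frame(sequence_id = "s", start = c(100, 300, 600),
                      end = c(200, 420, 700))
  set.seed(84)
  reads <- data.frame(sequence_id = "s", start = sample(0:950, 20))
  reads$end <- reads$start + 50
  got <- frip(reads, peaks)
  oracle <- mean(vapply(seq_len(nrow(reads)), function(i)
    any(reads$start[i] < peaks$end & reads$end[i] > peaks$start),
    logical(1)))
  expect_equal(got$frip, oracle)

  inside <- data.frame(sequence_id = "s", start = c(110, 310), end = c(150, 350))
  expect_equal(frip(inside, peaks)$frip, 1)
  expect_identical(frip(inside, peaks)$verdict, "ideal")
  expect_equal(frip(reads, peaks[0, ])$frip, 0)
  expect_error(frip(reads[0, ], peaks), "zero reads")

  # monotone non-decreasing when peaks are enlarged
  wider <- peaks; wider$start <- wider$start - 50; wider$end <- wider$end + 50
  expect_gte(frip(reads, wider)$frip, got$frip)
})

test_that("conservation classification agrees with exhaustive cross-allele checks", {
  # identical peak sets on an identity map: everything conserved
  mkpeaks <- function(al) data.frame(sequence_id = al,
                                     start = c(10, 200), end = c(60, 280),
                                     allele = al)
  peaks <- do.call(rbind, lapply(c("a", "b"), mkpeaks))
  idmap <- data.frame(seq_a = "a", start_a = 0, end_a = 500,
                      seq_b = "b", start_b = 0, end_b = 500)
  got <- classify_conservation(peaks, idmap)
  expect_true(all(got$conservation == "conserved"))

  # a peak outside every mapped region is lineage-specific
  peaks2 <- rbind(peaks, data.frame(sequence_id = "a", start = 600, end = 650,
                                    allele = "a"))
  got2 <- classify_conservation(peaks2, idmap)
  expect_identical(got2$conservation[5], "lineage_specific")

  expect_warning(all_ls <- classify_conservation(peaks, idmap[0, ]), "empty")
  expect_true(all(all_ls$conservation == "lineage_specific"))

  # 4-allele toy fixture versus brute-force evaluation of the definition
  set.seed(85)
  alleles <- c("w", "x", "y", "z")
  toy <- do.call(rbind, lapply(alleles, function(al) {
    st <- sort(sample(seq(0, 900, 20), 5))
    data.frame(sequence_id = al, start = st, end = st + 30, allele = al)
  }))
  segs <- seq(0, 950, 50)
  map <- do.call(rbind, lapply(1:3, function(i)
    do.call(rbind, lapply((i + 1):4, function(j)
      data.frame(seq_a = alleles[i], start_a = segs, end_a = segs + 50,
                 seq_b = alleles[j], start_b = segs, end_b = segs + 50)))))
  got3 <- classify_conservation(toy, map)
  ov <- function(s1, e1, s2, e2) s1 < e2 & e1 > s2
  oracle <- vapply(seq_len(nrow(toy)), function(i) {
    p <- toy[i, ]
    sym <- rbind(map,
                 setNames(map[, c(4, 5, 6, 1, 2, 3)], names(map)))
    all(vapply(setdiff(alleles, p$allele), function(al) {
      rows <- sym[sym$seq_a == p$sequence_id & sym$seq_b == al, ]
      q <- toy[toy$allele == al, ]
      any(vapply(seq_len(nrow(rows)), function(j)
        ov(p$start, p$end, rows$start_a[j], rows$end_a[j]) &&
          any(ov(rows$start_b[j], rows$end_b[j], q$start, q$end)),
        logical(1)))
    }, logical(1)))
  }, logical(1))
  expect_identical(got3$conservation,
                   ifelse(oracle, "conserved", "lineage_specific"))
})

test_that("sex-shared peak fraction counts merged clusters present in both sexes", {
  f <- data.frame(sequence_id = "s", start = c(0, 100, 300), end = c(50, 160, 360))
  expect_equal(sex_shared_fraction(f, f), 1)
  m_disj <- data.frame(sequence_id = "s", start = c(500, 700), end = c(550, 760))
  expect_equal(sex_shared_fraction(f, m_disj), 0)
  # hand enumeration: clusters {0-50 f}, {100-170 f+m}, {300-360 f}, {500-550 m}
  m <- data.frame(sequence_id = "s", start = c(120, 500), end = c(170, 550))
  expect_equal(sex_shared_fraction(f, m), 1 / 4)
  expect_error(sex_shared_fraction(f[0, ], m_disj[0, ]), "empty")
})

test_that("planted allele fixtures are recovered by the scan pipeline", {
  mot <- dsx_motif_synthetic()
  fx <- plant_allele_fixture(5, 3, 7, mot, allele = "Red-nSpots", seed = 86)
  hits <- scan_pssm(fx$sequence[[1]], mot, threshold = 5,
                    sequence_id = "Red-nSpots")
  # every planted instance is recovered at its exact position and strand
  for (i in seq_len(nrow(fx$truth))) {
    hit <- hits[hits$start == fx$truth$position[i] &
                  hits$strand == fx$truth$strand[i], ]
    expect_identical(nrow(hit), 1L)
  }
  ann <- intersect_hits_peaks(hits, fx$peaks)
  expect_identical(sum(ann$has_motif), 5L)
  expect_identical(sum(ann$n_motifs), nrow(fx$truth))
})
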
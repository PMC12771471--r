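test_that("a single disk yields one central distance peak", {
  m <- disk_mask(60, 60, 30, 30, 12)
  pk <- distance_peaks(m, 8)
  expect_identical(nrow(pk), 1L)
  expect_lte(abs(pk$row - 30), 1)
  expect_lte(abs(pk$col - 30), 1)
  expect_identical(nrow(distance_peaks(m & FALSE, 8)), 0L)
})

test_that("a fused dumbbell yields one peak per lobe", {
  m <- disk_mask(60, 90, 30, 30, 12) | disk_mask(60, 90, 30, 48, 12)
  pk <- distance_peaks(m, 8)
  expect_identical(nrow(pk), 2L)
  expect_lte(abs(pk$row[1] - 30), 1)
  expect_setequal(round(pk$col / 6) * 6, c(30, 48))
})

test_that("peak finding matches brute-force local-maximum enumeration", {
  set.seed(61)
  for (rep in 1:5) {
    noise <- matrix(rnorm(32 * 32), 32, 32)
    sm <- median_smooth(noise * 50 + 100, 3)
    m <- sm > quantile(sm, 0.6)
    got <- distance_peaks(m, 5)
    # oracle: explicit loops over the same definition
    d <- elytramorph:::distance_transform(m)
    is_max <- matrix(FALSE, 32, 32)
    for (i in 1:32) for (j in 1:32) {
      if (!m[i, j]) next
      nb <- c()
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        r <- i + di; c <- j + dj
        if (r >= 1 && r <= 32 && c >= 1 && c <= 32) nb <- c(nb, d[r, c])
      }
      is_max[i, j] <- all(d[i, j] >= nb)
    }
    lab <- elytramorph:::label_components(is_max & m)
    reps <- do.call(rbind, lapply(seq_len(max(lab)), function(k) {
      pix <- which(lab == k, arr.ind = TRUE)
      sel <- order(-d[pix], pix[, 1], pix[, 2])[1]
      data.frame(row = pix[sel, 1], col = pix[sel, 2], dist = d[pix][sel])
    }))
    reps <- reps[order(-reps$dist, reps$row, reps$col), , drop = FALSE]
    keep <- logical(nrow(reps))
    for (i in seq_len(nrow(reps))) {
      if (!any(keep)) { keep[i] <- TRUE; next }
      keep[i] <- all(sqrt((reps$row[keep] - reps$row[i])^2 +
                          (reps$col[keep] - reps$col[i])^2) >= 5)
    }
    oracle <- reps[keep, , drop = FALSE]
    rownames(oracle) <- NULL
    expect_equal(got, oracle)
  }
})

toy_template <- function() {
  lm <- matrix(0L, 40, 80)
  lm[10:20, 10:20] <- 3L
  lm[10:20, 40:50] <- 4L
  lm
}

test_that("peaks take containing or nearest template labels, ties low", {
  lm <- toy_template()
  pk <- data.frame(row = c(15, 15, 35), col = c(45, 30, 15),
                   dist = c(3, 2, 1))
  lab <- assign_peaks_to_template(pk, lm)
  expect_identical(lab[1], 4L)  # inside region 4
  expect_identical(lab[2], 3L)  # equidistant from 3 and 4 -> lower label
  expect_identical(lab[3], 3L)  # nearest region is 3
  # brute-force nearest-region oracle on random peaks
  set.seed(62)
  pk2 <- data.frame(row = sample(1:40, 20, TRUE), col = sample(1:80, 20, TRUE),
                    dist = runif(20))
  got <- assign_peaks_to_template(pk2, lm)
  pix3 <- which(lm == 3L, arr.ind = TRUE); pix4 <- which(lm == 4L, arr.ind = TRUE)
  oracle <- vapply(1:20, function(i) {
    if (lm[pk2$row[i], pk2$col[i]] > 0) return(lm[pk2$row[i], pk2$col[i]])
    d3 <- min((pix3[, 1] - pk2$row[i])^2 + (pix3[, 2] - pk2$col[i])^2)
    d4 <- min((pix4[, 1] - pk2$row[i])^2 + (pix4[, 2] - pk2$col[i])^2)
    if (d3 <= d4) 3L else 4L
  }, integer(1))
  expect_identical(got, oracle)
})

test_that("constrained watershed splits fused disks and conserves pixels", {
  m <- disk_mask(60, 100, 30, 32, 14) | disk_mask(60, 100, 30, 56, 11)
  pk <- distance_peaks(m, 8)
  expect_identical(nrow(pk), 2L)
  labels <- ifelse(pk$col < 44, 4L, 5L)
  ws <- constrained_watershed(m, pk, labels)
  got <- sort(unique(ws$labels[ws$labels > 0]))
  expect_identical(got, c(4L, 5L))
  # pixel conservation: the labeled pixels are exactly the mask
  expect_identical(ws$labels > 0, m)
  # each recovered lobe area within 10% of its planted disk area
  a4 <- sum(ws$labels == 4L); a5 <- sum(ws$labels == 5L)
  t4 <- sum(disk_mask(60, 100, 30, 32, 14)); t5 <- sum(disk_mask(60, 100, 30, 56, 11))
  expect_lt(abs(a4 - t4) / t4, 0.10)
  expect_lt(abs(a5 - t5) / t5, 0.10)
  # planted-size ordering is preserved in the recovery
  expect_gt(a4, a5)
})

test_that("spurious same-label peaks do not split a single spot", {
  m <- disk_mask(50, 50, 25, 25, 15)
  pk <- data.frame(row = c(22, 28), col = c(22, 28), dist = c(10, 10))
  ws <- constrained_watershed(m, pk, c(6L, 6L))
  expect_identical(sort(unique(ws$labels[ws$labels > 0])), 6L)
  expect_identical(ws$labels > 0, m)

  # without the template constraint the same peaks over-segment
  ws_u <- constrained_watershed(m, pk, c(1L, 2L))
  expect_identical(sort(unique(ws_u$labels[ws_u$labels > 0])), c(1L, 2L))
})

test_that("no peaks yields an empty label map with a warning", {
  m <- disk_mask(30, 30, 15, 15, 5)
  expect_warning(ws <- constrained_watershed(
    m, data.frame(row = integer(0), col = integer(0), dist = numeric(0)),
    integer(0)), "no peaks")
  expect_true(all(ws$labels == 0))
  expect_identical(ws$qc$n_unlabeled_pixels, sum(m))
})

test_that("area measurement normalizes by wing area and reports absences", {
  wing <- disk_mask(80, 80, 40, 40, 35)
  empty <- matrix(0L, 80, 80)
  a0 <- measure_areas(empty, wing)
  expect_identical(nrow(a0), 10L)
  expect_true(all(a0$normalized_area == 0))

  lm <- matrix(0L, 80, 80)
  lm[disk_mask(80, 80, 40, 30, 8)] <- 2L
  lm[disk_mask(80, 80, 40, 55, 6)] <- 7L
  a <- measure_areas(lm, wing)
  expect_equal(a$normalized_area[2], sum(lm == 2L) / sum(wing))
  expect_equal(a$normalized_area[7], sum(lm == 7L) / sum(wing))
  expect_true(all(a$normalized_area[-c(2, 7)] == 0))
  expect_lte(sum(a$normalized_area), 1)
  expect_error(measure_areas(lm, wing & FALSE), "empty")
})
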
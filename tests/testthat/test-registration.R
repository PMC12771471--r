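test_that("an already-canonical wing aligns to the identity transform", {
  m <- ellipse_mask(200, 300, 100.5, 150.5, 110, 70)
  al <- align_wing(m)
  expect_lt(abs(al$transform$theta) * 180 / pi, 0.5)
  pix <- which(al$wing, arr.ind = TRUE)
  expect_lt(abs(mean(pix[, 2]) - 150.5), 0.5)
  expect_lt(abs(mean(pix[, 1]) - 100.5), 0.5)
  expect_false(al$transform$flip_y)
  expect_gt(mask_jaccard(al$wing, m), 0.99)
})

test_that("rotated wings align back onto the canonical mask", {
  canonical <- ellipse_mask(240, 340, 120.5, 170.5, 120, 75)
  rotated <- ellipse_mask(240, 340, 120.5, 170.5, 120, 75, theta = 30 * pi / 180)
  al <- align_wing(rotated)
  expect_gt(mask_jaccard(al$wing, canonical), 0.98)

  # companions receive the same transform
  companion <- rotated  # a raster locked to the wing's frame
  al2 <- align_wing(rotated, companions = list(c = companion))
  expect_gt(mask_jaccard(al2$companions$c, canonical), 0.98)
})

test_that("the third-moment rule orients skewed and mirrored wings alike", {
  # asymmetric blob: ellipse plus a lobe, skewed in both axes
  base <- ellipse_mask(220, 320, 110.5, 160.5, 100, 60)
  lobe <- disk_mask(220, 320, 80.5, 230.5, 35)
  blob <- base | lobe
  al <- align_wing(blob)
  pix <- which(al$wing, arr.ind = TRUE)
  skx <- mean((pix[, 2] - mean(pix[, 2]))^3) / sd(pix[, 2])^3
  sky <- mean((pix[, 1] - mean(pix[, 1]))^3) / sd(pix[, 1])^3
  expect_gte(skx, -1e-3)
  expect_gte(sky, -1e-3)
  mirrored <- blob[nrow(blob):1, ]  # flip about the horizontal axis
  al_m <- align_wing(mirrored)
  expect_gt(mask_jaccard(al_m$wing, al$wing), 0.95)
})

test_that("degenerate wings are rejected by alignment", {
  line <- matrix(FALSE, 50, 50); line[25, 10:40] <- TRUE
  expect_error(align_wing(line), "degenerate|collinear")
  expect_error(align_wing(matrix(FALSE, 10, 10)), "empty")
})

test_that("bbox scaling equalizes sizes and is identity for singletons", {
  big <- ellipse_mask(300, 440, 150.5, 220.5, 160, 100)
  small <- ellipse_mask(300, 440, 150.5, 220.5, 80, 50)
  al <- list(align_wing(big), align_wing(small))
  sc <- scale_to_common_bbox(al)
  bb1 <- elytramorph:::mask_bbox(sc$wings[[1]])
  bb2 <- elytramorph:::mask_bbox(sc$wings[[2]])
  expect_identical(unname(bb1), unname(bb2))
  expect_gt(mask_jaccard(sc$wings[[1]], sc$wings[[2]]), 0.98)

  solo <- scale_to_common_bbox(al[1])
  expect_gt(mask_jaccard(solo$wings[[1]], al[[1]]$wing), 0.98)
  expect_error(elytramorph:::rescale_bbox(
    matrix(TRUE, 1, 1), c(xmin = 1, xmax = 1, ymin = 1, ymax = 1),
    c(10, 10), c(5, 5)), "zero-extent")
})

test_that("average images are per-pixel means with quantized values", {
  m1 <- disk_mask(60, 60, 20, 20, 10)
  m2 <- disk_mask(60, 60, 40, 40, 10)
  expect_equal(build_average_image(list(m1, m1)), m1 * 1)
  avg <- build_average_image(list(m1, m2))
  expect_equal(avg[20, 20], 0.5)
  expect_equal(avg[40, 40], 0.5)
  expect_true(all(avg %in% c(0, 0.5, 1)))
  avg3 <- build_average_image(list(m1, m2, m1 & m2))
  expect_true(all(abs(avg3 - round(avg3 * 3) / 3) < 1e-12))
  expect_error(build_average_image(list(m1, m1[1:30, ])), "shape")
})

test_that("template construction separates ten spots and errors otherwise", {
  q <- small_quantified_cohort()$result
  tpl <- q$template$template
  expect_identical(sort(unique(tpl$label_map[tpl$label_map > 0])), 1:10)
  expect_identical(nrow(tpl$centroids), 10L)

  # on a well-separated (jitter-free) cohort, template centroids land on
  # the true spot centers scaled to the common bbox
  coh0 <- render_cohort(3, seed = 433, radius_jitter_sdlog = 0,
                        center_jitter_sd = 0, rotation_jitter_sd = 0,
                        translation_jitter_sd = 0)
  seg0 <- lapply(coh0, function(e)
    list(wing = e$truth$wing_mask, spots = e$truth$label_mask > 0))
  t0 <- build_spot_template(seg0)
  lay <- elytra_spot_layout()
  bb <- t0$bbox
  ex <- (bb["xmin"] + bb["xmax"]) / 2 + lay$ex * (bb["xmax"] - bb["xmin"]) / 2
  ey <- (bb["ymin"] + bb["ymax"]) / 2 + lay$ey * (bb["ymax"] - bb["ymin"]) / 2
  d <- sqrt((t0$template$centroids$x - ex)^2 +
            (t0$template$centroids$y - ey)^2)
  expect_lt(max(d), 3)

  # an average with 9 blobs can never separate 10 spots
  avg9 <- Reduce(`|`, lapply(1:9, function(k)
    disk_mask(100, 200, 20 + 15 * ((k - 1) %/% 3 + 1),
              40 * ((k - 1) %% 3 + 1), 5))) * 1
  expect_error(template_from_average(avg9, 10), "achievable")
})

test_that("adding one cohort image barely moves the template", {
  truth_masks <- function(e) list(wing = e$truth$wing_mask,
                                  spots = e$truth$label_mask > 0)
  coh <- render_cohort(6, seed = 431)
  seg <- lapply(coh, truth_masks)
  t6 <- build_spot_template(seg)
  coh1 <- render_cohort(1, seed = 432)
  t7 <- build_spot_template(c(seg, list(truth_masks(coh1[[1]]))))
  shift <- sqrt((t6$template$centroids$x - t7$template$centroids$x)^2 +
                (t6$template$centroids$y - t7$template$centroids$y)^2)
  expect_lt(max(shift), 2)
})
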
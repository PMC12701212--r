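test_that("binarize is a strict threshold and monotone", {
  img <- matrix(c(0.4, 0.6, 0, 0.5), 2, 2)
  expect_equal(binarize(img, 0.5), matrix(c(FALSE, TRUE, FALSE, FALSE), 2, 2))
  expect_true(all(binarize(matrix(0, 4, 4), 0.3) == FALSE))
  set.seed(6)
  img <- matrix(runif(400), 20, 20)
  lo <- binarize(img, 0.3); hi <- binarize(img, 0.6)
  expect_true(all(lo[hi]))   # raising the threshold never adds foreground
  expect_error(binarize(img, 0), "threshold")
  expect_error(binarize(img, 1.2), "threshold")
})

test_that("morph_clean removes isolated pixels and closing merges close disks", {
  g <- matrix(FALSE, 64, 64); g[30, 30] <- TRUE
  expect_true(all(morph_clean(g, 2, 10) == FALSE))
  # two 8-px disks with a 12-px gap: the radius-10 closing bridges them
  # (gap < 2 x closing radius); verified against the brute-force oracle
  two <- disk_mask(64, c(32, 20), 8) | disk_mask(64, c(32, 48), 8)
  closed <- morph_clean(two, 0, 10)
  expect_equal(max(mammodelta:::label_components(closed)), 1L)
  expect_true(all(closed == bf_closing(two, 10)))
})

test_that("erosion of a solid square matches the analytic bound", {
  sq <- matrix(FALSE, 80, 80); sq[16:65, 16:65] <- TRUE   # 50x50
  out <- morph_clean(sq, 2, 0)
  expect_equal(max(mammodelta:::label_components(out)), 1L)
  expect_equal(sum(out), sum(bf_erode(sq, 2)))
  expect_lte(sum(out), 48 * 48)   # erosion shrinks at least 1 px per side
})

test_that("morph_clean agrees with brute-force set morphology on random grids", {
  set.seed(17)
  for (rep in 1:50) {
    g <- matrix(runif(64 * 64) < runif(1, 0.2, 0.5), 64, 64)
    mine <- morph_clean(g, 2, 10)
    oracle <- bf_closing(bf_erode(g, 2), 10)
    expect_true(all(mine == oracle))
  }
})

test_that("periphery removal deletes border-touching and off-breast regions", {
  breast <- annotation_mask(disk_mask(96, c(48, 48), 40) * 1)
  inner <- disk_mask(96, c(48, 48), 6)           # well inside
  border <- disk_mask(96, c(48, 85), 5)          # touches the breast border
  outside <- disk_mask(96, c(5, 5), 3)           # outside the breast
  out <- remove_periphery(inner | border | outside, breast, band = 15)
  expect_true(all(out[inner]))
  expect_false(any(out[border]))
  expect_false(any(out[outside]))
  expect_error(remove_periphery(inner, annotation_mask(matrix(0, 96, 96)), 15),
               "empty breast")
})

test_that("ROI extraction: counts, ordering, area filter", {
  g <- disk_mask(64, c(10, 10), 3) | disk_mask(64, c(40, 20), 4) |
    disk_mask(64, c(20, 50), 3)
  rois <- extract_rois(g, min_area = 9)
  expect_length(rois, 3)
  expect_equal(vapply(rois, function(r) r$roi_id, integer(1)), 1:3)
  # raster order of bounding boxes: (10,10) then (20,50) then (40,20)
  cent <- t(vapply(rois, function(r) r$centroid, numeric(2)))
  expect_equal(order(cent[, 1]), 1:3)
  expect_length(extract_rois(matrix(FALSE, 16, 16)), 0)
  g2 <- disk_mask(64, c(30, 30), 5); g2[2, 2] <- TRUE  # 1-px speck
  expect_length(extract_rois(g2, min_area = 9), 1)
})

test_that("ROIs are single 8-connected components with tight boxes", {
  diag2 <- matrix(FALSE, 16, 16)
  diag2[cbind(5:8, 5:8)] <- TRUE   # diagonal chain is one 8-connected component
  rois <- extract_rois(diag2, min_area = 1)
  expect_length(rois, 1)
  r <- rois[[1]]
  expect_equal(unname(r$bbox), c(4, 4, 8, 8))  # 0-based half-open
  expect_true(r$centroid[1] >= r$bbox[1] && r$centroid[1] <= r$bbox[3])
})

test_that("ground-truth labels follow the overlap-fraction rule", {
  rois <- extract_rois(disk_mask(64, c(30, 30), 5), min_area = 1)
  inside <- annotation_mask(disk_mask(64, c(30, 30), 10) * 1)
  expect_equal(assign_gt_labels(rois, inside)[[1]]$gt_label, "future_malignant")
  away <- annotation_mask(disk_mask(64, c(10, 10), 4) * 1)
  expect_equal(assign_gt_labels(rois, away)[[1]]$gt_label, "normal")
  expect_equal(assign_gt_labels(rois, NULL)[[1]]$gt_label, "normal")
  # a mask covering ~30% of the ROI flips with the threshold
  r <- rois[[1]]
  m <- matrix(0, 64, 64)
  m[r$pixels[seq_len(round(0.3 * r$area))]] <- 1
  part <- annotation_mask(m)
  expect_equal(assign_gt_labels(rois, part, 0.25)[[1]]$gt_label, "future_malignant")
  expect_equal(assign_gt_labels(rois, part, 0.5)[[1]]$gt_label, "normal")
})

test_that("every ROI lies inside the closing of the thresholded foreground", {
  set.seed(12)
  img <- matrix(runif(96 * 96), 96, 96) *
    mammodelta:::gaussian_blur(matrix(runif(96 * 96), 96, 96), 4)
  img <- img / max(img)
  breast <- annotation_mask((matrix(1, 96, 96)))
  bin <- binarize(img, 0.3)
  closed <- bf_closing(bin, 10)
  rois <- mammodelta:::segment_one(img, breast, segmentation_config(), 0.3)
  for (r in rois) expect_true(all(closed[r$pixels]))
})

test_that("threshold selection prefers the separating value, ties to lowest", {
  # one bright blob (the truth) over a dim distractor and faint speckle
  img <- matrix(0, 96, 96)
  img[disk_mask(96, c(50, 20), 10)] <- 0.1   # faint speckle region
  img[disk_mask(96, c(70, 70), 8)] <- 0.35   # distractor
  img[disk_mask(96, c(30, 30), 8)] <- 0.9    # true region
  truth <- annotation_mask(disk_mask(96, c(30, 30), 8) * 1)
  breast <- annotation_mask(matrix(1, 96, 96))
  cfg <- segmentation_config(periphery_band = 0)
  thr <- select_threshold(list(img), list(truth), list(breast), cfg,
                          candidate_probs = c(0.1, 0.3, 0.6, 0.9))
  # the separating candidates exclude the distractor (strict threshold) but
  # keep the bright truth region; the low candidate would admit a false ROI
  expect_gte(thr, 0.35)
  expect_lt(thr, 0.9)
  # all-equal scores return the lowest candidate: one radially decreasing
  # region stays a single correct ROI at every candidate threshold
  ggrid <- expand.grid(r = 1:96, c = 1:96)
  rad <- matrix(sqrt((ggrid$r - 48)^2 + (ggrid$c - 48)^2), 96, 96)
  img2 <- pmax(0.9 - 0.03 * rad, 0) * (rad <= 14)
  truth2 <- annotation_mask((rad <= 14) * 1)
  thr2 <- select_threshold(list(img2), list(truth2), list(breast), cfg,
                           candidate_probs = c(0.2, 0.5))
  pooled <- img2[img2 > 0]
  expect_equal(thr2, unname(quantile(pooled, 0.2)))
  expect_error(select_threshold(list(), list(), list(), cfg), "empty training")
})
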
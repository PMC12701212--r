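roi_from_mask <- function(mask) extract_rois(mask, min_area = 1)[[1]]

test_that("the registry holds 98 unique names in fixed groups", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 98L)
  expect_false(anyDuplicated(reg$name) > 0)
  expect_equal(as.integer(table(reg$group)[c("shape", "fos", "glcm", "epidemiological")]),
               c(15L, 9L, 72L, 2L))
  # stable across calls (order and content)
  expect_identical(feature_registry(), feature_registry())
})

test_that("shape features of a filled disk match the analytic circle", {
  roi <- roi_from_mask(disk_mask(64, c(32, 32), 20))
  s <- shape_features(roi)
  expect_gte(s["Circularity"], 0.9); expect_lte(s["Circularity"], 1.1)
  expect_equal(unname(s["Euler Number"]), 1)
  expect_equal(unname(s["Area"]), sum(disk_mask(64, c(32, 32), 20)))
  expect_lt(abs(s["Equivalent Diameter"] - 2 * sqrt(s["Area"] / pi)), 1e-9)
  expect_lt(abs(s["Shape Ratio"] - 1), 0.05)
  expect_gt(s["Solidity"], 0.95)
  expect_equal(unname(s["Compactness"] * s["Circularity"]), 1, tolerance = 1e-9)
})

test_that("a disk with a hole has Euler number 0 and larger filled area", {
  m <- disk_mask(64, c(32, 32), 15) & !disk_mask(64, c(32, 32), 5)
  roi <- roi_from_mask(m)
  s <- shape_features(roi)
  expect_equal(unname(s["Euler Number"]), 0)
  expect_gt(s["Filled Area"], s["Area"])
})

test_that("a solid axis-aligned square has full extent", {
  m <- matrix(FALSE, 32, 32); m[11:20, 11:20] <- TRUE
  s <- shape_features(roi_from_mask(m))
  expect_equal(unname(s["Area"]), 100)
  expect_equal(unname(s["Extent"]), 1.0)
  expect_lt(abs(s["Major Axis Length"] - s["Minor Axis Length"]), 1e-9)
})

test_that("shape features are invariant to translation and scale sensibly", {
  a <- shape_features(roi_from_mask(disk_mask(96, c(30, 30), 11)))
  b <- shape_features(roi_from_mask(disk_mask(96, c(60, 55), 11)))
  expect_equal(a, b)
  small <- shape_features(roi_from_mask(disk_mask(96, c(48, 48), 10)))
  big <- shape_features(roi_from_mask(disk_mask(96, c(48, 48), 20)))
  expect_equal(unname(big["Area"] / small["Area"]), 4, tolerance = 0.05)
  expect_equal(unname(big["Perimeter"] / small["Perimeter"]), 2, tolerance = 0.05)
})

test_that("first-order statistics match analytic cases", {
  m <- disk_mask(32, c(16, 16), 6)
  roi <- roi_from_mask(m)
  const <- matrix(0.7, 32, 32)
  f <- intensity_fos_features(roi, const)
  expect_equal(unname(f["Mean Intensity"]), 0.7)
  expect_equal(unname(f["Variance"]), 0)
  expect_equal(unname(f["Smoothness"]), 0)
  expect_equal(unname(f["Entropy"]), 0)
  # half zeros / half ones inside the ROI
  two <- matrix(0, 32, 32)
  idx <- which(m)
  two[idx[seq_len(floor(length(idx) / 2))]] <- 1
  f2 <- intensity_fos_features(roi, two)
  expect_equal(unname(f2["Mean Intensity"]), 0.5, tolerance = 0.01)
  expect_equal(unname(f2["Entropy"]), 1, tolerance = 0.01)
  set.seed(10)
  rnd <- matrix(runif(32 * 32), 32, 32)
  f3 <- intensity_fos_features(roi, rnd)
  expect_lt(abs(f3["Variance"] - f3["STD"]^2), 1e-12)
})

test_that("GLCM of a constant patch hits the degenerate values", {
  roi <- roi_from_mask(disk_mask(64, c(32, 32), 10))
  g <- glcm_features(roi, matrix(0.5, 64, 64))
  for (k in 1:3) for (ang in c("0", "45", "90", "135")) {
    expect_equal(unname(g[paste("Contrast", ang, paste0("D", k))]), 0)
    expect_equal(unname(g[paste("Energy", ang, paste0("D", k))]), 1)
    expect_equal(unname(g[paste("Homogeneity", ang, paste0("D", k))]), 1)
    expect_equal(unname(g[paste("Correlation", ang, paste0("D", k))]), 0)
  }
})

test_that("vertical stripes maximize contrast at offset 5, angle 0", {
  img <- matrix(0, 64, 64)
  img[, (((1:64) - 1) %/% 5) %% 2 == 1] <- 1   # width-5 vertical stripes
  m <- matrix(FALSE, 64, 64); m[17:48, 17:48] <- TRUE
  roi <- roi_from_mask(m)
  g <- glcm_features(roi, img, glcm_spec(offsets = c(5L, 15L, 25L), gray_levels = 2))
  # at offset 5 every horizontal pair crosses a stripe boundary: the
  # hand-built co-occurrence matrix is fully off-diagonal, contrast = (2-1)^2
  expect_equal(unname(g["Contrast 0 D1"]), 1)
  expect_equal(unname(g["Energy 0 D1"]), 0.5)
  # along the stripes nothing changes
  expect_equal(unname(g["Contrast 90 D1"]), 0)
})

test_that("each offset contributes 24 GLCM values", {
  roi <- roi_from_mask(disk_mask(64, c(32, 32), 9))
  g <- glcm_features(roi, make_test_image(64))
  expect_length(g, 72)
  for (k in 1:3)
    expect_equal(sum(grepl(paste0(" D", k, "$"), names(g))), 24L)
})

test_that("GLCM is invariant to adding a constant before quantization", {
  roi <- roi_from_mask(disk_mask(64, c(32, 32), 9))
  img <- make_test_image(64)
  expect_equal(glcm_features(roi, img), glcm_features(roi, img + 0.17))
})

test_that("patches smaller than an offset are padded and flagged", {
  m <- matrix(FALSE, 64, 64); m[30:36, 30:36] <- TRUE   # 7x7 < offsets 15, 25
  roi <- roi_from_mask(m)
  g <- glcm_features(roi, make_test_image(64))
  expect_length(g, 72)
  expect_true(all(is.finite(g)))
  expect_equal(attr(g, "padded_offsets"), c(15L, 25L))
})

test_that("the assembled vector has 98 registry-ordered finite values", {
  roi <- roi_from_mask(disk_mask(64, c(32, 32), 8))
  meta <- list(age = 63, birads_density = "c")
  v <- assemble_feature_vector(roi, make_test_image(64), meta)
  expect_length(v, 98)
  expect_identical(names(v), feature_registry()$name)
  expect_true(all(is.finite(v)))
  expect_equal(unname(v["Age"]), 63)
  expect_equal(unname(v["Breast Density"]), 3)   # "c" -> 3
  v2 <- assemble_feature_vector(roi, make_test_image(64), meta)
  expect_identical(v, v2)
  expect_error(assemble_feature_vector(roi, make_test_image(64), list(age = 60)),
               "birads")
})

test_that("feature tables carry metadata columns and registry order", {
  mask <- disk_mask(64, c(20, 20), 6) | disk_mask(64, c(45, 45), 7)
  rois <- assign_gt_labels(extract_rois(mask, 1), NULL)
  tab <- roi_feature_table(rois, make_test_image(64),
                           list(patient_id = "P1", view = "MLO",
                                age = 55, birads_density = "b"))
  expect_equal(nrow(tab), 2)
  expect_identical(names(tab), c(feature_registry()$name,
                                 "patient_id", "view", "roi_id", "label"))
  empty <- roi_feature_table(list(), make_test_image(64),
                             list(patient_id = "P1", view = "CC",
                                  age = 55, birads_density = "b"))
  expect_equal(nrow(empty), 0)
})
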
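test_that("16-bit image round trip is lossless and deterministic", {
  px <- matrix(sample(0:4095, 48 * 32, replace = TRUE) / 65535, 48, 32)
  path <- tempfile(fileext = ".tiff")
  write_image(px, path)
  m1 <- load_mammogram(path, view = "CC", round = "current", patient_id = "P1")
  m2 <- load_mammogram(path, view = "CC", round = "current", patient_id = "P1")
  expect_equal(m1$bit_depth, 16L)
  expect_identical(m1$pixels, m2$pixels)
  expect_equal(round(m1$pixels * 65535), round(px * 65535))
})

test_that("multi-channel input is rejected", {
  path <- tempfile(fileext = ".png")
  arr <- array(runif(20 * 20 * 3), dim = c(20, 20, 3))
  png::writePNG(arr, path)
  expect_error(
    load_mammogram(path, view = "CC", round = "prior", patient_id = "P1"),
    "single-channel")
})

test_that("DICOM paths raise an informative error", {
  expect_error(
    load_mammogram("x.dcm", view = "CC", round = "prior", patient_id = "P1"),
    "DICOM")
})

test_that("mammogram and mask invariants are enforced", {
  expect_error(mammogram(matrix(c(1, -1), 2, 1), "CC", "prior", "P1"),
               "non-negative")
  expect_error(mammogram(matrix(NaN, 2, 2), "CC", "prior", "P1"), "finite")
  expect_error(mammogram(matrix(1, 2, 2), "CC", "prior", ""), "non-empty")
  expect_error(annotation_mask(matrix(0.5, 2, 2)), "0 or 1")
  m <- annotation_mask(matrix(c(0, 1, 1, 0), 2, 2), source = "propagated")
  expect_equal(m$source, "propagated")
})

make_case_images <- function(pid, n = 16) {
  imgs <- list()
  for (ro in c("prior", "current", "future"))
    for (v in c("CC", "MLO"))
      imgs[[paste(ro, v, sep = "_")]] <-
        mammogram(matrix(runif(n * n), n, n), v, ro, pid)
  imgs
}

test_that("case-record invariants: slots, masks by label", {
  imgs <- make_case_images("P1")
  mask <- annotation_mask(disk_mask(16, c(8, 8), 3) * 1)
  expect_error(case_record("P1", 60, "b", "malignant", imgs[1:5]), "missing image")
  expect_error(case_record("P1", 60, "b", "malignant", imgs),
               "no future mask")
  expect_error(case_record("P1", 60, "b", "normal", imgs,
                           future_masks = list(CC = mask)), "must not carry")
  cs <- case_record("P1", 60, "b", "malignant", imgs,
                    future_masks = list(CC = mask))
  expect_s3_class(cs, "case_record")
})

test_that("manifest round trip preserves cases and is order-independent", {
  set.seed(3)
  cases <- lapply(c("P2", "P1"), function(pid)
    case_record(pid, 55, "c", "normal", make_case_images(pid)))
  co <- cohort_manifest(cases)
  expect_equal(unname(co$counts["total"]), 2)
  dir <- tempfile()
  write_manifest(co, dir)
  back <- load_manifest(file.path(dir, "manifest.json"))
  expect_equal(vapply(back$cases, function(x) x$patient_id, character(1)),
               c("P1", "P2"))  # sorted regardless of input order
  orig <- co$cases[[1]]$images$current_CC$pixels
  got <- back$cases[[1]]$images$current_CC$pixels
  expect_lt(max(abs(orig - got)), 1 / 65535)
  expect_error(cohort_manifest(c(cases, cases[1])), "duplicate patient_id")
})

test_that("malignant case without a future mask is reported by name", {
  dir <- tempfile(); dir.create(dir)
  img <- matrix(runif(64), 8, 8)
  for (slot in as.vector(outer(c("prior", "current", "future"),
                               c("CC", "MLO"), paste, sep = "_")))
    tiff::writeTIFF(img, file.path(dir, paste0(slot, ".tiff")),
                    bits.per.sample = 16)
  manifest <- list(cases = list(list(
    patient_id = "P77", age = 60, birads_density = "b", label = "malignant",
    images = as.list(setNames(
      paste0(as.vector(outer(c("prior", "current", "future"),
                             c("CC", "MLO"), paste, sep = "_")), ".tiff"),
      as.vector(outer(c("prior", "current", "future"),
                      c("CC", "MLO"), paste, sep = "_")))))))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE)
  expect_error(load_manifest(path), "P77")
})

test_that("feature table round trips at full precision", {
  reg <- feature_registry()$name
  set.seed(9)
  df <- as.data.frame(matrix(rnorm(3 * 98) * 10^runif(3 * 98, -6, 4), 3, 98))
  names(df) <- reg
  df$patient_id <- c("P1", "P1", "P2"); df$view <- "CC"
  df$roi_id <- 1:3; df$label <- c("normal", "future_malignant", "normal")
  path <- tempfile(fileext = ".csv")
  write_feature_table(df, path)
  back <- read_feature_table(path)
  expect_identical(names(back), names(df))
  for (nm in reg) expect_identical(back[[nm]], df[[nm]])

  empty <- df[0, ]
  path2 <- tempfile(fileext = ".csv")
  write_feature_table(empty, path2)
  expect_equal(nrow(read_feature_table(path2)), 0)
  expect_identical(names(read_feature_table(path2)), names(df))

  bad <- df; names(bad)[1] <- "Not A Feature"
  expect_error(write_feature_table(bad, tempfile()), "registry")
})
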
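# Readers and writers: PNG/TIFF images, binary masks, JSON cohort manifests
# and CSV feature tables.

read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("dcm", "dicom"))
    stop("DICOM input is not supported by this build; convert to 16-bit PNG/TIFF")
  if (!file.exists(path)) stop(sprintf("unreadable file: %s", path))
  if (ext == "png") {
    arr <- png::readPNG(path)
    bits <- 8L
    info <- attr(arr, "info")
    if (!is.null(info$bit.depth)) bits <- as.integer(info$bit.depth)
    # readPNG gives no bit depth attribute for plain reads; infer from the
    # value grid: 16-bit samples are multiples of 1/65535.
    if (is.null(info) && length(arr) > 0) {
      v <- unique(round(as.vector(arr) * 65535))
      bits <- if (all(v %% 257 == 0)) 8L else 16L
    }
  } else if (ext %in% c("tif", "tiff")) {
    arr <- tiff::readTIFF(path, info = TRUE)
    bits <- as.integer(attr(arr, "bits.per.sample") %||% 16L)
  } else {
    stop(sprintf("unsupported image format '%s' (PNG or TIFF required)", ext))
  }
  if (length(dim(arr)) == 3L) {
    if (dim(arr)[3] > 1L) stop("single-channel required (got a multi-channel image)")
    arr <- arr[, , 1]
  }
  arr <- matrix(as.numeric(arr), nrow(arr), ncol(arr))  # drop reader attributes
  list(pixels = arr, bit_depth = bits)
}

#' Load a mammogram from a PNG or TIFF file
#'
#' Reads a single-channel 8- or 16-bit image losslessly. Intensities are
#' normalized to [0, 1] by the file format's maximum (the reader libraries do
#' this division exactly, so integer sample values are recoverable); the
#' source bit depth is recorded on the object.
#'
#' @param path file path (.png, .tif/.tiff).
#' @param view,round,patient_id acquisition metadata (see [mammogram()]).
#' @param laterality breast side, "L" or "R".
#' @return a `mammogram`.
#' @export
load_mammogram <- function(path, view, round, patient_id, laterality = "L") {
  img <- read_gray_image(path)
  mammogram(img$pixels, view = view, round = round, patient_id = patient_id,
            laterality = laterality, bit_depth = img$bit_depth)
}

#' Write a mammogram (or matrix) as a 16-bit TIFF
#'
#' @param img matrix or `mammogram` with values in [0, 1].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  px <- as_pixels(img)
  px <- pmin(pmax(px, 0), 1)
  tiff::writeTIFF(px, path, bits.per.sample = 16L)
  invisible(path)
}

#' Load a binary annotation mask from PNG/TIFF
#'
#' @param path file path; any strictly positive pixel is foreground.
#' @param source provenance tag, see [annotation_mask()].
#' @return an `annotation_mask`.
#' @export
load_mask <- function(path, source = "expert") {
  img <- read_gray_image(path)
  annotation_mask((img$pixels > 0) * 1, source = source)
}

#' @rdname load_mask
#' @param mask an `annotation_mask` or 0/1 matrix.
#' @export
write_mask <- function(mask, path) {
  px <- as_pixels(mask)
  png::writePNG(px, path)
  invisible(path)
}

#' Load a cohort manifest from JSON
#'
#' The manifest lists one entry per case with demographics and per-slot
#' image paths (relative paths are resolved against the manifest's
#' directory). Every case must satisfy the case-record invariants; problems
#' are reported per case.
#'
#' @param path JSON manifest path.
#' @return a `cohort_manifest`.
#' @export
load_manifest <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = FALSE)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
  cases <- lapply(spec$cases, function(cs) {
    imgs <- list()
    for (slot in names(cs$images)) {
      parts <- strsplit(slot, "_", fixed = TRUE)[[1]]
      imgs[[slot]] <- load_mammogram(resolve(cs$images[[slot]]),
                                     view = parts[2], round = parts[1],
                                     patient_id = cs$patient_id)
    }
    masks <- list()
    for (v in names(cs$future_masks))
      masks[[v]] <- load_mask(resolve(cs$future_masks[[v]]), source = "expert")
    case_record(cs$patient_id, cs$age, cs$birads_density, cs$label,
                images = imgs, future_masks = masks)
  })
  cohort_manifest(cases)
}

#' Write a cohort manifest (and its images) to disk
#'
#' Images are written as 16-bit TIFF, masks as PNG, and a `manifest.json`
#' index is produced that [load_manifest()] can read back.
#'
#' @param cohort a `cohort_manifest`.
#' @param dir output directory (created if absent).
#' @return path of the written manifest JSON.
#' @export
write_manifest <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(cohort$cases, function(cs) {
    imgs <- list()
    for (slot in names(cs$images)) {
      fn <- sprintf("%s_%s.tiff", cs$patient_id, slot)
      write_image(cs$images[[slot]], file.path(dir, fn))
      imgs[[slot]] <- fn
    }
    masks <- list()
    for (v in names(cs$future_masks)) {
      fn <- sprintf("%s_future_%s_mask.png", cs$patient_id, v)
      write_mask(cs$future_masks[[v]], file.path(dir, fn))
      masks[[v]] <- fn
    }
    out <- list(patient_id = cs$patient_id, age = cs$age,
                birads_density = cs$birads_density, label = cs$label,
                images = imgs)
    if (length(masks)) out$future_masks <- masks
    out
  })
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(cases = entries), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Write a feature table to CSV
#'
#' One row per ROI: the metadata columns `patient_id`, `view`, `roi_id`,
#' `label` followed by the 98 feature columns in registry order. Values are
#' written with full precision so a read round-trip is exact.
#'
#' @param rows data.frame as produced by [roi_feature_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(rows, path) {
  meta <- c("patient_id", "view", "roi_id", "label")
  feats <- setdiff(names(rows), meta)
  reg <- feature_registry()$name
  if (!all(feats %in% reg) || !identical(feats, reg[reg %in% feats]))
    stop("feature columns do not match the feature registry order")
  out <- rows[, c(feats, meta), drop = FALSE]
  utils::write.csv(format(out, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path CSV path.
#' @return data.frame with numeric feature columns and metadata columns.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- intersect(c("patient_id", "view", "roi_id", "label"), names(df))
  for (nm in setdiff(names(df), c("patient_id", "view", "label")))
    df[[nm]] <- as.numeric(df[[nm]])
  df[, c(setdiff(names(df), meta), meta), drop = FALSE]
}
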
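#' Mammogram object
#'
#' A single mammographic projection: a rectangular non-negative intensity
#' grid plus acquisition metadata. The working representation is floating
#' point in [0, 1] (the original bit depth is kept as metadata); pixel
#' coordinates are (row, col) with origin at the top-left corner.
#'
#' @param pixels numeric matrix, finite and non-negative.
#' @param view "CC" or "MLO".
#' @param round screening round: "prior", "current" or "future".
#' @param patient_id non-empty string.
#' @param laterality "L" or "R".
#' @param bit_depth integer bit depth of the source image.
#' @param spacing optional pixel spacing in mm/pixel.
#' @return object of class `mammogram`.
#' @export
mammogram <- function(pixels, view, round, patient_id,
                      laterality = "L", bit_depth = 16L, spacing = NULL) {
  check_finite_matrix(pixels)
  if (any(pixels < 0)) stop("pixels must be non-negative")
  view <- match.arg(view, c("CC", "MLO"))
  round <- match.arg(round, c("prior", "current", "future"))
  laterality <- match.arg(laterality, c("L", "R"))
  if (!nzchar(patient_id)) stop("patient_id must be non-empty")
  structure(
    list(pixels = pixels, spacing = spacing, view = view,
         laterality = laterality, round = round,
         patient_id = patient_id, bit_depth = as.integer(bit_depth)),
    class = "mammogram")
}

#' @export
print.mammogram <- function(x, ...) {
  cat(sprintf("<mammogram %s %s/%s %dx%d px, %d-bit>\n",
              x$patient_id, x$round, x$view,
              nrow(x$pixels), ncol(x$pixels), x$bit_depth))
  invisible(x)
}

#' @export
dim.mammogram <- function(x) dim(x$pixels)

#' Binary annotation mask
#'
#' A 0/1 grid paired with an image of the same shape. `source` records how
#' the mask was produced: drawn by an expert, propagated from another round
#' through a deformation field, or injected by the synthetic generator.
#'
#' @param pixels matrix with values in {0, 1} (logical accepted).
#' @param source "expert", "propagated" or "synthetic".
#' @return object of class `annotation_mask`.
#' @export
annotation_mask <- function(pixels, source = c("expert", "propagated", "synthetic")) {
  source <- match.arg(source)
  px <- as_pixels(pixels)
  if (is.logical(px)) px <- px * 1
  check_finite_matrix(px, "mask pixels")
  if (!all(px %in% c(0, 1))) stop("mask values must be 0 or 1")
  structure(list(pixels = px, source = source), class = "annotation_mask")
}

#' @export
print.annotation_mask <- function(x, ...) {
  cat(sprintf("<annotation_mask %dx%d, %d positive px, source=%s>\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels), x$source))
  invisible(x)
}

#' @export
dim.annotation_mask <- function(x) dim(x$pixels)

#' Labeled components of a mask
#'
#' The package stores multiple masses per view as one union mask; this view
#' recovers the individual 8-connected regions.
#'
#' @param mask an `annotation_mask`.
#' @return integer matrix of component labels (0 = background).
#' @export
mask_components <- function(mask) label_components(mask)

#' Case record
#'
#' One study participant: six images (3 rounds x 2 views), demographics and
#' the case label. Malignant cases carry at least one future-round mass mask;
#' normal cases carry none.
#'
#' @param patient_id non-empty unique string.
#' @param age age in years.
#' @param birads_density BI-RADS density category "a".."d".
#' @param label "normal" or "malignant".
#' @param images named list with entries "<round>_<view>" for all six slots,
#'   each a `mammogram`.
#' @param future_masks named list (by view) of `annotation_mask`s; required
#'   non-empty for malignant cases, must be absent for normal cases.
#' @return object of class `case_record`.
#' @export
case_record <- function(patient_id, age, birads_density, label, images,
                        future_masks = list()) {
  label <- match.arg(label, c("normal", "malignant"))
  birads_density <- match.arg(birads_density, c("a", "b", "c", "d"))
  slots <- as.vector(outer(c("prior", "current", "future"), c("CC", "MLO"),
                           paste, sep = "_"))
  missing <- setdiff(slots, names(images))
  if (length(missing))
    stop(sprintf("case %s: missing image slots: %s",
                 patient_id, paste(missing, collapse = ", ")))
  if (label == "malignant" && length(future_masks) == 0L)
    stop(sprintf("malignant case %s has no future mask", patient_id))
  if (label == "normal" && length(future_masks) > 0L)
    stop(sprintf("normal case %s must not carry future masks", patient_id))
  for (v in names(future_masks)) {
    img <- images[[paste0("future_", v)]]
    if (!identical(dim(future_masks[[v]]$pixels), dim(img$pixels)))
      stop(sprintf("case %s: future mask shape differs from image (%s view)",
                   patient_id, v))
  }
  structure(
    list(patient_id = patient_id, age = age, birads_density = birads_density,
         label = label, images = images, future_masks = future_masks),
    class = "case_record")
}

#' @export
print.case_record <- function(x, ...) {
  cat(sprintf("<case_record %s: %s, age %.0f, density %s, %d images, %d masks>\n",
              x$patient_id, x$label, x$age, x$birads_density,
              length(x$images), length(x$future_masks)))
  invisible(x)
}

#' Cohort manifest
#'
#' An ordered collection of case records with unique patient ids, plus label
#' counts. Loading is order-independent: cases are stored sorted by
#' patient_id.
#'
#' @param cases list of `case_record`s.
#' @return object of class `cohort_manifest`.
#' @export
cohort_manifest <- function(cases) {
  ids <- vapply(cases, function(x) x$patient_id, character(1))
  if (anyDuplicated(ids))
    stop(sprintf("duplicate patient_id: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  cases <- cases[order(ids)]
  labels <- vapply(cases, function(x) x$label, character(1))
  structure(
    list(cases = cases,
         counts = c(normal = sum(labels == "normal"),
                    malignant = sum(labels == "malignant"),
                    total = length(cases))),
    class = "cohort_manifest")
}

#' @export
print.cohort_manifest <- function(x, ...) {
  cat(sprintf("<cohort_manifest: %d cases (%d malignant / %d normal)>\n",
              x$counts["total"], x$counts["malignant"], x$counts["normal"]))
  invisible(x)
}

#' @export
length.cohort_manifest <- function(x) length(x$cases)
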
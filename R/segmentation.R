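# Conversion of the enhanced subtraction image into candidate ROIs:
# thresholding, morphological cleanup, periphery removal, component
# extraction and ground-truth labeling.

#' Segmentation configuration
#'
#' @param threshold binarization threshold in (0, 1), or "auto" to pick it
#'   with [select_threshold()] on training images.
#' @param erosion_radius disk radius (px) of the initial erosion that removes
#'   isolated pixels from registration misalignment; kept smaller than the
#'   average mass so adjacent ROIs do not merge.
#' @param closing_radius disk radius (px) of the closing that merges the
#'   constituents of one mass.
#' @param periphery_band width (px) of the band inside the breast border in
#'   which high-intensity skin-line regions are deleted.
#' @param min_area minimum component area in px^2.
#' @param overlap_fraction fraction of an ROI that must lie inside the
#'   ground-truth mask for the ROI to be labeled `future_malignant`.
#' @return list of class `segmentation_config`.
#' @export
segmentation_config <- function(threshold = 0.06, erosion_radius = 2L,
                                closing_radius = 10L, periphery_band = 15L,
                                min_area = 9L, overlap_fraction = 0.25) {
  stopifnot(erosion_radius >= 0, closing_radius >= 0, periphery_band >= 0,
            min_area >= 0, overlap_fraction > 0, overlap_fraction <= 1)
  structure(list(threshold = threshold,
                 erosion_radius = as.integer(erosion_radius),
                 closing_radius = as.integer(closing_radius),
                 periphery_band = as.integer(periphery_band),
                 min_area = as.integer(min_area),
                 overlap_fraction = overlap_fraction),
            class = "segmentation_config")
}

#' Binarize an enhanced subtraction image
#'
#' Foreground wherever intensity strictly exceeds the threshold; eliminates
#' low-intensity normal areas. Monotone: raising the threshold never adds
#' foreground.
#'
#' @param img matrix or image object scaled to [0, 1].
#' @param threshold scalar strictly inside (0, 1).
#' @return logical matrix.
#' @export
binarize <- function(img, threshold) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly inside (0, 1)")
  as_pixels(img) > threshold
}

#' Morphological cleanup of the binary subtraction image
#'
#' Disk erosion (radius 2 by default) removes isolated pixels and structures
#' thinner than the element, then disk closing (radius 10 by default) merges
#' the nearby constituents of a single mass. Images are padded before the
#' closing so border behaviour equals ideal set-theoretic morphology with
#' background outside the frame.
#'
#' @param binary logical or 0/1 matrix.
#' @param erosion_radius,closing_radius disk radii in pixels.
#' @return logical matrix.
#' @export
morph_clean <- function(binary, erosion_radius = 2L, closing_radius = 10L) {
  px <- (as_pixels(binary) > 0) * 1
  shape <- dim(px)
  if (erosion_radius > 0) {
    # pad so pixels beyond the frame count as background (ideal set
    # morphology; EBImage would otherwise leave the border unshrunk)
    w <- erosion_radius + 1L
    pad <- pad_matrix(px, w, 0)
    pad <- as.matrix(EBImage::erode(EBImage::Image(pad), disk_kernel(erosion_radius)))
    px <- unpad_matrix(pad, w, shape)
  }
  if (closing_radius > 0) {
    w <- closing_radius + 1L
    pad <- pad_matrix(px, w, 0)
    k <- disk_kernel(closing_radius)
    pad <- as.matrix(EBImage::erode(EBImage::dilate(EBImage::Image(pad), k), k))
    px <- unpad_matrix(pad, w, shape)
  }
  px > 0
}

#' Remove peripheral components
#'
#' Deletes every component that lies outside the breast or intersects the
#' periphery band (the `band`-pixel-wide strip inside the breast border).
#' High-intensity regions along the skin line cannot be masses and would
#' otherwise dominate the candidate list.
#'
#' @param binary logical or 0/1 matrix of candidate foreground.
#' @param breast_mask breast-region `annotation_mask` from [segment_breast()].
#' @param band band width in pixels.
#' @return logical matrix.
#' @export
remove_periphery <- function(binary, breast_mask, band = 15L) {
  bm <- as_pixels(breast_mask) > 0
  if (!any(bm)) stop("empty breast mask")
  px <- as_pixels(binary) > 0
  interior <- if (band > 0)
    as.matrix(EBImage::erode(EBImage::Image(bm * 1), disk_kernel(band))) > 0
  else bm
  bad <- !interior  # outside breast, or in the band
  lab <- label_components(px)
  if (max(lab) == 0L) return(px)
  drop <- unique(lab[lab > 0 & bad])
  px[lab %in% drop] <- FALSE
  px
}

new_roi <- function(roi_id, lin, shape) {
  r <- ((lin - 1L) %% shape[1]) + 1L
  c <- ((lin - 1L) %/% shape[1]) + 1L
  structure(list(
    roi_id = as.integer(roi_id),
    pixels = lin,                       # linear indices into the full grid
    shape = shape,
    bbox = c(row0 = min(r) - 1L, col0 = min(c) - 1L,
             row1 = max(r), col1 = max(c)),   # 0-based, half-open
    centroid = c(row = mean(r) - 1, col = mean(c) - 1),
    area = length(lin),
    gt_label = "unassigned"),
    class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi #%d: %d px, centroid (%.1f, %.1f), label %s>\n",
              x$roi_id, x$area, x$centroid[1], x$centroid[2], x$gt_label))
  invisible(x)
}

#' Binary support of one ROI on the full grid
#' @param roi an `roi` object.
#' @return logical matrix of the ROI's shape.
#' @export
roi_mask <- function(roi) {
  m <- matrix(FALSE, roi$shape[1], roi$shape[2])
  m[roi$pixels] <- TRUE
  m
}

#' Extract ROIs from a cleaned binary image
#'
#' One ROI per 8-connected component with area at least `min_area`; ids are
#' assigned in raster order of the component bounding boxes (top-to-bottom,
#' then left-to-right).
#'
#' @param binary logical or 0/1 matrix.
#' @param min_area minimum component area in px^2.
#' @return list of `roi` objects.
#' @export
extract_rois <- function(binary, min_area = 9L) {
  px <- as_pixels(binary) > 0
  lab <- label_components(px)
  n <- max(lab)
  if (n == 0L) return(list())
  shape <- dim(px)
  comps <- split(which(lab > 0), lab[lab > 0])
  comps <- comps[vapply(comps, length, integer(1)) >= min_area]
  if (length(comps) == 0L) return(list())
  key <- t(vapply(comps, function(lin) {
    r <- ((lin - 1L) %% shape[1]) + 1L
    c <- ((lin - 1L) %/% shape[1]) + 1L
    c(min(r), min(c))
  }, numeric(2)))
  ord <- order(key[, 1], key[, 2])
  comps <- unname(comps[ord])
  mapply(function(lin, id) new_roi(id, lin, shape), comps,
         seq_along(comps), SIMPLIFY = FALSE)
}

#' Assign ground-truth labels to ROIs
#'
#' An ROI is `future_malignant` when at least `overlap_fraction` of its area
#' lies inside the propagated ground-truth mask, otherwise `normal`. With no
#' mask (normal cases) every ROI is `normal`.
#'
#' @param rois list of `roi` objects.
#' @param mask `annotation_mask` on the same grid, or NULL.
#' @param overlap_fraction threshold on |roi intersect mask| / |roi|.
#' @return the ROI list with `gt_label` filled in.
#' @export
assign_gt_labels <- function(rois, mask = NULL, overlap_fraction = 0.25) {
  if (is.null(mask)) {
    return(lapply(rois, function(r) { r$gt_label <- "normal"; r }))
  }
  mpx <- as_pixels(mask) > 0
  lapply(rois, function(r) {
    if (!identical(r$shape, dim(mpx))) stop("mask grid differs from ROI grid")
    ov <- sum(mpx[r$pixels]) / r$area
    r$gt_label <- if (ov >= overlap_fraction) "future_malignant" else "normal"
    r
  })
}

segment_one <- function(sub_img, breast_mask, cfg, threshold) {
  bin <- binarize(sub_img, threshold)
  bin <- morph_clean(bin, cfg$erosion_radius, cfg$closing_radius)
  bin <- remove_periphery(bin, breast_mask, cfg$periphery_band)
  extract_rois(bin, cfg$min_area)
}

#' Select the binarization threshold on training images
#'
#' Candidates are intensity quantiles of the pooled nonzero histogram of the
#' training subtraction images. Each candidate is scored by the global
#' classification rate of the resulting segmentation against the
#' ground-truth masks: TP / (TP + FP + FN), where TP counts ground-truth
#' mass components hit by a `future_malignant` ROI, FN counts missed
#' components, and FP counts ROIs without ground-truth overlap. Ties go to
#' the lower threshold.
#'
#' @param training_images list of enhanced subtraction images (matrices or
#'   `subtraction_image`s), scaled to [0, 1].
#' @param gt_masks list of `annotation_mask`s or NULLs, parallel to
#'   `training_images`.
#' @param breast_masks list of breast-region masks, parallel to the images.
#' @param cfg a [segmentation_config()].
#' @param candidate_probs quantile probabilities of the pooled nonzero
#'   histogram that form the candidate grid.
#' @return the selected threshold (scalar).
#' @export
select_threshold <- function(training_images, gt_masks, breast_masks,
                             cfg = segmentation_config(),
                             candidate_probs = c(0.90, 0.925, 0.95, 0.975, 0.99)) {
  if (length(training_images) == 0L) stop("empty training set")
  pooled <- unlist(lapply(training_images, function(im) {
    v <- as_pixels(im); v[v > 0]
  }))
  cand <- sort(unique(pmin(pmax(
    stats::quantile(pooled, candidate_probs, names = FALSE), 1e-6), 1 - 1e-6)))
  score_of <- function(thr) {
    tp <- fp <- fn <- 0L
    for (i in seq_along(training_images)) {
      rois <- segment_one(training_images[[i]], breast_masks[[i]], cfg, thr)
      m <- gt_masks[[i]]
      rois <- assign_gt_labels(rois, m, cfg$overlap_fraction)
      labs <- vapply(rois, function(r) r$gt_label, character(1))
      fp <- fp + sum(labs == "normal")
      if (!is.null(m)) {
        comp <- label_components(m)
        ncomp <- max(comp)
        hit <- 0L
        if (ncomp > 0 && any(labs == "future_malignant")) {
          hit_ids <- unique(unlist(lapply(rois[labs == "future_malignant"],
                                          function(r) comp[r$pixels])))
          hit <- length(setdiff(hit_ids, 0L))
        }
        tp <- tp + hit
        fn <- fn + (ncomp - hit)
      }
    }
    if (tp + fp + fn == 0L) 1 else tp / (tp + fp + fn)
  }
  scores <- vapply(cand, score_of, numeric(1))
  cand[which.max(scores)]  # which.max takes the first (lowest) on ties
}
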
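# Temporal subtraction: current minus registered prior, high-frequency
# enhancement, and the contrast-ratio metric.

#' Subtraction image
#'
#' @param pixels difference grid (matrix, finite).
#' @param patient_id,view provenance.
#' @param enhancement_applied logical flag set by [unsharp_enhance()].
#' @return object of class `subtraction_image`.
#' @export
subtraction_image <- function(pixels, patient_id = "", view = "",
                              enhancement_applied = FALSE) {
  check_finite_matrix(pixels)
  structure(list(pixels = pixels,
                 provenance = list(patient_id = patient_id, view = view),
                 enhancement_applied = enhancement_applied),
            class = "subtraction_image")
}

#' @export
print.subtraction_image <- function(x, ...) {
  cat(sprintf("<subtraction_image %dx%d (%s/%s)%s>\n",
              nrow(x$pixels), ncol(x$pixels),
              x$provenance$patient_id, x$provenance$view,
              if (x$enhancement_applied) ", enhanced" else ""))
  invisible(x)
}

#' Temporal subtraction of registered sequential mammograms
#'
#' Subtracts the registered prior image from the current one to highlight
#' interval change. New bright structure (a developing mass, new clutter)
#' survives; static background cancels. Negative differences are clipped to
#' zero by default because masses appear as new bright structure; set
#' `keep_signed = TRUE` to retain the signed difference.
#'
#' @param current matrix or `mammogram` (fixed frame).
#' @param prior_registered matrix or `mammogram`, already warped onto the
#'   current frame.
#' @param keep_signed keep negative differences instead of clipping.
#' @return a `subtraction_image`.
#' @export
temporal_subtract <- function(current, prior_registered, keep_signed = FALSE) {
  cur <- as_pixels(current); pri <- as_pixels(prior_registered)
  if (!identical(dim(cur), dim(pri))) stop("shape mismatch")
  diffi <- cur - pri
  if (!keep_signed) diffi[diffi < 0] <- 0
  pid <- if (inherits(current, "mammogram")) current$patient_id else ""
  vw <- if (inherits(current, "mammogram")) current$view else ""
  subtraction_image(diffi, patient_id = pid, view = vw)
}

#' Unsharp-mask enhancement
#'
#' `out = img + amount * (img - blur(img, radius))`, clipped at zero; boosts
#' high spatial frequencies so subtle new structure stands out in the
#' subtraction image. `amount = 0` is the identity; a constant image is a
#' fixed point.
#'
#' @param img `subtraction_image` or matrix.
#' @param radius Gaussian sigma of the blur, in pixels (> 0).
#' @param amount non-negative gain on the high-pass residual.
#' @return same type as `img` (flagged as enhanced).
#' @export
unsharp_enhance <- function(img, radius = 5, amount = 1.0) {
  stopifnot(radius > 0, amount >= 0)
  px <- as_pixels(img)
  out <- px + amount * (px - gaussian_blur(px, radius))
  out[out < 0] <- 0
  res <- replace_pixels(img, out)
  if (inherits(res, "subtraction_image")) res$enhancement_applied <- TRUE
  res
}

#' Contrast ratio of a masked region over its surround
#'
#' Mean intensity inside the mask divided by the mean intensity in a
#' surrounding annulus (the mask dilated by `annulus_width` minus the mask
#' itself). The background mean is floored at `eps` so the ratio is always
#' finite. A uniform image gives exactly 1.
#'
#' @param img matrix or image object.
#' @param mask `annotation_mask` or 0/1 matrix, non-empty.
#' @param annulus_width width of the background ring in pixels.
#' @param eps floor for the background mean.
#' @return scalar contrast ratio.
#' @export
contrast_ratio <- function(img, mask, annulus_width = 10L, eps = 1e-6) {
  px <- as_pixels(img)
  m <- as_pixels(mask) > 0
  if (!any(m)) stop("empty mask")
  if (!identical(dim(px), dim(m))) stop("mask and image shapes differ")
  dil <- as.matrix(EBImage::dilate(EBImage::Image(m * 1),
                                   disk_kernel(annulus_width))) > 0
  ann <- dil & !m
  if (!any(ann)) stop("empty background annulus")
  mean(px[m]) / max(mean(px[ann]), eps)
}
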
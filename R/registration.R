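# Intensity-driven deformable registration (classic Thirion demons) with
# Gaussian field regularization and a multi-resolution pyramid. Used twice in
# the pipeline: future -> current (ground-truth propagation) and
# prior -> current (subtraction alignment). The "current" round is always the
# fixed image.

#' Dense 2-D deformation field
#'
#' Backward-mapping displacements in pixels: a point (r, c) on the fixed grid
#' samples the moving image at (r + dr[r,c], c + dc[r,c]).
#'
#' @param dr,dc numeric matrices of row/column displacements (same shape).
#' @return object of class `deformation_field`.
#' @export
deformation_field <- function(dr, dc) {
  check_finite_matrix(dr, "dr"); check_finite_matrix(dc, "dc")
  if (!identical(dim(dr), dim(dc))) stop("dr and dc must have the same shape")
  structure(list(dr = dr, dc = dc, fixed_shape = dim(dr)),
            class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  mag <- sqrt(x$dr^2 + x$dc^2)
  cat(sprintf("<deformation_field %dx%d, mean |u| = %.3f px, max |u| = %.2f px>\n",
              x$fixed_shape[1], x$fixed_shape[2], mean(mag), max(mag)))
  invisible(x)
}

#' Demons registration configuration
#'
#' @param levels pyramid depth (level 1 = full resolution).
#' @param iterations_per_level iterations from coarsest to finest level.
#' @param smoothing_sigma Gaussian sigma (px) applied to the field after
#'   every update; controls deformation smoothness.
#' @param convergence_tol stop a level early when the relative SSD
#'   improvement over one iteration falls below this value.
#' @return list of class `demons_config`.
#' @export
demons_config <- function(levels = 3L, iterations_per_level = c(50L, 30L, 10L),
                          smoothing_sigma = 2.0, convergence_tol = 1e-4) {
  stopifnot(levels >= 1, smoothing_sigma > 0,
            length(iterations_per_level) == levels)
  structure(list(levels = as.integer(levels),
                 iterations_per_level = as.integer(iterations_per_level),
                 smoothing_sigma = smoothing_sigma,
                 convergence_tol = convergence_tol),
            class = "demons_config")
}

resize_matrix <- function(px, nr, nc) {
  as.matrix(EBImage::resize(EBImage::Image(px), w = nr, h = nc))
}

pad_to_common_shape <- function(a, b) {
  nr <- max(nrow(a), nrow(b)); nc <- max(ncol(a), ncol(b))
  grow <- function(px) {
    out <- matrix(0, nr, nc)
    out[seq_len(nrow(px)), seq_len(ncol(px))] <- px
    out
  }
  list(a = grow(a), b = grow(b))
}

ssd <- function(a, b) sum((a - b)^2)

demons_level <- function(fixed, moving, dr, dc, iters, sigma, tol) {
  grids <- index_grids(dim(fixed))
  # fixed-image gradient (central differences)
  nr <- nrow(fixed); nc <- ncol(fixed)
  gr <- (fixed[c(2:nr, nr), ] - fixed[c(1, 1:(nr - 1)), ]) / 2
  gc <- (fixed[, c(2:nc, nc)] - fixed[, c(1, 1:(nc - 1))]) / 2
  g2 <- gr^2 + gc^2
  # the per-iteration SSD oscillates near convergence, so a single
  # non-improving step is not a stopping signal; stop only after several
  # iterations without a relative improvement over the best SSD seen
  best <- Inf
  patience <- 0L
  for (it in seq_len(iters)) {
    mw <- matrix(bilinear_sample(moving, grids$r + dr, grids$c + dc), nr, nc)
    diffi <- fixed - mw
    cur <- sum(diffi^2)
    if (cur < best * (1 - tol)) {
      best <- cur
      patience <- 0L
    } else {
      patience <- patience + 1L
      if (patience >= 5L) break
    }
    denom <- g2 + diffi^2
    scale <- ifelse(denom > 1e-9, diffi / denom, 0)
    dr <- gaussian_blur(dr + scale * gr, sigma)
    dc <- gaussian_blur(dc + scale * gc, sigma)
  }
  list(dr = dr, dc = dc)
}

#' Demons deformable registration
#'
#' Estimates a dense displacement field warping `moving` onto `fixed` by the
#' classic demons update (fixed-image gradient, additive accumulation) with
#' Gaussian regularization of the field after each iteration, run over a
#' coarse-to-fine pyramid. Deterministic: there is no random initialization.
#' If the optimization fails to reduce the sum of squared differences versus
#' the unwarped baseline (which can happen on pathological inputs), the zero
#' field is returned with a warning, so registration never degrades
#' alignment.
#'
#' @param fixed,moving matrices or `mammogram`s; padded with zeros to a
#'   common shape if their shapes differ.
#' @param cfg a [demons_config()].
#' @return a `deformation_field` on the fixed grid.
#' @export
demons_register <- function(fixed, moving, cfg = demons_config()) {
  f <- as_pixels(fixed); m <- as_pixels(moving)
  if (!identical(dim(f), dim(m))) {
    padded <- pad_to_common_shape(f, m)
    f <- padded$a; m <- padded$b
  }
  shape <- dim(f)
  scales <- 2^((cfg$levels - 1):0)  # coarsest first
  dr <- dc <- NULL
  for (li in seq_len(cfg$levels)) {
    s <- scales[li]
    nr <- max(8L, round(shape[1] / s)); nc <- max(8L, round(shape[2] / s))
    fl <- if (s > 1) resize_matrix(f, nr, nc) else f
    ml <- if (s > 1) resize_matrix(m, nr, nc) else m
    if (is.null(dr)) {
      dr <- matrix(0, nr, nc); dc <- matrix(0, nr, nc)
    } else {
      fr <- nr / nrow(dr); fc <- nc / ncol(dr)
      dr <- resize_matrix(dr, nr, nc) * fr
      dc <- resize_matrix(dc, nr, nc) * fc
    }
    res <- demons_level(fl, ml, dr, dc, cfg$iterations_per_level[li],
                        cfg$smoothing_sigma, cfg$convergence_tol)
    dr <- res$dr; dc <- res$dc
  }
  field <- deformation_field(dr, dc)
  if (ssd(f, warp_pixels(m, field)) > ssd(f, m)) {
    warning("demons registration did not improve SSD; returning zero field")
    field <- deformation_field(matrix(0, shape[1], shape[2]),
                               matrix(0, shape[1], shape[2]))
  }
  field
}

warp_pixels <- function(px, field, fill = 0) {
  grids <- index_grids(dim(px))
  matrix(bilinear_sample(px, grids$r + field$dr, grids$c + field$dc, fill = fill),
         nrow(px), ncol(px))
}

#' Warp an image by a deformation field
#'
#' Backward warping with bilinear interpolation; samples falling outside the
#' image return 0.
#'
#' @param img matrix or `mammogram` whose shape equals the field's
#'   `fixed_shape`.
#' @param field a `deformation_field`.
#' @return same type as `img`.
#' @export
warp_image <- function(img, field) {
  px <- as_pixels(img)
  if (!identical(dim(px), field$fixed_shape))
    stop("image shape does not match the deformation field")
  replace_pixels(img, warp_pixels(px, field))
}

#' Propagate a future-round mass annotation onto the current grid
#'
#' Warps the mask as a float image through the future-to-current field
#' (computed with the current round as the fixed image) and rethresholds at
#' 0.5, which approximately preserves area under smooth deformations. The
#' result marks where the biopsy-confirmed future mass will appear in the
#' current mammogram and serves as the training ground truth. An empty
#' result (mass warped out of frame) is flagged for review via the
#' `flagged_empty` attribute and a warning.
#'
#' @param future_mask `annotation_mask` on the future image grid.
#' @param field `deformation_field` with the current image as fixed.
#' @return an `annotation_mask` with `source = "propagated"`.
#' @export
propagate_future_mask <- function(future_mask, field) {
  px <- as_pixels(future_mask)
  if (!identical(dim(px), field$fixed_shape))
    stop("mask shape does not match the deformation field")
  warped <- warp_pixels(px, field)
  out <- annotation_mask((warped >= 0.5) * 1, source = "propagated")
  if (sum(out$pixels) == 0) {
    warning("propagated mask is empty; flagged for review")
    attr(out, "flagged_empty") <- TRUE
  }
  out
}
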
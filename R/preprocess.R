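# Image enhancement and breast-region isolation, applied identically to
# every screening round before registration and subtraction.

#' Preprocessing configuration
#'
#' @param clahe_clip CLAHE clip limit as a fraction of the uniform histogram
#'   height (0.01 is common mammography practice).
#' @param clahe_tiles number of contextual tiles per image side.
#' @param gamma gamma-correction exponent (> 0; < 1 brightens).
#' @param border_margin width in pixels of the frame zeroed to suppress
#'   scanner-edge artifacts.
#' @return list of class `preprocess_config`.
#' @export
preprocess_config <- function(clahe_clip = 0.01, clahe_tiles = 8L,
                              gamma = 0.8, border_margin = 5L) {
  stopifnot(clahe_clip > 0, gamma > 0, border_margin >= 0, clahe_tiles >= 1)
  structure(list(clahe_clip = clahe_clip, clahe_tiles = as.integer(clahe_tiles),
                 gamma = gamma, border_margin = as.integer(border_margin)),
            class = "preprocess_config")
}

#' Min-max intensity normalization
#'
#' Maps the minimum to 0 and the maximum to 1; a constant image maps to
#' all zeros. Strictly monotone, hence order-preserving.
#'
#' @param img matrix or `mammogram`.
#' @return same type as `img`.
#' @export
normalize_intensity <- function(img) {
  px <- as_pixels(img)
  check_finite_matrix(px)
  rng <- range(px)
  if (rng[2] > rng[1]) px <- (px - rng[1]) / (rng[2] - rng[1])
  else px <- matrix(0, nrow(px), ncol(px))
  replace_pixels(img, px)
}

#' Contrast limited adaptive histogram equalization
#'
#' Local histogram equalization on a grid of tiles with a clipped histogram
#' (limits noise amplification in flat regions). Output is clamped to [0, 1].
#' A constant image is returned unchanged.
#'
#' @param img matrix or `mammogram`, values in [0, 1].
#' @param clip clip limit (fraction of uniform histogram height).
#' @param tiles tiles per side.
#' @return same type as `img`.
#' @export
apply_clahe <- function(img, clip = 0.01, tiles = 8L) {
  px <- as_pixels(img)
  if (min(dim(px)) < tiles)
    stop("CLAHE tile grid larger than image")
  if (diff(range(px)) == 0) return(img)
  bins <- 256L
  # the tile grid must divide the image evenly: replicate edges up to the
  # next multiple, equalize, crop back
  nr <- nrow(px); nc <- ncol(px)
  nr2 <- ceiling(nr / tiles) * tiles
  nc2 <- ceiling(nc / tiles) * tiles
  ext <- px[c(seq_len(nr), rep(nr, nr2 - nr)), c(seq_len(nc), rep(nc, nc2 - nc))]
  out <- EBImage::clahe(EBImage::Image(ext), nx = tiles, ny = tiles,
                        bins = bins, limit = max(clip * bins, 1))
  out <- as.matrix(out)[seq_len(nr), seq_len(nc)]
  replace_pixels(img, pmin(pmax(out, 0), 1))
}

#' Gamma correction
#'
#' Elementwise power transform `out = in^gamma` for images in [0, 1];
#' 0 and 1 are fixed points for every gamma.
#'
#' @param img matrix or `mammogram` in [0, 1].
#' @param gamma exponent, must be > 0.
#' @return same type as `img`.
#' @export
gamma_correct <- function(img, gamma) {
  if (gamma <= 0) stop("gamma must be > 0")
  px <- as_pixels(img)
  replace_pixels(img, px^gamma)
}

#' Zero a pixel frame around the image
#'
#' Sets a border of width `margin` to 0 and leaves the interior untouched;
#' suppresses bright scanner edges before breast segmentation.
#'
#' @param img matrix or `mammogram`.
#' @param margin frame width in pixels (>= 0).
#' @return same type as `img`.
#' @export
remove_border <- function(img, margin) {
  margin <- as.integer(margin)
  if (margin < 0) stop("margin must be >= 0")
  px <- as_pixels(img)
  if (margin >= floor(min(dim(px)) / 2))
    stop("margin must be smaller than half the smaller image dimension")
  if (margin > 0) {
    nr <- nrow(px); nc <- ncol(px)
    px[c(seq_len(margin), (nr - margin + 1):nr), ] <- 0
    px[, c(seq_len(margin), (nc - margin + 1):nc)] <- 0
  }
  replace_pixels(img, px)
}

#' Segment the breast region
#'
#' Binarizes the image and keeps the single largest 8-connected foreground
#' component (off-breast tags and labels are dropped), then fills interior
#' holes. The result is the support used for periphery removal during ROI
#' segmentation.
#'
#' @param img preprocessed matrix or `mammogram` in [0, 1].
#' @param threshold foreground threshold on [0, 1] intensities.
#' @return an `annotation_mask` of the breast region.
#' @export
segment_breast <- function(img, threshold = 0.05) {
  px <- as_pixels(img)
  fg <- px > threshold
  if (!any(fg)) stop("empty foreground: no breast region found")
  lab <- label_components(fg)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  mask <- (lab == keep) * 1
  mask <- as.matrix(EBImage::fillHull(EBImage::Image(mask)))
  annotation_mask(mask, source = "synthetic")
}

#' Full preprocessing chain
#'
#' Normalization, CLAHE, gamma correction and border removal, in that order
#' (border removal last so edge artifacts cannot influence the histogram
#' stages would be equivalent; the frame is zeroed before the breast mask is
#' computed either way). Deterministic and shape-preserving.
#'
#' @param img matrix or `mammogram`.
#' @param cfg a [preprocess_config()].
#' @return same type as `img`.
#' @export
preprocess_image <- function(img, cfg = preprocess_config()) {
  out <- normalize_intensity(img)
  out <- apply_clahe(out, clip = cfg$clahe_clip, tiles = cfg$clahe_tiles)
  out <- gamma_correct(out, cfg$gamma)
  remove_border(out, cfg$border_margin)
}
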
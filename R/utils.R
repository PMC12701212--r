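# Internal image helpers shared across modules. Images are plain numeric
# matrices in (row, col) orientation, 0-based coordinates are never used in
# R code itself; exported coordinates follow the package convention
# (0-based, row/col, origin top-left) only at serialization boundaries.

`%||%` <- function(a, b) if (is.null(a)) b else a

as_pixels <- function(x) {
  if (inherits(x, c("mammogram", "annotation_mask", "subtraction_image"))) x$pixels
  else if (is.matrix(x)) x
  else stop("expected a matrix, mammogram, annotation_mask or subtraction_image")
}

replace_pixels <- function(x, px) {
  if (is.matrix(x)) return(px)
  x$pixels <- px
  x
}

check_finite_matrix <- function(px, what = "pixels") {
  if (!is.matrix(px) || !is.numeric(px))
    stop(sprintf("%s must be a numeric matrix", what))
  if (!all(is.finite(px)))
    stop(sprintf("%s must be finite everywhere", what))
  invisible(px)
}

#' Disk-shaped structuring element
#'
#' Binary matrix of size (2r+1) x (2r+1) whose ones lie within Euclidean
#' distance `r` of the centre pixel. Used for all morphological operations so
#' the erosion/closing radii printed for the segmentation stage (2 px and
#' 10 px) have an unambiguous meaning.
#'
#' @param r integer radius in pixels (r >= 0).
#' @return numeric 0/1 matrix.
#' @export
disk_kernel <- function(r) {
  r <- as.integer(r)
  stopifnot(r >= 0)
  d <- 2L * r + 1L
  idx <- seq_len(d) - r - 1L
  g <- outer(idx^2, idx^2, "+")
  (g <= r^2) * 1
}

# Gaussian blur that tolerates sigma = 0 and preserves matrix type. When the
# kernel (about 6 sigma wide) would exceed the image, the blur is decomposed
# into repeated passes at a smaller sigma (variances add).
gaussian_blur <- function(px, sigma) {
  if (sigma <= 0) return(px)
  lim <- (min(dim(px)) - 1) / 7
  if (sigma <= lim) return(as.matrix(EBImage::gblur(px, sigma = sigma)))
  k <- ceiling((sigma / lim)^2)
  s <- sigma / sqrt(k)
  for (i in seq_len(k)) px <- as.matrix(EBImage::gblur(px, sigma = s))
  px
}

# 8-connected component labeling. Returns an integer matrix, 0 = background,
# components numbered 1..n in order of first (column-major) appearance.
label_components <- function(mask) {
  mask <- as_pixels(mask) > 0
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask)
  lab <- matrix(0L, nr, nc)
  if (length(fg) == 0L) return(lab)
  # edges between a foreground pixel and its E, S, SE, SW neighbours
  r <- ((fg - 1L) %% nr) + 1L
  c <- ((fg - 1L) %/% nr) + 1L
  edges <- integer(0)
  for (off in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- r + off[1]; c2 <- c + off[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    if (!any(ok)) next
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    keep <- mask[nb]
    if (any(keep)) edges <- c(edges, rbind(fg[ok][keep], nb[keep]))
  }
  ids <- match(seq_len(nr * nc), fg)  # map linear index -> vertex id
  g <- igraph::make_graph(ids[edges], n = length(fg), directed = FALSE)
  comp <- igraph::components(g)$membership
  # renumber components by first appearance in column-major order
  first <- match(unique(comp), comp)
  renum <- integer(max(comp))
  renum[comp[sort(first)]] <- seq_along(first)
  lab[fg] <- renum[comp]
  lab
}

# Bilinear sampling of matrix `px` at (rr, cc) (fractional, 1-based).
# Out-of-bounds samples return `fill`.
bilinear_sample <- function(px, rr, cc, fill = 0) {
  rr <- as.vector(rr); cc <- as.vector(cc)
  nr <- nrow(px); nc <- ncol(px)
  inb <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
  r0 <- pmin(pmax(floor(rr), 1), nr - 1L)
  c0 <- pmin(pmax(floor(cc), 1), nc - 1L)
  fr <- rr - r0; fc <- cc - c0
  fr <- pmin(pmax(fr, 0), 1); fc <- pmin(pmax(fc, 0), 1)
  v <- px[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    px[cbind(r0 + 1L, c0)] * fr * (1 - fc) +
    px[cbind(r0, c0 + 1L)] * (1 - fr) * fc +
    px[cbind(r0 + 1L, c0 + 1L)] * fr * fc
  v[!inb] <- fill
  v
}

# Row/column index grids for a given shape (matrices, same dim).
index_grids <- function(shape) {
  list(
    r = matrix(seq_len(shape[1]), shape[1], shape[2]),
    c = matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  )
}

# Deterministic per-task seed derived from a base seed (kept < 2^31).
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483647)
}

# Pad a matrix with a constant border of width w.
pad_matrix <- function(px, w, value = 0) {
  if (w <= 0) return(px)
  out <- matrix(value, nrow(px) + 2 * w, ncol(px) + 2 * w)
  out[(w + 1):(w + nrow(px)), (w + 1):(w + ncol(px))] <- px
  out
}

unpad_matrix <- function(px, w, shape) {
  if (w <= 0) return(px)
  px[(w + 1):(w + shape[1]), (w + 1):(w + shape[2])]
}
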
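# Shared fixtures and independent oracles used across test files.

# deterministic textured test image with an optional bright blob
make_test_image <- function(n = 96, blob_center = NULL, blob_sigma = 8,
                            blob_amp = 0.5, seed = 1) {
  set.seed(seed)
  tex <- mammodelta:::gaussian_blur(matrix(rnorm(n * n), n, n), 6)
  img <- 0.5 + 0.15 * tex / max(sd(tex), 1e-12)
  if (!is.null(blob_center)) {
    g <- expand.grid(r = seq_len(n), c = seq_len(n))
    img <- img + blob_amp * matrix(
      exp(-((g$r - blob_center[1])^2 + (g$c - blob_center[2])^2) /
            (2 * blob_sigma^2)), n, n)
  }
  img <- (img - min(img)) / (max(img) - min(img))
  img
}

# disk-shaped binary mask
disk_mask <- function(n, center, radius) {
  g <- expand.grid(r = seq_len(n), c = seq_len(n))
  matrix((g$r - center[1])^2 + (g$c - center[2])^2 <= radius^2, n, n)
}

# integer circular shift of image content by (dr, dc), zero-filled
shift_image <- function(img, dr, dc) {
  n <- nrow(img); m <- ncol(img)
  out <- matrix(0, n, m)
  rs <- seq_len(n) + dr; cs <- seq_len(m) + dc
  okr <- rs >= 1 & rs <= n; okc <- cs >= 1 & cs <= m
  out[okr, okc] <- img[rs[okr], cs[okc]]
  out
}

# numerical inverse of a smooth backward-warp field by fixed-point
# iteration: if moving = warp(fixed, t), the field demons should recover is
# the inverse u with u(x) = -t(x + u(x))
invert_field <- function(fld, iters = 25) {
  ur <- -fld$dr; uc <- -fld$dc
  grids <- mammodelta:::index_grids(fld$fixed_shape)
  for (i in seq_len(iters)) {
    tr <- matrix(mammodelta:::bilinear_sample(fld$dr, grids$r + ur, grids$c + uc),
                 nrow(ur), ncol(ur))
    tc <- matrix(mammodelta:::bilinear_sample(fld$dc, grids$r + ur, grids$c + uc),
                 nrow(ur), ncol(ur))
    ur <- -tr; uc <- -tc
  }
  deformation_field(ur, uc)
}

# textured half-ellipse phantom (breast-like support over smooth texture)
make_phantom <- function(n = 128, seed = 1) {
  set.seed(seed)
  g <- expand.grid(r = 1:n, c = 1:n)
  support <- matrix((g$c / (0.9 * n))^2 + ((g$r - n / 2) / (0.42 * n))^2 <= 1, n, n)
  tex <- mammodelta:::gaussian_blur(matrix(rnorm(n * n), n, n), 10) +
    0.5 * mammodelta:::gaussian_blur(matrix(rnorm(n * n), n, n), 4)
  img <- (0.5 + 0.25 * tex / sd(tex)) * support
  list(img = pmin(pmax(img, 0), 1), support = support)
}

# smooth random backward-warp field with the given max amplitude
make_smooth_field <- function(n, amp, smoothness = 30, seed = 1) {
  set.seed(seed)
  dr <- mammodelta:::gaussian_blur(matrix(rnorm(n * n), n, n), smoothness)
  dc <- mammodelta:::gaussian_blur(matrix(rnorm(n * n), n, n), smoothness)
  sc <- amp / max(sqrt(dr^2 + dc^2))
  deformation_field(dr * sc, dc * sc)
}

# ---- brute-force set-theoretic morphology (independent oracle) -----------

bf_shift <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- (1:nr) - dr; cs <- (1:nc) - dc
  okr <- rs >= 1 & rs <= nr; okc <- cs >= 1 & cs <= nc
  out[okr, okc] <- m[rs[okr], cs[okc]]
  out
}

bf_erode <- function(m, r) {
  k <- which(disk_kernel(r) == 1, arr.ind = TRUE) - r - 1L
  out <- matrix(TRUE, nrow(m), ncol(m))
  for (i in seq_len(nrow(k))) out <- out & bf_shift(m, -k[i, 1], -k[i, 2])
  out
}

bf_dilate <- function(m, r) {
  k <- which(disk_kernel(r) == 1, arr.ind = TRUE) - r - 1L
  out <- matrix(FALSE, nrow(m), ncol(m))
  for (i in seq_len(nrow(k))) out <- out | bf_shift(m, k[i, 1], k[i, 2])
  out
}

# closing on the infinite plane (dilation may extend beyond the frame and
# erosion must see it): pad, compute, crop
bf_closing <- function(m, r) {
  w <- r + 1L
  nr <- nrow(m); nc <- ncol(m)
  pm <- matrix(FALSE, nr + 2 * w, nc + 2 * w)
  pm[(w + 1):(w + nr), (w + 1):(w + nc)] <- m
  out <- bf_erode(bf_dilate(pm, r), r)
  out[(w + 1):(w + nr), (w + 1):(w + nc)]
}

# small labeled two-class feature data with one informative feature
make_separable_data <- function(n = 60, p = 6, seed = 1, gap = 3) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("f", seq_len(p))
  y <- rep(c(0, 1), length.out = n)
  X[y == 1, 1] <- X[y == 1, 1] + gap
  list(X = X, y = factor(y))
}

# tiny synthetic cohort shared by the pipeline tests (cheap: small images,
# low clutter)
tiny_cohort_config <- function(seed = 7) {
  synthetic_config(n_patients = 6, malignant_fraction = 0.5,
                   image_shape = c(128L, 128L), clutter_rate = 12,
                   mass_radius_range = c(7, 10), seed = seed)
}
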
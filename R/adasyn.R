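# Adaptive synthetic oversampling (ADASYN) of the minority class: synthetic
# samples are allotted per minority point in proportion to the local
# majority density (harder points get more), and generated by interpolation
# between minority neighbours. Applied to training folds only; test folds
# are never augmented.

#' ADASYN class balancing
#'
#' Brings the minority class to (approximate) parity with the majority.
#' For each minority sample, the fraction of majority points among its
#' `n_neighbors` nearest neighbours (in the full training set) weights how
#' many synthetic points it seeds; each synthetic point is a random convex
#' combination of the seed and one of its minority-class neighbours, so all
#' synthetic points lie on segments between minority originals. Original
#' rows are retained unchanged. If the minority class is too small for the
#' neighbourhood (< `n_neighbors + 1` samples), balanced random duplication
#' is used instead with a warning.
#'
#' @param X numeric matrix (rows = samples).
#' @param y two-level factor/vector; the rarer level is the minority.
#' @param seed RNG seed.
#' @param n_neighbors neighbourhood size K.
#' @return list with balanced `X`, `y`, and `synthetic` (logical row marker).
#' @export
adasyn_balance <- function(X, y, seed = 0L, n_neighbors = 5L) {
  X <- as.matrix(X)
  y <- factor(y)
  stopifnot(nlevels(y) == 2L, nrow(X) == length(y))
  counts <- table(y)
  minority <- names(counts)[which.min(counts)]
  n_min <- min(counts); n_maj <- max(counts)
  G <- n_maj - n_min
  if (G == 0)
    return(list(X = X, y = y, synthetic = rep(FALSE, nrow(X))))
  min_idx <- which(y == minority)
  set.seed(seed)
  if (n_min < n_neighbors + 1L) {
    warning("minority class too small for ADASYN; falling back to random duplication")
    dup <- sample(min_idx, G, replace = TRUE)
    return(list(X = rbind(X, X[dup, , drop = FALSE]),
                y = factor(c(as.character(y), as.character(y[dup])),
                           levels = levels(y)),
                synthetic = c(rep(FALSE, nrow(X)), rep(TRUE, G))))
  }
  Xm <- X[min_idx, , drop = FALSE]
  # K nearest neighbours of each minority point in the full set
  # (squared euclidean cross distances computed directly; the full pairwise
  # matrix over all training rows would be needlessly large)
  K <- n_neighbors
  d_all <- outer(rowSums(Xm^2), rowSums(X^2), "+") - 2 * Xm %*% t(X)
  r <- numeric(n_min)
  for (i in seq_len(n_min)) {
    di <- d_all[i, ]; di[min_idx[i]] <- Inf  # exclude self
    nb <- order(di)[seq_len(K)]
    r[i] <- sum(y[nb] != minority) / K
  }
  if (sum(r) == 0) r <- rep(1, n_min)  # no border points: spread uniformly
  g <- floor(r / sum(r) * G)
  # distribute the rounding remainder to the hardest points
  rem <- G - sum(g)
  if (rem > 0) {
    ord <- order(r, decreasing = TRUE)
    g[ord[seq_len(rem)]] <- g[ord[seq_len(rem)]] + 1L
  }
  # minority-minority neighbours for interpolation
  dmm <- as.matrix(stats::dist(Xm))
  diag(dmm) <- Inf
  Km <- min(K, n_min - 1L)
  syn <- vector("list", n_min)
  for (i in seq_len(n_min)) {
    if (g[i] == 0) next
    nb <- order(dmm[i, ])[seq_len(Km)]
    z <- nb[sample.int(Km, g[i], replace = TRUE)]
    lam <- stats::runif(g[i])
    syn[[i]] <- Xm[rep(i, g[i]), , drop = FALSE] +
      lam * (Xm[z, , drop = FALSE] - Xm[rep(i, g[i]), , drop = FALSE])
  }
  Xs <- do.call(rbind, syn[!vapply(syn, is.null, logical(1))])
  ns <- if (is.null(Xs)) 0L else nrow(Xs)
  list(X = rbind(X, Xs),
       y = factor(c(as.character(y), rep(minority, ns)), levels = levels(y)),
       synthetic = c(rep(FALSE, nrow(X)), rep(TRUE, ns)))
}
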
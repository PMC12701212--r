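# The 98-value feature vector per ROI: 15 shape features, 9 intensity /
# first-order statistics, 72 GLCM texture values (4 base features x
# (4 angles + mean + STD) x 3 offsets) and 2 epidemiological variables.
# The printed total of 98 and every published feature name are reproduced;
# the exact complement beyond the published names is a documented
# reconstruction (see the methods vignette).

GLCM_BASES <- c("Contrast", "Correlation", "Energy", "Homogeneity")
GLCM_COMPONENTS <- c("0", "45", "90", "135", "Mean", "STD")

#' GLCM specification
#'
#' @param offsets pixel offsets, positive and increasing (published values
#'   5, 15, 25).
#' @param gray_levels quantization depth of the co-occurrence matrix.
#' @return list of class `glcm_spec`.
#' @export
glcm_spec <- function(offsets = c(5L, 15L, 25L), gray_levels = 32L) {
  stopifnot(all(offsets > 0), all(diff(offsets) > 0), gray_levels >= 2)
  structure(list(offsets = as.integer(offsets),
                 angles = c(0, 45, 90, 135),
                 gray_levels = as.integer(gray_levels)),
            class = "glcm_spec")
}

#' Feature registry
#'
#' The fixed, ordered list of the 98 feature names with their group. The
#' registry is identical across runs; feature tables and selections refer to
#' these names.
#'
#' @return data.frame with columns `name` and `group`.
#' @export
feature_registry <- function() {
  shape <- c("Area", "Convex Area", "Filled Area", "Perimeter",
             "Major Axis Length", "Minor Axis Length", "Equivalent Diameter",
             "Eccentricity", "Solidity", "Extent", "Orientation",
             "Euler Number", "Circularity", "Compactness", "Shape Ratio")
  fos <- c("Mean Intensity", "Max Intensity", "Min Intensity", "STD",
           "Variance", "Smoothness", "Skewness", "Kurtosis", "Entropy")
  glcm <- as.vector(vapply(1:3, function(k)
    as.vector(vapply(GLCM_BASES, function(b)
      paste(b, GLCM_COMPONENTS, paste0("D", k)), character(6))),
    character(24)))
  epi <- c("Age", "Breast Density")
  data.frame(
    name = c(shape, fos, glcm, epi),
    group = c(rep("shape", length(shape)), rep("fos", length(fos)),
              rep("glcm", length(glcm)), rep("epidemiological", length(epi))),
    stringsAsFactors = FALSE)
}

#' Export the feature registry as JSON
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_feature_registry <- function(path) {
  jsonlite::write_json(list(registry_version = "1.0",
                            features = feature_registry()),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# perimeter of a binary patch: total length of its 0.5-level contours
# (sub-pixel marching-squares polylines; close to the true boundary length
# of the underlying region, unlike raw boundary-pixel counts)
mask_perimeter <- function(mask) {
  pm <- pad_matrix(mask * 1, 1L, 0)
  cl <- grDevices::contourLines(x = seq_len(nrow(pm)), y = seq_len(ncol(pm)),
                                z = pm, levels = 0.5)
  if (length(cl) == 0L) return(0)
  sum(vapply(cl, function(cc) {
    xs <- cc$x; ys <- cc$y
    # two corner-cutting passes remove the marching-squares staircase bias
    # (a digital disk would otherwise read ~7% long); straight edges are
    # essentially unaffected
    for (it in 1:2) {
      if (length(xs) < 3) break
      xs2 <- (xs + c(xs[-1], xs[1])) / 2
      ys2 <- (ys + c(ys[-1], ys[1])) / 2
      xs <- xs2; ys <- ys2
    }
    xs <- c(xs, xs[1]); ys <- c(ys, ys[1])
    sum(sqrt(diff(xs)^2 + diff(ys)^2))
  }, numeric(1)))
}

count_holes <- function(mask) {
  pm <- pad_matrix((!mask) * 1, 1L, 1)  # background, padded with background
  lab <- label_components_4(pm > 0)
  border_ids <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  length(setdiff(unique(lab[lab > 0]), border_ids))
}

# 4-connected labeling (for background/hole counting, the complement of
# 8-connected foreground)
label_components_4 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask)
  lab <- matrix(0L, nr, nc)
  if (length(fg) == 0L) return(lab)
  r <- ((fg - 1L) %% nr) + 1L
  c <- ((fg - 1L) %/% nr) + 1L
  edges <- integer(0)
  for (off in list(c(0L, 1L), c(1L, 0L))) {
    r2 <- r + off[1]; c2 <- c + off[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    if (!any(ok)) next
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    keep <- mask[nb]
    if (any(keep)) edges <- c(edges, rbind(fg[ok][keep], nb[keep]))
  }
  ids <- match(seq_len(nr * nc), fg)
  g <- igraph::make_graph(ids[edges], n = length(fg), directed = FALSE)
  lab[fg] <- igraph::components(g)$membership
  lab
}

#' Shape features of one ROI
#'
#' Region geometry computed from the binary support: areas (raw, filled,
#' convex), contour-based perimeter, the inertia-ellipse axes, topology
#' (Euler number = components minus holes) and the derived descriptors
#' Circularity = 4*pi*A/P^2, Compactness = P^2/(4*pi*A) and
#' Shape Ratio = major/minor axis.
#'
#' @param roi an `roi` object.
#' @return named numeric vector of 15 values.
#' @export
shape_features <- function(roi) {
  if (roi$area == 0L) stop("empty ROI mask")
  lin <- roi$pixels
  shape <- roi$shape
  r <- ((lin - 1L) %% shape[1]) + 1L
  c <- ((lin - 1L) %/% shape[1]) + 1L
  r0 <- min(r); c0 <- min(c)
  patch <- matrix(FALSE, max(r) - r0 + 1L, max(c) - c0 + 1L)
  patch[cbind(r - r0 + 1L, c - c0 + 1L)] <- TRUE

  area <- roi$area
  filled <- as.matrix(EBImage::fillHull(EBImage::Image(patch * 1))) > 0
  filled_area <- sum(filled)
  perim <- mask_perimeter(patch)

  # convex hull over pixel centres; pixel-coverage area via shoelace +
  # half the hull perimeter + 1 (Pick-style correction)
  pts <- cbind(r, c)
  if (nrow(unique(pts)) >= 3) {
    h <- grDevices::chull(pts[, 2], pts[, 1])
    hx <- pts[h, 2]; hy <- pts[h, 1]
    shoe <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
    hper <- sum(sqrt(diff(c(hx, hx[1]))^2 + diff(c(hy, hy[1]))^2))
    convex_area <- shoe + hper / 2 + 1
  } else convex_area <- area

  # inertia ellipse from central moments
  mr <- mean(r); mc <- mean(c)
  m20 <- mean((r - mr)^2); m02 <- mean((c - mc)^2); m11 <- mean((r - mr) * (c - mc))
  common <- sqrt(max((m20 - m02)^2 + 4 * m11^2, 0))
  l1 <- (m20 + m02 + common) / 2
  l2 <- (m20 + m02 - common) / 2
  major <- 4 * sqrt(max(l1, 0))
  minor <- 4 * sqrt(max(l2, 0))
  ecc <- if (l1 > 0) sqrt(pmax(1 - l2 / l1, 0)) else 0
  orient <- if (common > 0) 0.5 * atan2(2 * m11, m02 - m20) * 180 / pi else 0

  euler <- 1L - count_holes(patch)  # one 8-connected component per ROI
  bbox_area <- prod(dim(patch))
  eqd <- sqrt(4 * area / pi)
  circ <- 4 * pi * area / max(perim^2, 1e-12)
  c("Area" = area,
    "Convex Area" = convex_area,
    "Filled Area" = filled_area,
    "Perimeter" = perim,
    "Major Axis Length" = major,
    "Minor Axis Length" = minor,
    "Equivalent Diameter" = eqd,
    "Eccentricity" = ecc,
    "Solidity" = area / max(convex_area, 1e-12),
    "Extent" = area / bbox_area,
    "Orientation" = orient,
    "Euler Number" = euler,
    "Circularity" = circ,
    "Compactness" = 1 / max(circ, 1e-12),
    "Shape Ratio" = major / max(minor, 0.5))
}

#' Intensity and first-order-statistics features of one ROI
#'
#' Computed over the ROI's pixels of the enhanced subtraction image:
#' mean/max/min, STD and variance, Smoothness = 1 - 1/(1 + variance),
#' skewness, kurtosis (Pearson, non-excess) and Shannon entropy of a
#' 64-bin histogram over [0, 1] in bits.
#'
#' @param roi an `roi` object.
#' @param img matrix or image object on the ROI's grid.
#' @return named numeric vector of 9 values.
#' @export
intensity_fos_features <- function(roi, img) {
  if (roi$area == 0L) stop("empty ROI")
  v <- as_pixels(img)[roi$pixels]
  n <- length(v)
  mu <- mean(v)
  va <- if (n > 1) stats::var(v) else 0
  m2 <- mean((v - mu)^2)
  skew <- if (m2 > 1e-24) mean((v - mu)^3) / m2^1.5 else 0
  kurt <- if (m2 > 1e-24) mean((v - mu)^4) / m2^2 else 0
  bins <- pmin(pmax(floor(v * 64) + 1L, 1L), 64L)
  p <- tabulate(bins, 64L) / n
  p <- p[p > 0]
  c("Mean Intensity" = mu,
    "Max Intensity" = max(v),
    "Min Intensity" = min(v),
    "STD" = sqrt(va),
    "Variance" = va,
    "Smoothness" = 1 - 1 / (1 + va),
    "Skewness" = skew,
    "Kurtosis" = kurt,
    "Entropy" = -sum(p * log2(p)))
}

glcm_matrix <- function(q, G, dr, dc) {
  nr <- nrow(q); nc <- ncol(q)
  r1 <- max(1, 1 - dr):min(nr, nr - dr)
  c1 <- max(1, 1 - dc):min(nc, nc - dc)
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + dr, c1 + dc, drop = FALSE]
  counts <- tabulate((a - 1L) * G + b, G * G)
  m <- matrix(counts, G, G, byrow = TRUE)
  m <- m + t(m)  # symmetric
  s <- sum(m)
  if (s > 0) m / s else m
}

glcm_stats <- function(p, G) {
  i <- matrix(seq_len(G), G, G)
  j <- t(i)
  d <- abs(i - j)
  contrast <- sum(p * d^2)
  energy <- sum(p^2)
  homog <- sum(p / (1 + d))
  mu <- sum(p * i)           # symmetric: row and column means equal
  va <- sum(p * (i - mu)^2)
  corr <- if (va > 1e-12) sum(p * (i - mu) * (j - mu)) / va else 0
  c(Contrast = contrast, Correlation = corr, Energy = energy, Homogeneity = homog)
}

#' GLCM texture features of one ROI
#'
#' The bounding-box patch of the enhanced subtraction image is quantized to
#' `gray_levels` levels over its own intensity range (so texture is invariant
#' to adding a constant). For every offset and angle a symmetric, normalized
#' co-occurrence matrix yields Contrast, Correlation, Energy and Homogeneity;
#' per offset the four per-angle values are reported together with their mean
#' and STD, i.e. 24 values per offset and 72 in total. A patch smaller than
#' an offset is edge-padded first and the result flagged via the
#' `padded_offsets` attribute. A constant patch gives Contrast 0, Energy 1,
#' Homogeneity 1 and (by the degenerate-variance rule) Correlation 0.
#'
#' @param roi an `roi` object.
#' @param img matrix or image object on the ROI's grid.
#' @param spec a [glcm_spec()].
#' @return named numeric vector of 72 values.
#' @export
glcm_features <- function(roi, img, spec = glcm_spec()) {
  px <- as_pixels(img)
  b <- roi$bbox
  patch <- px[(b["row0"] + 1L):b["row1"], (b["col0"] + 1L):b["col1"], drop = FALSE]
  G <- spec$gray_levels
  out <- numeric(0)
  padded <- integer(0)
  for (k in seq_along(spec$offsets)) {
    d <- spec$offsets[k]
    pk <- patch
    if (min(dim(pk)) <= d) {
      padded <- c(padded, d)
      while (nrow(pk) <= d) pk <- rbind(pk, pk[nrow(pk), , drop = FALSE])
      while (ncol(pk) <= d) pk <- cbind(pk, pk[, ncol(pk), drop = FALSE])
    }
    rng <- range(pk)
    q <- if (rng[2] > rng[1])
      pmin(1L + as.integer(floor((pk - rng[1]) / (rng[2] - rng[1]) * G)), G)
    else matrix(1L, nrow(pk), ncol(pk))
    q <- matrix(q, nrow(pk), ncol(pk))
    offs <- list(`0` = c(0L, d), `45` = c(-d, d), `90` = c(-d, 0L), `135` = c(-d, -d))
    per_angle <- vapply(offs, function(o)
      glcm_stats(glcm_matrix(q, G, o[1], o[2]), G), numeric(4))
    for (base in GLCM_BASES) {
      v <- per_angle[base, ]
      vals <- c(v, mean(v), stats::sd(v))
      names(vals) <- paste(base, GLCM_COMPONENTS, paste0("D", k))
      out <- c(out, vals)
    }
  }
  if (length(padded)) attr(out, "padded_offsets") <- padded
  out
}

#' Assemble the full 98-value feature vector of one ROI
#'
#' Shape (15) + intensity/FOS (9) + GLCM (72) + epidemiological (2: age in
#' years and BI-RADS density a-d encoded 1-4), in fixed registry order.
#'
#' @param roi an `roi` object.
#' @param img the enhanced subtraction image (matrix or object).
#' @param case_meta list with `age` and `birads_density`.
#' @param spec a [glcm_spec()].
#' @return named numeric vector of length 98 with attribute
#'   `registry_version`.
#' @export
assemble_feature_vector <- function(roi, img, case_meta, spec = glcm_spec()) {
  if (is.null(case_meta$age) || is.null(case_meta$birads_density))
    stop("case_meta must provide age and birads_density")
  dens <- match(case_meta$birads_density, c("a", "b", "c", "d"))
  if (is.na(dens)) stop("birads_density must be one of a, b, c, d")
  vals <- c(shape_features(roi),
            intensity_fos_features(roi, img),
            glcm_features(roi, img, spec),
            "Age" = as.numeric(case_meta$age),
            "Breast Density" = as.numeric(dens))
  reg <- feature_registry()$name
  vals <- vals[reg]
  if (length(vals) != 98L || any(is.na(names(vals))) || !all(is.finite(vals)))
    stop("feature assembly failed: registry mismatch or non-finite value")
  attr(vals, "registry_version") <- "1.0"
  vals
}

#' Feature table for a list of ROIs
#'
#' @param rois list of labeled `roi` objects.
#' @param img the enhanced subtraction image.
#' @param case_meta list with `patient_id`, `view`, `age`, `birads_density`.
#' @param spec a [glcm_spec()].
#' @return data.frame: 98 feature columns plus patient_id, view, roi_id,
#'   label.
#' @export
roi_feature_table <- function(rois, img, case_meta, spec = glcm_spec()) {
  reg <- feature_registry()$name
  if (length(rois) == 0L) {
    out <- as.data.frame(matrix(numeric(0), 0, length(reg)))
    names(out) <- reg
    out$patient_id <- character(0); out$view <- character(0)
    out$roi_id <- integer(0); out$label <- character(0)
    return(out)
  }
  mat <- t(vapply(rois, function(r)
    as.numeric(assemble_feature_vector(r, img, case_meta, spec)),
    numeric(length(reg))))
  out <- as.data.frame(mat)
  names(out) <- reg
  out$patient_id <- case_meta$patient_id
  out$view <- case_meta$view
  out$roi_id <- vapply(rois, function(r) r$roi_id, integer(1))
  out$label <- vapply(rois, function(r) r$gt_label, character(1))
  out
}
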
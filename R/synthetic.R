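# Reproducible synthetic mammogram triplets emulating the structure of the
# screening cohort: 75 patients (34 malignant / 41 normal), two views, three
# rounds related by smooth deformations, multi-scale background texture,
# interval clutter, and -- in malignant cases -- a future-round mass with a
# faint deformation-consistent precursor in the current round.

#' Synthetic cohort configuration
#'
#' Defaults emulate the study population: 75 patients with 34 malignant,
#' ages uniform in 46-79, BI-RADS densities drawn in proportion 13/29/29/4
#' (a/b/c/d). `clutter_rate` controls the expected number of interval-change
#' blobs per image and is tuned so segmentation yields on the order of the
#' study's ~49 candidate ROIs per image; `precursor_contrast` scales the
#' current-round precursor relative to the future mass amplitude (faint
#' enough to be invisible against the texture, visible after subtraction).
#'
#' @param n_patients number of cases.
#' @param malignant_fraction fraction of malignant cases (34/75 by default).
#' @param image_shape (rows, cols) of every image.
#' @param texture_scale amplitude of the background texture.
#' @param deformation_amplitude max inter-round displacement in pixels.
#' @param deformation_smoothness Gaussian sigma (px) of the random fields.
#' @param mass_radius_range (min, max) mass radius in pixels.
#' @param precursor_contrast precursor amplitude as a fraction of the mass
#'   amplitude.
#' @param clutter_rate expected clutter blobs per image (Poisson).
#' @param noise_sd iid pixel noise per round.
#' @param seed master seed; every random draw derives from it.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 75L, malignant_fraction = 34 / 75,
                             image_shape = c(256L, 256L), texture_scale = 0.12,
                             deformation_amplitude = 8, deformation_smoothness = 40,
                             mass_radius_range = c(9, 14),
                             precursor_contrast = 0.15, clutter_rate = 50,
                             noise_sd = 0.004, seed = 0L) {
  stopifnot(malignant_fraction > 0, malignant_fraction < 1,
            deformation_amplitude >= 0, length(image_shape) == 2)
  structure(list(n_patients = as.integer(n_patients),
                 malignant_fraction = malignant_fraction,
                 image_shape = as.integer(image_shape),
                 texture_scale = texture_scale,
                 deformation_amplitude = deformation_amplitude,
                 deformation_smoothness = deformation_smoothness,
                 mass_radius_range = mass_radius_range,
                 precursor_contrast = precursor_contrast,
                 clutter_rate = clutter_rate, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# breast-shaped support: half-ellipse against the left (chest-wall) edge;
# the MLO view adds a pectoral wedge in the upper corner
breast_support <- function(shape, view) {
  g <- index_grids(shape)
  a <- 0.92 * shape[2]            # horizontal semi-axis (from the left edge)
  b <- 0.42 * shape[1]            # vertical semi-axis
  cy <- shape[1] / 2
  mask <- (g$c / a)^2 + ((g$r - cy) / b)^2 <= 1
  if (view == "MLO") {
    wedge <- (g$r + g$c) < 0.55 * shape[1]
    mask <- mask | (wedge & g$c < 0.45 * shape[2])
  }
  mask
}

smooth_noise_field <- function(shape, sigma) {
  f <- gaussian_blur(matrix(stats::rnorm(prod(shape)), shape[1], shape[2]), sigma)
  f / max(stats::sd(f), 1e-12)
}

# multi-scale background texture in [0, 1]-ish units; dominated by smooth
# parenchyma-scale structure (a deformable registration can realign it),
# with only a small fine-scale component
background_texture <- function(shape, scale) {
  tex <- 0.45 +
    scale * 0.7 * smooth_noise_field(shape, 32) +
    scale * 0.35 * smooth_noise_field(shape, 12) +
    scale * 0.08 * smooth_noise_field(shape, 4)
  pmin(pmax(tex, 0.05), 0.95)
}

random_deformation <- function(shape, amplitude, smoothness) {
  if (amplitude <= 0) {
    z <- matrix(0, shape[1], shape[2])
    return(deformation_field(z, z))
  }
  dr <- smooth_noise_field(shape, smoothness)
  dc <- smooth_noise_field(shape, smoothness)
  mx <- max(sqrt(dr^2 + dc^2))
  s <- amplitude / max(mx, 1e-12) * stats::runif(1, 0.6, 1)
  deformation_field(dr * s, dc * s)
}

# flat-top (super-Gaussian) blob: ~constant plateau of radius R with a soft
# shoulder; masses and precursors use this profile so their thresholded
# support is stable
flat_blob <- function(shape, center, radius, amplitude) {
  g <- index_grids(shape)
  r2 <- ((g$r - center[1])^2 + (g$c - center[2])^2) / radius^2
  amplitude * exp(-r2^2)
}

gaussian_blob <- function(shape, center, sigma, amplitude) {
  g <- index_grids(shape)
  amplitude * exp(-((g$r - center[1])^2 + (g$c - center[2])^2) / (2 * sigma^2))
}

random_point_in <- function(mask) {
  idx <- which(mask)
  lin <- idx[sample.int(length(idx), 1)]
  c(((lin - 1L) %% nrow(mask)) + 1L, ((lin - 1L) %/% nrow(mask)) + 1L)
}

# interval clutter: Poisson count of small bright blobs, placed with a
# minimum mutual spacing so the closing step of segmentation does not fuse
# unrelated changes into one giant region
add_clutter <- function(shape, region, rate, min_spacing = 22) {
  n <- stats::rpois(1, rate)
  out <- matrix(0, shape[1], shape[2])
  if (n == 0 || !any(region)) return(out)
  centers <- matrix(numeric(0), 0, 2)
  attempts <- 0L
  while (nrow(centers) < n && attempts < 40L * n) {
    attempts <- attempts + 1L
    ctr <- random_point_in(region)
    if (nrow(centers) == 0 ||
        min((centers[, 1] - ctr[1])^2 + (centers[, 2] - ctr[2])^2) >= min_spacing^2)
      centers <- rbind(centers, ctr)
  }
  for (i in seq_len(nrow(centers))) {
    sigma <- stats::runif(1, 2.2, 3.2)
    amp <- stats::runif(1, 0.45, 0.7)
    out <- out + gaussian_blob(shape, centers[i, ], sigma, amp)
  }
  out
}

#' Generate one synthetic case
#'
#' Per view, a shared anatomical texture is deformed independently for the
#' prior and future rounds (the current round is the reference frame), each
#' round receives its own interval clutter and pixel noise, and malignant
#' cases get a bright future-round mass plus a faint precursor at the
#' deformation-consistent location in the current round. The future mask is
#' the exact injected mass support. Fully deterministic given
#' `config$seed` and `patient_index`.
#'
#' @param config a [synthetic_config()].
#' @param patient_index 1-based case index; indices
#'   `1..round(malignant_fraction * n)` are malignant.
#' @return a `case_record` (with a `truth` attribute carrying the generator's
#'   current-round mass centers and radii for self-consistency checks).
#' @export
generate_case <- function(config, patient_index) {
  set.seed(derive_seed(config$seed, patient_index))
  n_mal <- round(config$malignant_fraction * config$n_patients)
  label <- if (patient_index <= n_mal) "malignant" else "normal"
  pid <- sprintf("P%03d", patient_index)
  age <- stats::runif(1, 46, 79)
  density <- sample(c("a", "b", "c", "d"), 1, prob = c(13, 29, 29, 4) / 75)
  shape <- config$image_shape
  images <- list()
  masks <- list()
  truth <- list()
  for (view in c("CC", "MLO")) {
    support <- breast_support(shape, view)
    base <- background_texture(shape, config$texture_scale) * support
    # clearance from the skin line / image frame: enough for the periphery
    # band plus the closing at the default scale, reduced on small canvases
    margin <- as.integer(min(max(config$mass_radius_range) + 22,
                             max(floor(min(shape) / 4),
                                 max(config$mass_radius_range) + 2)))
    interior <- as.matrix(EBImage::erode(EBImage::Image(support * 1),
                                         disk_kernel(margin))) > 0
    # also stay clear of the image frame (chest-wall edge included)
    interior[c(seq_len(margin), (shape[1] - margin + 1):shape[1]), ] <- FALSE
    interior[, c(seq_len(margin), (shape[2] - margin + 1):shape[2])] <- FALSE
    mass_amp <- 1.0
    mass <- NULL
    clutter_region <- interior
    if (label == "malignant") {
      if (!any(interior))
        stop("mass radius exceeds the breast support at this image size")
      radius <- stats::runif(1, config$mass_radius_range[1],
                             config$mass_radius_range[2])
      ctr <- random_point_in(interior)
      mass <- list(center = ctr, radius = radius)
      truth[[view]] <- mass
      # interval clutter represents unrelated change; keep it clear of the
      # mass site so the closing step cannot fuse the two
      g <- index_grids(shape)
      near <- ((g$r - ctr[1])^2 + (g$c - ctr[2])^2) <= (radius + 26)^2
      clutter_region <- interior & !near
    }
    fields <- list(prior = random_deformation(shape, config$deformation_amplitude,
                                              config$deformation_smoothness),
                   future = random_deformation(shape, config$deformation_amplitude,
                                               config$deformation_smoothness))
    for (round in c("prior", "current", "future")) {
      # interval change accumulates: most clutter is new in the current
      # round (it is what subtraction must flag); the prior round carries a
      # little of its own, the future round an intermediate amount
      rate <- config$clutter_rate *
        switch(round, prior = 0.15, current = 1.0, future = 0.3)
      content <- base + add_clutter(shape, clutter_region, rate)
      if (!is.null(mass)) {
        if (round == "future")
          content <- content + flat_blob(shape, mass$center, mass$radius, mass_amp)
        if (round == "current")
          content <- content + flat_blob(shape, mass$center, mass$radius,
                                         config$precursor_contrast * mass_amp)
      }
      if (round != "current") {
        content <- warp_pixels(content, fields[[round]])
        content <- content * (warp_pixels(support * 1, fields[[round]]) > 0.5)
      }
      content <- content + stats::rnorm(prod(shape), sd = config$noise_sd)
      content <- pmin(pmax(content, 0), 1.2) / 1.2
      images[[paste(round, view, sep = "_")]] <-
        mammogram(matrix(content, shape[1], shape[2]), view = view,
                  round = round, patient_id = pid, bit_depth = 16L)
      if (round == "future" && !is.null(mass)) {
        g <- index_grids(shape)
        m0 <- ((g$r - mass$center[1])^2 + (g$c - mass$center[2])^2) <= mass$radius^2
        masks[[view]] <- annotation_mask(
          (warp_pixels(m0 * 1, fields$future) >= 0.5) * 1, source = "synthetic")
      }
    }
  }
  rec <- case_record(pid, age, density, label, images, masks)
  attr(rec, "truth") <- truth
  rec
}

#' Sample cohort demographics
#'
#' Age uniform in 46-79 years; BI-RADS densities multinomial with the
#' study's a/b/c/d proportions 13/29/29/4 out of 75.
#'
#' @param n number of patients.
#' @param seed RNG seed.
#' @return data.frame with `age` and `birads_density`.
#' @export
sample_demographics <- function(n, seed = 0L) {
  set.seed(seed)
  data.frame(age = stats::runif(n, 46, 79),
             birads_density = sample(c("a", "b", "c", "d"), n, replace = TRUE,
                                     prob = c(13, 29, 29, 4) / 75),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort
#'
#' `round(malignant_fraction * n_patients)` malignant cases followed by
#' normal cases, all derived from the single master seed. Optionally writes
#' images, masks and a JSON manifest to `dir` in the format
#' [load_manifest()] reads.
#'
#' @param config a [synthetic_config()].
#' @param dir optional output directory.
#' @param progress print one line per case.
#' @return a `cohort_manifest` (cases carry their generator `truth`
#'   attributes).
#' @export
generate_cohort <- function(config = synthetic_config(), dir = NULL,
                            progress = FALSE) {
  cases <- lapply(seq_len(config$n_patients), function(i) {
    if (progress) message(sprintf("generating case %d/%d", i, config$n_patients))
    generate_case(config, i)
  })
  cohort <- cohort_manifest(cases)
  if (!is.null(dir)) write_manifest(cohort, dir)
  cohort
}
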
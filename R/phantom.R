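#' Configuration for the synthetic ultrasound phantom generator
#'
#' The phantom generator emulates the statistical difficulties of
#' clinical B-mode ultrasound: smallish lesions with irregular star-convex
#' contours, low lesion/background contrast, fuzzy (Gaussian-blurred)
#' boundaries, multiplicative speckle noise, and depth-attenuating
#' acoustic shadow bands. Lesions are hypoechoic (darker than background)
#' by default.
#'
#' @param image_size Pixels per side (square images), >= 32.
#' @param lesion_area_fraction_range `(min, max)` fraction of the image
#'   area occupied by the lesion, `0 < min <= max < 1`.
#' @param boundary_irregularity Nonnegative amplitude of the smooth random
#'   radial perturbation of the lesion contour (0 = exact ellipse).
#' @param contrast Mean relative intensity gap between lesion and
#'   background before noise, in `(0, 1]`.
#' @param background_level Background echo intensity `b0` in `(0, 1]`;
#'   the lesion's ideal level is `b0 * (1 - contrast)`.
#' @param boundary_blur_sigma Gaussian blur (pixels) applied to the ideal
#'   two-level field (fuzzy boundaries).
#' @param speckle_strength Variance of the unit-mean multiplicative
#'   speckle (Gamma-distributed pixel factors); 0 disables speckle.
#' @param shadow_probability Probability of inserting a vertical acoustic
#'   shadow band whose attenuation grows with depth.
#' @param hyperechoic If TRUE the lesion is brighter than background.
#' @param seed Master integer seed; per-sample seeds are derived from it
#'   (see [phantom_sample_seed()]) so each sample is independently
#'   reproducible.
#' @return An object of class `us_phantom_config`.
#' @export
phantom_config <- function(image_size = 512,
                           lesion_area_fraction_range = c(0.03, 0.2),
                           boundary_irregularity = 0.25,
                           contrast = 0.35,
                           background_level = 0.65,
                           boundary_blur_sigma = 2,
                           speckle_strength = 0.3,
                           shadow_probability = 0.3,
                           hyperechoic = FALSE,
                           seed = 1L) {
  r <- lesion_area_fraction_range
  stopifnot(
    image_size >= 32,
    length(r) == 2, r[1] > 0, r[1] <= r[2], r[2] < 1,
    boundary_irregularity >= 0,
    contrast > 0, contrast <= 1,
    background_level > 0, background_level <= 1,
    boundary_blur_sigma >= 0,
    speckle_strength >= 0,
    shadow_probability >= 0, shadow_probability <= 1
  )
  structure(list(
    image_size = as.integer(image_size),
    lesion_area_fraction_range = as.numeric(r),
    boundary_irregularity = boundary_irregularity,
    contrast = contrast,
    background_level = background_level,
    boundary_blur_sigma = boundary_blur_sigma,
    speckle_strength = speckle_strength,
    shadow_probability = shadow_probability,
    hyperechoic = isTRUE(hyperechoic),
    seed = as.integer(seed)
  ), class = "us_phantom_config")
}

#' Per-sample seed derivation
#'
#' Maps a master seed and sample index to an independent sample seed by a
#' fixed affine rule modulo a Mersenne prime, so any sample of a dataset
#' can be regenerated in isolation.
#'
#' @param master_seed Integer master seed.
#' @param index 1-based sample index.
#' @return An integer seed.
#' @export
phantom_sample_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) * 48271 + as.numeric(index) * 16807) %%
               2147483647)
}

#' Sample an irregular star-convex lesion mask
#'
#' Draws an ellipse with random center, orientation and axis ratio, then
#' perturbs its boundary radius by a smooth random radial function (a
#' low-order Fourier series in the polar angle) with amplitude
#' proportional to `boundary_irregularity`, and fills the region. The
#' draw is repeated until the lesion area lands inside
#' `lesion_area_fraction_range` (at most `max_retries` attempts).
#'
#' @param cfg A [phantom_config()].
#' @param seed Integer seed for this sample.
#' @param max_retries Attempts before giving up (default 100); exceeding
#'   it signals an infeasible configuration.
#' @return A binary `image_size x image_size` matrix (1 = lesion).
#' @export
sample_lesion_mask <- function(cfg, seed = cfg$seed, max_retries = 100L) {
  stopifnot(inherits(cfg, "us_phantom_config"))
  withr::with_seed(as.integer(seed), {
    n <- cfg$image_size
    lo <- cfg$lesion_area_fraction_range[1]
    hi <- cfg$lesion_area_fraction_range[2]
    for (try in seq_len(max_retries)) {
      frac <- stats::runif(1, lo, hi)
      # ellipse with the target area: pi*a*b = frac*n^2
      ratio <- stats::runif(1, 0.5, 1)   # b/a
      a <- sqrt(frac * n^2 / (pi * ratio))
      b <- a * ratio
      theta0 <- stats::runif(1, 0, pi)
      margin <- 0.05 * n
      if (margin + a >= n - margin - a) next # lesion too large to place
      cx <- stats::runif(1, margin + a, n - margin - a)
      cy <- stats::runif(1, margin + a, n - margin - a)
      # smooth periodic radial perturbation
      nh <- 4L
      amp <- stats::rnorm(nh, 0, 1) / seq_len(nh)
      phase <- stats::runif(nh, 0, 2 * pi)
      xg <- matrix(rep(seq_len(n) - cx, each = n), n, n)   # col offsets
      yg <- matrix(rep(seq_len(n) - cy, times = n), n, n)  # row offsets
      xr <- cos(theta0) * xg + sin(theta0) * yg
      yr <- -sin(theta0) * xg + cos(theta0) * yg
      ang <- atan2(yr / b, xr / a)
      pert <- matrix(0, n, n)
      for (h in seq_len(nh)) {
        pert <- pert + amp[h] * cos(h * ang + phase[h])
      }
      pert <- pert / max(1e-9, max(abs(pert)))
      radial <- sqrt((xr / a)^2 + (yr / b)^2)
      mask <- (radial <= 1 + cfg$boundary_irregularity * pert) * 1
      area <- sum(mask) / n^2
      if (area >= lo && area <= hi) {
        storage.mode(mask) <- "double"
        return(mask)
      }
    }
    stop(sprintf(
      "could not satisfy lesion area fraction [%g, %g] in %d attempts; %s",
      lo, hi, max_retries, "the phantom configuration looks infeasible"))
  })
}

#' Render a phantom ultrasound image from a lesion mask
#'
#' Rendering pipeline: (a) ideal two-level field with background `b0` and
#' lesion `b0 * (1 - contrast)` (hypoechoic; reversed if `hyperechoic`),
#' (b) Gaussian blur of `boundary_blur_sigma` pixels, (c) multiplicative
#' unit-mean Gamma speckle with variance `speckle_strength`, (d) with
#' probability `shadow_probability` a vertical band below a random row is
#' attenuated by a profile that decays with depth, (e) clipping to
#' `[0, 1]`.
#'
#' @param mask Binary lesion mask.
#' @param cfg A [phantom_config()] whose `image_size` matches the mask.
#' @param seed Integer seed for the stochastic stages (speckle/shadow).
#' @return A numeric matrix in `[0, 1]` with attribute `"shadow"` (TRUE
#'   if a shadow band was inserted).
#' @export
render_image <- function(mask, cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "us_phantom_config"))
  if (!all(dim(mask) == cfg$image_size)) {
    stop("mask size does not match cfg$image_size")
  }
  withr::with_seed(as.integer(seed), {
    b0 <- cfg$background_level
    lesion_level <- if (cfg$hyperechoic) {
      min(1, b0 * (1 + cfg$contrast))
    } else {
      b0 * (1 - cfg$contrast)
    }
    img <- b0 + (lesion_level - b0) * mask
    if (cfg$boundary_blur_sigma > 0) {
      img <- ebi_gblur(img, cfg$boundary_blur_sigma)
    }
    if (cfg$speckle_strength > 0) {
      shape <- 1 / cfg$speckle_strength
      f <- matrix(stats::rgamma(length(img), shape = shape, rate = shape),
                  nrow(img), ncol(img))
      img <- img * f
    }
    shadow <- stats::runif(1) < cfg$shadow_probability
    if (shadow) {
      n <- nrow(img)
      w <- max(2L, round(stats::runif(1, 0.08, 0.2) * n))
      c0 <- sample.int(n - w + 1L, 1L)
      r0 <- sample.int(max(1L, n %/% 2L), 1L)
      depth <- pmax(0, seq_len(n) - r0)
      atten <- exp(-3 * depth / n)
      img[, c0:(c0 + w - 1L)] <-
        img[, c0:(c0 + w - 1L)] * atten
    }
    img[img < 0] <- 0
    img[img > 1] <- 1
    attr(img, "shadow") <- shadow
    img
  })
}

# EBImage's Gaussian blur on a plain matrix
ebi_gblur <- function(m, sigma) {
  out <- EBImage::imageData(EBImage::gblur(EBImage::Image(m), sigma = sigma))
  matrix(out, nrow(m), ncol(m))
}

#' Generate one phantom sample
#'
#' @param cfg A [phantom_config()].
#' @param index Sample index (>= 1); the sample seed is
#'   `phantom_sample_seed(cfg$seed, index)`.
#' @return A list of class `us_phantom_sample` with `image` (matrix in
#'   `[0,1]`), `mask` (binary matrix), `seed`, `index`, and `shadow`.
#' @export
generate_phantom <- function(cfg, index = 1L) {
  sd <- phantom_sample_seed(cfg$seed, index)
  mask <- sample_lesion_mask(cfg, seed = sd)
  img <- render_image(mask, cfg, seed = sd + 1L)
  structure(list(image = img, mask = mask, seed = sd, index = index,
                 shadow = attr(img, "shadow")),
            class = "us_phantom_sample")
}

#' Generate a phantom dataset on disk
#'
#' Writes `n` PNG pairs `img_<i>.png` / `mask_<i>.png` (8-bit; masks use
#' values 0/255) plus a JSON manifest recording the configuration and the
#' per-sample seeds, so the dataset is fully reproducible from
#' `(cfg, n)`.
#'
#' @param cfg A [phantom_config()].
#' @param n Number of samples (> 0).
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a tibble manifest (id, image, mask, seed, shadow,
#'   area_fraction).
#' @export
generate_dataset <- function(cfg, n, out_dir) {
  stopifnot(n > 0)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    s <- generate_phantom(cfg, i)
    img8 <- round(s$image * 255) / 255
    img_path <- file.path(out_dir, sprintf("img_%d.png", i))
    mask_path <- file.path(out_dir, sprintf("mask_%d.png", i))
    png::writePNG(img8, img_path)
    png::writePNG(s$mask, mask_path)
    rows[[i]] <- tibble::tibble(
      id = as.character(i), image = basename(img_path),
      mask = basename(mask_path), seed = s$seed, shadow = s$shadow,
      area_fraction = sum(s$mask) / length(s$mask)
    )
  }
  manifest <- dplyr::bind_rows(rows)
  jsonlite::write_json(
    list(config = unclass(cfg), n = n, samples = manifest),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(manifest)
}

#' @export
print.us_phantom_sample <- function(x, ...) {
  cat(sprintf(
    "<us_phantom_sample> #%d: %dx%d, lesion area %.1f%%, shadow: %s\n",
    x$index, nrow(x$image), ncol(x$image),
    100 * sum(x$mask) / length(x$mask), x$shadow))
  invisible(x)
}
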
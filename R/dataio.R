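#' Load paired image/mask PNGs from a directory
#'
#' Reads `img_<id>.png` / `mask_<id>.png` pairs, rescales images to
#' `[0, 1]` with three channels (grayscale replicated, alpha dropped),
#' binarizes masks at the midpoint, and resizes everything to
#' `size x size` (bilinear for images, nearest neighbour for masks, which
#' keeps them strictly binary). Orphan images or masks are an error that
#' names the offending ids.
#'
#' @param dir Directory containing the pairs.
#' @param size Standardized square size (default 512).
#' @return A list of sample pairs, each a list with `image`
#'   (`size x size x 3` array), `mask` (binary matrix), and `id`.
#' @export
load_pairs <- function(dir, size = 512) {
  stopifnot(dir.exists(dir))
  imgs <- list.files(dir, pattern = "^img_.*\\.png$")
  masks <- list.files(dir, pattern = "^mask_.*\\.png$")
  img_ids <- sub("^img_(.*)\\.png$", "\\1", imgs)
  mask_ids <- sub("^mask_(.*)\\.png$", "\\1", masks)
  orphans_i <- setdiff(img_ids, mask_ids)
  orphans_m <- setdiff(mask_ids, img_ids)
  if (length(orphans_i) || length(orphans_m)) {
    stop("unpaired files - images without masks: [",
         paste(orphans_i, collapse = ", "), "]; masks without images: [",
         paste(orphans_m, collapse = ", "), "]")
  }
  ids <- sort(img_ids)
  lapply(ids, function(id) {
    img <- png::readPNG(file.path(dir, paste0("img_", id, ".png")))
    msk <- png::readPNG(file.path(dir, paste0("mask_", id, ".png")))
    img <- standardize_image(img, size)
    msk <- standardize_mask(msk, size)
    list(image = img, mask = msk, id = id)
  })
}

standardize_image <- function(img, size) {
  if (length(dim(img)) == 3) {
    if (dim(img)[3] >= 3) {
      img <- img[, , 1:3, drop = FALSE]
    } else {
      img <- img[, , 1]
    }
  }
  if (length(dim(img)) == 3) {
    out <- array(0, c(size, size, 3))
    for (c in 1:3) out[, , c] <- resize_bilinear(img[, , c], size)
    out
  } else {
    r <- resize_bilinear(img, size)
    array(rep(r, 3), c(size, size, 3))
  }
}

standardize_mask <- function(msk, size) {
  if (length(dim(msk)) == 3) msk <- msk[, , 1]
  m <- resize_nearest(msk, size)
  (m > 0.5) * 1
}

resize_bilinear <- function(m, size) {
  if (all(dim(m) == size)) return(m)
  out <- EBImage::imageData(EBImage::resize(EBImage::Image(m), w = size,
                                            h = size, filter = "bilinear"))
  matrix(pmin(pmax(out, 0), 1), size, size)
}

resize_nearest <- function(m, size) {
  if (all(dim(m) == size)) return(m)
  out <- EBImage::imageData(EBImage::resize(EBImage::Image(m), w = size,
                                            h = size, filter = "none"))
  matrix(out, size, size)
}

#' Split sample pairs into training and test sets
#'
#' Deterministic random partition: `round(train_fraction * n)` pairs go
#' to training, the rest to test; the two sets are disjoint and their
#' union is the input.
#'
#' @param pairs List of sample pairs (from [load_pairs()] or built in
#'   memory).
#' @param train_fraction Fraction of pairs for training (default 0.8,
#'   the 8:2 protocol).
#' @param seed Integer seed.
#' @return A list with elements `train` and `test`.
#' @export
split_pairs <- function(pairs, train_fraction = 0.8, seed = 1L) {
  n <- length(pairs)
  stopifnot(n >= 2, train_fraction > 0, train_fraction < 1)
  n_train <- round(train_fraction * n)
  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  list(train = pairs[sort(perm[seq_len(n_train)])],
       test = pairs[sort(perm[setdiff(seq_len(n), seq_len(n_train))])])
}

#' Augment an image/mask pair
#'
#' The three augmentations of the training protocol, applied jointly so
#' geometry stays mask-consistent:
#' * `hflip` mirrors image and mask left/right (an involution);
#' * `affine` applies one random rotation (+-15 degrees), isotropic scale
#'   (0.9-1.1) and translation (+-5% of the side) to both, sampling the
#'   image bilinearly and the mask by nearest neighbour;
#' * `contrast` applies a random gamma stretch to the image only.
#'
#' Masks remain strictly binary and images are clipped to `[0, 1]`.
#'
#' @param pair A sample pair (list with `image`, `mask`, `id`).
#' @param ops Character subset of `c("hflip", "affine", "contrast")`,
#'   applied in the given order.
#' @param seed Integer seed for the random transform parameters.
#' @param params Optional list overriding the random draw: `angle`
#'   (degrees), `scale`, `shift` (length-2, pixels), `gamma`.
#' @return The augmented pair.
#' @export
augment_pair <- function(pair, ops = c("hflip", "affine", "contrast"),
                         seed = 1L, params = list()) {
  known <- c("hflip", "affine", "contrast")
  bad <- setdiff(ops, known)
  if (length(bad)) stop("unknown augmentation op(s): ",
                        paste(bad, collapse = ", "))
  img <- pair$image
  msk <- pair$mask
  n <- nrow(msk)
  draws <- withr::with_seed(as.integer(seed), list(
    angle = stats::runif(1, -15, 15),
    scale = stats::runif(1, 0.9, 1.1),
    shift = stats::runif(2, -0.05, 0.05) * n,
    gamma = exp(stats::runif(1, -0.35, 0.35))
  ))
  draws[names(params)] <- params
  for (op in ops) {
    if (op == "hflip") {
      img <- img[, rev(seq_len(ncol(msk))), , drop = FALSE]
      msk <- msk[, rev(seq_len(ncol(msk))), drop = FALSE]
    } else if (op == "affine") {
      for (c in 1:3) {
        img[, , c] <- affine_sample(img[, , c], draws$angle, draws$scale,
                                    draws$shift, bilinear = TRUE)
      }
      msk <- affine_sample(msk, draws$angle, draws$scale, draws$shift,
                           bilinear = FALSE)
    } else if (op == "contrast") {
      img <- img^draws$gamma
    }
  }
  img[img < 0] <- 0
  img[img > 1] <- 1
  list(image = img, mask = msk, id = pair$id,
       augment = draws[c("angle", "scale", "shift", "gamma")])
}

# Inverse-mapped affine resampling about the image center. The identity
# transform (angle 0, scale 1, zero shift) reproduces the input exactly;
# out-of-range samples are filled with 0.
affine_sample <- function(m, angle, scale, shift, bilinear = TRUE) {
  h <- nrow(m)
  w <- ncol(m)
  cy <- (h + 1) / 2
  cx <- (w + 1) / 2
  th <- angle * pi / 180
  rows <- matrix(rep(seq_len(h), times = w), h, w) - cy - shift[1]
  cols <- matrix(rep(seq_len(w), each = h), h, w) - cx - shift[2]
  src_r <- (cos(th) * rows + sin(th) * cols) / scale + cy
  src_c <- (-sin(th) * rows + cos(th) * cols) / scale + cx
  if (!bilinear) {
    ri <- round(src_r)
    ci <- round(src_c)
    ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
    out <- matrix(0, h, w)
    out[ok] <- m[cbind(ri[ok], ci[ok])]
    return(out)
  }
  r0 <- floor(src_r)
  c0 <- floor(src_c)
  fr <- src_r - r0
  fc <- src_c - c0
  getm <- function(ri, ci) {
    ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
    v <- matrix(0, h, w)
    v[ok] <- m[cbind(ri[ok], ci[ok])]
    v
  }
  (1 - fr) * (1 - fc) * getm(r0, c0) + fr * (1 - fc) * getm(r0 + 1, c0) +
    (1 - fr) * fc * getm(r0, c0 + 1) + fr * fc * getm(r0 + 1, c0 + 1)
}

#' Expand a dataset by cycling random augmentations
#'
#' Keeps the originals and appends randomly augmented copies (cycling
#' through the originals with fresh augmentation draws) until `n` pairs
#' are reached — the mechanism used to grow a few hundred clinical images
#' to a few thousand training samples.
#'
#' @param pairs List of sample pairs.
#' @param n Target number of pairs (>= `length(pairs)`).
#' @param ops Augmentations to draw from (see [augment_pair()]).
#' @param seed Integer seed.
#' @return A list of `n` pairs; augmented copies get ids `<id>_aug<k>`.
#' @export
expand_dataset <- function(pairs, n, ops = c("hflip", "affine", "contrast"),
                           seed = 1L) {
  stopifnot(n >= length(pairs))
  out <- pairs
  k <- 0L
  while (length(out) < n) {
    k <- k + 1L
    src <- pairs[[((k - 1L) %% length(pairs)) + 1L]]
    sub <- withr::with_seed(seed + k, {
      chosen <- sample(ops, size = sample.int(length(ops), 1))
      chosen
    })
    aug <- augment_pair(src, sub, seed = seed + 7919L * k)
    aug$id <- paste0(src$id, "_aug", k)
    out[[length(out) + 1L]] <- aug
  }
  out
}

# Stack pairs into dense arrays for the network: images (H,W,3,N),
# masks (H,W,1,N).
pairs_to_arrays <- function(pairs) {
  n <- length(pairs)
  d <- dim(pairs[[1]]$image)
  imgs <- array(0, c(d[1], d[2], 3, n))
  msks <- array(0, c(d[1], d[2], 1, n))
  for (i in seq_len(n)) {
    imgs[, , , i] <- pairs[[i]]$image
    msks[, , 1, i] <- pairs[[i]]$mask
  }
  list(images = imgs, masks = msks)
}

# Phantom samples (grayscale) -> standard 3-channel pairs
phantom_to_pair <- function(sample) {
  n <- nrow(sample$image)
  list(image = array(rep(as.vector(sample$image), 3), c(n, n, 3)),
       mask = sample$mask, id = as.character(sample$index))
}

#' Generate an in-memory phantom pair set
#'
#' Convenience wrapper producing `n` standardized 3-channel sample pairs
#' directly from a phantom configuration, without touching disk.
#'
#' @param cfg A [phantom_config()].
#' @param n Number of samples.
#' @param offset Index offset (samples get indices `offset + 1:n`), so
#'   disjoint sets can be drawn from one master seed.
#' @return A list of sample pairs.
#' @export
phantom_pairs <- function(cfg, n, offset = 0L) {
  lapply(seq_len(n), function(i) {
    phantom_to_pair(generate_phantom(cfg, offset + i))
  })
}
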
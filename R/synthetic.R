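# Seeded generator of colonoscopy-like frames with exact binary polyp masks.
# Polyps are rendered as bright, reddish, smoothly-bounded protrusions --
# ellipses whose radius is perturbed by a small radial Fourier series,
# r(theta) = r0 * (1 + sum_k a_k sin(k theta + phi_k)) -- on a textured
# mucosa-like background with specular highlights, vignetting and noise.
# The generator is the stand-in for real paired image/mask datasets so the
# full pipeline is trainable and testable without downloads.

#' Configuration of the synthetic colonoscopy-like image generator
#'
#' @param image_size side of the square frame in pixels (>= 32).
#' @param n_polyps_range integer interval `c(lo, hi)` for the number of
#'   polyps per frame.
#' @param radius_range polyp radius interval as a fraction of `image_size`.
#' @param boundary_harmonics `c(count, amplitude)`: number of radial Fourier
#'   perturbation terms and their total amplitude as a fraction of the radius
#'   (must stay below 1 so the boundary cannot self-intersect).
#' @param polyp_color,background_color RGB mean triples in `[0,1]`.
#' @param texture_noise_sd standard deviation of the pixel noise.
#' @param n_highlights number of specular highlight blobs.
#' @param vignette_strength vignetting strength in `[0,1]`.
#' @param seed integer master seed.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(image_size = 256L,
                             n_polyps_range = c(1L, 3L),
                             radius_range = c(0.08, 0.25),
                             boundary_harmonics = c(4L, 0.15),
                             polyp_color = c(0.78, 0.48, 0.40),
                             background_color = c(0.55, 0.30, 0.25),
                             texture_noise_sd = 0.03,
                             n_highlights = 3L,
                             vignette_strength = 0.35,
                             seed = 1L) {
  assert_that(image_size >= 32, "image_size must be >= 32")
  assert_that(n_polyps_range[1] <= n_polyps_range[2] && n_polyps_range[1] >= 0,
              "n_polyps_range must be a non-degenerate nonnegative interval")
  assert_that(radius_range[1] <= radius_range[2] && radius_range[1] >= 0,
              "radius_range must be non-degenerate")
  assert_that(boundary_harmonics[2] < 1, "harmonic amplitude fraction must be < 1")
  assert_that(vignette_strength >= 0 && vignette_strength <= 1,
              "vignette_strength must lie in [0,1]")
  structure(list(image_size = as.integer(image_size),
                 n_polyps_range = as.integer(n_polyps_range),
                 radius_range = as.double(radius_range),
                 boundary_harmonics = c(as.integer(boundary_harmonics[1]),
                                        as.double(boundary_harmonics[2])),
                 polyp_color = polyp_color,
                 background_color = background_color,
                 texture_noise_sd = texture_noise_sd,
                 n_highlights = as.integer(n_highlights),
                 vignette_strength = vignette_strength,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' An image paired with its binary polyp mask
#'
#' The atomic training/evaluation unit: an RGB frame with values in `[0,1]`
#' and a co-registered mask with 1 = polyp, 0 = background.
#'
#' @param image `HxWx3` numeric array in `[0,1]`.
#' @param mask `HxW` matrix with values in `{0,1}`.
#' @param id identifier string.
#' @return object of class `labeled_image`.
#' @export
labeled_image <- function(image, mask, id = "img") {
  if (is.matrix(image)) dim(image) <- c(dim(image), 1L)
  stopifnot(length(dim(image)) == 3L, is.matrix(mask))
  if (!all(dim(image)[1:2] == dim(mask)))
    stop_data("image and mask of '%s' disagree in size", id)
  if (any(!is.finite(image))) stop_data("non-finite image values in '%s'", id)
  if (!all(mask %in% c(0, 1))) stop_data("mask of '%s' is not binary", id)
  structure(list(image = image, mask = mask, id = as.character(id)),
            class = "labeled_image")
}

#' @export
print.labeled_image <- function(x, ...) {
  cat(sprintf("<labeled_image '%s' %dx%d, foreground %.3f>\n", x$id,
              nrow(x$mask), ncol(x$mask), mean(x$mask)))
  invisible(x)
}

#' Generate one polyp region as a binary mask
#'
#' The region is star-convex about `center`: an ellipse (random axis ratio
#' and orientation unless given) whose boundary radius is modulated by
#' `harmonics[1]` sinusoidal terms with total amplitude `harmonics[2]`.
#' Random phases/amplitudes are drawn from the current RNG stream.  A radius
#' below one pixel yields an empty region.
#'
#' @param image_size frame side in pixels.
#' @param center `c(row, col)` center in pixels (1-based).
#' @param radius mean radius in pixels.
#' @param harmonics `c(count, amplitude)` radial perturbation spec.
#' @param axis_ratio optional minor/major axis ratio (drawn in `[0.7, 1]` if
#'   `NULL`).
#' @param orientation optional ellipse orientation in radians.
#' @return `image_size x image_size` binary matrix.
#' @export
generate_polyp_mask <- function(image_size, center, radius,
                                harmonics = c(4L, 0.15),
                                axis_ratio = NULL, orientation = NULL) {
  n <- as.integer(image_size)
  mask <- matrix(0, n, n)
  if (radius < 1) return(mask)
  stopifnot(center[1] >= 1, center[1] <= n, center[2] >= 1, center[2] <= n)
  k <- as.integer(harmonics[1]); amp <- as.double(harmonics[2])
  if (is.null(axis_ratio)) axis_ratio <- runif(1, 0.7, 1)
  if (is.null(orientation)) orientation <- runif(1, 0, pi)
  amps <- if (k > 0 && amp > 0) {
    raw <- runif(k, -1, 1)
    raw * (amp * runif(1, 0.5, 1)) / max(sum(abs(raw)), .Machine$double.eps)
  } else numeric(0)
  phases <- if (k > 0) runif(k, 0, 2 * pi) else numeric(0)
  dr <- matrix(seq_len(n) - center[1], n, n)
  dc <- matrix(seq_len(n) - center[2], n, n, byrow = TRUE)
  ca <- cos(orientation); sa <- sin(orientation)
  xr <- ca * dr + sa * dc
  yr <- -sa * dr + ca * dc
  rho <- sqrt(xr^2 + (yr / axis_ratio)^2)
  theta <- atan2(yr, xr)
  bound <- radius
  for (i in seq_along(amps))
    bound <- bound + radius * amps[i] * sin(i * theta + phases[i])
  mask[rho <= bound] <- 1
  mask
}

# Low-frequency multiplicative texture field emulating mucosal shading.
texture_field <- function(n) {
  f <- matrix(rnorm(n * n), n, n)
  f <- box_blur(f, passes = max(3L, n %/% 32))
  f / max(stats::sd(f), .Machine$double.eps)
}

#' Render one labelled synthetic frame
#'
#' Draws the polyp count, positions and shapes from the current RNG stream,
#' composites polyps over the textured background with a softly blended
#' boundary, then applies specular highlights, vignetting and pixel noise to
#' the image only; the mask stays the exact union of the generated regions.
#'
#' @param config a [synthetic_config()].
#' @param id identifier for the returned [labeled_image()].
#' @return a [labeled_image()].
#' @export
render_labeled_image <- function(config, id = "img") {
  n <- config$image_size
  n_polyps <- if (config$n_polyps_range[1] == config$n_polyps_range[2])
    config$n_polyps_range[1]
  else sample(config$n_polyps_range[1]:config$n_polyps_range[2], 1)
  mask <- matrix(0, n, n)
  for (p in seq_len(n_polyps)) {
    margin <- ceiling(0.1 * n)
    center <- c(sample(seq(margin, n - margin), 1),
                sample(seq(margin, n - margin), 1))
    radius <- runif(1, config$radius_range[1], config$radius_range[2]) * n
    mask <- pmax(mask, generate_polyp_mask(n, center, radius,
                                           config$boundary_harmonics))
  }
  tex <- texture_field(n)
  alpha <- box_blur(mask, passes = 2L)          # soft compositing edge
  shade <- 1 + 0.12 * tex
  img <- array(0, dim = c(n, n, 3))
  for (ch in 1:3) {
    bg <- config$background_color[ch] * shade
    fg <- config$polyp_color[ch] * (1 + 0.08 * tex)
    img[, , ch] <- bg * (1 - alpha) + fg * alpha
  }
  # specular highlights: small saturated Gaussian blobs, image only
  if (config$n_highlights > 0) {
    rows <- matrix(seq_len(n), n, n)
    cols <- matrix(seq_len(n), n, n, byrow = TRUE)
    for (hgt in seq_len(config$n_highlights)) {
      hc <- runif(2, 1, n)
      sigma <- runif(1, 0.006, 0.02) * n
      ampl <- runif(1, 0.5, 1)
      blob <- ampl * exp(-((rows - hc[1])^2 + (cols - hc[2])^2) / (2 * sigma^2))
      for (ch in 1:3) img[, , ch] <- img[, , ch] + blob
    }
  }
  if (config$vignette_strength > 0) {
    ctr <- (n + 1) / 2
    rows <- matrix(seq_len(n), n, n)
    cols <- matrix(seq_len(n), n, n, byrow = TRUE)
    r2 <- ((rows - ctr)^2 + (cols - ctr)^2) / (2 * (ctr - 1)^2)
    vig <- 1 - config$vignette_strength * r2
    for (ch in 1:3) img[, , ch] <- img[, , ch] * vig
  }
  if (config$texture_noise_sd > 0)
    img <- img + rnorm(length(img), sd = config$texture_noise_sd)
  labeled_image(clamp01(img), mask, id)
}

#' Generate a reproducible synthetic dataset
#'
#' Per-image RNG streams are derived from `(seed, item counter)` with
#' [derive_seed()], so item k is bit-identical no matter how many other items
#' are generated.
#'
#' @param n number of images (>= 0).
#' @param config a [synthetic_config()].
#' @param seed master seed; defaults to `config$seed`.
#' @return list of [labeled_image()] with unique ids.
#' @export
generate_dataset <- function(n, config = synthetic_config(), seed = config$seed) {
  stopifnot(n >= 0)
  lapply(seq_len(n), function(i) {
    with_seed(derive_seed(seed, i),
              render_labeled_image(config, id = sprintf("img%05d", i)))
  })
}

#' Write a dataset in the paired images/masks folder layout
#'
#' Produces `<root>/images/<id>.<ext>` and `<root>/masks/<id>.png`; masks are
#' stored as 8-bit grayscale with values {0, 255}.
#'
#' @param dataset list of [labeled_image()].
#' @param root output directory (created if missing).
#' @param image_format "png" (built-in codec) or "jpg" (requires the optional
#'   'jpeg' package).
#' @return `root`, invisibly.
#' @export
write_dataset <- function(dataset, root, image_format = c("png", "jpg")) {
  image_format <- match.arg(image_format)
  img_dir <- file.path(root, "images")
  msk_dir <- file.path(root, "masks")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(msk_dir, recursive = TRUE, showWarnings = FALSE)
  for (item in dataset) {
    write_image(item$image, file.path(img_dir, paste0(item$id, ".", image_format)))
    write_png(item$mask * 255, file.path(msk_dir, paste0(item$id, ".png")))
  }
  invisible(root)
}
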
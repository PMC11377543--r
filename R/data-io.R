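# Paired image/mask dataset input-output, normalisation to the network's
# square working size, affine augmentation and train/val/fold splitting.
#
# Coordinate convention used throughout: row-major, origin at the top-left
# pixel, matrices indexed (row, col); affine transforms act on (row, col)
# coordinates about the image center.

#' Describe a paired image/mask dataset on disk
#'
#' @param root dataset root directory.
#' @param image_subdir,mask_subdir subfolder names (Kvasir-style defaults).
#' @param image_extensions accepted image file extensions.
#' @return object of class `dataset_spec`.
#' @export
dataset_spec <- function(root, image_subdir = "images", mask_subdir = "masks",
                         image_extensions = c("jpg", "jpeg", "png", "tif", "tiff")) {
  spec <- structure(list(root = root, image_subdir = image_subdir,
                         mask_subdir = mask_subdir,
                         image_extensions = tolower(image_extensions)),
                    class = "dataset_spec")
  spec
}

#' Load all image/mask pairs of a dataset
#'
#' Pairs are matched by file stem and returned sorted by stem.  Masks are
#' read as grayscale and binarised at the 8-bit midpoint (>= 128 is polyp).
#' Original sizes are preserved; resizing is a separate step
#' ([preprocess_pair()]).
#'
#' @param spec a [dataset_spec()].
#' @return list of [labeled_image()].
#' @export
load_pairs <- function(spec) {
  img_dir <- file.path(spec$root, spec$image_subdir)
  msk_dir <- file.path(spec$root, spec$mask_subdir)
  if (!dir.exists(img_dir) || !dir.exists(msk_dir))
    stop_data("dataset subdirectories not found under %s", spec$root)
  pat <- paste0("\\.(", paste(spec$image_extensions, collapse = "|"), ")$")
  imgs <- sort(list.files(img_dir, pattern = pat, ignore.case = TRUE))
  msks <- sort(list.files(msk_dir, pattern = pat, ignore.case = TRUE))
  msk_stems <- tools::file_path_sans_ext(msks)
  lapply(imgs, function(f) {
    stem <- tools::file_path_sans_ext(f)
    hit <- which(msk_stems == stem)
    if (length(hit) == 0)
      stop_data("no mask found for image stem '%s'", stem)
    if (length(hit) > 1)
      stop_data("multiple masks found for image stem '%s'", stem)
    img <- read_image(file.path(img_dir, f)) / 255
    if (dim(img)[3] == 1L) img <- array(rep(img, 3), dim = c(dim(img)[1:2], 3L))
    msk <- read_image(file.path(msk_dir, msks[hit]))
    if (dim(msk)[3] > 1L) msk <- msk[, , 1L, drop = FALSE]  # grayscale view
    labeled_image(img, matrix(as.double(msk >= 128), dim(msk)[1], dim(msk)[2]),
                  id = stem)
  })
}

# Binarise a mask that may live on the 0-255 or the 0-1 scale: the midpoint
# rule 'value >= 128' on the 8-bit scale, equivalently >= 128/255 on [0,1].
binarize_mask <- function(m) {
  thr <- if (max(m) > 1) 128 else 128 / 255
  matrix(as.double(m >= thr), nrow(m), ncol(m))
}

#' Resize a pair to the square working size
#'
#' The image is resized with bilinear interpolation and kept in `[0,1]`; the
#' mask is resized with nearest-neighbour interpolation and then binarised at
#' the 8-bit midpoint (128), so nearest-neighbour resampling of an already
#' binary mask is a no-op on its value set.
#'
#' @param pair a [labeled_image()] (the mask may be on the 0-255 scale).
#' @param target side of the square output, >= 32 (the network working size
#'   is 256).
#' @return a [labeled_image()] of size `target x target`.
#' @export
preprocess_pair <- function(pair, target = 256L) {
  assert_that(target >= 32, "target size must be >= 32")
  mask <- pair$mask
  if (!is.matrix(mask)) stop_data("mask of '%s' must be a 2-D matrix", pair$id)
  img <- cpp_resize_bilinear(pair$image, target, target)
  msk <- cpp_resize_nearest(array(mask, dim = c(dim(mask), 1L)), target, target)
  labeled_image(clamp01(img), binarize_mask(matrix(msk, target, target)),
                id = pair$id)
}

#' Affine transform parameters
#'
#' The forward map sends pixel `(r, c)` (about the image center) to
#' `rot(angle) %*% shear(shear) %*% scale(s) %*% flip %*% (r, c) + translate`,
#' with `rot(90deg)` mapping `(r, c)` to `(c, -r)` about the center (so a
#' single-pixel mask at (r, c) on an NxN frame lands on `(c, N - 1 - r)` in
#' 0-based coordinates).
#'
#' @param angle rotation in degrees.
#' @param scale isotropic scale factor.
#' @param shear shear in degrees.
#' @param translate `c(rows, cols)` translation in pixels.
#' @param flip_h,flip_v horizontal (column) / vertical (row) mirroring.
#' @return object of class `affine_params`.
#' @export
affine_params <- function(angle = 0, scale = 1, shear = 0,
                          translate = c(0, 0), flip_h = FALSE, flip_v = FALSE) {
  structure(list(angle = angle, scale = scale, shear = shear,
                 translate = translate, flip_h = flip_h, flip_v = flip_v),
            class = "affine_params")
}

#' Sample random affine parameters for augmentation
#'
#' Draws from the current RNG stream.  Defaults (rotation within 30 degrees,
#' scale 0.8-1.2, shear within 10 degrees, random flips) are configurable.
#'
#' @param max_angle,scale_range,max_shear,flip sampling ranges.
#' @return an [affine_params()].
#' @export
random_affine <- function(max_angle = 30, scale_range = c(0.8, 1.2),
                          max_shear = 10, flip = TRUE) {
  affine_params(angle = runif(1, -max_angle, max_angle),
                scale = runif(1, scale_range[1], scale_range[2]),
                shear = runif(1, -max_shear, max_shear),
                flip_h = flip && runif(1) < 0.5,
                flip_v = flip && runif(1) < 0.5)
}

affine_matrix <- function(tr, n) {
  a <- tr$angle * pi / 180
  sh <- tan(tr$shear * pi / 180)
  # (r, c) -> (c, -r) for a 90 degree rotation
  rot <- matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2)
  shear <- matrix(c(1, 0, sh, 1), 2, 2)
  flip <- diag(c(if (tr$flip_v) -1 else 1, if (tr$flip_h) -1 else 1))
  A <- rot %*% shear %*% (tr$scale * flip)
  ctr <- (n - 1) / 2  # 0-based center
  offset <- ctr - A %*% c(ctr, ctr) + tr$translate
  list(A = A, b = as.vector(offset))
}

#' Apply one affine transform to an image/mask pair
#'
#' The identical geometric map is applied to both: bilinear interpolation for
#' the image, nearest-neighbour for the mask, which is then re-binarised.
#' Out-of-frame regions are filled with 0.
#'
#' @param pair a [labeled_image()].
#' @param transform an [affine_params()].
#' @return transformed [labeled_image()].
#' @export
affine_augment <- function(pair, transform) {
  n <- nrow(pair$mask)
  m <- affine_matrix(transform, n)
  if (abs(det(m$A)) < 1e-12) stop_data("singular affine transform")
  Ainv <- solve(m$A)
  binv <- -Ainv %*% m$b
  Minv <- cbind(Ainv, binv)
  img <- cpp_warp_affine(pair$image, Minv, method = 1L, fill = 0)
  msk <- cpp_warp_affine(array(pair$mask, dim = c(dim(pair$mask), 1L)),
                         Minv, method = 0L, fill = 0)
  labeled_image(clamp01(img), binarize_mask(matrix(msk, n, n)), id = pair$id)
}

#' Train/validation split plus balanced cross-validation folds
#'
#' Indices (1-based) are shuffled by `seed`; the train set takes
#' `round(n * ratio)` items and the remainder goes to validation.  The k
#' folds partition all n indices with sizes differing by at most one.
#'
#' @param n number of items (>= k).
#' @param ratio train fraction in (0, 1).
#' @param k fold count (>= 1).
#' @param seed shuffling seed.
#' @return object of class `split_indices` with fields `train`, `val`,
#'   `folds`.
#' @export
make_splits <- function(n, ratio = 0.8, k = 5L, seed = 1L) {
  assert_that(n >= k && k >= 1, "need n >= k >= 1 (n=%d, k=%d)", n, k)
  assert_that(ratio > 0 && ratio < 1, "ratio must lie strictly in (0,1)")
  perm <- with_seed(seed, sample.int(n))
  n_train <- round(n * ratio)
  folds <- split(perm, rep_len(seq_len(k), n))
  names(folds) <- NULL
  structure(list(train = sort(perm[seq_len(n_train)]),
                 val = sort(perm[setdiff(seq_len(n), seq_len(n_train))]),
                 folds = lapply(folds, sort)),
            class = "split_indices")
}

#' Export split indices as JSON
#'
#' @param splits a [make_splits()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_splits <- function(splits, path) {
  jsonlite::write_json(unclass(splits), path)
  invisible(path)
}
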
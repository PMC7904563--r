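#' Soft Dice coefficient between a probability map and a binary mask
#'
#' The differentiable overlap measure used as the segmentation training
#' objective: `(2 * sum(p * g) + s) / (sum(p) + sum(g) + s)` with
#' smoothing term `s`. Tricellular junctions occupy a tiny fraction of the
#' image, so pixel-wise cross-entropy would be dominated by background;
#' overlap is the quantity that matters. The training loss is
#' `1 - soft_dice`.
#'
#' @param prediction Numeric matrix in \[0, 1\].
#' @param target Binary matrix of the same shape.
#' @param smoothing Small positive constant stabilising the empty-mask
#'   case; the default 1 is the conventional choice.
#' @return A value in \[0, 1\].
#' @export
soft_dice <- function(prediction, target, smoothing = 1) {
  if (!all(dim(prediction) == dim(target)))
    stop("prediction and target must have the same shape")
  if (any(target != 0 & target != 1)) stop("target must be binary")
  (2 * sum(prediction * target) + smoothing) /
    (sum(prediction) + sum(target) + smoothing)
}

#' Augmentation recipe for training pairs
#'
#' Geometric variants (tiled crops x rotations by 90/180/270 degrees x
#' horizontal flip) are applied identically to image and label; random
#' colour jitter (brightness offset and contrast factor) is applied to the
#' image only, seeded for reproducibility.
#'
#' @param crop_size_px Side of the square crops; crops tile the image.
#' @param rotations Subset of `c(90, 180, 270)`.
#' @param horizontal_flip Include the horizontally flipped variants.
#' @param brightness_range Additive intensity offset range.
#' @param contrast_range Multiplicative contrast factor range.
#' @param rng_seed Seed for the jitter draws.
#' @return An object of class `augmentation_spec`.
#' @export
augmentation_spec <- function(crop_size_px, rotations = c(90, 180, 270),
                              horizontal_flip = TRUE,
                              brightness_range = c(0, 0),
                              contrast_range = c(1, 1), rng_seed = 1L) {
  stopifnot(crop_size_px > 0, all(rotations %in% c(90, 180, 270)))
  structure(list(crop_size_px = as.integer(crop_size_px),
                 rotations = rotations, horizontal_flip = horizontal_flip,
                 brightness_range = brightness_range,
                 contrast_range = contrast_range,
                 rng_seed = as.integer(rng_seed)),
            class = "augmentation_spec")
}

.rot90 <- function(m) t(m)[, nrow(m):1, drop = FALSE]
.rotk <- function(m, k) { for (i in seq_len(k)) m <- .rot90(m); m }
.hflip <- function(m) m[, ncol(m):1, drop = FALSE]

#' Augment one image/label pair
#'
#' @param image,label_mask Matrices of identical shape.
#' @param spec An [augmentation_spec()].
#' @return List of `list(image, mask)` pairs: one per crop x rotation
#'   (including 0 degrees) x flip state, with seeded colour jitter on the
#'   images only.
#' @export
augment_pair <- function(image, label_mask, spec) {
  if (!all(dim(image) == dim(label_mask)))
    stop("image and label_mask must have the same shape")
  cs <- spec$crop_size_px
  if (cs > nrow(image) || cs > ncol(image))
    stop("crop larger than image")
  set.seed(spec$rng_seed)
  r0 <- seq(1, nrow(image) - cs + 1, by = cs)
  c0 <- seq(1, ncol(image) - cs + 1, by = cs)
  ks <- c(0, spec$rotations / 90)
  out <- list()
  for (ri in r0) for (ci in c0) {
    im <- image[ri:(ri + cs - 1), ci:(ci + cs - 1), drop = FALSE]
    mk <- label_mask[ri:(ri + cs - 1), ci:(ci + cs - 1), drop = FALSE]
    for (k in ks) {
      imr <- .rotk(im, k); mkr <- .rotk(mk, k)
      flips <- if (spec$horizontal_flip) c(FALSE, TRUE) else FALSE
      for (fl in flips) {
        imf <- if (fl) .hflip(imr) else imr
        mkf <- if (fl) .hflip(mkr) else mkr
        br <- runif(1, spec$brightness_range[1], spec$brightness_range[2])
        cf <- runif(1, spec$contrast_range[1], spec$contrast_range[2])
        out[[length(out) + 1]] <-
          list(image = pmin(pmax(imf * cf + br, 0), 1), mask = mkf)
      }
    }
  }
  out
}
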
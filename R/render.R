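#' Render the cell-border (immunostain-like) channel
#'
#' Rasterises tessellation edges as flat-topped ridges of width
#' `border_width_px` at `border_peak_intensity`, then applies Gaussian blur
#' and additive Gaussian noise. Intensities are returned in \[0, 1\];
#' quantisation to the configured bit depth happens only on export
#' ([save_image()]).
#'
#' @param tess A `cell_tessellation`.
#' @param params A [render_params()].
#' @param rng_seed Optional seed for the noise realisation; `NULL` uses the
#'   current RNG state.
#' @return A height x width numeric matrix in \[0, 1\].
#' @export
render_border_channel <- function(tess, params = render_params(),
                                  rng_seed = NULL) {
  stopifnot(inherits(tess, "cell_tessellation"),
            inherits(params, "render_params"))
  H <- tess$field$height_px; W <- tess$field$width_px
  half <- params$border_width_px / 2
  img <- matrix(0, H, W)
  if (nrow(tess$edges) > 0) {
    d <- cpp_segment_distance_map(H, W, tess$edges, half + 1)
    img[d <= half] <- params$border_peak_intensity
  }
  if (params$blur_sigma_px > 0)
    img <- gaussian_blur(img, params$blur_sigma_px)
  if (params$noise_sd > 0) {
    if (!is.null(rng_seed)) set.seed(rng_seed)
    img <- img + matrix(rnorm(H * W, 0, params$noise_sd), H, W)
  }
  pmin(pmax(img, 0), 1)
}

#' Gaussian blur with replicated borders
#'
#' Thin wrapper around `EBImage::filter2` with an explicitly normalised
#' Gaussian kernel, so that a constant image stays exactly constant.
#'
#' @param img Numeric matrix.
#' @param sigma Gaussian sigma in px.
#' @param radius Kernel half-width; defaults to `ceiling(3 * sigma)`.
#' @return Blurred matrix of the same size.
#' @export
gaussian_blur <- function(img, sigma, radius = ceiling(3 * sigma)) {
  stopifnot(sigma > 0)
  k <- 2L * as.integer(radius) + 1L
  g <- exp(-((seq_len(k) - 1 - radius)^2) / (2 * sigma^2))
  kern <- outer(g, g)
  kern <- kern / sum(kern)
  as.matrix(EBImage::filter2(img, kern, boundary = "replicate"))
}

#' Annotation mask of uniform-size junction disks
#'
#' Builds the binary label image used to train the segmentation model: a
#' disk of `radius_px` at every junction centroid (uniform junction size),
#' overlapping disks unioned. A pixel belongs to a disk when its centre is
#' within `radius_px` of the centroid (0-based row/col coordinates, origin
#' top-left).
#'
#' @param junctions A [junction_set()].
#' @param radius_px Disk radius in px (> 0).
#' @param field A [field_spec()] giving the mask size.
#' @return Binary (0/1) matrix of field size.
#' @export
make_annotation_mask <- function(junctions, radius_px, field) {
  if (radius_px <= 0) stop("radius_px must be positive")
  .disk_mask(junctions, radius_px, field$height_px, field$width_px)
}

.disk_mask <- function(junctions, radius_px, H, W) {
  mask <- matrix(0L, H, W)
  r <- ceiling(radius_px)
  for (i in seq_len(nrow(junctions))) {
    cx <- junctions$x[i]; cy <- junctions$y[i]
    cs <- max(0, floor(cx - r)):min(W - 1, ceiling(cx + r))
    rs <- max(0, floor(cy - r)):min(H - 1, ceiling(cy + r))
    if (length(cs) == 0 || length(rs) == 0) next
    dd <- outer((rs - cy)^2, (cs - cx)^2, "+")
    sub <- mask[rs + 1, cs + 1, drop = FALSE]
    sub[dd <= radius_px^2] <- 1L
    mask[rs + 1, cs + 1] <- sub
  }
  mask
}
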
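#' Predict the per-pixel junction probability map
#'
#' Runs the network over an arbitrary-size single-channel image. Images up
#' to the configured input size are padded (replicate) to a
#' pooling-compatible size and predicted in one pass; larger images are
#' tiled with overlapping windows whose predictions are blended with a
#' linear taper over the overlap, so tile seams do not appear in the map.
#'
#' @param model A `tj_segmenter`.
#' @param border_image Numeric matrix.
#' @param tile Tile side; defaults to the training input size.
#' @param overlap Overlap between adjacent tiles in px.
#' @return Matrix of junction probabilities in \[0, 1\], same size as the
#'   input.
#' @export
predict_probability <- function(model, border_image,
                                tile = model$config$input_size_px,
                                overlap = 32L) {
  H <- nrow(border_image); W <- ncol(border_image)
  if (H <= tile && W <= tile)
    return(.predict_whole(model, border_image))
  step <- tile - overlap
  stopifnot(step > 0)
  acc <- matrix(0, H, W); wt <- matrix(0, H, W)
  ramp <- .taper(tile, overlap)
  w2d <- outer(ramp, ramp)
  r0s <- unique(pmin(seq(1, H, by = step), H - tile + 1))
  c0s <- unique(pmin(seq(1, W, by = step), W - tile + 1))
  r0s <- r0s[r0s >= 1]; c0s <- c0s[c0s >= 1]
  for (r0 in r0s) for (c0 in c0s) {
    rs <- r0:(r0 + tile - 1); cs <- c0:(c0 + tile - 1)
    p <- .predict_whole(model, border_image[rs, cs])
    acc[rs, cs] <- acc[rs, cs] + p * w2d
    wt[rs, cs] <- wt[rs, cs] + w2d
  }
  acc / wt
}

.taper <- function(n, overlap) {
  w <- rep(1, n)
  if (overlap > 1) {
    edge <- seq_len(overlap) / (overlap + 1)
    w[seq_len(overlap)] <- edge
    w[n + 1 - seq_len(overlap)] <- edge
  }
  w
}

# pad (replicate) to a multiple of the pooling factor, predict, crop back
.predict_whole <- function(model, img) {
  fac <- 2^(model$config$n_levels - 1)
  H <- nrow(img); W <- ncol(img)
  Hp <- ceiling(H / fac) * fac; Wp <- ceiling(W / fac) * fac
  if (Hp != H || Wp != W) {
    img <- img[c(seq_len(H), rep(H, Hp - H)), c(seq_len(W), rep(W, Wp - W))]
  }
  p <- .net_fwd(model$params, model$config, img)$prob
  p[seq_len(H), seq_len(W), drop = FALSE]
}

#' Detect junction centroids with the trained model
#'
#' Convenience wrapper: [predict_probability()] then
#' [binarize_and_split()].
#'
#' @param model A `tj_segmenter`.
#' @param border_image Numeric matrix.
#' @param prob_threshold Binarisation threshold.
#' @param ... Passed to [binarize_and_split()].
#' @return As [binarize_and_split()].
#' @export
segment_junctions <- function(model, border_image, prob_threshold = 0.5,
                              ...) {
  prob <- predict_probability(model, border_image)
  binarize_and_split(prob, prob_threshold = prob_threshold, ...)
}
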
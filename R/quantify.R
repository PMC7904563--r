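#' Adaptive thresholding of the tracer channel
#'
#' Separates tracer accumulation from background fluorescence: a pixel is
#' foreground iff its value strictly exceeds the local Gaussian-weighted
#' mean scaled by `(1 + sensitivity)`. The local mean uses a normalised
#' Gaussian kernel of sigma `neighbourhood_px / 4` with replicated
#' borders, so an exactly constant image yields an empty foreground.
#'
#' @param tracer_image Numeric matrix.
#' @param params A [threshold_params()]; a `NULL` neighbourhood defaults
#'   to the nearest odd integer to `min(dim) / 8`.
#' @return Logical matrix of foreground pixels.
#' @export
adaptive_threshold <- function(tracer_image, params = threshold_params()) {
  nb <- params$neighbourhood_px
  if (is.null(nb)) {
    nb <- round(min(dim(tracer_image)) / 8)
    if (nb %% 2 == 0) nb <- nb + 1
    nb <- max(nb, 3)
  }
  sigma <- nb / 4
  local_mean <- gaussian_blur(tracer_image, sigma, radius = nb %/% 2)
  tracer_image > local_mean * (1 + params$sensitivity)
}

#' Total tracer accumulation over the thresholded foreground
#'
#' The sum of the original pixel values over all foreground pixels, in
#' relative fluorescence units (RFU).
#'
#' @param tracer_image Numeric matrix.
#' @param foreground Logical matrix of the same shape.
#' @return A scalar (0 for an empty foreground).
#' @export
total_accumulation <- function(tracer_image, foreground) {
  stopifnot(all(dim(tracer_image) == dim(foreground)))
  sum(tracer_image[foreground])
}

#' Label tracer-accumulation spots
#'
#' Labels the 8-connected components of the thresholded foreground; each
#' spot carries its pixel list, unweighted centroid and integrated
#' intensity (sum of original pixel values over its pixels).
#'
#' @param foreground Logical matrix.
#' @param tracer_image Numeric matrix of the same shape.
#' @param min_spot_px Components smaller than this many pixels are
#'   discarded as speckle; 1 keeps everything.
#' @return A `spot_set`: data frame (`label`, `x`, `y`, `n_pixels`,
#'   `integrated_intensity`) with the per-spot 0-based pixel coordinate
#'   matrices in `attr(, "pixels")`.
#' @export
label_spots <- function(foreground, tracer_image, min_spot_px = 1L) {
  stopifnot(all(dim(foreground) == dim(tracer_image)))
  lab <- cpp_label8(foreground)
  if (min_spot_px > 1 && max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_spot_px)
    relab <- integer(length(sizes))
    relab[keep] <- seq_along(keep)
    lab[lab > 0] <- relab[lab[lab > 0]]
  }
  n <- max(lab)
  if (n == 0) {
    out <- data.frame(label = integer(), x = numeric(), y = numeric(),
                      n_pixels = integer(), integrated_intensity = numeric())
    attr(out, "pixels") <- list()
    class(out) <- c("spot_set", "data.frame")
    return(out)
  }
  idx <- which(lab > 0)
  l <- lab[idx]
  ys <- (idx - 1) %% nrow(lab)        # 0-based row
  xs <- (idx - 1) %/% nrow(lab)       # 0-based col
  vals <- tracer_image[idx]
  out <- data.frame(label = seq_len(n),
                    x = as.numeric(tapply(xs, l, mean)),
                    y = as.numeric(tapply(ys, l, mean)),
                    n_pixels = as.integer(table(factor(l, levels = seq_len(n)))),
                    integrated_intensity = as.numeric(tapply(vals, l, sum)))
  attr(out, "pixels") <- lapply(split(data.frame(x = xs, y = ys), l),
                                as.matrix)
  class(out) <- c("spot_set", "data.frame")
  out
}

#' Associate tracer spots with tricellular junctions (2-pixel rule)
#'
#' A junction is permeable iff the Euclidean distance from its centroid to
#' the nearest pixel centre of any spot is at most
#' `distance_threshold_px`. Each spot lying within the threshold of at
#' least one junction is assigned to its nearest such junction (ties to
#' the lowest junction index); spots near no junction stay unassigned, so
#' a spot is counted at most once downstream.
#'
#' @param junctions A [junction_set()].
#' @param spots A `spot_set` from [label_spots()].
#' @param distance_threshold_px Association radius; the assay's rule is 2.
#' @return List: `permeable` (logical per junction), `assignment` (integer
#'   junction index per spot, `NA` if unassigned), `junction_distance`
#'   (per-junction distance to the nearest spot pixel).
#' @export
associate <- function(junctions, spots, distance_threshold_px = 2) {
  nj <- nrow(junctions); ns <- nrow(spots)
  pixels <- attr(spots, "pixels")
  jdist <- rep(Inf, nj)
  # per-spot, per-junction minimum pixel distance
  assignment <- rep(NA_integer_, ns)
  sp_min <- matrix(Inf, ns, nj)
  for (s in seq_len(ns)) {
    px <- pixels[[s]]
    for (j in seq_len(nj)) {
      d2 <- min((px[, "x"] - junctions$x[j])^2 +
                (px[, "y"] - junctions$y[j])^2)
      sp_min[s, j] <- sqrt(d2)
    }
  }
  if (ns > 0 && nj > 0) {
    jdist <- apply(sp_min, 2, min)
    for (s in seq_len(ns)) {
      within <- which(sp_min[s, ] <= distance_threshold_px)
      if (length(within) > 0)
        assignment[s] <- within[which.min(sp_min[s, within])]
    }
  }
  list(permeable = jdist <= distance_threshold_px, assignment = assignment,
       junction_distance = jdist)
}

#' Per-image permeability report
#'
#' The four metrics of the spatially resolved permeability analysis plus
#' raw counts: fraction of permeable junctions, total tracer accumulation
#' (RFU), junction-associated accumulation and its share of the total, and
#' the mean accumulation per permeable junction.
#'
#' @param junctions A [junction_set()].
#' @param spots A `spot_set`.
#' @param flags Logical permeability flags per junction ([associate()]).
#' @param assignment Integer spot-to-junction assignment ([associate()]).
#' @param tracer_image,foreground The image and thresholded foreground.
#' @return An object of class `permeability_report`.
#' @export
compute_report <- function(junctions, spots, flags, assignment,
                           tracer_image, foreground) {
  n_j <- nrow(junctions)
  if (n_j == 0)
    stop("no junctions detected: image rejected as unanalysable")
  n_perm <- sum(flags)
  total <- total_accumulation(tracer_image, foreground)
  tj_acc <- sum(spots$integrated_intensity[!is.na(assignment)])
  structure(list(
    n_junctions = n_j, n_permeable = n_perm,
    total_accumulation = total, tj_accumulation = tj_acc,
    fraction_permeable = n_perm / n_j,
    tj_fraction = if (total > 0) tj_acc / total else 0,
    mean_per_permeable = if (n_perm > 0) tj_acc / n_perm else NA_real_),
    class = "permeability_report")
}

#' @export
print.permeability_report <- function(x, ...) {
  cat(sprintf(
    paste0("<permeability_report> %d/%d junctions permeable (%.1f%%); ",
           "total %.1f RFU, %.1f%% via tricellular junctions; ",
           "%.2f RFU per permeable junction\n"),
    x$n_permeable, x$n_junctions, 100 * x$fraction_permeable,
    x$total_accumulation, 100 * x$tj_fraction,
    if (is.na(x$mean_per_permeable)) NA else x$mean_per_permeable))
  invisible(x)
}

#' Quantify one tracer image against a set of junction centroids
#'
#' Runs the full quantification chain: adaptive thresholding, spot
#' labelling, 2-px association and the permeability report. Junction
#' centroids may come from the trained segmenter, the geometric detector,
#' or ground truth.
#'
#' @param tracer_image Numeric matrix.
#' @param junctions A [junction_set()].
#' @param params A [threshold_params()].
#' @param distance_threshold_px Association radius in px.
#' @param min_spot_px Minimum spot size in pixels (see [label_spots()]);
#'   the default 5 suppresses single-pixel noise excursions while keeping
#'   any resolvable accumulation spot.
#' @return List: `report`, `spots`, `foreground`, `association`.
#' @export
quantify_image <- function(tracer_image, junctions,
                           params = threshold_params(),
                           distance_threshold_px = 2, min_spot_px = 5L) {
  fg <- adaptive_threshold(tracer_image, params)
  spots <- label_spots(fg, tracer_image, min_spot_px)
  fg <- matrix(FALSE, nrow(fg), ncol(fg))
  px <- attr(spots, "pixels")
  for (p in px) fg[cbind(p[, "y"] + 1, p[, "x"] + 1)] <- TRUE
  assoc <- associate(junctions, spots, distance_threshold_px)
  report <- compute_report(junctions, spots, assoc$permeable,
                           assoc$assignment, tracer_image, fg)
  list(report = report, spots = spots, foreground = fg, association = assoc)
}
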
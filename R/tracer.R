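#' Render the bound-tracer channel with exact ground truth
#'
#' Emulates a substrate-bound tracer image from the spatially resolved
#' permeability assay. `round(permeable_fraction * n_junctions)` junctions
#' are drawn without replacement and receive a Gaussian spot whose centre
#' is jittered by at most 1 px (so it stays inside the 2-px association
#' radius by construction); `n_offjunction_spots` further spots are placed
#' on cell borders or interiors more than 5 px from every junction
#' centroid. Off-junction amplitudes are rescaled so the expected
#' junction-associated share of above-background signal equals
#' `tj_signal_share`. The returned ground truth records what was actually
#' realised: per-spot provenance and pixel-summed integrals, the realised
#' permeable flags, and the realised signal share.
#'
#' @param tess A `cell_tessellation`.
#' @param params A [tracer_params()].
#' @param rng_seed Integer seed.
#' @return List with `image` (matrix in \[0, 1\]) and `truth`, a
#'   `tracer_truth` object: `junctions` (junction set with `permeable`),
#'   `spots` (data frame: `x`, `y`, `amplitude`, `sigma`, `junction` index
#'   or `NA`, `integral`), `tj_signal`, `total_signal`, `realised_share`,
#'   `n_permeable`.
#' @export
render_tracer_channel <- function(tess, params = tracer_params(), rng_seed = 1L) {
  stopifnot(inherits(tess, "cell_tessellation"),
            inherits(params, "tracer_params"))
  set.seed(rng_seed)
  H <- tess$field$height_px; W <- tess$field$width_px
  jn <- tess$vertices
  n_j <- nrow(jn)
  n_perm <- round(params$permeable_fraction * n_j)
  if (n_perm < 1 && params$permeable_fraction > 0 && params$tj_signal_share > 0)
    warning("permeable_fraction * n_junctions < 1: zero permeable junctions")
  perm_idx <- if (n_perm > 0) sort(sample.int(n_j, n_perm)) else integer()

  spots <- data.frame(x = numeric(), y = numeric(), amplitude = numeric(),
                      sigma = numeric(), junction = integer())
  if (n_perm > 0) {
    jit <- .runif_disk(n_perm, 1)
    spots <- rbind(spots, data.frame(
      x = jn$x[perm_idx] + jit[, 1], y = jn$y[perm_idx] + jit[, 2],
      amplitude = .rlnorm_mean_cv(n_perm, params$spot_amplitude_mean,
                                  params$spot_amplitude_cv),
      sigma = params$spot_sigma_px, junction = perm_idx))
  }
  share <- params$tj_signal_share
  n_off <- params$n_offjunction_spots
  if (is.na(n_off)) {
    # size the off-junction population so its spots can follow the same
    # amplitude law as junction spots while meeting the share set-point
    n_off <- if (n_perm == 0 || share >= 1) 0L else
      max(1L, as.integer(round(
        sum(spots$amplitude) * (1 - share) / share /
          params$spot_amplitude_mean)))
  }
  if (n_off > 0) {
    off <- .place_off_junction(tess, n_off, min_dist = 5)
    amp0 <- .rlnorm_mean_cv(nrow(off), params$spot_amplitude_mean,
                            params$spot_amplitude_cv)
    # rescale so the analytic share of junction signal hits the set-point
    s_j <- sum(spots$amplitude) * 2 * pi * params$spot_sigma_px^2
    scale <- if (n_perm == 0) 1
      else if (share >= 1) 0
      else (s_j * (1 - share) / share) /
           (sum(amp0) * 2 * pi * params$spot_sigma_px^2)
    amp0 <- amp0 * scale
    keep <- amp0 > 0
    if (any(keep))
      spots <- rbind(spots, data.frame(
        x = off[keep, 1], y = off[keep, 2], amplitude = amp0[keep],
        sigma = params$spot_sigma_px, junction = NA_integer_))
  }
  rend <- .render_spots(H, W, spots)
  img <- rend$signal + params$background_level
  if (params$background_noise_sd > 0)
    img <- img + matrix(rnorm(H * W, 0, params$background_noise_sd), H, W)
  img <- pmin(pmax(img, 0), 1)

  spots$integral <- rend$integrals
  jn$permeable <- seq_len(n_j) %in% perm_idx
  tj_sig <- sum(spots$integral[!is.na(spots$junction)])
  tot_sig <- sum(spots$integral)
  truth <- structure(list(
    junctions = jn, spots = spots, tj_signal = tj_sig,
    total_signal = tot_sig,
    realised_share = if (tot_sig > 0) tj_sig / tot_sig else 0,
    n_permeable = n_perm, params = params), class = "tracer_truth")
  list(image = img, truth = truth)
}

# n points uniform in a disk of given radius
.runif_disk <- function(n, radius) {
  r <- radius * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  cbind(r * cos(th), r * sin(th))
}

# lognormal draws with given mean and coefficient of variation
.rlnorm_mean_cv <- function(n, mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# sample points on edges (or interiors), > min_dist from all junctions
.place_off_junction <- function(tess, n, min_dist = 5) {
  H <- tess$field$height_px; W <- tess$field$width_px
  jn <- tess$vertices
  out <- matrix(NA_real_, n, 2)
  got <- 0; tries <- 0
  ne <- nrow(tess$edges)
  while (got < n && tries < 1000 * n) {
    tries <- tries + 1
    if (ne > 0 && runif(1) < 0.6) {
      e <- tess$edges[sample.int(ne, 1), ]
      t <- runif(1)
      p <- c(e[1] + t * (e[3] - e[1]), e[2] + t * (e[4] - e[2]))
    } else {
      p <- c(runif(1, 0, W - 1), runif(1, 0, H - 1))
    }
    if (nrow(jn) > 0 &&
        min(sqrt((jn$x - p[1])^2 + (jn$y - p[2])^2)) <= min_dist) next
    got <- got + 1
    out[got, ] <- p
  }
  out[seq_len(got), , drop = FALSE]
}

# accumulate Gaussian spots; returns the noiseless signal field and each
# spot's realised (in-field, pixel-summed) integral
.render_spots <- function(H, W, spots) {
  signal <- matrix(0, H, W)
  n <- nrow(spots)
  integrals <- numeric(n)
  for (i in seq_len(n)) {
    s <- spots$sigma[i]; a <- spots$amplitude[i]
    cx <- spots$x[i]; cy <- spots$y[i]
    r <- ceiling(4 * s)
    cs <- max(0, floor(cx - r)):min(W - 1, ceiling(cx + r))
    rs <- max(0, floor(cy - r)):min(H - 1, ceiling(cy + r))
    if (length(cs) == 0 || length(rs) == 0) next
    g <- a * exp(-outer((rs - cy)^2, (cs - cx)^2, "+") / (2 * s^2))
    signal[rs + 1, cs + 1] <- signal[rs + 1, cs + 1] + g
    integrals[i] <- sum(g)
  }
  list(signal = signal, integrals = integrals)
}

#' @export
print.tracer_truth <- function(x, ...) {
  cat(sprintf(
    "<tracer_truth> %d/%d junctions permeable, %d spots, realised TJ share %.3f\n",
    x$n_permeable, nrow(x$junctions), nrow(x$spots), x$realised_share))
  invisible(x)
}

#' Experimental-condition presets for the tracer generator
#'
#' Returns generator set-points encoding the five monolayer conditions
#' studied with this assay. Permeable fractions are the measured
#' percentages of permeable tricellular junctions (untreated 38.1%,
#' S1P 20.3%, thrombin 47.3%, multidirectional shear 40.7%, uniaxial shear
#' 28.9%); junction-associated signal shares sit in the measured 0.80-0.87
#' band; per-junction amplitude scalings encode the ~+25% (thrombin) and
#' ~-31% (uniaxial) changes in mean accumulation per permeable junction.
#'
#' @param name One of `"untreated"`, `"s1p"`, `"thrombin"`,
#'   `"multidirectional"`, `"uniaxial"`.
#' @return A [tracer_params()] for the named condition.
#' @seealso [condition_presets()] for the full table.
#' @export
condition_preset <- function(name) {
  tab <- condition_presets()
  i <- match(name, tab$condition)
  if (is.na(i))
    stop("unknown condition '", name, "'; valid names: ",
         paste(tab$condition, collapse = ", "))
  tracer_params(permeable_fraction = tab$permeable_fraction[i],
                tj_signal_share = tab$tj_signal_share[i],
                spot_amplitude_mean = 0.5 * tab$amplitude_scale[i])
}

#' @rdname condition_preset
#' @export
condition_presets <- function() {
  data.frame(
    condition = c("untreated", "s1p", "thrombin", "multidirectional",
                  "uniaxial"),
    permeable_fraction = c(0.381, 0.203, 0.473, 0.407, 0.289),
    tj_signal_share = c(0.84, 0.84, 0.84, 0.85, 0.87),
    amplitude_scale = c(1, 1, 1.25, 1, 0.69))
}

#' Root-mean-square radius of free 2-D diffusion
#'
#' Returns `sqrt(4 * D * t)`, the RMS displacement of a freely diffusing
#' particle in two dimensions. Used as a documented sanity bound when
#' judging whether tracer-spot growth could be explained by unbound lateral
#' diffusion; both the diffusivity and the elapsed time are arguments
#' because neither is fixed by the assay.
#'
#' @param diffusivity Diffusion coefficient (length^2 / time).
#' @param elapsed Elapsed time. Units must be consistent with `diffusivity`;
#'   the result is in the corresponding length unit.
#' @return RMS displacement.
#' @examples
#' # a ~66 kDa protein, D = 4.2e-7 cm^2/s = 42 um^2/s, after 12 min:
#' free_diffusion_radius(42, 720) # ~348 um
#' @export
free_diffusion_radius <- function(diffusivity, elapsed) {
  if (diffusivity <= 0 || elapsed <= 0)
    stop("diffusivity and elapsed must be positive")
  sqrt(4 * diffusivity * elapsed)
}
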
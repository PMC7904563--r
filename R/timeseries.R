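#' Generate a live-imaging time series of tracer accumulation
#'
#' Emulates live-cell imaging of tracer crossing the monolayer: the
#' permeable-designate junctions are chosen as in
#' [render_tracer_channel()]; each closed designate opens with probability
#' `junction_opening_rate` per frame (opened junctions stay open), and an
#' open junction's spot sigma grows by `spot_growth_rate` px per frame
#' while its peak amplitude stays fixed, so integrated spot intensity is
#' nondecreasing. Frame 0 is background-only unless `open_at_start` is
#' `TRUE` (all designates open at frame 0).
#'
#' @param tess A `cell_tessellation`.
#' @param t_params A [tracer_params()]; off-junction spots are not placed
#'   in time series.
#' @param ts A [timeseries_params()].
#' @param rng_seed Integer seed.
#' @param open_at_start If `TRUE` all designates are open from frame 0.
#' @return List with `frames` (list of matrices), `truth`: data frame of
#'   designates (`junction`, `x`, `y`, `amplitude`, `open_frame`, `NA` if
#'   never opened) and the per-frame spot tables in `spots_by_frame`.
#' @export
generate_timeseries <- function(tess, t_params = tracer_params(),
                                ts = timeseries_params(), rng_seed = 1L,
                                open_at_start = FALSE) {
  stopifnot(inherits(ts, "timeseries_params"), ts$n_frames >= 2)
  set.seed(rng_seed)
  H <- tess$field$height_px; W <- tess$field$width_px
  jn <- tess$vertices
  n_j <- nrow(jn)
  n_des <- round(t_params$permeable_fraction * n_j)
  des <- if (n_des > 0) sort(sample.int(n_j, n_des)) else integer()
  jit <- .runif_disk(length(des), 1)
  amp <- .rlnorm_mean_cv(length(des), t_params$spot_amplitude_mean,
                         t_params$spot_amplitude_cv)
  open_frame <- rep(NA_integer_, length(des))
  if (open_at_start) open_frame[] <- 0L
  frames <- vector("list", ts$n_frames)
  spots_by_frame <- vector("list", ts$n_frames)
  for (k in seq_len(ts$n_frames) - 1L) {
    if (k > 0 || !open_at_start) {
      closed <- which(is.na(open_frame))
      if (length(closed) > 0 && k > 0) {
        opens <- runif(length(closed)) < ts$junction_opening_rate
        open_frame[closed[opens]] <- k
      }
    }
    open <- which(!is.na(open_frame) & open_frame <= k)
    spots <- data.frame(
      x = jn$x[des[open]] + jit[open, 1], y = jn$y[des[open]] + jit[open, 2],
      amplitude = amp[open],
      sigma = t_params$spot_sigma_px +
        ts$spot_growth_rate * (k - open_frame[open]),
      junction = des[open])
    rend <- .render_spots(H, W, spots)
    img <- rend$signal + t_params$background_level
    if (t_params$background_noise_sd > 0)
      img <- img + matrix(rnorm(H * W, 0, t_params$background_noise_sd), H, W)
    frames[[k + 1]] <- pmin(pmax(img, 0), 1)
    spots$integral <- rend$integrals
    spots_by_frame[[k + 1]] <- spots
  }
  truth <- data.frame(junction = des,
                      x = jn$x[des] + jit[, 1], y = jn$y[des] + jit[, 2],
                      amplitude = amp, open_frame = open_frame)
  list(frames = frames, truth = truth, spots_by_frame = spots_by_frame)
}
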
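#' Imaging-field specification
#'
#' Describes one synthetic acquisition field: its pixel dimensions, the
#' number of cells tiling it, and the seed that makes the geometry
#' reproducible. Real acquisitions in this assay are 1024 x 1024 px; any
#' size from 64 px up is accepted so that tests can run on small fields.
#'
#' @param height_px,width_px Field size in pixels (>= 64).
#' @param n_cells Number of cells tiling the field (>= 3).
#' @param rng_seed Integer seed controlling seed-point placement.
#' @return An object of class `field_spec`.
#' @export
field_spec <- function(height_px = 512L, width_px = 512L, n_cells = 100L,
                       rng_seed = 1L) {
  stopifnot(height_px >= 64, width_px >= 64, n_cells >= 3)
  structure(list(height_px = as.integer(height_px),
                 width_px = as.integer(width_px),
                 n_cells = as.integer(n_cells),
                 rng_seed = as.integer(rng_seed)),
            class = "field_spec")
}

#' Cell-border rendering parameters
#'
#' Controls how tessellation edges are turned into an immunostain-like
#' border channel: ridge width and brightness, Gaussian blur standing in
#' for the microscope point-spread, and additive Gaussian noise.
#' Intensities live in \[0, 1\] internally; `bit_depth` only affects export.
#'
#' @param border_width_px Full width of the rendered border ridge (px).
#' @param border_peak_intensity Ridge intensity before blur, in (0, 1].
#' @param blur_sigma_px Gaussian blur sigma (px); 0 disables blur.
#' @param noise_sd Additive Gaussian noise standard deviation; 0 disables.
#' @param bit_depth 8 or 16; used when writing images to disk.
#' @return An object of class `render_params`.
#' @export
render_params <- function(border_width_px = 2.5, border_peak_intensity = 0.8,
                          blur_sigma_px = 1, noise_sd = 0.02, bit_depth = 16L) {
  stopifnot(border_width_px > 0,
            border_peak_intensity > 0, border_peak_intensity <= 1,
            blur_sigma_px >= 0, noise_sd >= 0, bit_depth %in% c(8L, 16L))
  if (border_peak_intensity <= noise_sd)
    stop("border_peak_intensity must exceed the noise floor")
  structure(list(border_width_px = border_width_px,
                 border_peak_intensity = border_peak_intensity,
                 blur_sigma_px = blur_sigma_px, noise_sd = noise_sd,
                 bit_depth = as.integer(bit_depth)),
            class = "render_params")
}

#' Tracer-channel generation parameters
#'
#' Set-points for the synthetic bound-tracer channel. `permeable_fraction`
#' is the expected fraction of tricellular junctions that receive a tracer
#' spot and `tj_signal_share` the expected fraction of total above-background
#' tracer signal carried by those junction-centred spots; both mirror the
#' quantities the analysis pipeline estimates, so generator runs have a
#' known truth to recover.
#'
#' @param permeable_fraction Expected fraction of junctions with a spot, in \[0, 1\].
#' @param tj_signal_share Expected junction-associated share of above-background
#'   signal, in \[0, 1\].
#' @param spot_sigma_px Gaussian spot sigma (px).
#' @param spot_amplitude_mean,spot_amplitude_cv Mean and coefficient of
#'   variation of the lognormal per-spot peak amplitude.
#' @param n_offjunction_spots Number of spots placed along cell borders or
#'   interiors, away (> 5 px) from any junction. The default `NA` sizes
#'   the count so that off-junction spots follow the same amplitude law as
#'   junction spots while the signal-share set-point is met; a fixed count
#'   instead rescales their amplitudes.
#' @param background_level,background_noise_sd Constant background and
#'   additive Gaussian noise sd, both in \[0, 1\] units.
#' @return An object of class `tracer_params`.
#' @export
tracer_params <- function(permeable_fraction = 0.381, tj_signal_share = 0.84,
                          spot_sigma_px = 1.2, spot_amplitude_mean = 0.5,
                          spot_amplitude_cv = 0.3,
                          n_offjunction_spots = NA_integer_,
                          background_level = 0.05, background_noise_sd = 0.01) {
  stopifnot(permeable_fraction >= 0, permeable_fraction <= 1,
            tj_signal_share >= 0, tj_signal_share <= 1,
            spot_sigma_px > 0, spot_amplitude_mean > 0, spot_amplitude_cv > 0,
            is.na(n_offjunction_spots) || n_offjunction_spots >= 0,
            background_level >= 0, background_noise_sd >= 0)
  structure(list(permeable_fraction = permeable_fraction,
                 tj_signal_share = tj_signal_share,
                 spot_sigma_px = spot_sigma_px,
                 spot_amplitude_mean = spot_amplitude_mean,
                 spot_amplitude_cv = spot_amplitude_cv,
                 n_offjunction_spots = as.integer(n_offjunction_spots),
                 background_level = background_level,
                 background_noise_sd = background_noise_sd),
            class = "tracer_params")
}

#' Time-series generation parameters
#'
#' Describes live-imaging dynamics: how many frames, how far apart, how
#' fast an open junction's spot radius grows, and the per-frame probability
#' that a closed permeable-designate junction opens. Opened junctions stay
#' open and spot radii never shrink.
#'
#' @param n_frames Number of frames (>= 2).
#' @param frame_interval_s Seconds between frames.
#' @param spot_growth_rate Spot radius (sigma) increase per frame, px.
#' @param junction_opening_rate Per-frame opening probability in \[0, 1\].
#' @return An object of class `timeseries_params`.
#' @export
timeseries_params <- function(n_frames = 10L, frame_interval_s = 30,
                              spot_growth_rate = 0.3,
                              junction_opening_rate = 0.2) {
  stopifnot(n_frames >= 2, frame_interval_s > 0, spot_growth_rate > 0,
            junction_opening_rate >= 0, junction_opening_rate <= 1)
  structure(list(n_frames = as.integer(n_frames),
                 frame_interval_s = frame_interval_s,
                 spot_growth_rate = spot_growth_rate,
                 junction_opening_rate = junction_opening_rate),
            class = "timeseries_params")
}

#' Adaptive-threshold parameters for tracer spot detection
#'
#' A pixel is foreground when its value strictly exceeds the local
#' Gaussian-weighted mean scaled by `(1 + sensitivity)`. The neighbourhood
#' is the full width of the Gaussian window; its sigma is
#' `neighbourhood_px / 4`. When `neighbourhood_px` is `NULL` it defaults at
#' call time to the nearest odd integer to `image_size / 8`.
#'
#' @param neighbourhood_px Odd integer >= 3, or `NULL` for the size-derived
#'   default.
#' @param sensitivity Relative excess over the local mean required for
#'   foreground, in \[0, 1\].
#' @return An object of class `threshold_params`.
#' @export
threshold_params <- function(neighbourhood_px = NULL, sensitivity = 0.5) {
  if (!is.null(neighbourhood_px)) {
    neighbourhood_px <- as.integer(neighbourhood_px)
    stopifnot(neighbourhood_px >= 3, neighbourhood_px %% 2 == 1)
  }
  stopifnot(sensitivity >= 0, sensitivity <= 1)
  structure(list(neighbourhood_px = neighbourhood_px,
                 sensitivity = sensitivity),
            class = "threshold_params")
}

#' Construct a junction set
#'
#' A junction set is a data frame of junction centroids in 0-based pixel
#' coordinates (`x` = column, `y` = row), with optional per-junction
#' attributes such as `degree` (number of meeting cells) or `permeable`.
#'
#' @param x,y Numeric centroid coordinates.
#' @param ... Further equal-length per-junction columns.
#' @return A `junction_set` (also a data frame).
#' @export
junction_set <- function(x = numeric(), y = numeric(), ...) {
  df <- data.frame(x = as.numeric(x), y = as.numeric(y), ...)
  class(df) <- c("junction_set", "data.frame")
  df
}

#' @export
print.field_spec <- function(x, ...) {
  cat(sprintf("<field_spec> %d x %d px, %d cells, seed %d\n",
              x$height_px, x$width_px, x$n_cells, x$rng_seed))
  invisible(x)
}
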
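#' Write / read a single-channel image
#'
#' Images are held in \[0, 1\] internally and quantised to the requested
#' bit depth only here. TIFF supports 8 and 16 bit; PNG is written as an
#' 8-bit container.
#'
#' @param img Numeric matrix in \[0, 1\].
#' @param path Output path ending in `.tif`, `.tiff` or `.png`.
#' @param bit_depth 8 or 16.
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path, bit_depth = 16L) {
  stopifnot(bit_depth %in% c(8L, 16L))
  img <- pmin(pmax(img, 0), 1)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img, path, bits.per.sample = as.integer(bit_depth))
  } else if (ext == "png") {
    png::writePNG(img, path)
  } else stop("unsupported image extension: ", ext)
  invisible(path)
}

#' @rdname save_image
#' @export
load_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
         else if (ext == "png") png::readPNG(path)
         else stop("unsupported image extension: ", ext)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

#' Write / read junction centroids as CSV (x, y, permeable)
#' @param junctions A [junction_set()].
#' @param path CSV path.
#' @export
write_junctions_csv <- function(junctions, path) {
  df <- as.data.frame(junctions)
  if (is.null(df$permeable)) df$permeable <- NA
  write.csv(df[c("x", "y", "permeable")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_junctions_csv
#' @export
read_junctions_csv <- function(path) {
  df <- read.csv(path)
  junction_set(df$x, df$y, permeable = df$permeable)
}

#' Write generator ground truth as JSON
#' @param truth A `tracer_truth`.
#' @param path JSON path.
#' @export
write_ground_truth_json <- function(truth, path) {
  jsonlite::write_json(list(
    junctions = truth$junctions, spots = truth$spots,
    tj_signal = truth$tj_signal, total_signal = truth$total_signal,
    realised_share = truth$realised_share,
    n_permeable = truth$n_permeable), path, auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(path)
}

#' Flatten a permeability report to a one-row data frame
#' @param report A `permeability_report`.
#' @param ... Extra columns (condition, replicate, image, ...).
#' @export
report_as_row <- function(report, ...) {
  data.frame(..., n_junctions = report$n_junctions,
             n_permeable = report$n_permeable,
             total_accumulation = report$total_accumulation,
             tj_accumulation = report$tj_accumulation,
             fraction_permeable = report$fraction_permeable,
             tj_fraction = report$tj_fraction,
             mean_per_permeable = report$mean_per_permeable)
}

#' Write a spot table as CSV
#' @param spots A `spot_set`.
#' @param assignment Optional junction assignment from [associate()].
#' @param path CSV path.
#' @export
write_spots_csv <- function(spots, path, assignment = NULL) {
  df <- as.data.frame(spots)
  df$assigned_junction <- if (is.null(assignment)) NA_integer_ else assignment
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
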
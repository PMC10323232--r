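#' Scale factors between a movie's calibration and the reference scale
#'
#' The returned factors convert sizes and coordinates from the movie's own
#' scale to the reference scale by multiplication: a movie with coarser
#' pixels than the reference (larger um/pixel) has a spatial factor > 1 and
#' is upsampled. `spatial_factor = pixel_size / pixel_size_ref`,
#' `temporal_factor = frame_interval / frame_interval_ref`.
#'
#' @param pixel_size um/pixel of the movie.
#' @param frame_interval min/frame of the movie.
#' @param ref a [reference_scale()].
#' @return named numeric vector `c(spatial = ..., temporal = ...)`.
#' @export
compute_scale_factors <- function(pixel_size, frame_interval,
                                  ref = reference_scale()) {
  if (!is.finite(pixel_size) || pixel_size <= 0 ||
      !is.finite(frame_interval) || frame_interval <= 0)
    stop_invalid("calibration must be strictly positive")
  c(spatial = pixel_size / ref$pixel_size_ref,
    temporal = frame_interval / ref$frame_interval_ref)
}

#' Scale factors from observed cell features
#'
#' For tissues whose absolute calibration is not comparable to the training
#' tissue (different cell sizes, different event durations), the rescaling is
#' derived from cellular features instead: the factors map the observed cell
#' diameter to the reference ~25 px and the observed extrusion duration to
#' the reference ~4.5 frames. As with [compute_scale_factors()], factors
#' multiply movie-scale sizes to give reference-scale sizes, so
#' `spatial_factor = cell_diameter_ref / observed_cell_diameter`.
#'
#' @param observed_cell_diameter_px typical cell diameter in the movie, px.
#' @param observed_extrusion_frames typical extrusion duration, frames.
#' @param ref a [reference_scale()].
#' @return named numeric vector `c(spatial = ..., temporal = ...)`.
#' @export
scale_factors_from_cell_features <- function(observed_cell_diameter_px,
                                             observed_extrusion_frames,
                                             ref = reference_scale()) {
  if (!is.finite(observed_cell_diameter_px) || observed_cell_diameter_px <= 0 ||
      !is.finite(observed_extrusion_frames) || observed_extrusion_frames <= 0)
    stop_invalid("observed cell features must be strictly positive")
  c(spatial = ref$cell_diameter_px / observed_cell_diameter_px,
    temporal = ref$extrusion_duration_frames / observed_extrusion_frames)
}

#' Resample a movie to the reference scale
#'
#' Spatial resampling is bilinear; temporal resampling picks the nearest
#' source frame (no temporal interpolation is invented: frame decimation /
#' duplication only). Output sizes are `round_half_away(size * factor)` per
#' axis. The output calibration equals the reference within the rounding of
#' integer shapes.
#'
#' @param mov an [movie()].
#' @param ref a [reference_scale()].
#' @param factors optional explicit `c(spatial, temporal)` factors, e.g. from
#'   [scale_factors_from_cell_features()]; default derives them from the
#'   movie calibration.
#' @return a rescaled `epi_movie` carrying the reference calibration.
#' @export
rescale_movie_to_reference <- function(mov, ref = reference_scale(),
                                       factors = NULL) {
  stopifnot(inherits(mov, "epi_movie"))
  if (is.null(factors))
    factors <- compute_scale_factors(mov$pixel_size, mov$frame_interval, ref)
  rescale_movie(mov, factors,
                pixel_size_out = mov$pixel_size / factors[["spatial"]],
                frame_interval_out = mov$frame_interval / factors[["temporal"]])
}

#' Resample a movie by explicit scale factors
#'
#' @param mov an [movie()].
#' @param factors named `c(spatial, temporal)` multipliers for sizes.
#' @param pixel_size_out,frame_interval_out calibration recorded on the
#'   output movie.
#' @return an `epi_movie`.
#' @export
rescale_movie <- function(mov, factors, pixel_size_out = NULL,
                          frame_interval_out = NULL) {
  stopifnot(inherits(mov, "epi_movie"))
  fs <- factors[["spatial"]]; ft <- factors[["temporal"]]
  if (!is.finite(fs) || fs <= 0 || !is.finite(ft) || ft <= 0)
    stop_invalid("scale factors must be strictly positive")
  d <- dim(mov$frames)
  nt <- as.integer(round_half_away(d[1] * ft))
  ny <- as.integer(round_half_away(d[2] * fs))
  nx <- as.integer(round_half_away(d[3] * fs))
  if (nt < 1L) stop_invalid("temporal rescaling leaves fewer than one frame")
  if (ny < 1L || nx < 1L) stop_invalid("spatial rescaling collapses the image")
  # nearest source frame for each output frame
  src <- pmin(d[1] - 1L, pmax(0L, as.integer(round_half_away((seq_len(nt) - 1L) / ft))))
  out <- array(0, dim = c(nt, ny, nx))
  done <- new.env(parent = emptyenv())  # cache resized frames (decimation reuse)
  for (i in seq_len(nt)) {
    key <- as.character(src[i])
    if (is.null(done[[key]])) {
      fr <- mov$frames[src[i] + 1L, , ]
      done[[key]] <- if (ny == d[2] && nx == d[3]) fr
                     else resize_bilinear(fr, ny, nx)
    }
    out[i, , ] <- done[[key]]
  }
  movie(pmax(out, 0),
        pixel_size = pixel_size_out %||% (mov$pixel_size / fs),
        frame_interval = frame_interval_out %||% (mov$frame_interval / ft))
}

# bilinear 2D resize of a (y, x) matrix via EBImage (which expects (x, y))
resize_bilinear <- function(img, ny, nx) {
  t(EBImage::resize(t(img), w = nx, h = ny, antialias = FALSE))
}

#' Map event points between coordinate scales
#'
#' Multiplies (direction `"to_reference"`) or divides (`"to_original"`)
#' coordinates by the scale factors and rounds half away from zero. Class and
#' probability are preserved.
#'
#' @param events an [event_set()].
#' @param factors named `c(spatial, temporal)` factors, oriented as returned
#'   by [compute_scale_factors()].
#' @param direction `"to_reference"` or `"to_original"`.
#' @param pixel_size,frame_interval optional calibration recorded on the
#'   output set.
#' @return an `epi_events` with mapped coordinates.
#' @export
map_points <- function(events, factors,
                       direction = c("to_reference", "to_original"),
                       pixel_size = NA_real_, frame_interval = NA_real_) {
  direction <- match.arg(direction)
  fs <- factors[["spatial"]]; ft <- factors[["temporal"]]
  if (!is.finite(fs) || fs <= 0 || !is.finite(ft) || ft <= 0)
    stop_invalid("scale factors must be strictly positive")
  if (direction == "to_original") { fs <- 1 / fs; ft <- 1 / ft }
  df <- data.frame(x = round_half_away(events$x * fs),
                   y = round_half_away(events$y * fs),
                   t = pmax(0, round_half_away(events$t * ft)),
                   class = events$class, probability = events$probability,
                   stringsAsFactors = FALSE)
  # distinct points can collide on the coarser grid; keep the first
  df <- df[!duplicated(df[c("x", "y", "t", "class")]), , drop = FALSE]
  as_event_set(df, pixel_size = pixel_size, frame_interval = frame_interval)
}
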
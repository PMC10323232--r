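#' Event classes recognised by the pipeline
#'
#' The closed set of window/event labels: `"none"` (no event), `"extrusion"`
#' (apical constriction terminating in cell elimination), `"sop"` (sensory
#' organ precursor, a persistently small-apex cell) and `"division"`
#' (cytokinesis with furrow formation). `"none"` is always a valid class;
#' classifiers with fewer than four classes use a prefix of this ordering.
#'
#' @export
EVENT_CLASSES <- c("none", "extrusion", "sop", "division")

#' Create a movie object
#'
#' A movie is a 3D intensity stack ordered (t, y, x) plus its physical
#' calibration: pixel size in micrometres per pixel and frame interval in
#' minutes per frame. Coordinates are 0-based throughout the package; `t` is
#' a frame index and is converted to minutes only at reporting boundaries.
#'
#' @param frames numeric 3D array `(t, y, x)` of non-negative intensities.
#' @param pixel_size micrometres per pixel, > 0.
#' @param frame_interval minutes per frame, > 0.
#' @return an object of class `epi_movie`.
#' @export
movie <- function(frames, pixel_size, frame_interval) {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop_invalid("frames must be a 3D array ordered (t, y, x)")
  if (dim(frames)[1] < 1L)
    stop_invalid("movie must have at least one frame")
  if (any(!is.finite(frames)) || any(frames < 0))
    stop_invalid("frame intensities must be finite and non-negative")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop_invalid("pixel_size must be a positive scalar (um/pixel)")
  if (!is.numeric(frame_interval) || length(frame_interval) != 1L || frame_interval <= 0)
    stop_invalid("frame_interval must be a positive scalar (min/frame)")
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval),
            class = "epi_movie")
}

#' @export
print.epi_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<epi_movie> %d frames of %dx%d px  (%.4g um/px, %.4g min/frame)\n",
              d[1], d[2], d[3], x$pixel_size, x$frame_interval))
  invisible(x)
}

#' @export
dim.epi_movie <- function(x) dim(x$frames)

#' Reference spatiotemporal scale
#'
#' The fixed calibration every movie is resampled to before classification:
#' 0.275 um/pixel and 5 min/frame, at which a typical epithelial cell is
#' about 25 pixels across and an extrusion spans about 4-5 frames. The cell
#' features are used to derive scale factors for tissues whose absolute
#' calibration is not comparable (see [scale_factors_from_cell_features()]).
#'
#' @param pixel_size_ref um/pixel of the reference scale.
#' @param frame_interval_ref min/frame of the reference scale.
#' @param cell_diameter_px typical cell diameter at reference scale, pixels.
#' @param extrusion_duration_frames typical extrusion duration at reference
#'   scale, frames (4.5 = midpoint of "four or five").
#' @return an object of class `epi_reference_scale`.
#' @export
reference_scale <- function(pixel_size_ref = 0.275, frame_interval_ref = 5.0,
                            cell_diameter_px = 25, extrusion_duration_frames = 4.5) {
  vals <- c(pixel_size_ref, frame_interval_ref, cell_diameter_px,
            extrusion_duration_frames)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop_invalid("all reference-scale parameters must be positive")
  structure(list(pixel_size_ref = pixel_size_ref,
                 frame_interval_ref = frame_interval_ref,
                 cell_diameter_px = cell_diameter_px,
                 extrusion_duration_frames = extrusion_duration_frames),
            class = "epi_reference_scale")
}

#' Create an annotation set of point events
#'
#' An annotation set is a data frame of classed point events at integer
#' (x, y, t), with an optional detection probability, plus the calibration of
#' the coordinate system the points live in. Duplicate (x, y, t, class) rows
#' are invalid.
#'
#' @param x,y pixel coordinates (0-based).
#' @param t frame indices (0-based integers).
#' @param class event classes, each one of [EVENT_CLASSES].
#' @param probability optional detection probabilities in \[0, 1\] (NA when
#'   absent, e.g. for manual annotations).
#' @param pixel_size,frame_interval calibration of the source coordinates.
#' @return an object of class `epi_events` (a data frame with columns
#'   `x, y, t, class, probability`).
#' @export
event_set <- function(x = numeric(), y = numeric(), t = numeric(),
                      class = character(), probability = NULL,
                      pixel_size = NA_real_, frame_interval = NA_real_) {
  n <- length(x)
  if (length(y) != n || length(t) != n || length(class) != n)
    stop_invalid("x, y, t and class must have equal length")
  if (is.null(probability)) probability <- rep(NA_real_, n)
  if (length(probability) != n)
    stop_invalid("probability must match the number of events")
  if (n > 0) {
    if (any(!class %in% EVENT_CLASSES))
      stop_invalid("unknown event class: ",
                   paste(unique(setdiff(class, EVENT_CLASSES)), collapse = ", "))
    if (any(t < 0) || any(t != floor(t)))
      stop_invalid("t must be non-negative integer frame indices")
    ok <- is.na(probability) | (probability >= 0 & probability <= 1)
    if (!all(ok)) stop_invalid("probabilities must be in [0, 1] or NA")
  }
  df <- data.frame(x = as.numeric(x), y = as.numeric(y), t = as.integer(t),
                   class = as.character(class),
                   probability = as.numeric(probability),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df[c("x", "y", "t", "class")]))
    stop_invalid("duplicate (x, y, t, class) entries are not allowed")
  structure(df, class = c("epi_events", "data.frame"),
            pixel_size = pixel_size, frame_interval = frame_interval)
}

#' Coerce a data frame to an annotation set
#' @param df data frame with columns x, y, t, class and optionally probability.
#' @inheritParams event_set
#' @export
as_event_set <- function(df, pixel_size = NA_real_, frame_interval = NA_real_) {
  event_set(df$x, df$y, df$t, df$class,
            if ("probability" %in% names(df)) df$probability else NULL,
            pixel_size = pixel_size, frame_interval = frame_interval)
}

#' @export
print.epi_events <- function(x, ...) {
  cat(sprintf("<epi_events> %d events (%s)\n", nrow(x),
              paste(sprintf("%s: %d", names(table(x$class)), table(x$class)),
                    collapse = ", ")))
  if (nrow(x) > 0) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

# keep the epi_events class through subsetting
#' @export
`[.epi_events` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("x", "y", "t", "class") %in% names(out))) {
    class(out) <- c("epi_events", "data.frame")
    attr(out, "pixel_size") <- attr(x, "pixel_size")
    attr(out, "frame_interval") <- attr(x, "frame_interval")
  }
  out
}

check_events_in_bounds <- function(events, mov) {
  d <- dim(mov$frames)
  bad <- events$x < 0 | events$x > d[3] - 1 |
         events$y < 0 | events$y > d[2] - 1 |
         events$t < 0 | events$t > d[1] - 1
  if (any(bad))
    stop_invalid(sum(bad), " event(s) fall outside the movie bounds")
  invisible(TRUE)
}
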
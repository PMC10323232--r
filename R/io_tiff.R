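#' Read a multi-page TIFF time series as a movie
#'
#' Pages are interpreted as frames of a single-channel 2D time series. RGB
#' pages are converted to grayscale by channel averaging. The calibration is
#' attached from the arguments: any calibration present in the TIFF metadata
#' is deliberately ignored (and noted in a message), because silently trusting
#' heterogeneous metadata is the pipeline's worst failure mode.
#'
#' @param path TIFF file.
#' @param pixel_size um/pixel.
#' @param frame_interval min/frame.
#' @return an [movie()]. Intensities are on the \[0, 1\] scale used by the
#'   `tiff` package.
#' @export
read_tiff_movie <- function(path, pixel_size, frame_interval) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = FALSE),
                    error = function(e) stop_format("unreadable TIFF: ",
                                                    conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0L) stop_format("TIFF has no pages: ", path)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) {
      # RGB(A) page -> grayscale mean over colour channels
      apply(p[, , seq_len(min(3L, dim(p)[3])), drop = FALSE], c(1, 2), mean)
    } else p
  })
  shp <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p), shp), TRUE)))
    stop_format("TIFF pages have mismatched shapes")
  frames <- array(0, dim = c(length(pages), shp[1], shp[2]))
  for (i in seq_along(pages)) frames[i, , ] <- pages[[i]]
  movie(frames, pixel_size, frame_interval)
}

#' Write a movie as a multi-page TIFF
#'
#' @param mov an [movie()]; intensities are clipped to \[0, 1\].
#' @param path output file.
#' @param bits 8 or 16 bits per sample.
#' @return `path`, invisibly.
#' @export
write_tiff_movie <- function(mov, path, bits = 16L) {
  stopifnot(inherits(mov, "epi_movie"))
  d <- dim(mov$frames)
  pages <- lapply(seq_len(d[1]), function(i) pmin(pmax(mov$frames[i, , ], 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits),
                  compression = "none")
  invisible(path)
}

#' Export a probability map as 8-bit TIFF stacks
#'
#' One multi-page TIFF per event class, voxel value `round(p * 255)` (half
#' away from zero), so a probability of 1 maps to 255 and 0.5 to 128.
#'
#' @param pmap an `epi_probability_map` (see [classify_movie()]).
#' @param path_prefix output prefix; files are named
#'   `<prefix>_<class>.tif`.
#' @return named character vector of written paths, invisibly.
#' @export
write_probability_map <- function(pmap, path_prefix) {
  stopifnot(inherits(pmap, "epi_probability_map"))
  if (any(pmap$values < 0 | pmap$values > 1))
    stop_invalid("probability map values must be in [0, 1]")
  cls <- pmap$classes
  out <- character(0)
  for (k in seq_along(cls)) {
    v <- pmap$values[, , , k]
    v8 <- round_half_away(v * 255) / 255   # quantised to the 8-bit grid
    d <- dim(v)
    pages <- lapply(seq_len(d[1]), function(i) v8[i, , ])
    p <- paste0(path_prefix, "_", cls[k], ".tif")
    tiff::writeTIFF(pages, p, bits.per.sample = 8L, compression = "none")
    out[cls[k]] <- p
  }
  invisible(out)
}
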
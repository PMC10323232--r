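# Whole-movie inference: sliding-window enumeration, batched classification,
# and probability-map assembly by local allocation and averaging.

#' Enumerate sliding-window origins along the movie axes
#'
#' Origins are placed at multiples of the stride; when the last stride
#' position does not reach the far edge, one extra origin flush with the
#' edge is added so every voxel is covered. For the defaults this gives 50%
#' spatial overlap (45 px window, 22 px stride) and a 10-frame window every
#' 2 frames.
#'
#' @param movie_shape integer (T, Y, X).
#' @param window_shape integer (T, H, W).
#' @param spatial_stride,temporal_stride strides in px / frames.
#' @return data frame of 0-based origins with columns `t, y, x`.
#' @export
enumerate_windows <- function(movie_shape, window_shape = c(10L, 45L, 45L),
                              spatial_stride = 22L, temporal_stride = 2L) {
  axis_origins <- function(n, w, s) {
    if (n < w) stop_invalid("movie extent ", n, " smaller than window ", w)
    o <- as.integer(seq(0L, n - w, by = s))
    if (o[length(o)] != n - w) o <- c(o, as.integer(n - w))
    o
  }
  ot <- axis_origins(movie_shape[1], window_shape[1], temporal_stride)
  oy <- axis_origins(movie_shape[2], window_shape[2], spatial_stride)
  ox <- axis_origins(movie_shape[3], window_shape[3], spatial_stride)
  expand.grid(t = ot, y = oy, x = ox, KEEP.OUT.ATTRS = FALSE)
}

#' Build a probability-map object
#' @param values 4D array (t, y, x, class) of probabilities in \[0, 1\].
#' @param classes character vector naming the class axis.
#' @param coverage 3D array of per-voxel contributing-window counts.
#' @return an `epi_probability_map`.
#' @export
probability_map <- function(values, classes, coverage = NULL) {
  if (length(dim(values)) != 4L || dim(values)[4] != length(classes))
    stop_invalid("values must be (t, y, x, class) matching classes")
  if (any(values < 0 | values > 1))
    stop_invalid("probabilities must lie in [0, 1]")
  structure(list(values = values, classes = classes,
                 coverage = coverage %||% array(1L, dim(values)[1:3])),
            class = "epi_probability_map")
}

#' @export
print.epi_probability_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<epi_probability_map> %dx%dx%d (t,y,x), classes: %s\n",
              d[1], d[2], d[3], paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Classify a whole movie into an event probability map
#'
#' Every sliding window is classified in batches; for each non-"none" class
#' the window's probability is allocated uniformly into an
#' `allocation_patch` (5 frames x 22 x 22 px by default) centred on the
#' window centre, and each voxel's final value is the mean over all windows
#' whose patches cover it. With several networks the per-network maps are
#' averaged voxel-wise. The patch spans `[c-11, c+11)` spatially and
#' `[c-2, c+3)` temporally, clipped at the movie border.
#'
#' @param nets list of trained `epi_network`s with identical specs.
#' @param mov a reference-scale [movie()].
#' @param config an [run_config()].
#' @return an `epi_probability_map` over the movie, one channel per event
#'   class (the "none" class gets no map).
#' @export
classify_movie <- function(nets, mov, config = run_config()) {
  if (length(nets) < 1L) stop_invalid("need at least one network")
  specs <- lapply(nets, function(n) unclass(n$spec))
  if (length(nets) > 1L && !all(vapply(specs[-1], identical, TRUE, specs[[1]])))
    stop_invalid("all networks must share the same spec")
  cls_all <- nets[[1]]$classes
  if (length(nets) > 1L &&
      !all(vapply(nets[-1], function(n) identical(n$classes, cls_all), TRUE)))
    stop_invalid("all networks must share the same class ordering")
  ws <- config$window_shape
  if (!all(ws == nets[[1]]$spec$window_shape))
    stop_invalid("config window_shape does not match the network spec")
  d <- dim(mov$frames)
  origins <- enumerate_windows(d, ws, config$spatial_stride,
                               config$temporal_stride)
  event_cls <- setdiff(cls_all, "none")
  maps <- lapply(nets, function(net) {
    assemble_probability_map(net, mov, origins, config, event_cls)
  })
  if (length(maps) == 1L) maps[[1]] else ensemble_maps(maps)
}

assemble_probability_map <- function(net, mov, origins, config, event_cls) {
  d <- dim(mov$frames)
  ws <- config$window_shape
  ap <- config$allocation_patch
  nE <- length(event_cls)
  acc <- array(0, c(d, nE))
  cnt <- array(0L, d)
  # window centres: origin + half window (centre frame index T%/%2)
  cts <- origins$t + ws[1] %/% 2L
  cys <- origins$y + ws[2] %/% 2L
  cxs <- origins$x + ws[3] %/% 2L
  # patch half-extents: [c - e, c + (ap - e)) with e = ap %/% 2
  et <- ap[1] %/% 2L; ey <- ap[2] %/% 2L; ex <- ap[3] %/% 2L
  cls_idx <- match(event_cls, net$classes)
  # batched per-window classification (windows are standardised as wholes,
  # so per-frame encodings cannot be shared between overlapping windows)
  P <- matrix(0, nrow(origins), net$spec$n_classes)
  bs <- max(32L, config$batch_size)
  i <- 1L
  while (i <= nrow(origins)) {
    j <- min(i + bs - 1L, nrow(origins))
    vox <- lapply(i:j, function(k)
      mov$frames[origins$t[k] + seq_len(ws[1]),
                 origins$y[k] + seq_len(ws[2]),
                 origins$x[k] + seq_len(ws[3]), drop = FALSE])
    P[i:j, ] <- predict_windows(net, vox, batch_size = bs)
    i <- j + 1L
  }
  for (w in seq_len(nrow(origins))) {
    # patches of edge windows are extended to the movie border so that
    # every voxel is covered by at least one window
    t_lo <- if (origins$t[w] == 0L) 1L else max(1L, cts[w] - et + 1L)
    t_hi <- if (origins$t[w] == d[1] - ws[1]) d[1] else min(d[1], cts[w] + (ap[1] - et))
    y_lo <- if (origins$y[w] == 0L) 1L else max(1L, cys[w] - ey + 1L)
    y_hi <- if (origins$y[w] == d[2] - ws[2]) d[2] else min(d[2], cys[w] + (ap[2] - ey))
    x_lo <- if (origins$x[w] == 0L) 1L else max(1L, cxs[w] - ex + 1L)
    x_hi <- if (origins$x[w] == d[3] - ws[3]) d[3] else min(d[3], cxs[w] + (ap[3] - ex))
    tr <- t_lo:t_hi; yr <- y_lo:y_hi; xr <- x_lo:x_hi
    for (e in seq_len(nE))
      acc[tr, yr, xr, e] <- acc[tr, yr, xr, e] + P[w, cls_idx[e]]
    cnt[tr, yr, xr] <- cnt[tr, yr, xr] + 1L
  }
  vals <- array(0, c(d, nE))
  nz <- cnt > 0L
  for (e in seq_len(nE)) {
    v <- acc[, , , e]
    v[nz] <- v[nz] / cnt[nz]
    vals[, , , e] <- v
  }
  probability_map(vals, event_cls, coverage = cnt)
}

#' Average probability maps voxel-wise
#'
#' Used for two-network ensembling: stochastic false positives of one
#' network are damped by the other.
#'
#' @param maps list of `epi_probability_map` with identical shapes and
#'   classes.
#' @return the voxel-wise mean `epi_probability_map`.
#' @export
ensemble_maps <- function(maps) {
  if (length(maps) < 1L) stop_invalid("no maps to ensemble")
  d0 <- dim(maps[[1]]$values)
  for (m in maps[-1]) {
    if (!identical(dim(m$values), d0) ||
        !identical(m$classes, maps[[1]]$classes))
      stop_invalid("probability maps have mismatched shapes or classes")
  }
  vals <- Reduce(`+`, lapply(maps, function(m) m$values)) / length(maps)
  cov <- Reduce(pmin, lapply(maps, function(m) m$coverage))
  probability_map(vals, maps[[1]]$classes, coverage = cov)
}

#' Rescale a probability map to another movie shape
#'
#' Nearest-frame temporal resampling and bilinear spatial resampling, used
#' to export maps in the original movie geometry.
#'
#' @param pmap an `epi_probability_map` at reference scale.
#' @param shape_out integer (T, Y, X) of the target movie.
#' @return an `epi_probability_map` with the requested shape.
#' @export
rescale_probability_map <- function(pmap, shape_out) {
  d <- dim(pmap$values)[1:3]
  nE <- length(pmap$classes)
  out <- array(0, c(shape_out, nE))
  tsrc <- pmin(d[1], pmax(1L, round_half_away(seq_len(shape_out[1]) * d[1] /
                                                shape_out[1])))
  for (e in seq_len(nE)) {
    for (i in seq_len(shape_out[1])) {
      fr <- pmap$values[tsrc[i], , , e]
      out[i, , , e] <- if (all(dim(fr) == shape_out[2:3])) fr
                       else pmin(pmax(resize_bilinear(fr, shape_out[2],
                                                      shape_out[3]), 0), 1)
    }
  }
  probability_map(out, pmap$classes)
}
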
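# Training-window generation: extraction of classifier windows around
# annotated events, random no-event controls, class balancing, augmentation,
# and the temporal movie-doubling augmentation for high-frame-rate movies.

#' Extract one classifier window from a reference-scale movie
#'
#' The window spans frames `[t-5, t+5)` — five frames before the event frame,
#' the event frame itself and four after, so the event-defining dynamics
#' (progressive apical constriction) precede the window's end. Spatially the
#' crop is centred at (x, y) with the centre pixel at index (22, 22) of a
#' 45x45 crop. Voxels outside the movie are zero-padded, so events at the
#' movie borders and at its first/last frames remain extractable.
#'
#' @param mov reference-scale [movie()].
#' @param x,y,t 0-based event centre.
#' @param window_shape integer (T, H, W).
#' @param label event class attached to the window.
#' @return an object of class `epi_window`: list(voxels (T, H, W) array,
#'   label, origin).
#' @export
extract_window <- function(mov, x, y, t, window_shape = c(10L, 45L, 45L),
                           label = "none") {
  d <- dim(mov$frames)
  x <- as.integer(round(x)); y <- as.integer(round(y)); t <- as.integer(round(t))
  if (x < 0 || x >= d[3] || y < 0 || y >= d[2] || t < 0 || t >= d[1])
    stop_invalid("window centre (", x, ",", y, ",", t, ") outside movie bounds")
  wt <- window_shape[1]; wh <- window_shape[2]; ww <- window_shape[3]
  ct <- wt %/% 2            # centre frame index within the window (5 for T=10)
  ch <- wh %/% 2; cw <- ww %/% 2
  t0 <- t - ct; y0 <- y - ch; x0 <- x - cw
  vox <- array(0, dim = c(wt, wh, ww))
  tsrc <- intersect(seq(t0, t0 + wt - 1L), 0:(d[1] - 1L))
  ysrc <- intersect(seq(y0, y0 + wh - 1L), 0:(d[2] - 1L))
  xsrc <- intersect(seq(x0, x0 + ww - 1L), 0:(d[3] - 1L))
  if (length(tsrc) > 0 && length(ysrc) > 0 && length(xsrc) > 0)
    vox[tsrc - t0 + 1L, ysrc - y0 + 1L, xsrc - x0 + 1L] <-
      mov$frames[tsrc + 1L, ysrc + 1L, xsrc + 1L]
  structure(list(voxels = vox, label = label, origin = c(x = x, y = y, t = t)),
            class = "epi_window")
}

#' Windows centred (with jitter) on annotated events
#'
#' One window per annotation, displaced by an independent uniform integer
#' jitter in `[-jitter, +jitter]` on each axis so that events are not always
#' perfectly centred. Jitter is kept well below the matching tolerances.
#'
#' @param mov reference-scale [movie()].
#' @param events an [event_set()] in the same coordinates.
#' @param jitter_space,jitter_time maximum absolute shift (px, frames).
#' @param window_shape integer (T, H, W).
#' @param relabel optional named character vector mapping annotation classes
#'   to window labels (e.g. `c(division = "none")` for a two-class
#'   extrusion-vs-rest classifier).
#' @return list of `epi_window`.
#' @export
sample_event_windows <- function(mov, events, jitter_space = 5L,
                                 jitter_time = 1L,
                                 window_shape = c(10L, 45L, 45L),
                                 relabel = NULL) {
  if (jitter_space < 0 || jitter_time < 0)
    stop_invalid("jitter bounds must be >= 0")
  d <- dim(mov$frames)
  lapply(seq_len(nrow(events)), function(i) {
    jx <- sample.int(2L * jitter_space + 1L, 1L) - jitter_space - 1L
    jy <- sample.int(2L * jitter_space + 1L, 1L) - jitter_space - 1L
    jt <- sample.int(2L * jitter_time + 1L, 1L) - jitter_time - 1L
    cx <- min(max(events$x[i] + jx, 0L), d[3] - 1L)
    cy <- min(max(events$y[i] + jy, 0L), d[2] - 1L)
    ct <- min(max(events$t[i] + jt, 0L), d[1] - 1L)
    lab <- events$class[i]
    if (!is.null(relabel) && lab %in% names(relabel)) lab <- relabel[[lab]]
    extract_window(mov, cx, cy, ct, window_shape, label = lab)
  })
}

window_contains <- function(cx, cy, ct, window_shape, ex, ey, et) {
  wt <- window_shape[1]; wh <- window_shape[2]; ww <- window_shape[3]
  any(et >= ct - wt %/% 2 & et < ct - wt %/% 2 + wt &
      ey >= cy - wh %/% 2 & ey < cy - wh %/% 2 + wh &
      ex >= cx - ww %/% 2 & ex < cx - ww %/% 2 + ww)
}

#' Random no-event control windows
#'
#' Control positions are drawn uniformly over the window centres whose
#' window lies fully inside the movie — the same population the sliding
#' windows of whole-movie inference are drawn from, so the "none" class is
#' not separable from event windows by border padding alone — and rejected
#' whenever any annotation of any class falls inside the window's full
#' spatiotemporal extent (the strictest reading of "no event in the
#' window").
#'
#' @param mov reference-scale [movie()].
#' @param events annotations to avoid.
#' @param n number of control windows.
#' @param window_shape integer (T, H, W).
#' @param max_attempts rejection-sampling budget.
#' @return list of `epi_window` labelled `"none"`.
#' @export
sample_control_windows <- function(mov, events, n,
                                   window_shape = c(10L, 45L, 45L),
                                   max_attempts = 200L * n) {
  d <- dim(mov$frames)
  if (d[1] < window_shape[1] || d[2] < window_shape[2] ||
      d[3] < window_shape[3])
    stop_invalid("movie smaller than the window")
  # valid centre ranges for a fully inside window (0-based, inclusive)
  lo <- window_shape %/% 2L
  hi <- c(d[1] - (window_shape[1] - lo[1] - 1L),
          d[2] - (window_shape[2] - lo[2] - 1L),
          d[3] - (window_shape[3] - lo[3] - 1L)) - 1L
  out <- vector("list", n)
  got <- 0L; tries <- 0L
  while (got < n) {
    if (tries >= max_attempts)
      stop_invalid("could not place ", n, " control windows in ", max_attempts,
                   " attempts; annotations too dense")
    tries <- tries + 1L
    ct <- lo[1] + sample.int(hi[1] - lo[1] + 1L, 1L) - 1L
    cy <- lo[2] + sample.int(hi[2] - lo[2] + 1L, 1L) - 1L
    cx <- lo[3] + sample.int(hi[3] - lo[3] + 1L, 1L) - 1L
    if (nrow(events) > 0 &&
        window_contains(cx, cy, ct, window_shape, events$x, events$y, events$t))
      next
    got <- got + 1L
    out[[got]] <- extract_window(mov, cx, cy, ct, window_shape, label = "none")
  }
  out
}

#' Equalise per-class window counts
#'
#' Every class present is downsampled uniformly at random to the minimum
#' class count; the relative order of the surviving windows is preserved.
#'
#' @param windows list of `epi_window`.
#' @return list of `epi_window` with equal per-class counts.
#' @export
balance_classes <- function(windows) {
  labels <- vapply(windows, function(w) w$label, "")
  counts <- table(labels)
  m <- min(counts)
  keep <- logical(length(windows))
  for (cl in names(counts)) {
    idx <- which(labels == cl)
    keep[if (length(idx) > m) sort(sample(idx, m)) else idx] <- TRUE
  }
  windows[keep]
}

#' Randomly augment a training window
#'
#' Applies the training-time corruptions: a small spatiotemporal shift of
#' the crop content, additive Gaussian noise, a white or black square patch,
#' and a multiplicative illumination change applied either to all frames or
#' to a single frame. Shape and label are preserved. `strength = 0` is the
#' identity.
#'
#' @param window an `epi_window`.
#' @param strength overall augmentation strength in \[0, 1\]; scales the
#'   shift range, noise sigma, patch size and illumination amplitude.
#' @param ops which corruptions to apply (default: all).
#' @param noise_sd explicit Gaussian noise sd, overriding the
#'   strength-derived default (which is 5% of the window's dynamic range at
#'   full strength).
#' @return an augmented `epi_window`.
#' @export
augment_window <- function(window, strength = 0.5,
                           ops = c("shift", "noise", "patch", "illumination"),
                           noise_sd = NULL) {
  if (strength <= 0) return(window)
  v <- window$voxels
  d <- dim(v)
  rng_int <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L
  if ("shift" %in% ops) {
    # sub-window shift (content moved, zero fill)
    ms <- max(0L, as.integer(round(3 * strength)))
    mt <- if (strength >= 0.5) 1L else 0L
    sx <- rng_int(-ms, ms); sy <- rng_int(-ms, ms); st <- rng_int(-mt, mt)
    if (sx != 0 || sy != 0 || st != 0) {
      out <- array(0, d)
      tdst <- intersect(seq_len(d[1]) + st, seq_len(d[1]))
      ydst <- intersect(seq_len(d[2]) + sy, seq_len(d[2]))
      xdst <- intersect(seq_len(d[3]) + sx, seq_len(d[3]))
      out[tdst, ydst, xdst] <- v[tdst - st, ydst - sy, xdst - sx]
      v <- out
    }
  }
  if ("noise" %in% ops) {
    # additive Gaussian noise, sigma relative to the window's dynamic range
    rng <- diff(range(v)); if (rng == 0) rng <- 1
    sigma <- noise_sd %||% (0.05 * strength * rng)
    v <- v + array(stats::rnorm(length(v), 0, sigma), d)
  }
  if ("patch" %in% ops && stats::runif(1) < strength) {
    # white or black square on every frame
    side <- max(2L, as.integer(round(6 * strength)))
    py <- rng_int(1L, d[2] - side); px <- rng_int(1L, d[3] - side)
    val <- if (stats::runif(1) < 0.5) max(v) else min(v)
    v[, py:(py + side - 1L), px:(px + side - 1L)] <- val
  }
  if ("illumination" %in% ops) {
    # illumination change on all frames or a single frame
    gain <- 1 + stats::runif(1, -0.3, 0.3) * strength
    if (stats::runif(1) < 0.5) v <- v * gain
    else { fr <- rng_int(1L, d[1]); v[fr, , ] <- v[fr, , ] * gain }
  }
  structure(list(voxels = v, label = window$label, origin = window$origin),
            class = "epi_window")
}

#' Double a high-frame-rate movie by temporal decimation
#'
#' Splits a movie into its even frames (0, 2, 4, ...) and its odd frames
#' (1, 3, 5, ...), each with a doubled frame interval. Used to balance the
#' under-representation of movies acquired at high temporal resolution.
#'
#' @param mov an [movie()] with at least 4 frames.
#' @return list of two `epi_movie`.
#' @export
augment_movie_temporal <- function(mov) {
  d <- dim(mov$frames)
  if (d[1] < 4L) stop_invalid("need at least 4 frames to split temporally")
  even <- seq(1L, d[1], by = 2L)
  odd <- seq(2L, d[1], by = 2L)
  list(movie(mov$frames[even, , , drop = FALSE], mov$pixel_size,
             2 * mov$frame_interval),
       movie(mov$frames[odd, , , drop = FALSE], mov$pixel_size,
             2 * mov$frame_interval))
}

#' Assemble a labelled training set with a train/validation split
#'
#' @param windows list of `epi_window`.
#' @param validation_fraction fraction of windows held out for validation.
#' @param balance equalise per-class counts first.
#' @return list with elements `windows` and logical `validation` flag vector.
#' @export
training_set <- function(windows, validation_fraction = 0.25, balance = TRUE) {
  if (balance) windows <- balance_classes(windows)
  n <- length(windows)
  nval <- max(1L, as.integer(round(n * validation_fraction)))
  val <- logical(n)
  val[sample.int(n, nval)] <- TRUE
  list(windows = windows, validation = val)
}

#' Persist windows as TIFF stacks in class-named folders
#'
#' Mirrors the conventional on-disk training-set layout: one folder per
#' class, one TIFF stack per window, plus an `index.csv` manifest.
#'
#' @param windows list of `epi_window`.
#' @param dir output directory.
#' @param scale intensity divisor applied before writing (windows are stored
#'   on the \[0, 1\] TIFF scale).
#' @return path of the manifest, invisibly.
#' @export
write_window_set <- function(windows, dir, scale = 1) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- vector("list", length(windows))
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    cdir <- file.path(dir, w$label)
    if (!dir.exists(cdir)) dir.create(cdir)
    f <- file.path(cdir, sprintf("window_%05d.tif", i))
    v <- pmin(pmax(w$voxels / scale, 0), 1)
    pages <- lapply(seq_len(dim(v)[1]), function(k) v[k, , ])
    tiff::writeTIFF(pages, f, bits.per.sample = 16L, compression = "none")
    rows[[i]] <- data.frame(file = f, label = w$label, x = w$origin["x"],
                            y = w$origin["y"], t = w$origin["t"])
  }
  idx <- do.call(rbind, rows)
  manifest <- file.path(dir, "index.csv")
  utils::write.csv(idx, manifest, row.names = FALSE)
  invisible(manifest)
}
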
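# Synthetic junction-labelled epithelium movies with planted, exactly
# ground-truthed cellular events. Cell geometry is a scaled (power-diagram
# style) Voronoi tessellation of drifting seed points: bright junctions are
# the tessellation boundaries, an extrusion is a cell whose scale shrinks to
# zero (its neighbours converge into a rosette that seals), a division
# replaces one seed by two separating daughters (the new boundary is the
# furrow), an SOP is a persistently small-scale cell, and a "confuser" is a
# transient constriction that relaxes — visible, but not an event.

#' Synthetic-movie configuration
#'
#' Defaults emulate the reference scale: ~25 px cell diameter, extrusions
#' spanning 4-5 frames, divisions 2-3 frames, bright junctions over a dark
#' interior with Gaussian sensor noise. Intensities are on \[0, 1\].
#'
#' @param image_size integer (Y, X) pixels.
#' @param n_frames number of frames.
#' @param n_cells number of cells; the default packs cells of
#'   `cell_diameter` into the field.
#' @param cell_diameter mean cell diameter, px.
#' @param junction_intensity,background junction / interior intensity.
#' @param junction_sigma junction line width (Gaussian), px.
#' @param noise_sd additive Gaussian noise sd.
#' @param n_extrusions,n_divisions,n_sops,n_confusers planted event counts
#'   (confusers are transient constrictions that relax: rendered, never
#'   annotated).
#' @param extrusion_duration,division_duration candidate durations (frames)
#'   sampled per event.
#' @param drift_sd per-frame seed drift sd, px (slow junction fluctuation).
#' @param min_separation_px,min_separation_frames minimum spatiotemporal
#'   separation between planted events (one window by default).
#' @param seed RNG seed.
#' @return an `epi_synth_config`.
#' @export
synth_config <- function(image_size = c(256L, 256L), n_frames = 60L,
                         n_cells = NULL, cell_diameter = 25,
                         junction_intensity = 0.65, background = 0.12,
                         junction_sigma = 0.8, noise_sd = 0.03,
                         n_extrusions = 12L, n_divisions = 8L, n_sops = 0L,
                         n_confusers = 0L,
                         extrusion_duration = c(4L, 5L),
                         division_duration = c(2L, 3L),
                         drift_sd = 0.12,
                         min_separation_px = 45,
                         min_separation_frames = 10,
                         seed = 1L) {
  if (is.null(n_cells))
    n_cells <- max(4L, round(prod(image_size) / (pi * (cell_diameter / 2)^2)))
  cfg <- structure(list(image_size = as.integer(image_size),
                        n_frames = as.integer(n_frames),
                        n_cells = as.integer(n_cells),
                        cell_diameter = cell_diameter,
                        junction_intensity = junction_intensity,
                        background = background,
                        junction_sigma = junction_sigma,
                        noise_sd = noise_sd,
                        n_extrusions = as.integer(n_extrusions),
                        n_divisions = as.integer(n_divisions),
                        n_sops = as.integer(n_sops),
                        n_confusers = as.integer(n_confusers),
                        extrusion_duration = as.integer(extrusion_duration),
                        division_duration = as.integer(division_duration),
                        drift_sd = drift_sd,
                        min_separation_px = min_separation_px,
                        min_separation_frames = min_separation_frames,
                        seed = as.integer(seed)),
                   class = "epi_synth_config")
  if (cfg$n_cells > prod(cfg$image_size) / 16)
    stop_invalid("n_cells incompatible with the field size")
  if (cfg$n_frames < 12L)
    stop_invalid("need at least 12 frames to fit planted events")
  cfg
}

# base tissue geometry: Lloyd-relaxed seeds plus a slow per-frame drift
# track; no events yet
synth_geometry <- function(config) {
  set.seed(config$seed)
  ny <- config$image_size[1]; nx <- config$image_size[2]
  n <- config$n_cells
  seeds <- cbind(stats::runif(n, 1, ny), stats::runif(n, 1, nx))
  # Lloyd relaxation on a coarse grid for near-centroidal cells
  gs <- 2L
  gy <- seq(1, ny, by = gs); gx <- seq(1, nx, by = gs)
  G <- cbind(rep(gy, times = length(gx)), rep(gx, each = length(gy)))
  for (it in 1:4) {
    D <- outer(G[, 1], seeds[, 1], "-")^2 + outer(G[, 2], seeds[, 2], "-")^2
    lab <- max.col(-D, ties.method = "first")
    seeds <- cbind(tapply(G[, 1], factor(lab, levels = 1:n), mean),
                   tapply(G[, 2], factor(lab, levels = 1:n), mean))
    miss <- which(is.na(seeds[, 1]))
    if (length(miss) > 0)
      seeds[miss, ] <- cbind(stats::runif(length(miss), 1, ny),
                             stats::runif(length(miss), 1, nx))
  }
  # smooth random drift of every seed (junction fluctuation)
  drift <- array(0, c(config$n_frames, n, 2))
  if (config$n_frames > 1) {
    for (ax in 1:2) {
      steps <- matrix(stats::rnorm((config$n_frames - 1L) * n, 0,
                                   config$drift_sd), config$n_frames - 1L, n)
      drift[2:config$n_frames, , ax] <- apply(steps, 2L, cumsum)
    }
  }
  list(config = config, seeds = seeds, drift = drift,
       n_frames = config$n_frames, image_size = config$image_size)
}

# event schedule: which cells do what and when; daughters of divisions are
# appended as extra seeds
schedule_events <- function(geom, config) {
  set.seed(config$seed + 7777L)
  n <- nrow(geom$seeds)
  nf <- config$n_frames
  margin <- 23
  ny <- config$image_size[1]; nx <- config$image_size[2]
  eligible <- which(geom$seeds[, 1] > margin & geom$seeds[, 1] < ny - margin &
                    geom$seeds[, 2] > margin & geom$seeds[, 2] < nx - margin)
  wanted <- c(rep("extrusion", config$n_extrusions),
              rep("division", config$n_divisions),
              rep("sop", config$n_sops),
              rep("confuser", config$n_confusers))
  placed <- data.frame(cell = integer(0), type = character(0), t0 = integer(0),
                       dur = integer(0))
  pool <- sample(eligible)
  for (w in wanted) {
    t_lo <- 8L; t_hi <- nf - 6L
    ok_cell <- NA_integer_; ok_t <- NA_integer_
    for (cand in pool) {
      if (cand %in% placed$cell) next
      for (tt in sample(seq(t_lo, t_hi))) {
        if (nrow(placed) > 0) {
          dsp <- sqrt((geom$seeds[placed$cell, 1] - geom$seeds[cand, 1])^2 +
                      (geom$seeds[placed$cell, 2] - geom$seeds[cand, 2])^2)
          dtm <- abs(placed$t0 - tt)
          if (any(dsp < config$min_separation_px &
                  dtm < config$min_separation_frames)) next
        }
        ok_cell <- cand; ok_t <- tt; break
      }
      if (!is.na(ok_cell)) break
    }
    if (is.na(ok_cell))
      stop_invalid("cannot place all requested events under the separation ",
                   "constraints; reduce event counts or enlarge the field")
    dur <- switch(w,
                  extrusion = sample(config$extrusion_duration, 1L),
                  division = sample(config$division_duration, 1L),
                  sop = 3L,
                  confuser = 3L)
    placed <- rbind(placed, data.frame(cell = ok_cell, type = w, t0 = ok_t,
                                       dur = dur))
  }
  placed
}

# per-frame seed positions and scale factors implied by the schedule
build_dynamics <- function(geom, schedule) {
  config <- geom$config
  nf <- config$n_frames
  n0 <- nrow(geom$seeds)
  n_div <- sum(schedule$type == "division")
  n <- n0 + n_div
  pos <- array(0, c(nf, n, 2))
  scl <- matrix(1, nf, n)
  for (i in seq_len(n0))
    pos[, i, ] <- geom$drift[, i, ] + matrix(geom$seeds[i, ], nf, 2, byrow = TRUE)
  if (n_div > 0) scl[, (n0 + 1):n] <- 0  # daughters inactive until division
  div_idx <- 0L
  for (r in seq_len(nrow(schedule))) {
    i <- schedule$cell[r]; t0 <- schedule$t0[r]; dur <- schedule$dur[r]
    if (schedule$type[r] == "extrusion") {
      for (t in seq_len(nf)) {
        tt <- t - 1L
        scl[t, i] <- if (tt < t0 - dur) 1
                     else if (tt < t0) (t0 - tt) / dur
                     else 0
      }
    } else if (schedule$type[r] == "sop") {
      for (t in seq_len(nf)) {
        tt <- t - 1L
        scl[t, i] <- if (tt < t0) 1
                     else max(0.3, 1 - 0.7 * (tt - t0 + 1) / dur)
      }
    } else if (schedule$type[r] == "confuser") {
      # recurring transient constriction: shrink over dur frames, relax over
      # dur frames, repeat with a fixed period
      period <- 4L * dur
      for (t in seq_len(nf)) {
        ph <- (t - 1L - t0) %% period
        if (t - 1L < t0) { scl[t, i] <- 1; next }
        scl[t, i] <- if (ph < dur) 1 - 0.65 * (ph + 1) / dur
                     else if (ph < 2L * dur) 0.35 + 0.65 * (ph - dur + 1) / dur
                     else 1
      }
    } else if (schedule$type[r] == "division") {
      div_idx <- div_idx + 1L
      j <- n0 + div_idx
      ang <- stats::runif(1, 0, pi)
      u <- c(sin(ang), cos(ang))
      pos[, j, ] <- pos[, i, ]   # daughter rides the mother until t0
      for (t in seq_len(nf)) {
        tt <- t - 1L
        if (tt < t0) next
        delta <- min(1, (tt - t0 + 1) / dur) * config$cell_diameter / 4
        pos[t, i, ] <- pos[t, i, ] - u * delta
        pos[t, j, ] <- pos[t, j, ] + u * delta
        scl[t, j] <- min(1, 0.4 + 0.6 * (tt - t0 + 1) / dur)
        scl[t, i] <- min(scl[t, i], 0.4 + 0.6 * min(1, (tt - t0 + 1) / dur))
      }
    }
  }
  list(pos = pos, scl = scl)
}

# label image (ny x nx, integer cell ids) for one frame
synth_labels_frame <- function(dyn, frame, image_size) {
  ny <- image_size[1]; nx <- image_size[2]
  act <- which(dyn$scl[frame, ] > 1e-3)
  py <- rep(seq_len(ny), times = nx)
  px <- rep(seq_len(nx), each = ny)
  D <- matrix(0, ny * nx, length(act))
  for (k in seq_along(act)) {
    i <- act[k]
    D[, k] <- ((py - dyn$pos[frame, i, 1])^2 +
               (px - dyn$pos[frame, i, 2])^2) / dyn$scl[frame, i]
  }
  lab <- act[max.col(-D, ties.method = "first")]
  matrix(lab, ny, nx)
}

#' Generate a synthetic junction-labelled epithelium movie (no events)
#'
#' Renders a Lloyd-relaxed Voronoi cell mesh as a bright junction skeleton
#' over a dark interior, with slow random junction fluctuations across
#' frames. Reproducible from the config seed.
#'
#' @param config an [synth_config()].
#' @return list with `movie` (an [movie()] at reference calibration) and
#'   `geometry` (opaque; pass to [plant_events()]).
#' @export
generate_epithelium <- function(config = synth_config()) {
  geom <- synth_geometry(config)
  empty <- data.frame(cell = integer(0), type = character(0),
                      t0 = integer(0), dur = integer(0))
  mov <- render_movie(geom, empty)
  list(movie = mov, geometry = geom)
}

render_movie <- function(geom, schedule) {
  config <- geom$config
  dyn <- build_dynamics(geom, schedule)
  nf <- config$n_frames
  frames <- array(0, c(nf, config$image_size[1], config$image_size[2]))
  for (t in seq_len(nf)) {
    lab <- synth_labels_frame(dyn, t, config$image_size)
    frames[t, , ] <- render_frame_clean(lab, config)
  }
  # reproducible sensor noise, independent of the schedule details
  set.seed(config$seed + 31337L)
  frames <- frames + array(stats::rnorm(length(frames), 0, config$noise_sd),
                           dim(frames))
  movie(pmin(pmax(frames, 0), 1), pixel_size = 0.275, frame_interval = 5)
}

# junction rendering: blurred boundary mask scaled so straight lines peak
# near the junction intensity
render_frame_clean <- function(lab, config) {
  ny <- nrow(lab); nx <- ncol(lab)
  edge <- matrix(FALSE, ny, nx)
  edge[-ny, ] <- edge[-ny, ] | (lab[-ny, ] != lab[-1, ])
  edge[, -nx] <- edge[, -nx] | (lab[, -nx] != lab[, -1])
  prof <- gauss_smooth3(array(edge * 1, c(1L, ny, nx)), sigma_t = 0,
                        sigma_xy = config$junction_sigma)[1, , ]
  r <- ceiling(3 * config$junction_sigma)
  k <- exp(-((-r):r)^2 / (2 * config$junction_sigma^2))
  k <- k / sum(k)
  line_peak <- max(k)          # peak response of the blur to a 1 px line
  prof <- pmin(1, prof / line_peak)
  config$background + (config$junction_intensity - config$background) * prof
}

#' Plant ground-truthed cellular events into a synthetic epithelium
#'
#' Selected cells are animated: an extrusion's apical area shrinks
#' monotonically to zero with its neighbours' junctions converging to the
#' closure point; a division splits a cell in two with a new furrow
#' junction; an SOP shrinks once and persists small; a confuser constricts
#' transiently and relaxes (and recurs), and is *not* annotated. Ground
#' truth is exact by construction: one annotation per planted event
#' (extrusions at the closure point/frame, divisions at furrow onset, SOPs
#' at the small-cell centre) and nothing else.
#'
#' @param mov the movie from [generate_epithelium()] (unused for rendering —
#'   the geometry is re-rendered with the event dynamics — but kept so the
#'   call site reads naturally).
#' @param geometry geometry from [generate_epithelium()].
#' @param config the same [synth_config()] (event counts are taken from it).
#' @return list with `movie`, `events` (an [event_set()]), and `schedule`
#'   (data frame of planted cells/types/times, confusers included).
#' @export
plant_events <- function(mov, geometry, config = geometry$config) {
  schedule <- schedule_events(geometry, config)
  out <- render_movie(geometry, schedule)
  ann <- schedule[schedule$type != "confuser", , drop = FALSE]
  if (nrow(ann) > 0) {
    dyn <- build_dynamics(geometry, schedule)
    xs <- ys <- ts <- numeric(nrow(ann)); cls <- character(nrow(ann))
    for (r in seq_len(nrow(ann))) {
      i <- ann$cell[r]
      t_annot <- switch(ann$type[r],
                        extrusion = ann$t0[r],          # closure frame
                        division = ann$t0[r],           # furrow onset
                        sop = min(config$n_frames - 1L, ann$t0[r] + ann$dur[r]))
      p <- dyn$pos[t_annot + 1L, i, ]
      ys[r] <- round(p[1]) - 1; xs[r] <- round(p[2]) - 1; ts[r] <- t_annot
      cls[r] <- ann$type[r]
    }
    d <- dim(out$frames)
    events <- event_set(pmin(pmax(xs, 0), d[3] - 1),
                        pmin(pmax(ys, 0), d[2] - 1), ts, cls,
                        pixel_size = 0.275, frame_interval = 5)
  } else {
    events <- event_set(pixel_size = 0.275, frame_interval = 5)
  }
  list(movie = out, events = events, schedule = schedule)
}

#' Generate a set of independent synthetic movies with ground truth
#'
#' @param config an [synth_config()]; movie i uses `config$seed + i - 1`.
#' @param n_movies number of movies.
#' @param dir optional output directory: movies are written as TIFF, ground
#'   truth as ImageJ ROI zip + CSV, plus a `manifest.csv`.
#' @return list of `list(movie, events, schedule)`; with `dir`, the manifest
#'   path is attached as attribute `manifest`.
#' @export
generate_dataset <- function(config = synth_config(), n_movies = 1L,
                             dir = NULL) {
  out <- vector("list", n_movies)
  rows <- vector("list", n_movies)
  for (i in seq_len(n_movies)) {
    cfg_i <- config
    cfg_i$seed <- config$seed + i - 1L
    geom <- synth_geometry(cfg_i)
    out[[i]] <- plant_events(NULL, geom, cfg_i)
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      mp <- file.path(dir, sprintf("synthetic_movie_%02d.tif", i))
      rp <- file.path(dir, sprintf("synthetic_movie_%02d_rois.zip", i))
      cp <- file.path(dir, sprintf("synthetic_movie_%02d_events.csv", i))
      write_tiff_movie(out[[i]]$movie, mp)
      write_imagej_rois(out[[i]]$events, rp)
      write_events_csv(out[[i]]$events, cp)
      rows[[i]] <- data.frame(movie = mp, rois = rp, csv = cp,
                              seed = cfg_i$seed,
                              n_events = nrow(out[[i]]$events))
    } else {
      rows[[i]] <- data.frame(movie = sprintf("movie_%02d", i), rois = NA,
                              csv = NA, seed = cfg_i$seed,
                              n_events = nrow(out[[i]]$events))
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir)) {
    mf <- file.path(dir, "manifest.csv")
    utils::write.csv(manifest, mf, row.names = FALSE)
    attr(out, "manifest") <- mf
  }
  attr(out, "manifest_table") <- manifest
  out
}

# per-cell apical area trajectories measured from the rendered geometry
# (label-image pixel counts); used to verify event discriminability
synth_area_trajectories <- function(geometry, schedule, cells) {
  dyn <- build_dynamics(geometry, schedule)
  nf <- geometry$config$n_frames
  areas <- matrix(0, nf, length(cells))
  for (t in seq_len(nf)) {
    lab <- synth_labels_frame(dyn, t, geometry$config$image_size)
    tab <- table(lab)
    for (k in seq_along(cells))
      areas[t, k] <- if (as.character(cells[k]) %in% names(tab))
        tab[[as.character(cells[k])]] else 0
  }
  areas
}
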
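# Probability map -> discrete point events: thresholding, 26-connected
# component extraction, minimum-volume filtering, watershed separation of
# merged blobs, centroid export.

#' Threshold a probability map into a binary detection mask
#'
#' A voxel is positive iff `round(p * 255) >= threshold`; the threshold is
#' exposed on the 0-255 display scale to match the published operating
#' point (180).
#'
#' @param pmap an `epi_probability_map`.
#' @param probability_threshold threshold on the 0-255 scale.
#' @param class which class channel to threshold.
#' @return logical 3D array (t, y, x).
#' @export
threshold_map <- function(pmap, probability_threshold = 180,
                          class = "extrusion") {
  if (probability_threshold < 0 || probability_threshold > 255)
    stop_invalid("probability_threshold must be in [0, 255]")
  e <- match(class, pmap$classes)
  if (is.na(e)) stop_invalid("map has no class '", class, "'")
  v <- pmap$values[, , , e, drop = FALSE]
  dim(v) <- dim(pmap$values)[1:3]
  m <- round_half_away(v * 255) >= probability_threshold
  dim(m) <- dim(pmap$values)[1:3]
  m
}

# 26-connected components of a 3D logical mask (compiled union-find);
# returns an integer label array (0 = background)
label_components_3d <- function(mask) {
  cpp_label3d_26(mask, dim(mask))
}

#' Extract connected high-probability components
#'
#' Labels the positive voxels of a detection mask in 3D (26-connectivity:
#' an extruding blob drifts slightly between frames, so face-only
#' connectivity would fragment it) and discards components smaller than the
#' volume threshold (800 reference-scale voxels by default: extrusions last
#' 20-30 min and cover at least a cell diameter, false positives are
#' smaller and shorter).
#'
#' @param mask logical 3D array (t, y, x).
#' @param volume_threshold minimum voxel count.
#' @param pmap optional `epi_probability_map` supplying peak probabilities.
#' @param class class recorded on the components.
#' @return list of components: each
#'   `list(voxels (n x 3 matrix, 1-based (t, y, x)), volume, centroid,
#'   peak_probability, class)`.
#' @export
extract_components <- function(mask, volume_threshold = 800, pmap = NULL,
                               class = "extrusion") {
  lab <- label_components_3d(mask)
  idx <- which(lab > 0L)
  if (length(idx) == 0L) return(list())
  d <- dim(mask)
  coords <- arrayInd(idx, d)
  labs <- lab[idx]
  vols <- tabulate(labs)
  keep <- which(vols >= volume_threshold)
  pv <- if (is.null(pmap)) NULL else {
    a <- pmap$values[, , , match(class, pmap$classes), drop = FALSE]
    dim(a) <- dim(pmap$values)[1:3]
    a
  }
  lapply(keep, function(l) {
    sel <- labs == l
    vox <- coords[sel, , drop = FALSE]
    colnames(vox) <- c("t", "y", "x")
    list(voxels = vox, volume = sum(sel),
         centroid = colMeans(vox),
         peak_probability = if (is.null(pv)) NA_real_ else max(pv[vox]),
         class = class)
  })
}

# greedy selection of seed voxels: regional maxima of the smoothed relief
# inside the component, suppressed (a) when within min_sep px (xy) AND
# min_sep_t frames of an already kept, higher seed, and (b) when lacking
# relative prominence: if the saddle connecting a seed to a stronger seed
# lies above min_prominence_ratio of the seed's own height, the seed is a
# noise shoulder of the same event, not a second event (a genuine second
# event keeps a deep dip between the two peaks). Maxima are found with
# vectorised shifted comparisons on the component's bounding box.
find_seeds <- function(vox, relief, min_sep = 12, min_sep_t = 4L,
                       min_prominence_ratio = 0.85, margin = 8L) {
  n <- nrow(vox)
  dr <- dim(relief)
  # bounding box of the component plus a margin of real relief, so that
  # maxima and saddle decisions do not depend on where the detection
  # threshold happened to cut the blob
  lo <- pmax(apply(vox, 2L, min) - margin, 1L)
  hi <- pmin(apply(vox, 2L, max) + margin, dr)
  dd <- hi - lo + 1L
  sub <- relief[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  dim(sub) <- dd
  subc <- cbind(vox[, 1] - lo[1] + 1L, vox[, 2] - lo[2] + 1L,
                vox[, 3] - lo[3] + 1L)
  vals <- relief[vox]
  # padded array so every 26-neighbour comparison is a plain shift
  pad <- array(-Inf, dd + 2L)
  pad[1L + seq_len(dd[1]), 1L + seq_len(dd[2]), 1L + seq_len(dd[3])] <- sub
  ismax <- array(TRUE, dd)
  for (ot in -1:1) for (oy in -1:1) for (ox in -1:1) {
    if (ot == 0 && oy == 0 && ox == 0) next
    nbv <- pad[1L + ot + seq_len(dd[1]), 1L + oy + seq_len(dd[2]),
               1L + ox + seq_len(dd[3]), drop = FALSE]
    ismax <- ismax & (sub >= nbv)
  }
  cand <- which(ismax[subc])
  if (length(cand) == 0L) return(integer(0))
  # the averaged map is piecewise constant over allocation patches, so a
  # voxel-wise ">= neighbours" test marks whole plateaus; reduce candidates
  # to one representative per connected cluster first
  cmask <- array(FALSE, dd)
  cmask[subc[cand, , drop = FALSE]] <- TRUE
  clab <- cpp_label3d_26(cmask, dim(cmask))
  cl <- clab[subc[cand, , drop = FALSE]]
  best_per <- vapply(split(cand, cl), function(ix) ix[which.max(vals[ix])], 0L)
  cand <- as.integer(best_per)
  cand <- cand[order(vals[cand], decreasing = TRUE)]
  if (length(cand) > 200L) cand <- cand[1:200]  # degenerate-map guard
  # keep only regional maxima of the relief: the connected level set
  # {relief >= v} through the candidate must contain nothing higher,
  # otherwise the "plateau" is a shoulder of a stronger peak (adjacent
  # allocation tiles create such shoulders routinely)
  eps <- 1e-12
  regional <- vapply(cand, function(i) {
    v <- vals[i]
    gl <- cpp_label3d_26(sub >= v - eps, dd)
    mine <- gl[subc[i, 1], subc[i, 2], subc[i, 3]]
    max(sub[gl == mine]) <= v + eps
  }, TRUE)
  cand <- cand[regional]
  if (length(cand) == 0L) return(integer(0))
  kept <- integer(0)
  for (i in cand) {
    if (length(kept) > 0) {
      dy <- vox[kept, 2] - vox[i, 2]
      dx <- vox[kept, 3] - vox[i, 3]
      dt <- abs(vox[kept, 1] - vox[i, 1])
      if (any(dy^2 + dx^2 < min_sep^2 & dt <= min_sep_t)) next
    }
    kept <- c(kept, i)
  }
  if (length(kept) <= 1L) return(kept)
  # prominence filter: scan descending level sets; the first level at which
  # a seed's region joins a stronger seed's region is its saddle
  ord <- kept[order(vals[kept], decreasing = TRUE)]
  resolved <- stats::setNames(rep(NA, length(ord)), ord)
  resolved[1L] <- TRUE                     # the global peak always survives
  levels <- sort(unique(stats::quantile(vals, seq(0, 1, length.out = 33),
                                        names = FALSE, type = 7)),
                 decreasing = TRUE)
  for (lv in levels) {
    if (!anyNA(resolved)) break
    gl <- cpp_label3d_26(sub >= lv, dd)
    reg <- gl[subc[ord, , drop = FALSE]]
    reg[vals[ord] < lv] <- 0L              # seed not yet above this level
    for (g in unique(reg[reg > 0L])) {
      members <- which(reg == g)
      if (length(members) < 2L) next
      # members are in descending value order; all but the first joining
      # here have their saddle at this level
      for (mi in members[-1L]) {
        if (!is.na(resolved[mi])) next
        resolved[mi] <- lv < min_prominence_ratio * vals[ord[mi]]
      }
    }
  }
  resolved[is.na(resolved)] <- TRUE        # never joined: isolated peak
  sort(ord[resolved])
}

#' Watershed separation of merged detection components
#'
#' Each component is re-partitioned by a seeded watershed on the inverted
#' probability relief: seeds are local maxima of the Gaussian-smoothed
#' probability (sigma 2 px, 1 frame) separated by at least half a cell
#' diameter (12 px) within four frames (about one event duration), and
#' voxels are flooded from the seeds in descending probability bands. Sub-components smaller than the volume threshold are
#' merged into their largest neighbour, so the voxel multiset is conserved.
#'
#' @param pmap the `epi_probability_map` used as relief.
#' @param components output of [extract_components()].
#' @param volume_threshold minimum voxel count for a split-off component.
#' @param n_bands number of descending flooding bands.
#' @return list of components in the same format, with merged blobs split.
#' @export
watershed_split <- function(pmap, components, volume_threshold = 800,
                            n_bands = 32L) {
  if (length(components) == 0L) return(components)
  cls <- components[[1]]$class
  pv <- pmap$values[, , , match(cls, pmap$classes), drop = FALSE]
  dim(pv) <- dim(pmap$values)[1:3]
  relief <- gauss_smooth3(pv, sigma_t = 1, sigma_xy = 2)
  out <- list()
  for (comp in components) {
    vox <- comp$voxels
    seeds <- find_seeds(vox, relief)
    if (length(seeds) <= 1L) { out <- c(out, list(comp)); next }
    assign <- if (comp$volume > 50L * max(volume_threshold, 1))
      nearest_seed_assign(vox, seeds)   # degenerate, movie-scale blob
    else flood_from_seeds(vox, relief[vox], seeds, n_bands)
    # merge undersized fragments into their largest touching neighbour
    assign <- merge_small_fragments(vox, assign, volume_threshold)
    for (l in sort(unique(assign))) {
      sel <- assign == l
      v <- vox[sel, , drop = FALSE]
      out <- c(out, list(list(voxels = v, volume = sum(sel),
                              centroid = colMeans(v),
                              peak_probability = max(pv[v]),
                              class = cls)))
    }
  }
  out
}

# priority flood restricted to the component's voxels: descending value
# bands, within each band repeated label propagation across the
# 26-neighbourhood until stable
flood_from_seeds <- function(vox, vals, seeds, n_bands) {
  n <- nrow(vox)
  # neighbour lists via a local dense sub-array
  lo <- apply(vox, 2L, min); hi <- apply(vox, 2L, max)
  dd <- hi - lo + 1L
  sub <- array(0L, dd)
  sub[cbind(vox[, 1] - lo[1] + 1L, vox[, 2] - lo[2] + 1L,
            vox[, 3] - lo[3] + 1L)] <- seq_len(n)
  assign <- integer(n)
  assign[seeds] <- seq_along(seeds)
  bands <- stats::quantile(vals, probs = seq(1, 0, length.out = n_bands + 1L),
                           names = FALSE, type = 7)
  offs <- as.matrix(expand.grid(dt = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  subc <- cbind(vox[, 1] - lo[1] + 1L, vox[, 2] - lo[2] + 1L,
                vox[, 3] - lo[3] + 1L)
  for (b in seq_len(n_bands)) {
    active <- vals >= bands[b + 1L]
    repeat {
      todo <- which(active & assign == 0L)
      if (length(todo) == 0L) break
      changed <- FALSE
      for (r in seq_len(nrow(offs))) {
        nb <- sweep(subc[todo, , drop = FALSE], 2L, offs[r, ], "+")
        ok <- nb[, 1] >= 1 & nb[, 1] <= dd[1] & nb[, 2] >= 1 & nb[, 2] <= dd[2] &
              nb[, 3] >= 1 & nb[, 3] <= dd[3]
        if (!any(ok)) next
        nbid <- integer(length(todo))
        nbid[ok] <- sub[nb[ok, , drop = FALSE]]
        src_lab <- ifelse(nbid > 0L, assign[pmax(nbid, 1L)], 0L)
        take <- src_lab > 0L & assign[todo] == 0L
        if (any(take)) {
          assign[todo[take]] <- src_lab[take]
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  # any voxel still unlabelled (isolated plateau) joins the nearest seed
  left <- which(assign == 0L)
  if (length(left) > 0) {
    for (i in left) {
      dsts <- (vox[seeds, 1] - vox[i, 1])^2 + (vox[seeds, 2] - vox[i, 2])^2 +
              (vox[seeds, 3] - vox[i, 3])^2
      assign[i] <- which.min(dsts)
    }
  }
  assign
}

# fallback partition for degenerate components far beyond the expected
# event volume: assign each voxel to its nearest seed (anisotropy: one
# frame counts as one pixel). The band-flooded watershed is quadratic-ish
# in pathological movie-sized blobs, which only arise from uninformative
# probability maps.
nearest_seed_assign <- function(vox, seeds) {
  n <- nrow(vox)
  assign <- integer(n)
  sv <- vox[seeds, , drop = FALSE]
  chunk <- 50000L
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    D <- outer(vox[i:j, 1], sv[, 1], "-")^2 +
         outer(vox[i:j, 2], sv[, 2], "-")^2 +
         outer(vox[i:j, 3], sv[, 3], "-")^2
    assign[i:j] <- max.col(-D, ties.method = "first")
    i <- j + 1L
  }
  assign
}

merge_small_fragments <- function(vox, assign, volume_threshold) {
  # dense label image on the bounding box for vectorised adjacency checks
  lo <- apply(vox, 2L, min)
  dd <- apply(vox, 2L, max) - lo + 1L
  subc <- cbind(vox[, 1] - lo[1] + 1L, vox[, 2] - lo[2] + 1L,
                vox[, 3] - lo[3] + 1L)
  repeat {
    vols <- tapply(rep(1L, length(assign)), assign, sum)
    small <- names(vols)[vols < volume_threshold]
    if (length(small) == 0L || length(vols) == 1L) break
    l <- as.integer(small[which.min(vols[small])])
    lab <- array(0L, dd + 2L)
    lab[subc + 1L] <- assign
    sel <- assign == l
    sc <- subc[sel, , drop = FALSE]
    nb_labs <- integer(0)
    for (ot in -1:1) for (oy in -1:1) for (ox in -1:1) {
      if (ot == 0 && oy == 0 && ox == 0) next
      v <- lab[cbind(sc[, 1] + 1L + ot, sc[, 2] + 1L + oy, sc[, 3] + 1L + ox)]
      nb_labs <- c(nb_labs, v[v > 0L & v != l])
    }
    if (length(nb_labs) == 0L) break  # isolated fragment: keep as is
    touching <- unique(nb_labs)
    tgt <- touching[which.max(vols[as.character(touching)])]
    assign[sel] <- tgt
  }
  assign
}

#' Convert detection components to point events
#'
#' One event per component at the rounded centroid, carrying the component's
#' peak probability, mapped back to original-movie coordinates when scale
#' factors are supplied.
#'
#' @param components list of components (reference scale, 1-based voxels).
#' @param scale_factors optional `c(spatial, temporal)` factors of the
#'   original movie (as from [compute_scale_factors()]); when given, events
#'   are mapped `to_original`.
#' @return an [event_set()].
#' @export
components_to_events <- function(components, scale_factors = NULL) {
  if (length(components) == 0L) return(event_set())
  cen <- t(vapply(components, function(c) c$centroid, numeric(3)))
  fs <- 1; ft <- 1
  if (!is.null(scale_factors)) {       # single rounding after rescaling
    fs <- scale_factors[["spatial"]]; ft <- scale_factors[["temporal"]]
  }
  df <- data.frame(
    x = round_half_away((cen[, 3] - 1) / fs),   # 0-based float centroid
    y = round_half_away((cen[, 2] - 1) / fs),
    t = pmax(0, round_half_away((cen[, 1] - 1) / ft)),
    class = vapply(components, function(c) c$class, ""),
    probability = vapply(components, function(c) c$peak_probability, 0))
  df <- df[!duplicated(df[c("x", "y", "t", "class")]), , drop = FALSE]
  as_event_set(df)
}

#' Detect point events in a movie
#'
#' The full pipeline: rescale the movie to the reference scale, classify all
#' sliding windows into a probability map (averaging over the supplied
#' networks), then for each event class threshold the map, filter connected
#' components by volume, separate merged blobs by watershed and export the
#' component centroids as point events in original-movie coordinates.
#' Deterministic given the networks and configuration.
#'
#' @param nets list of trained `epi_network`s.
#' @param mov an [movie()] in its own calibration.
#' @param config an [run_config()].
#' @param ref the [reference_scale()].
#' @return list with `events` (an [event_set()] in original-movie
#'   coordinates) and `map` (the reference-scale `epi_probability_map`).
#' @export
detect_events <- function(nets, mov, config = run_config(),
                          ref = reference_scale()) {
  factors <- compute_scale_factors(mov$pixel_size, mov$frame_interval, ref)
  mref <- rescale_movie_to_reference(mov, ref)
  pmap <- classify_movie(nets, mref, config)
  all_ev <- list()
  for (cls in pmap$classes) {
    mask <- threshold_map(pmap, config$probability_threshold, cls)
    comps <- extract_components(mask, config$volume_threshold, pmap, cls)
    comps <- watershed_split(pmap, comps, config$volume_threshold)
    ev <- components_to_events(comps, scale_factors = factors)
    all_ev[[cls]] <- as.data.frame(ev)
  }
  df <- do.call(rbind, all_ev)
  events <- if (is.null(df) || nrow(df) == 0L) {
    event_set(pixel_size = mov$pixel_size, frame_interval = mov$frame_interval)
  } else {
    df <- df[!duplicated(df[c("x", "y", "t", "class")]), , drop = FALSE]
    # clamp to the original movie bounds (rounding at the border)
    d <- dim(mov$frames)
    df$x <- pmin(pmax(df$x, 0), d[3] - 1)
    df$y <- pmin(pmax(df$y, 0), d[2] - 1)
    df$t <- pmin(pmax(df$t, 0), d[1] - 1)
    as_event_set(df, pixel_size = mov$pixel_size,
                 frame_interval = mov$frame_interval)
  }
  list(events = events, map = pmap)
}
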
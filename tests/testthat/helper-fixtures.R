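# shared fixtures, built in code at test time

# smooth synthetic image: low-frequency sinusoid mixture (interpolates well)
smooth_frame <- function(ny, nx, phase = 0) {
  y <- seq(0, 2 * pi, length.out = ny)
  x <- seq(0, 2 * pi, length.out = nx)
  0.5 + 0.25 * outer(sin(y + phase), cos(x)) + 0.15 * outer(cos(2 * y), sin(x + phase))
}

smooth_movie <- function(nt = 6, ny = 40, nx = 40, pixel_size = 0.275,
                         frame_interval = 5) {
  fr <- array(0, c(nt, ny, nx))
  for (t in seq_len(nt)) fr[t, , ] <- smooth_frame(ny, nx, phase = t / 3)
  movie(fr, pixel_size, frame_interval)
}

random_events <- function(n, d = c(30, 200, 200), classes = "extrusion",
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    df <- data.frame(x = sample.int(d[3], n, replace = TRUE) - 1L,
                     y = sample.int(d[2], n, replace = TRUE) - 1L,
                     t = sample.int(d[1], n, replace = TRUE) - 1L,
                     class = sample(classes, n, replace = TRUE),
                     probability = rep(NA_real_, n))
    if (!anyDuplicated(df[c("x", "y", "t", "class")])) return(as_event_set(df))
  }
}

# a tiny network spec that exercises all four conv blocks quickly
tiny_spec <- function(n_classes = 2L) {
  network_spec(n_classes = n_classes, base_filters = 2L,
               recurrent_units = 6L, dense_sizes = 5L, dropout_rate = 0,
               window_shape = c(4L, 18L, 18L))
}

tiny_window <- function(label = "none", shape = c(4L, 18L, 18L),
                        bright = FALSE) {
  v <- array(stats::runif(prod(shape), 0, 0.3), shape)
  if (bright) {
    cy <- (shape[2] %/% 2) + (-3:3); cx <- (shape[3] %/% 2) + (-3:3)
    v[, cy, cx] <- v[, cy, cx] + 0.6
  }
  structure(list(voxels = v, label = label, origin = c(x = 0, y = 0, t = 0)),
            class = "epi_window")
}

# brute-force flood fill (stack-based) for connected-component volumes;
# independent of the igraph-based implementation
flood_fill_volumes <- function(mask) {
  d <- dim(mask)
  seen <- array(FALSE, d)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  vols <- integer(0)
  for (start in which(mask & !seen)) {
    if (seen[start]) next
    stack <- arrayInd(start, d)
    seen[start] <- TRUE
    vol <- 0L
    while (nrow(stack) > 0) {
      cur <- stack[nrow(stack), ]
      stack <- stack[-nrow(stack), , drop = FALSE]
      vol <- vol + 1L
      for (r in seq_len(nrow(offs))) {
        nb <- cur + offs[r, ]
        if (any(nb < 1) || any(nb > d)) next
        if (mask[nb[1], nb[2], nb[3]] && !seen[nb[1], nb[2], nb[3]]) {
          seen[nb[1], nb[2], nb[3]] <- TRUE
          stack <- rbind(stack, nb)
        }
      }
    }
    vols <- c(vols, vol)
  }
  sort(vols)
}

# exhaustive optimal one-to-one matching (maximum TP) for small instances
optimal_match_tp <- function(predicted, annotated, cfg) {
  np <- nrow(predicted); na <- nrow(annotated)
  if (np == 0 || na == 0) return(0L)
  ds <- sqrt(outer(predicted$x, annotated$x, "-")^2 +
             outer(predicted$y, annotated$y, "-")^2)
  dt <- abs(outer(predicted$t, annotated$t, "-"))
  ok <- ds <= cfg$spatial_tol & dt <= cfg$temporal_tol &
        outer(predicted$class, annotated$class, "==")
  best <- 0L
  # recursive assignment over predictions
  rec <- function(p, used, tp) {
    if (tp + (np - p + 1) <= best) return()
    if (p > np) { best <<- max(best, tp); return() }
    rec(p + 1L, used, tp)  # leave p unmatched
    for (a in which(ok[p, ] & !used)) {
      used2 <- used; used2[a] <- TRUE
      rec(p + 1L, used2, tp + 1L)
    }
  }
  rec(1L, logical(na), 0L)
  best
}
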
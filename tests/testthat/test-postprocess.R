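make_map <- function(vals3d) {
  probability_map(array(vals3d, c(dim(vals3d), 1L)), "extrusion")
}

test_that("thresholding follows the 0-255 rule and is monotone", {
  m <- make_map(array(0.5, c(3, 6, 6)))
  expect_false(any(threshold_map(m, 180)))        # 128 < 180
  m2 <- make_map(array(0.8, c(3, 6, 6)))
  expect_true(all(threshold_map(m2, 180)))        # 204 >= 180
  set.seed(10)
  for (i in 1:100) {
    r <- make_map(array(stats::runif(4 * 8 * 8), c(4, 8, 8)))
    t1 <- sort(stats::runif(2, 0, 255))
    lo <- threshold_map(r, t1[1]); hi <- threshold_map(r, t1[2])
    expect_true(all(hi <= lo))                    # raising never adds voxels
  }
})

test_that("connected components respect the volume threshold and the flood-fill oracle", {
  mask <- array(FALSE, c(10, 30, 30))
  mask[2:8, 2:11, 2:11] <- TRUE                   # 7*10*10 = 700 voxels
  expect_length(extract_components(mask, 800), 0)
  expect_length(extract_components(mask, 700), 1)

  mask[2:10, 15:24, 15:24] <- TRUE                # 900-voxel second blob
  comps <- extract_components(mask, 800)
  expect_length(comps, 1)
  expect_equal(comps[[1]]$volume, 900)

  set.seed(20)
  for (rep in 1:5) {
    m <- array(stats::runif(8 * 14 * 14) < 0.25, c(8, 14, 14))
    got <- sort(vapply(extract_components(m, 1), `[[`, 0, "volume"))
    expect_equal(got, flood_fill_volumes(m))
  }
})

test_that("component centroids and diagonal connectivity behave as documented", {
  mask <- array(FALSE, c(12, 20, 20))
  mask[1:10, 1:10, 1:10] <- TRUE
  comp <- extract_components(mask, 10)[[1]]
  expect_equal(unname(comp$centroid), c(5.5, 5.5, 5.5))   # 1-based centroid
  # diagonal (26-connectivity) contact joins two cubes
  m2 <- array(FALSE, c(6, 6, 6))
  m2[1:2, 1:2, 1:2] <- TRUE
  m2[3:4, 3:4, 3:4] <- TRUE
  expect_length(extract_components(m2, 1), 1)
})

test_that("watershed splits dumbbell blobs and conserves voxels", {
  # two Gaussian peaks (temporally enveloped) joined by a probability bridge
  nt <- 9; ny <- 40; nx <- 40
  v <- array(0, c(nt, ny, nx))
  env <- exp(-((1:nt) - 5)^2 / 18)
  for (t in 1:nt) for (p in list(c(12, 12), c(28, 28))) {
    yy <- outer((1:ny - p[1])^2, rep(1, nx))
    xx <- outer(rep(1, ny), (1:nx - p[2])^2)
    v[t, , ] <- pmax(v[t, , ], 0.95 * env[t] * exp(-(yy + xx) / (2 * 36)))
  }
  bridge <- 0.75
  for (t in 1:nt) {
    idx <- cbind(round(seq(12, 28, length.out = 24)),
                 round(seq(12, 28, length.out = 24)))
    v[t, , ][idx] <- pmax(v[t, , ][idx], bridge * env[t])
  }
  pm <- make_map(v)
  mask <- threshold_map(pm, 180)
  comps <- extract_components(mask, 50, pm, "extrusion")
  expect_length(comps, 1)                          # merged dumbbell
  split <- watershed_split(pm, comps, 50)
  expect_length(split, 2)
  expect_equal(sum(vapply(split, `[[`, 0, "volume")), comps[[1]]$volume)
  vox_in <- comps[[1]]$voxels
  vox_out <- do.call(rbind, lapply(split, `[[`, "voxels"))
  expect_setequal(paste(vox_in[, 1], vox_in[, 2], vox_in[, 3]),
                  paste(vox_out[, 1], vox_out[, 2], vox_out[, 3]))

  # single-peak blob is returned unchanged
  single <- array(0, c(5, 20, 20))
  env1 <- exp(-((1:5) - 3)^2 / 8)
  for (t in 1:5) single[t, , ] <- 0.9 * env1[t] *
    exp(-(outer((1:20 - 10)^2, rep(1, 20)) +
          outer(rep(1, 20), (1:20 - 10)^2)) / 40)
  pms <- make_map(single)
  cs <- extract_components(threshold_map(pms, 180), 10, pms, "extrusion")
  expect_length(watershed_split(pms, cs, 10), length(cs))
})

test_that("components become events at rounded centroids in original coordinates", {
  comps <- list(list(voxels = cbind(t = rep(1:10, each = 100),
                                    y = rep(rep(1:10, each = 10), 10),
                                    x = rep(1:10, 100)),
                     volume = 1000, centroid = c(5.5, 5.5, 5.5),
                     peak_probability = 0.9, class = "extrusion"))
  ev <- components_to_events(comps)
  expect_equal(nrow(ev), 1)
  expect_equal(c(ev$x, ev$y, ev$t), c(5, 5, 5))   # 0-based rounded centroid
  expect_equal(ev$probability, 0.9)
  half <- components_to_events(comps, c(spatial = 2, temporal = 2))
  expect_equal(c(half$x, half$y, half$t), c(2, 2, 2))
  expect_equal(nrow(components_to_events(list())), 0)
})

# random blob map: a low background plus a few smooth bumps, the shape a
# detection probability map actually takes (thresholds are designed to sit
# above the background; below it the mask percolates into one spanning
# component and event counts are not meaningful)
random_blob_map <- function(nt = 10, ny = 30, nx = 30, n_blobs = NULL) {
  v <- array(stats::runif(nt * ny * nx, 0, 0.15), c(nt, ny, nx))
  if (is.null(n_blobs)) n_blobs <- sample(2:5, 1)
  for (b in seq_len(n_blobs)) {
    c0 <- c(stats::runif(1, 2, nt - 1), stats::runif(1, 4, ny - 3),
            stats::runif(1, 4, nx - 3))
    amp <- stats::runif(1, 0.7, 1)
    sig <- stats::runif(1, 2, 4)
    for (t in 1:nt) {
      g <- exp(-((t - c0[1])^2 / 8 +
                 outer((1:ny - c0[2])^2, rep(1, nx)) / (2 * sig^2) +
                 outer(rep(1, ny), (1:nx - c0[3])^2) / (2 * sig^2)))
      v[t, , ] <- pmax(v[t, , ], amp * g)
    }
  }
  make_map(pmin(v, 1))
}

test_that("raising thresholds never increases the number of detections", {
  set.seed(30)
  n_events <- function(pm, pt, vt) {
    comps <- extract_components(threshold_map(pm, pt), vt, pm, "extrusion")
    length(watershed_split(pm, comps, vt))
  }
  for (rep in 1:10) {
    pm <- random_blob_map()
    for (pt in c(120, 150, 180, 210)) {
      ns <- vapply(c(10, 50, 150, 400), function(vt) n_events(pm, pt, vt), 0)
      expect_true(all(diff(ns) <= 0))              # volume monotone
    }
    # probability monotonicity at event-scale volume thresholds (at
    # speck-scale volumes, overlapping blobs whose saddle region drops out
    # of the mask can fragment; see the methods vignette)
    for (vt in c(50, 150)) {
      ns <- vapply(c(100, 140, 180, 220), function(pt) n_events(pm, pt, vt), 0)
      expect_true(all(diff(ns) <= 0))              # probability monotone
    }
  }
})
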
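test_that("window origins stride and cover the movie, flush at the far edge", {
  o <- epievents:::enumerate_windows  # alias for brevity
  expect_setequal(unique(enumerate_windows(c(10, 90, 90))$y), c(0, 22, 44, 45))
  expect_setequal(unique(enumerate_windows(c(20, 45, 45))$t),
                  c(0, 2, 4, 6, 8, 10))
  expect_identical(unique(enumerate_windows(c(10, 45, 45))$x), 0L)
  expect_error(enumerate_windows(c(5, 45, 45)),
               class = "epievents_invalid_input")
  # every voxel covered by at least one window
  org <- enumerate_windows(c(14, 70, 70))
  covered <- array(FALSE, c(14, 70, 70))
  for (i in seq_len(nrow(org)))
    covered[org$t[i] + 1:10, org$y[i] + 1:45, org$x[i] + 1:45] <- TRUE
  expect_true(all(covered))
})

test_that("probability-map assembly equals the brute-force per-voxel mean", {
  cfg <- run_config(base_filters = 2L, window_shape = c(4L, 18L, 18L),
                    spatial_stride = 8L, temporal_stride = 2L,
                    allocation_patch = c(3L, 8L, 8L))
  net <- build_network(tiny_spec(2L), seed = 13)
  mov <- smooth_movie(nt = 14, ny = 60, nx = 60)
  pm <- classify_movie(list(net), mov, cfg)
  expect_true(all(pm$values >= 0 & pm$values <= 1))
  expect_gte(min(pm$coverage), 1)

  # independent oracle: per-window predictions + per-voxel scan
  org <- enumerate_windows(dim(mov$frames), cfg$window_shape,
                           cfg$spatial_stride, cfg$temporal_stride)
  vox <- lapply(seq_len(nrow(org)), function(k)
    mov$frames[org$t[k] + 1:4, org$y[k] + 1:18, org$x[k] + 1:18, drop = FALSE])
  P <- predict_windows(net, vox)
  d <- dim(mov$frames)
  patches <- lapply(seq_len(nrow(org)), function(w) {
    ct <- org$t[w] + 2L; cy <- org$y[w] + 9L; cx <- org$x[w] + 9L
    list(t = (if (org$t[w] == 0) 1 else max(1, ct - 1 + 1)):
           (if (org$t[w] == d[1] - 4) d[1] else min(d[1], ct + 2)),
         y = (if (org$y[w] == 0) 1 else max(1, cy - 4 + 1)):
           (if (org$y[w] == d[2] - 18) d[2] else min(d[2], cy + 4)),
         x = (if (org$x[w] == 0) 1 else max(1, cx - 4 + 1)):
           (if (org$x[w] == d[3] - 18) d[3] else min(d[3], cx + 4)))
  })
  set.seed(4)
  probe <- cbind(sample(d[1], 60, TRUE), sample(d[2], 60, TRUE),
                 sample(d[3], 60, TRUE))
  for (r in seq_len(nrow(probe))) {
    vals <- unlist(lapply(seq_along(patches), function(w) {
      p <- patches[[w]]
      if (probe[r, 1] %in% p$t && probe[r, 2] %in% p$y && probe[r, 3] %in% p$x)
        P[w, "extrusion"] else NULL
    }))
    expected <- if (length(vals) > 0) mean(vals) else 0
    expect_equal(pm$values[probe[r, 1], probe[r, 2], probe[r, 3], 1],
                 expected, tolerance = 1e-12)
  }
})

test_that("map values are contractive means of window probabilities", {
  cfg <- run_config(base_filters = 2L, window_shape = c(4L, 18L, 18L),
                    spatial_stride = 9L, temporal_stride = 2L,
                    allocation_patch = c(3L, 8L, 8L))
  net <- build_network(tiny_spec(2L), seed = 17)
  mov <- smooth_movie(nt = 10, ny = 40, nx = 40)
  org <- enumerate_windows(dim(mov$frames), cfg$window_shape,
                           cfg$spatial_stride, cfg$temporal_stride)
  vox <- lapply(seq_len(nrow(org)), function(k)
    mov$frames[org$t[k] + 1:4, org$y[k] + 1:18, org$x[k] + 1:18, drop = FALSE])
  P <- predict_windows(net, vox)
  pm <- classify_movie(list(net), mov, cfg)
  covered <- pm$coverage > 0
  expect_lte(max(pm$values[, , , 1][covered]), max(P[, "extrusion"]) + 1e-12)
  expect_gte(min(pm$values[, , , 1][covered]), min(P[, "extrusion"]) - 1e-12)
})

test_that("ensembling averages maps voxel-wise", {
  d <- c(3, 5, 5, 1)
  m1 <- probability_map(array(0.2, d), "extrusion")
  m2 <- probability_map(array(0.6, d), "extrusion")
  avg <- ensemble_maps(list(m1, m2))
  expect_equal(as.vector(avg$values), rep(0.4, prod(d)))
  expect_equal(ensemble_maps(list(m1, m1))$values, m1$values)
  m3 <- probability_map(array(0.5, c(3, 4, 5, 1)), "extrusion")
  expect_error(ensemble_maps(list(m1, m3)), class = "epievents_invalid_input")
  # two identical networks ensemble to the single-network map
  cfg <- run_config(base_filters = 2L, window_shape = c(4L, 18L, 18L),
                    spatial_stride = 9L, temporal_stride = 2L,
                    allocation_patch = c(3L, 8L, 8L))
  net <- build_network(tiny_spec(2L), seed = 23)
  mov <- smooth_movie(nt = 8, ny = 36, nx = 36)
  one <- classify_movie(list(net), mov, cfg)
  two <- classify_movie(list(net, net), mov, cfg)
  expect_equal(two$values, one$values, tolerance = 1e-12)
})
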
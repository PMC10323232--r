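test_that("scale factors are the calibration ratios, identity at reference", {
  expect_equal(compute_scale_factors(0.275, 5),
               c(spatial = 1, temporal = 1))
  expect_equal(compute_scale_factors(0.1375, 2.5),
               c(spatial = 0.5, temporal = 0.5))
  expect_equal(compute_scale_factors(0.55, 5),
               c(spatial = 2, temporal = 1))
  expect_error(compute_scale_factors(-1, 5), class = "epievents_invalid_input")
  expect_error(compute_scale_factors(0.275, 0), class = "epievents_invalid_input")
})

test_that("cell-feature scale factors map observed features onto the reference", {
  expect_equal(scale_factors_from_cell_features(25, 4.5),
               c(spatial = 1, temporal = 1))
  f <- scale_factors_from_cell_features(80, 10)
  expect_equal(f[["spatial"]], 25 / 80)      # 80 px cells resized to 25 px
  expect_equal(80 * f[["spatial"]], 25)
  expect_equal(10 * f[["temporal"]], 4.5)    # 10-frame extrusions to ~4.5
  expect_equal(unname(scale_factors_from_cell_features(50, 9)),
               c(0.5, 0.5))
  expect_error(scale_factors_from_cell_features(0, 5),
               class = "epievents_invalid_input")
})

test_that("movie rescaling changes shapes by the rounded factors", {
  mov <- smooth_movie(nt = 20, ny = 100, nx = 100)
  same <- rescale_movie_to_reference(mov)
  expect_identical(dim(same$frames), dim(mov$frames))

  coarse <- movie(mov$frames, 0.55, 5)
  up <- rescale_movie_to_reference(coarse)
  expect_identical(dim(up$frames), c(20L, 200L, 200L))
  expect_equal(up$pixel_size, 0.275)

  fast <- movie(smooth_movie(nt = 40, ny = 30, nx = 30)$frames, 0.275, 2.5)
  dec <- rescale_movie_to_reference(fast)
  expect_identical(dim(dec$frames), c(20L, 30L, 30L))
  expect_equal(dec$frame_interval, 5)
  # temporal decimation by 2 keeps every other frame exactly
  expect_equal(dec$frames[2, , ], fast$frames[3, , ])
})

test_that("rescale round trip restores shape and intensities approximately", {
  mov <- smooth_movie(nt = 8, ny = 50, nx = 50)
  for (f in c(2, 0.5)) {
    up <- rescale_movie(mov, c(spatial = f, temporal = 1))
    back <- rescale_movie(up, c(spatial = 1 / f, temporal = 1))
    expect_identical(dim(back$frames), dim(mov$frames))
    rngv <- diff(range(mov$frames))
    expect_lt(mean(abs(back$frames - mov$frames)), 0.05 * rngv)
  }
})

test_that("map_points multiplies and rounds; round trip stays within 1 px/frame", {
  ev <- event_set(100, 50, 10, "extrusion")
  to <- map_points(ev, c(spatial = 2, temporal = 0.5), "to_reference")
  expect_equal(c(to$x, to$y, to$t), c(200, 100, 5))
  unchanged <- map_points(ev, c(spatial = 1, temporal = 1), "to_reference")
  expect_equal(as.data.frame(unchanged), as.data.frame(ev))

  set.seed(11)
  for (rep in 1:25) {
    # both coordinates are integer grids, so a to-reference step with a
    # factor f < 1 quantises at 1/f original pixels: the round-trip error
    # bound is 1 px for f >= 0.5 and ceil(0.5/f + 0.5) px below that
    f <- c(spatial = stats::runif(1, 0.25, 4), temporal = stats::runif(1, 0.25, 4))
    bound <- function(fa) if (fa >= 0.5) 1 else ceiling(0.5 / fa + 0.5)
    ev <- random_events(100, d = c(500, 2000, 2000))
    rt <- map_points(map_points(ev, f, "to_reference"), f, "to_original")
    expect_equal(nrow(rt), 100)   # row order is preserved
    expect_true(all(abs(rt$x - ev$x) <= bound(f[["spatial"]])))
    expect_true(all(abs(rt$y - ev$y) <= bound(f[["spatial"]])))
    expect_true(all(abs(rt$t - ev$t) <= bound(f[["temporal"]])))
  }
  # within the calibration range met in practice the error stays at 1 px
  for (rep in 1:10) {
    f <- c(spatial = stats::runif(1, 0.5, 4), temporal = stats::runif(1, 0.5, 4))
    ev <- random_events(50, d = c(500, 2000, 2000))
    rt <- map_points(map_points(ev, f, "to_reference"), f, "to_original")
    expect_true(all(abs(rt$x - ev$x) <= 1))
    expect_true(all(abs(rt$t - ev$t) <= 1))
  }
})

test_that("domain types enforce their invariants", {
  expect_error(movie(array(1, c(0, 4, 4)), 0.275, 5),
               class = "epievents_invalid_input")
  expect_error(movie(matrix(1, 4, 4), 0.275, 5),
               class = "epievents_invalid_input")
  expect_error(event_set(1, 1, 1, "explosion"),
               class = "epievents_invalid_input")
  expect_error(event_set(c(1, 1), c(2, 2), c(3, 3),
                         c("extrusion", "extrusion")),
               class = "epievents_invalid_input")  # duplicates
  expect_error(reference_scale(pixel_size_ref = 0),
               class = "epievents_invalid_input")
  expect_silent(event_set(1, 1, 1, "sop", 0.5))
})
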
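test_that("extract_window centres the event and zero-pads at borders", {
  mov <- smooth_movie(nt = 20, ny = 60, nx = 60)
  w <- extract_window(mov, x = 30, y = 30, t = 5)
  expect_identical(dim(w$voxels), c(10L, 45L, 45L))
  # temporal span is frames t-5 .. t+4 (event frame at index 6)
  expect_equal(w$voxels[1, , ], mov$frames[1, 30 - 22 + 1:45, 30 - 22 + 1:45])
  expect_equal(w$voxels[10, , ], mov$frames[10, 30 - 22 + 1:45, 30 - 22 + 1:45])
  # centre voxel of the crop is the event pixel
  expect_equal(w$voxels[6, 23, 23], mov$frames[6, 31, 31])

  w0 <- extract_window(mov, 30, 30, 0)
  expect_true(all(w0$voxels[1:5, , ] == 0))       # five padded frames before
  expect_equal(w0$voxels[6, 23, 23], mov$frames[1, 31, 31])

  wc <- extract_window(mov, 0, 0, 10)
  expect_true(all(wc$voxels[, 1:22, ] == 0))      # 22 px zero margins
  expect_true(all(wc$voxels[, , 1:22] == 0))
  expect_gt(sum(wc$voxels[, 23:45, 23:45] != 0), 0)

  expect_error(extract_window(mov, 100, 30, 5),
               class = "epievents_invalid_input")
})

test_that("extract_window is translation equivariant away from borders", {
  mov <- smooth_movie(nt = 12, ny = 80, nx = 80)
  w1 <- extract_window(mov, 35, 33, 6)
  shifted <- movie(mov$frames[, c(4:80, 1:3), c(3:80, 1:2)],
                   mov$pixel_size, mov$frame_interval)
  w2 <- extract_window(shifted, 35 - 2, 33 - 3, 6)
  expect_equal(w2$voxels, w1$voxels)
})

test_that("jittered event windows stay within the jitter bound", {
  mov <- smooth_movie(nt = 20, ny = 80, nx = 80)
  ev <- random_events(15, d = c(20, 80, 80) - 0, classes = "extrusion",
                      seed = 21)
  set.seed(1)
  w0 <- sample_event_windows(mov, ev, jitter_space = 0, jitter_time = 0)
  expect_length(w0, 15)
  for (i in seq_len(15)) {
    direct <- extract_window(mov, ev$x[i], ev$y[i], ev$t[i],
                             label = ev$class[i])
    expect_equal(w0[[i]]$voxels, direct$voxels)
  }
  set.seed(2)
  w3 <- sample_event_windows(mov, ev, jitter_space = 3, jitter_time = 1)
  for (i in seq_len(15)) {
    expect_lte(max(abs(w3[[i]]$origin[c("x", "y")] - c(ev$x[i], ev$y[i]))), 3)
    expect_lte(abs(w3[[i]]$origin[["t"]] - ev$t[i]), 1)
  }
})

test_that("control windows never contain an annotation", {
  mov <- smooth_movie(nt = 30, ny = 90, nx = 90)
  ev <- random_events(10, d = c(30, 90, 90), classes = c("extrusion", "sop"),
                      seed = 31)
  set.seed(3)
  ws <- c(4L, 15L, 15L)
  ctrl <- sample_control_windows(mov, ev, n = 400, window_shape = ws)
  expect_length(ctrl, 400)
  for (w in ctrl) {
    o <- w$origin
    # brute-force containment oracle over every annotation
    inside <- ev$t >= o[["t"]] - 2 & ev$t < o[["t"]] + 2 &
              ev$y >= o[["y"]] - 7 & ev$y < o[["y"]] + 8 &
              ev$x >= o[["x"]] - 7 & ev$x < o[["x"]] + 8
    expect_false(any(inside))
    expect_equal(w$label, "none")
  }
  # no annotations: everything is accepted
  set.seed(4)
  free <- sample_control_windows(mov, event_set(), n = 5, window_shape = ws)
  expect_length(free, 5)
  # saturated field: placement must fail
  dense <- movie(array(0.5, c(4, 15, 15)), 0.275, 5)
  centre <- event_set(7, 7, 1, "extrusion")
  expect_error(sample_control_windows(dense, centre, n = 1,
                                      window_shape = ws, max_attempts = 50),
               class = "epievents_invalid_input")
})

test_that("balance_classes equalises counts exactly, preserving order", {
  set.seed(7)
  mk <- function(lbl, n) lapply(seq_len(n), function(i) tiny_window(lbl))
  w <- c(mk("none", 100), mk("extrusion", 40))
  b <- balance_classes(w)
  expect_equal(as.integer(table(vapply(b, `[[`, "", "label"))), c(40L, 40L))

  w4 <- c(mk("none", 90), mk("extrusion", 30), mk("sop", 60),
          mk("division", 45))
  b4 <- balance_classes(w4)
  counts <- table(vapply(b4, `[[`, "", "label"))
  expect_true(all(counts == 30))
  expect_equal(max(counts) - min(counts), 0)

  already <- c(mk("none", 10), mk("extrusion", 10))
  expect_equal(length(balance_classes(already)), 20)
})

test_that("augmentation preserves shape/label and adds calibrated noise", {
  set.seed(12)
  w <- tiny_window("extrusion", shape = c(10L, 45L, 45L))
  for (i in 1:50) {
    a <- augment_window(w, strength = stats::runif(1))
    expect_identical(dim(a$voxels), dim(w$voxels))
    expect_identical(a$label, "extrusion")
  }
  expect_identical(augment_window(w, strength = 0)$voxels, w$voxels)
  # noise-only augmentation: sample sd of the perturbation matches sigma
  a <- augment_window(w, strength = 1, ops = "noise", noise_sd = 0.1)
  s_hat <- stats::sd(a$voxels - w$voxels)   # 20250 voxels
  expect_lt(abs(s_hat - 0.1) / 0.1, 0.1)
})

test_that("temporal movie doubling splits even/odd frames at half rate", {
  mov <- smooth_movie(nt = 10, ny = 20, nx = 20, frame_interval = 2.5)
  pair <- augment_movie_temporal(mov)
  expect_identical(dim(pair[[1]]$frames)[1], 5L)
  expect_identical(dim(pair[[2]]$frames)[1], 5L)
  expect_equal(pair[[1]]$frames[2, , ], mov$frames[3, , ])
  expect_equal(pair[[2]]$frames[2, , ], mov$frames[4, , ])
  expect_equal(pair[[1]]$frame_interval, 5)
  short <- movie(mov$frames[1:3, , , drop = FALSE], 0.275, 5)
  expect_error(augment_movie_temporal(short),
               class = "epievents_invalid_input")
})

test_that("window sets persist to class folders with an index", {
  set.seed(8)
  w <- c(lapply(1:3, function(i) tiny_window("extrusion")),
         lapply(1:2, function(i) tiny_window("none")))
  d <- withr::local_tempdir()
  manifest <- write_window_set(w, d)
  idx <- utils::read.csv(manifest)
  expect_equal(nrow(idx), 5)
  expect_setequal(basename(dirname(idx$file)), c("extrusion", "none"))
  expect_true(all(file.exists(idx$file)))
})
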
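test_that("the default architecture reproduces the printed dimension chain", {
  spec <- network_spec()
  ch <- dimension_chain(spec)
  expect_identical(ch$sides, c(45L, 22L, 11L, 5L))
  expect_identical(ch$filters, c(8L, 16L, 32L, 64L))
  expect_identical(spec$feature_dim, 64L)
  # base_filters * 2^(blocks-1) = feature_dim holds for reduced nets too
  expect_identical(network_spec(base_filters = 4L)$feature_dim, 32L)
  # windows too small for four halvings are rejected
  expect_error(network_spec(window_shape = c(10L, 15L, 15L)),
               class = "epievents_invalid_input")
  expect_silent(network_spec(window_shape = c(10L, 16L, 16L)))
})

test_that("the per-frame encoder emits feature_dim features per frame", {
  spec <- tiny_spec()
  net <- build_network(spec, seed = 3)
  set.seed(1)
  A <- epievents:::windows_to_input(list(tiny_window()$voxels,
                                         tiny_window()$voxels),
                                    spec$window_shape)
  feats <- epievents:::net_encode_frames(net, A)$features
  expect_identical(dim(feats), c(2L * spec$window_shape[1], spec$feature_dim))
})

test_that("predictions are softmax-normalised, deterministic and batch-invariant", {
  net <- build_network(tiny_spec(3L), seed = 5)
  set.seed(2)
  vox <- lapply(1:7, function(i) tiny_window()$voxels)
  P <- predict_windows(net, vox)
  expect_equal(rowSums(P), rep(1, 7), tolerance = 1e-9)
  expect_true(all(P >= 0))
  expect_identical(P, predict_windows(net, vox))             # deterministic
  expect_equal(predict_windows(net, vox, batch_size = 2), P) # batch-invariant
  p1 <- predict_window(net, vox[[1]])
  expect_named(p1, c("none", "extrusion", "sop"))
  expect_equal(unname(p1), P[1, ], ignore_attr = TRUE)
  bad <- array(0, c(3, 18, 18))
  expect_error(predict_window(net, bad), class = "epievents_invalid_input")
})

test_that("analytic gradients agree with finite differences", {
  spec <- tiny_spec(3L)
  net <- build_network(spec, seed = 7)
  set.seed(42)
  vox <- lapply(1:3, function(i) tiny_window()$voxels)
  y <- c(1L, 2L, 3L)
  A <- epievents:::windows_to_input(vox, spec$window_shape)
  fw <- epievents:::net_forward(net, A, training = TRUE, keep_cache = TRUE)
  grads <- epievents:::net_backward(net, fw, y)
  eps <- 1e-5
  worst <- 0
  for (k in names(grads)) {
    p <- net$params[[k]]
    for (i in unique(round(seq(1, length(p), length.out = min(3, length(p)))))) {
      net2 <- net
      net2$params[[k]][i] <- p[i] + eps
      l1 <- epievents:::ce_loss(
        epievents:::net_forward(net2, A, training = TRUE)$probs, y)
      net2$params[[k]][i] <- p[i] - eps
      l2 <- epievents:::ce_loss(
        epievents:::net_forward(net2, A, training = TRUE)$probs, y)
      gnum <- (l1 - l2) / (2 * eps)
      worst <- max(worst, abs(gnum - grads[[k]][i]) /
                            max(1e-6, abs(gnum) + abs(grads[[k]][i])))
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("training separates a bright-vs-dark toy problem and logs history", {
  set.seed(31)
  ws <- c(10L, 45L, 45L)
  wins <- c(lapply(1:30, function(i) tiny_window("extrusion", shape = ws,
                                                 bright = TRUE)),
            lapply(1:30, function(i) tiny_window("none", shape = ws)))
  ts <- training_set(wins, 0.25, balance = TRUE)
  cfg <- run_config(epochs = 8L, base_filters = 2L, augmentation_factor = 1L,
                    batch_size = 16L, learning_rate = 3e-3)
  spec <- network_spec(2L, base_filters = 2L, recurrent_units = 16L,
                       dense_sizes = 8L, dropout_rate = 0, window_shape = ws)
  for (seed in 1:3) {
    net <- build_network(spec, seed = seed)
    net <- train_network(net, ts, cfg, rng_seed = seed)
    h <- net$history
    expect_equal(nrow(h), 8)
    expect_true(all(is.finite(h$loss)))
    expect_gt(utils::tail(h$accuracy, 1), 0.95)
    # validation loss decreases from the first epoch to the best epoch
    expect_lt(min(h$val_loss), h$val_loss[1])
  }
})

test_that("single-class training sets are rejected", {
  wins <- lapply(1:8, function(i) tiny_window("none"))
  ts <- training_set(wins, 0.25, balance = FALSE)
  net <- build_network(tiny_spec(), seed = 1)
  expect_error(train_network(net, ts, run_config(epochs = 1L)),
               class = "epievents_invalid_input")
})

test_that("saved networks reload with identical predictions and metadata", {
  set.seed(9)
  net <- build_network(tiny_spec(3L), seed = 11)
  net$trained <- TRUE
  d <- withr::local_tempdir()
  save_network(net, d)
  back <- load_network(d)
  expect_identical(back$classes, c("none", "extrusion", "sop"))
  vox <- lapply(1:10, function(i) tiny_window()$voxels)
  expect_identical(predict_windows(back, vox), predict_windows(net, vox))
  # class-count mismatch between sidecar and weights is a format error
  cfg_lines <- readLines(file.path(d, "config.txt"))
  cfg_lines[grepl("^n_classes=", cfg_lines)] <- "n_classes=4"
  cfg_lines[grepl("^classes=", cfg_lines)] <- "classes=none,extrusion,sop,division"
  writeLines(cfg_lines, file.path(d, "config.txt"))
  expect_error(load_network(d), class = "epievents_format_error")
})
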
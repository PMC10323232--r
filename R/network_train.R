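# Training of the window classifier: categorical cross-entropy, Adam,
# on-the-fly augmentation, and reinforcement against recurring false
# positives.

net_backward <- function(net, fw, labels_idx) {
  spec <- net$spec
  p <- net$params
  cache <- fw$cache
  B <- cache$B
  P <- fw$probs
  Y <- matrix(0, nrow(P), ncol(P))
  Y[cbind(seq_len(nrow(P)), labels_idx)] <- 1
  dZ <- (P - Y) / nrow(P)
  grads <- list()
  n_dense <- length(spec$dense_sizes) + 1L
  for (i in rev(seq_len(n_dense))) {
    dc <- cache$dense[[i]]
    grads[[paste0("denseW", i)]] <- crossprod(dc$X, dZ)
    grads[[paste0("denseb", i)]] <- colSums(dZ)
    dX <- tcrossprod(dZ, p[[paste0("denseW", i)]])
    if (i > 1L) dZ <- relu_bw(dX, cache$dense[[i - 1L]]$relu)
    else dZ <- dX
  }
  dh <- dZ
  if (!is.null(cache$dropout)) dh <- dh * cache$dropout
  gb <- gru_bw(dh, cache$gru)
  for (gate in c("z", "r", "h")) {
    grads[[paste0("gruW", gate)]] <- gb$grads[[paste0("W", gate)]]
    grads[[paste0("gruU", gate)]] <- gb$grads[[paste0("U", gate)]]
    grads[[paste0("grub", gate)]] <- gb$grads[[paste0("b", gate)]]
  }
  Tn <- spec$window_shape[1]
  dF <- gb$dX
  dim(dF) <- c(Tn * B, spec$feature_dim)
  nb <- spec$n_conv_blocks
  dA <- NULL
  for (b in rev(seq_len(nb))) {
    ck <- cache$blocks[[b]]
    dPool <- if (b == nb) gpool_bw(dF, ck$pool) else pool_bw(dA, ck$pool)
    bnb <- bn_bw(dPool, ck$bn)   # fused ReLU gate applied inside
    grads[[paste0("bng", b)]] <- bnb$dgamma
    grads[[paste0("bnb", b)]] <- bnb$dbeta
    cvb <- conv_bw(bnb$dX, ck$conv, need_dx = b > 1L)
    grads[[paste0("convW", b)]] <- cvb$dW
    dA <- cvb$dX
  }
  grads
}

# recompute batch-norm running statistics for a given parameter set by one
# training-mode pass over the windows (no weight updates)
refresh_bn_stats <- function(net, vox_list, batch_size) {
  nb <- net$spec$n_conv_blocks
  for (b in seq_len(nb)) {
    net$bn[[paste0("mean", b)]] <- 0 * net$bn[[paste0("mean", b)]]
    net$bn[[paste0("var", b)]] <- 0 * net$bn[[paste0("var", b)]] + 1
  }
  i <- 1L
  while (i <= length(vox_list)) {
    j <- min(i + batch_size - 1L, length(vox_list))
    A <- windows_to_input(vox_list[i:j], net$spec$window_shape)
    fw <- net_forward(net, A, training = TRUE)
    net$bn <- fw$bn
    i <- j + 1L
  }
  net
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(grads)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = params, state = state)
}

ce_loss <- function(P, labels_idx) {
  -mean(log(pmax(P[cbind(seq_len(nrow(P)), labels_idx)], 1e-12)))
}

#' Train the window classifier
#'
#' Minimises the categorical cross-entropy with Adam. Augmentation is applied
#' on the fly: each epoch every training window contributes
#' `config$augmentation_factor` samples, the first unaugmented and the rest
#' freshly corrupted by [augment_window()]. Validation metrics are computed
#' in inference mode (running batch-norm statistics, no dropout). Accuracy is
#' the proportion of correct predictions out of all predictions.
#'
#' @param net an [build_network()] network (untrained or pre-trained; a
#'   pre-trained network is fine-tuned, which is how re-training on new
#'   tissues works).
#' @param tset a [training_set()].
#' @param config an [run_config()]; uses `epochs`, `augmentation_factor`,
#'   `batch_size`, `learning_rate`.
#' @param rng_seed seed for shuffling, augmentation and dropout.
#' @param verbose print per-epoch metrics.
#' @return the trained `epi_network`, with a `history` data frame
#'   (epoch, loss, accuracy, val_loss, val_accuracy).
#' @export
train_network <- function(net, tset, config = run_config(),
                          rng_seed = config$seed, verbose = FALSE) {
  windows <- tset$windows
  val <- tset$validation
  if (length(windows) == 0L) stop_invalid("empty training set")
  labels <- vapply(windows, function(w) w$label, "")
  if (length(unique(labels)) < 2L)
    stop_invalid("training set must contain at least 2 classes")
  idx_all <- match(labels, net$classes)
  if (anyNA(idx_all))
    stop_invalid("training labels outside network classes: ",
                 paste(unique(labels[is.na(idx_all)]), collapse = ", "))
  tr <- which(!val); va <- which(val)
  if (length(tr) == 0L) stop_invalid("no training windows after split")
  vox_tr <- lapply(windows[tr], function(w) w$voxels)
  lab_tr <- idx_all[tr]
  vox_va <- lapply(windows[va], function(w) w$voxels)
  lab_va <- idx_all[va]
  set.seed(rng_seed)
  if (is.null(net$adam)) net$adam <- adam_init(net$params)
  aug <- max(1L, config$augmentation_factor)
  hist_rows <- vector("list", config$epochs)
  best <- NULL
  swa_from <- max(1L, ceiling(0.6 * config$epochs))
  swa_sum <- NULL; swa_n <- 0L
  for (epoch in seq_len(config$epochs)) {
    samp_win <- rep(seq_along(vox_tr), each = aug)
    samp_aug <- rep(seq_len(aug) > 1L, times = length(vox_tr))
    ord <- sample.int(length(samp_win))
    samp_win <- samp_win[ord]; samp_aug <- samp_aug[ord]
    ep_loss <- 0; ep_correct <- 0L; ep_n <- 0L
    i <- 1L
    while (i <= length(samp_win)) {
      j <- min(i + config$batch_size - 1L, length(samp_win))
      sel <- i:j
      vox <- lapply(seq_along(sel), function(k) {
        w <- vox_tr[[samp_win[sel[k]]]]
        if (samp_aug[sel[k]])
          augment_window(structure(list(voxels = w, label = "", origin = NULL),
                                   class = "epi_window"))$voxels
        else w
      })
      yb <- lab_tr[samp_win[sel]]
      A <- windows_to_input(vox, net$spec$window_shape)
      fw <- net_forward(net, A, training = TRUE, keep_cache = TRUE)
      net$bn <- fw$bn
      loss <- ce_loss(fw$probs, yb)
      if (!is.finite(loss)) stop("non-finite training loss at epoch ", epoch)
      grads <- net_backward(net, fw, yb)
      st <- adam_step(net$params, grads, net$adam, lr = config$learning_rate)
      net$params <- st$params
      net$adam <- st$state
      nb <- length(sel)
      ep_loss <- ep_loss + loss * nb
      ep_correct <- ep_correct + sum(max.col(fw$probs, ties.method = "first") == yb)
      ep_n <- ep_n + nb
      i <- j + 1L
    }
    if (length(vox_va) > 0L) {
      Pv <- predict_windows(net, vox_va, batch_size = config$batch_size)
      val_loss <- ce_loss(Pv, lab_va)
      val_acc <- mean(max.col(Pv, ties.method = "first") == lab_va)
    } else {
      val_loss <- NA_real_; val_acc <- NA_real_
    }
    hist_rows[[epoch]] <- data.frame(epoch = epoch,
                                     loss = ep_loss / ep_n,
                                     accuracy = ep_correct / ep_n,
                                     val_loss = val_loss,
                                     val_accuracy = val_acc)
    if (!is.na(val_loss) && (is.null(best) || val_loss < best$val_loss))
      best <- list(val_loss = val_loss, params = net$params, bn = net$bn,
                   epoch = epoch)
    if (epoch >= swa_from) {
      swa_sum <- if (is.null(swa_sum)) net$params
                 else Map(`+`, swa_sum, net$params)
      swa_n <- swa_n + 1L
    }
    if (verbose)
      message(sprintf("epoch %d/%d loss %.4f acc %.3f val_loss %.4f val_acc %.3f",
                      epoch, config$epochs, ep_loss / ep_n, ep_correct / ep_n,
                      val_loss, val_acc))
  }
  # candidate 1: best-validation checkpoint; candidate 2: weight average of
  # the final epochs with batch-norm statistics refreshed over the training
  # windows; keep whichever validates better
  if (!is.null(swa_sum) && swa_n > 1L && length(vox_va) > 0L) {
    swa_net <- net
    swa_net$params <- lapply(swa_sum, function(p) p / swa_n)
    swa_net <- refresh_bn_stats(swa_net, vox_tr, config$batch_size)
    Pv <- predict_windows(swa_net, vox_va, batch_size = config$batch_size)
    swa_loss <- ce_loss(Pv, lab_va)
    if (is.null(best) || swa_loss < best$val_loss)
      best <- list(val_loss = swa_loss, params = swa_net$params,
                   bn = swa_net$bn, epoch = NA_integer_)
  }
  if (!is.null(best)) {
    net$params <- best$params
    net$bn <- best$bn
    net$best_epoch <- best$epoch     # NA marks the weight-averaged model
  }
  net$trained <- TRUE
  net$history <- do.call(rbind, hist_rows)
  net$train_config <- list(epochs = config$epochs,
                           augmentation_factor = config$augmentation_factor,
                           batch_size = config$batch_size,
                           learning_rate = config$learning_rate,
                           balance = config$balance,
                           seed = rng_seed,
                           classes = net$classes)
  net
}

#' Reinforce a trained network against its own false positives
#'
#' Runs detection on annotated movies, collects the false-positive
#' detections (predictions unmatched to any annotation under the matching
#' tolerances), extracts windows at their locations labelled `"none"`,
#' appends them to the training windows and retrains; repeated
#' `config$reinforcement_iterations` times. If a round produces no false
#' positives the network is returned unchanged for that round with a log
#' notice.
#'
#' @param net a trained `epi_network`.
#' @param movies list of [movie()] (any calibration).
#' @param annotations list of [event_set()] in each movie's own coordinates.
#' @param config an [run_config()].
#' @param windows optional list of base training windows; by default event
#'   and control windows are sampled from the movies.
#' @param iterations number of reinforcement rounds (default from config).
#' @return the reinforced `epi_network`; `$reinforce_log` records the
#'   false-positive count per round.
#' @export
reinforce <- function(net, movies, annotations, config = run_config(),
                      windows = NULL, iterations = config$reinforcement_iterations) {
  stopifnot(length(movies) == length(annotations))
  ref <- reference_scale()
  set.seed(config$seed + 101L)
  movs_ref <- lapply(movies, rescale_movie_to_reference, ref = ref)
  facs <- lapply(movies, function(m)
    compute_scale_factors(m$pixel_size, m$frame_interval, ref))
  ann_ref <- lapply(seq_along(movies), function(i)
    map_points(annotations[[i]], facs[[i]], "to_reference"))
  relab <- stats::setNames(rep("none", 4), EVENT_CLASSES)
  relab[net$classes] <- net$classes
  if (is.null(windows)) {
    windows <- list()
    for (i in seq_along(movies)) {
      ev <- sample_event_windows(movs_ref[[i]], ann_ref[[i]],
                                 config$jitter_space, config$jitter_time,
                                 config$window_shape, relabel = relab)
      ct <- sample_control_windows(movs_ref[[i]], ann_ref[[i]],
                                   n = max(1L, nrow(ann_ref[[i]])),
                                   window_shape = config$window_shape)
      windows <- c(windows, ev, ct)
    }
  }
  log_rows <- vector("list", iterations)
  for (k in seq_len(iterations)) {
    fp_windows <- list()
    n_fp <- 0L
    for (i in seq_along(movies)) {
      det <- detect_events(list(net), movies[[i]], config)
      mcfg <- match_config(config$match_spatial_tol, config$match_temporal_tol)
      m <- match_events(det$events, annotations[[i]], mcfg)
      fp <- det$events[m$unmatched_predicted, , drop = FALSE]
      n_fp <- n_fp + nrow(fp)
      if (nrow(fp) > 0) {
        fp_ref <- map_points(as_event_set(fp), facs[[i]], "to_reference")
        d <- dim(movs_ref[[i]]$frames)
        for (r in seq_len(nrow(fp_ref))) {
          cx <- min(max(fp_ref$x[r], 0), d[3] - 1)
          cy <- min(max(fp_ref$y[r], 0), d[2] - 1)
          ct <- min(max(fp_ref$t[r], 0), d[1] - 1)
          fp_windows <- c(fp_windows,
                          list(extract_window(movs_ref[[i]], cx, cy, ct,
                                              config$window_shape,
                                              label = "none")))
        }
      }
    }
    log_rows[[k]] <- data.frame(round = k, n_false_positives = n_fp)
    if (n_fp == 0L) {
      message("reinforcement round ", k, ": no false positives; network unchanged")
      next
    }
    windows <- c(windows, fp_windows)
    ts <- training_set(windows, config$validation_fraction,
                       balance = config$balance)
    net <- train_network(net, ts, config, rng_seed = config$seed + k)
  }
  net$reinforce_log <- do.call(rbind, log_rows)
  net
}
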
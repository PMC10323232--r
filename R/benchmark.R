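#' End-to-end synthetic detection benchmark
#'
#' The package's self-contained recovery experiment: generate reference-scale
#' synthetic epithelium movies (256 x 256 px, 60 frames, ~100 cells) with 12
#' planted extrusions and 8 divisions each at high signal-to-noise, train a
#' reduced two-class extrusion classifier (4 base filters, 10 epochs) on all
#' but one movie, and run the full detection pipeline with the default
#' thresholds on the held-out movie, scoring against the exact ground truth
#' with the default matching tolerances (15 px, 4 frames).
#'
#' Training windows are built to match the sliding-window population the
#' classifier will face at inference: positives are drawn around each
#' annotated event with a jitter of half the spatial stride (so the nearest
#' sliding-window column of every event lies inside the supervised
#' displacement range), and the "none" class combines the divisions
#' (relabelled), uniformly drawn event-free control windows, and
#' temporal-contrast controls — windows at an event's location but at a
#' distant, event-free time, which force the classifier to key on the
#' constriction dynamics rather than on static tissue appearance.
#'
#' @param seed integer seed; movie i uses `seed + i - 1`, training uses
#'   `seed + 100`.
#' @param n_movies movies generated (one is held out).
#' @param test_index which movie is held out.
#' @param config detection/training configuration; the default is the
#'   standard [run_config()] reduced to `base_filters = 4`, `epochs = 10`,
#'   with learning rate 3e-3 and batch size 16 (more, smaller steps suit
#'   the short epoch budget).
#' @param synth a [synth_config()] describing the study movies.
#' @param event_window_draws jittered training windows drawn per annotated
#'   event.
#' @param control_per_event uniformly drawn control windows per annotated
#'   event.
#' @param temporal_contrast_per_event temporal-contrast control windows per
#'   annotated event.
#' @param data optional pre-generated dataset (as from
#'   [generate_dataset()]); lets several folds share one generation pass.
#' @return list: `report` (an `epi_metric_report` on the held-out movie),
#'   `window_val_accuracy` (final validation accuracy of the classifier),
#'   `net`, `detections`, `truth`.
#' @export
run_synthetic_benchmark <- function(seed = 1L, n_movies = 3L, test_index = n_movies,
                                    config = NULL, synth = NULL,
                                    event_window_draws = 20L,
                                    control_per_event = 8L,
                                    temporal_contrast_per_event = 4L,
                                    data = NULL) {
  if (is.null(config))
    config <- run_config(base_filters = 4L, epochs = 10L,
                         learning_rate = 3e-3, batch_size = 16L, seed = seed)
  if (is.null(synth))
    synth <- synth_config(image_size = c(256L, 256L), n_frames = 60L,
                          n_cells = 100L, n_extrusions = 12L, n_divisions = 8L,
                          seed = seed)
  if (is.null(data)) data <- generate_dataset(synth, n_movies)
  train_idx <- setdiff(seq_len(n_movies), test_index)
  set.seed(seed + 100L)
  relab <- c(none = "none", extrusion = "extrusion", sop = "none",
             division = "none")
  ws <- config$window_shape
  # supervise the spatial displacement range the sliding windows produce
  # (up to half a stride); temporal jitter stays small so the constriction
  # phase remains roughly centred, as in training-window generation
  jit <- config$spatial_stride %/% 2L
  windows <- list()
  for (i in train_idx) {
    mov <- data[[i]]$movie
    ann <- data[[i]]$events
    for (dr in seq_len(event_window_draws))
      windows <- c(windows,
                   sample_event_windows(mov, ann, jit, config$jitter_time,
                                        ws, relabel = relab))
    # controls drawn from the sliding-window grid itself (event-free
    # framings of the exact window population the detector will classify)
    org <- enumerate_windows(dim(mov$frames), ws, config$spatial_stride,
                             config$temporal_stride)
    ctr <- cbind(org$x + ws[3] %/% 2L, org$y + ws[2] %/% 2L,
                 org$t + ws[1] %/% 2L)
    free <- vapply(seq_len(nrow(ctr)), function(k)
      !window_contains(ctr[k, 1], ctr[k, 2], ctr[k, 3], ws,
                       ann$x, ann$y, ann$t), TRUE)
    pick <- sample(which(free),
                   min(control_per_event * nrow(ann), sum(free)))
    windows <- c(windows, lapply(pick, function(k)
      extract_window(mov, ctr[k, 1], ctr[k, 2], ctr[k, 3], ws,
                     label = "none")))
    d <- dim(mov$frames)
    for (r in seq_len(nrow(ann))) {
      for (k in seq_len(temporal_contrast_per_event)) {
        for (try in 1:20) {
          dt <- sample(12:20, 1) * sample(c(-1, 1), 1)
          tt <- ann$t[r] + dt
          if (tt < ws[1] %/% 2L || tt > d[1] - ws[1] %/% 2L) next
          if (window_contains(ann$x[r], ann$y[r], tt, ws,
                              ann$x, ann$y, ann$t)) next
          windows <- c(windows,
                       list(extract_window(mov, ann$x[r], ann$y[r], tt, ws,
                                           label = "none")))
          break
        }
      }
    }
  }
  ts <- training_set(windows, config$validation_fraction, config$balance)
  spec <- network_spec(n_classes = 2L, base_filters = config$base_filters,
                       window_shape = ws)
  net <- build_network(spec, seed = seed + 100L)
  net <- train_network(net, ts, config, rng_seed = seed + 100L)
  det <- detect_events(list(net), data[[test_index]]$movie, config)
  truth <- data[[test_index]]$events
  truth_ext <- truth[truth$class == "extrusion", , drop = FALSE]
  m <- match_events(det$events, truth_ext,
                    match_config(config$match_spatial_tol,
                                 config$match_temporal_tol))
  list(report = compute_scores(m$counts),
       window_val_accuracy = utils::tail(net$history$val_accuracy, 1),
       net = net, detections = det$events, truth = truth)
}
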
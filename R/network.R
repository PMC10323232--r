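#' Window-classifier architecture specification
#'
#' The classifier encodes each frame of a (T, H, W) window with a
#' convolutional stack — four repetitions of 3x3 same-padding convolution,
#' batch normalisation, ReLU and max pooling, with the filter count doubling
#' per block (8, 16, 32, 64 by default) while 2x2 pooling halves the spatial
#' side (45, 22, 11, 5); the fourth block's pool is global and collapses the
#' remaining 5x5 grid into a per-frame feature vector of length
#' `base_filters * 2^(n_conv_blocks - 1)` (64 by default). The T x 64
#' feature sequence feeds a gated recurrent unit, then dropout, a small
#' dense head, and a softmax layer of `n_classes` units.
#'
#' @param n_classes 2, 3 or 4 event classes; the class ordering is the fixed
#'   prefix of `(none, extrusion, sop, division)`.
#' @param base_filters convolution filters in the first block.
#' @param n_conv_blocks number of conv blocks (4).
#' @param recurrent_units GRU hidden size.
#' @param dense_sizes sizes of the dense hidden layers.
#' @param dropout_rate dropout before the dense head, in \[0, 1).
#' @param window_shape integer (T, H, W) with H == W.
#' @return an object of class `epi_network_spec`.
#' @export
network_spec <- function(n_classes = 2L, base_filters = 8L,
                         n_conv_blocks = 4L, recurrent_units = 64L,
                         dense_sizes = 32L, dropout_rate = 0.5,
                         window_shape = c(10L, 45L, 45L)) {
  if (!n_classes %in% 2:4) stop_invalid("n_classes must be 2, 3 or 4")
  if (window_shape[2] != window_shape[3])
    stop_invalid("window must be spatially square")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop_invalid("dropout_rate must be in [0, 1)")
  spec <- structure(list(n_classes = as.integer(n_classes),
                         base_filters = as.integer(base_filters),
                         n_conv_blocks = as.integer(n_conv_blocks),
                         feature_dim = as.integer(base_filters * 2^(n_conv_blocks - 1L)),
                         recurrent_units = as.integer(recurrent_units),
                         dense_sizes = as.integer(dense_sizes),
                         dropout_rate = dropout_rate,
                         window_shape = as.integer(window_shape)),
                    class = "epi_network_spec")
  dimension_chain(spec)  # errors if the window is too small for the stack
  spec
}

#' Spatial side and filter-count chains of the conv stack
#'
#' For input side s the per-block input sides are s, floor(s/2),
#' floor(s/2/2), ... (45, 22, 11, 5 for the default window); the
#' configuration is invalid when the final block's side drops below 2.
#'
#' @param spec an [network_spec()].
#' @return list with `sides` (input side of each conv block) and `filters`
#'   (filter count of each block).
#' @export
dimension_chain <- function(spec) {
  s <- spec$window_shape[2]
  sides <- integer(spec$n_conv_blocks)
  for (b in seq_len(spec$n_conv_blocks)) {
    sides[b] <- s
    if (b < spec$n_conv_blocks) s <- s %/% 2L
  }
  if (sides[spec$n_conv_blocks] < 2L)
    stop_invalid("window side ", spec$window_shape[2],
                 " is too small for ", spec$n_conv_blocks, " conv blocks")
  list(sides = sides,
       filters = as.integer(spec$base_filters * 2L^(seq_len(spec$n_conv_blocks) - 1L)))
}

#' Build an (untrained) window-classifier network
#'
#' Weights are initialised with He (convolutions, dense) and Glorot (GRU)
#' scaling from the given seed; batch-normalisation scale/offset start at
#' 1/0 and the running statistics at 0/1.
#'
#' @param spec an [network_spec()].
#' @param seed integer seed for weight initialisation.
#' @return an object of class `epi_network`.
#' @export
build_network <- function(spec, seed = 1L) {
  chain <- dimension_chain(spec)
  set.seed(seed)
  params <- list()
  bn <- list()
  cin <- 1L
  for (b in seq_len(spec$n_conv_blocks)) {
    cout <- chain$filters[b]
    params[[paste0("convW", b)]] <-
      matrix(stats::rnorm(9L * cin * cout, 0, sqrt(2 / (9 * cin))), 9L * cin, cout)
    params[[paste0("bng", b)]] <- rep(1, cout)
    params[[paste0("bnb", b)]] <- numeric(cout)
    bn[[paste0("mean", b)]] <- numeric(cout)
    bn[[paste0("var", b)]] <- rep(1, cout)
    cin <- cout
  }
  D <- spec$feature_dim; U <- spec$recurrent_units
  gl <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / (nr + nc))), nr, nc)
  for (gate in c("z", "r", "h")) {
    params[[paste0("gruW", gate)]] <- gl(D, U)
    params[[paste0("gruU", gate)]] <- gl(U, U)
    params[[paste0("grub", gate)]] <- numeric(U)
  }
  sizes <- c(U, spec$dense_sizes, spec$n_classes)
  for (i in seq_len(length(sizes) - 1L)) {
    params[[paste0("denseW", i)]] <-
      matrix(stats::rnorm(sizes[i] * sizes[i + 1L], 0, sqrt(2 / sizes[i])),
             sizes[i], sizes[i + 1L])
    params[[paste0("denseb", i)]] <- numeric(sizes[i + 1L])
  }
  structure(list(spec = spec,
                 classes = EVENT_CLASSES[seq_len(spec$n_classes)],
                 params = params, bn = bn, trained = FALSE,
                 train_config = NULL),
            class = "epi_network")
}

#' @export
print.epi_network <- function(x, ...) {
  ch <- dimension_chain(x$spec)
  cat(sprintf("<epi_network> %d-class (%s), window %s\n", x$spec$n_classes,
              paste(x$classes, collapse = ", "),
              paste(x$spec$window_shape, collapse = "x")))
  cat(sprintf("  conv sides %s | filters %s | GRU %d | dense %s | %s\n",
              paste(ch$sides, collapse = ","),
              paste(ch$filters, collapse = ","),
              x$spec$recurrent_units,
              paste(x$spec$dense_sizes, collapse = ","),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# stack a list of windows into the (H, W, N, 1) activation layout
# (N = batch * T, frame index fastest). Each window is standardised as a
# whole (mean 0, sd 1 over all its voxels): absolute intensity and overall
# illumination cancel, while the relative intensity changes between frames
# — e.g. the brightening rosette of a closing extrusion — are preserved.
windows_to_input <- function(voxels_list, window_shape) {
  Tn <- window_shape[1]; H <- window_shape[2]; W <- window_shape[3]
  B <- length(voxels_list)
  A0 <- array(0, c(Tn, H, W, B))
  for (b in seq_len(B)) {
    v <- voxels_list[[b]]
    if (!all(dim(v) == window_shape))
      stop_invalid("window shape ", paste(dim(v), collapse = "x"),
                   " does not match spec ", paste(window_shape, collapse = "x"))
    A0[, , , b] <- (v - mean(v)) / (stats::sd(v) + 1e-6)
  }
  A <- aperm(A0, c(2, 3, 1, 4))   # (H, W, T, B): frame index fastest in N
  dim(A) <- c(H, W, Tn * B, 1L)
  A
}

# convolutional frame encoder: (H, W, N, 1) images -> (N, feature_dim)
net_encode_frames <- function(net, A, training = FALSE, keep_cache = FALSE) {
  spec <- net$spec
  p <- net$params
  nb <- spec$n_conv_blocks
  caches <- if (keep_cache) vector("list", 0) else NULL
  bn_new <- net$bn
  for (b in seq_len(nb)) {
    cf <- conv_fw(A, p[[paste0("convW", b)]], keep_cache = keep_cache)
    bf <- bn_fw(cf$out, p[[paste0("bng", b)]], p[[paste0("bnb", b)]],
                bn_new[[paste0("mean", b)]], bn_new[[paste0("var", b)]],
                training = training, relu = TRUE)
    bn_new[[paste0("mean", b)]] <- bf$run_mean
    bn_new[[paste0("var", b)]] <- bf$run_var
    pf <- if (b < nb) pool_fw(bf$out, keep_cache = keep_cache)
          else gpool_fw(bf$out, keep_cache = keep_cache)
    if (keep_cache)
      caches[[b]] <- list(conv = cf$cache, bn = bf$cache, pool = pf$cache)
    A <- pf$out
  }
  list(features = A, bn = bn_new, caches = caches)
}

# full forward pass; returns probabilities and (optionally) all caches
net_forward <- function(net, A, training = FALSE, keep_cache = FALSE,
                        dropout_mask = NULL) {
  spec <- net$spec
  p <- net$params
  enc <- net_encode_frames(net, A, training = training, keep_cache = keep_cache)
  caches <- enc$caches
  bn_new <- enc$bn
  A <- enc$features
  # A is now the (N, feature_dim) per-frame feature matrix
  Tn <- spec$window_shape[1]
  B <- nrow(A) %/% Tn
  Xseq <- array(A, c(Tn, B, spec$feature_dim))
  gp <- list(Wz = p$gruWz, Wr = p$gruWr, Wh = p$gruWh,
             Uz = p$gruUz, Ur = p$gruUr, Uh = p$gruUh,
             bz = p$grubz, br = p$grubr, bh = p$grubh)
  gf <- gru_fw(Xseq, gp)
  h <- gf$out
  if (training && spec$dropout_rate > 0) {
    if (is.null(dropout_mask))
      dropout_mask <- matrix((stats::runif(length(h)) > spec$dropout_rate) /
                               (1 - spec$dropout_rate), nrow(h), ncol(h))
    h <- h * dropout_mask
  }
  n_dense <- length(spec$dense_sizes) + 1L
  dense_caches <- vector("list", n_dense)
  X <- h
  for (i in seq_len(n_dense)) {
    Z <- sweep(X %*% p[[paste0("denseW", i)]], 2L, p[[paste0("denseb", i)]], "+")
    if (i < n_dense) {
      rf <- relu_fw(Z)
      dense_caches[[i]] <- list(X = X, relu = rf$cache)
      X <- rf$out
    } else {
      dense_caches[[i]] <- list(X = X)
      X <- Z
    }
  }
  probs <- softmax_rows(X)
  list(probs = probs, bn = bn_new,
       cache = if (keep_cache) list(blocks = caches, gru = gf$cache,
                                    dropout = dropout_mask,
                                    dense = dense_caches, B = B) else NULL)
}

# recurrent + dense head on a precomputed (T, B, D) feature sequence
# (inference only: no dropout, running batch-norm stats untouched)
net_head_forward <- function(net, Xseq) {
  p <- net$params
  spec <- net$spec
  gp <- list(Wz = p$gruWz, Wr = p$gruWr, Wh = p$gruWh,
             Uz = p$gruUz, Ur = p$gruUr, Uh = p$gruUh,
             bz = p$grubz, br = p$grubr, bh = p$grubh)
  X <- gru_fw(Xseq, gp)$out
  n_dense <- length(spec$dense_sizes) + 1L
  for (i in seq_len(n_dense)) {
    X <- sweep(X %*% p[[paste0("denseW", i)]], 2L, p[[paste0("denseb", i)]], "+")
    if (i < n_dense) X <- X * (X > 0)
  }
  softmax_rows(X)
}

#' Class probabilities for one window
#'
#' Inference is deterministic: dropout is disabled and batch normalisation
#' uses the stored running statistics. The output is a named vector of
#' length `n_classes` that sums to 1.
#'
#' @param net an [build_network()] network (usually trained).
#' @param window an `epi_window` or a bare (T, H, W) array.
#' @return named probability vector over the network's classes.
#' @export
predict_window <- function(net, window) {
  v <- if (inherits(window, "epi_window")) window$voxels else window
  p <- predict_windows(net, list(v))
  stats::setNames(p[1L, ], net$classes)
}

#' Class probabilities for a list of windows (batched)
#'
#' @param net an `epi_network`.
#' @param voxels_list list of (T, H, W) arrays or `epi_window`s.
#' @param batch_size inference batch size; results are independent of it.
#' @return matrix (n_windows x n_classes) of probabilities.
#' @export
predict_windows <- function(net, voxels_list, batch_size = 64L) {
  voxels_list <- lapply(voxels_list, function(w)
    if (inherits(w, "epi_window")) w$voxels else w)
  n <- length(voxels_list)
  out <- matrix(0, n, net$spec$n_classes,
                dimnames = list(NULL, net$classes))
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    A <- windows_to_input(voxels_list[i:j], net$spec$window_shape)
    out[i:j, ] <- net_forward(net, A, training = FALSE)$probs
    i <- j + 1L
  }
  out
}

#' Persist / restore a trained network
#'
#' The model directory holds a binary weights file plus a flat key=value
#' sidecar (`config.txt`) recording the architecture, the class ordering and
#' a snapshot of the training configuration, so a reloaded network
#' reproduces its predictions exactly and its provenance is inspectable.
#'
#' @param net an `epi_network`.
#' @param dir model directory (created if needed).
#' @return `save_network` returns `dir` invisibly; `load_network` returns
#'   the restored `epi_network`.
#' @export
save_network <- function(net, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  saveRDS(list(params = net$params, bn = net$bn, trained = net$trained),
          file.path(dir, "weights.rds"))
  sc <- net$spec
  lines <- c(sprintf("n_classes=%d", sc$n_classes),
             sprintf("base_filters=%d", sc$base_filters),
             sprintf("n_conv_blocks=%d", sc$n_conv_blocks),
             sprintf("recurrent_units=%d", sc$recurrent_units),
             sprintf("dense_sizes=%s", paste(sc$dense_sizes, collapse = ",")),
             sprintf("dropout_rate=%.17g", sc$dropout_rate),
             sprintf("window_shape=%s", paste(sc$window_shape, collapse = ",")),
             sprintf("classes=%s", paste(net$classes, collapse = ",")))
  if (!is.null(net$train_config)) {
    tc <- net$train_config
    lines <- c(lines, vapply(names(tc), function(k)
      sprintf("train.%s=%s", k, paste(tc[[k]], collapse = ",")), ""))
  }
  writeLines(lines, file.path(dir, "config.txt"))
  invisible(dir)
}

#' @rdname save_network
#' @export
load_network <- function(dir) {
  wfile <- file.path(dir, "weights.rds")
  cfile <- file.path(dir, "config.txt")
  if (!file.exists(wfile) || !file.exists(cfile))
    stop_format("not a model directory (missing weights.rds/config.txt): ", dir)
  kv <- strsplit(readLines(cfile, warn = FALSE), "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, function(p) paste(p[-1], collapse = "="), "")
  getv <- function(k) vals[match(k, keys)]
  spec <- network_spec(n_classes = as.integer(getv("n_classes")),
                       base_filters = as.integer(getv("base_filters")),
                       n_conv_blocks = as.integer(getv("n_conv_blocks")),
                       recurrent_units = as.integer(getv("recurrent_units")),
                       dense_sizes = as.integer(strsplit(getv("dense_sizes"), ",")[[1]]),
                       dropout_rate = as.numeric(getv("dropout_rate")),
                       window_shape = as.integer(strsplit(getv("window_shape"), ",")[[1]]))
  w <- readRDS(wfile)
  net <- structure(list(spec = spec,
                        classes = strsplit(getv("classes"), ",")[[1]],
                        params = w$params, bn = w$bn,
                        trained = isTRUE(w$trained),
                        train_config = NULL),
                   class = "epi_network")
  # consistency: output layer must match n_classes, encoder must match spec
  nd <- length(spec$dense_sizes) + 1L
  if (ncol(net$params[[paste0("denseW", nd)]]) != spec$n_classes ||
      length(net$classes) != spec$n_classes)
    stop_format("weights/spec mismatch: class count")
  if (nrow(net$params$gruWz) != spec$feature_dim)
    stop_format("weights/spec mismatch: feature dimension")
  net
}
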
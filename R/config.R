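#' Pipeline run configuration
#'
#' One record holding every tunable default of the pipeline. Defaults are the
#' published operating point of the method: a 10x45x45 (t, y, x) window, 50%
#' spatial overlap (stride 22 px), temporal stride 2 frames, window
#' probabilities allocated into a 5x22x22 patch around the window centre,
#' probability threshold 180 on the 0-255 display scale, minimum event
#' volume 800 voxels, matching tolerances of 15 px and 4 frames, 40 training
#' epochs, augmentation factor 2, 8 base convolution filters, a 75/25
#' train/validation split and 5 reinforcement iterations.
#'
#' @param window_shape integer (T, H, W) classifier window.
#' @param spatial_stride window stride in x and y, pixels.
#' @param temporal_stride window stride in t, frames.
#' @param allocation_patch integer (T, H, W) patch receiving each window's
#'   probability, centred on the window centre.
#' @param probability_threshold detection threshold on the 0-255 scale.
#' @param volume_threshold minimum connected high-probability volume, voxels.
#' @param match_spatial_tol,match_temporal_tol tolerances (px, frames) for
#'   counting a detection as matching an annotation.
#' @param n_networks number of independently trained networks whose
#'   probability maps are averaged (1 or 2).
#' @param epochs,augmentation_factor,base_filters,validation_fraction,
#'   reinforcement_iterations training hyperparameters.
#' @param balance equalise per-class window counts before training.
#' @param jitter_space,jitter_time random shift applied to training window
#'   centres (px, frames).
#' @param batch_size minibatch size for training and inference.
#' @param learning_rate Adam learning rate.
#' @param seed integer seed driving sampling, augmentation, initialisation
#'   and shuffling.
#' @return an object of class `epi_config` (a named list).
#' @export
run_config <- function(window_shape = c(10L, 45L, 45L),
                       spatial_stride = 22L,
                       temporal_stride = 2L,
                       allocation_patch = c(5L, 22L, 22L),
                       probability_threshold = 180,
                       volume_threshold = 800,
                       match_spatial_tol = 15,
                       match_temporal_tol = 4,
                       n_networks = 1L,
                       epochs = 40L,
                       augmentation_factor = 2L,
                       base_filters = 8L,
                       validation_fraction = 0.25,
                       reinforcement_iterations = 5L,
                       balance = TRUE,
                       jitter_space = 5L,
                       jitter_time = 1L,
                       batch_size = 32L,
                       learning_rate = 1e-3,
                       seed = 1L) {
  cfg <- list(window_shape = as.integer(window_shape),
              spatial_stride = as.integer(spatial_stride),
              temporal_stride = as.integer(temporal_stride),
              allocation_patch = as.integer(allocation_patch),
              probability_threshold = as.numeric(probability_threshold),
              volume_threshold = as.numeric(volume_threshold),
              match_spatial_tol = as.numeric(match_spatial_tol),
              match_temporal_tol = as.numeric(match_temporal_tol),
              n_networks = as.integer(n_networks),
              epochs = as.integer(epochs),
              augmentation_factor = as.integer(augmentation_factor),
              base_filters = as.integer(base_filters),
              validation_fraction = as.numeric(validation_fraction),
              reinforcement_iterations = as.integer(reinforcement_iterations),
              balance = as.logical(balance),
              jitter_space = as.integer(jitter_space),
              jitter_time = as.integer(jitter_time),
              batch_size = as.integer(batch_size),
              learning_rate = as.numeric(learning_rate),
              seed = as.integer(seed))
  if (length(cfg$window_shape) != 3L || any(cfg$window_shape < 1L))
    stop_invalid("window_shape must be three positive integers (T, H, W)")
  if (length(cfg$allocation_patch) != 3L || any(cfg$allocation_patch < 1L))
    stop_invalid("allocation_patch must be three positive integers (T, H, W)")
  if (cfg$probability_threshold < 0 || cfg$probability_threshold > 255)
    stop_invalid("probability_threshold must be on the 0-255 scale")
  if (!cfg$n_networks %in% c(1L, 2L))
    stop_invalid("n_networks must be 1 or 2")
  if (cfg$validation_fraction <= 0 || cfg$validation_fraction >= 1)
    stop_invalid("validation_fraction must be in (0, 1)")
  structure(cfg, class = "epi_config")
}

#' Write / read a run configuration as a flat key=value text file
#'
#' The on-disk form is diff-friendly and lossless: vectors are
#' comma-separated, logicals are `true`/`false`.
#'
#' @param cfg an [run_config()].
#' @param path file path.
#' @return `read_config` returns an `epi_config`; `write_config` returns
#'   `path` invisibly.
#' @export
write_config <- function(cfg, path) {
  fmt <- function(v) {
    if (is.logical(v)) return(ifelse(v, "true", "false"))
    paste(format(v, digits = 17, scientific = FALSE, trim = TRUE), collapse = ",")
  }
  lines <- vapply(names(cfg), function(k) paste0(k, "=", fmt(cfg[[k]])), "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_format("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, function(p) paste(p[-1], collapse = "="), "")
  defaults <- run_config()
  out <- defaults
  for (i in seq_along(keys)) {
    k <- trimws(keys[i]); v <- trimws(vals[i])
    if (!k %in% names(defaults)) stop_format("unknown config key: ", k)
    proto <- defaults[[k]]
    parsed <- if (is.logical(proto)) identical(tolower(v), "true")
              else if (is.integer(proto)) as.integer(strsplit(v, ",")[[1]])
              else as.numeric(strsplit(v, ",")[[1]])
    out[[k]] <- parsed
  }
  do.call(run_config, unclass(out))
}

#' @export
print.epi_config <- function(x, ...) {
  cat("<epi_config>\n")
  for (k in names(x)) cat(sprintf("  %-26s %s\n", k, paste(x[[k]], collapse = ",")))
  invisible(x)
}
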
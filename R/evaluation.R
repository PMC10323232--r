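# Scoring of detections against annotations: one-to-one spatiotemporal
# matching, precision/recall/F1, distance histograms, cumulative counts and
# random review subsets for unannotated movies.

#' Matching tolerances for detection scoring
#'
#' A detection matches an annotation when their xy Euclidean distance is at
#' most `spatial_tol` pixels and their frame distance at most
#' `temporal_tol`. Defaults (15 px, 4 frames at reference scale, i.e. about
#' one cell radius and +/- 20 min) are for the trained tissue; both are
#' overridable for tissues with larger cells or slower events.
#'
#' @param spatial_tol pixels.
#' @param temporal_tol frames.
#' @return an `epi_match_config`.
#' @export
match_config <- function(spatial_tol = 15, temporal_tol = 4) {
  if (spatial_tol <= 0 || temporal_tol <= 0)
    stop_invalid("matching tolerances must be positive")
  structure(list(spatial_tol = spatial_tol, temporal_tol = temporal_tol),
            class = "epi_match_config")
}

#' Match predicted events to annotations one-to-one
#'
#' Candidate pairs are those of the same class within the tolerance box.
#' Pairs are accepted in ascending spatial distance (ties broken by temporal
#' distance, then input order), each event matched at most once, with a
#' maximum-cardinality guarantee: a pair is skipped, even if both events are
#' free, when accepting it would reduce the total number of matches
#' achievable (verified with an augmenting-path bipartite matching). The
#' result is the deterministic, distance-lexicographic maximum matching.
#' TP = matched pairs, FP = unmatched predictions, FN = unmatched
#' annotations.
#'
#' @param predicted,annotated [event_set()]s in the same coordinate scale.
#' @param cfg an [match_config()].
#' @param by_class require matched events to share the class (default); set
#'   `FALSE` to score localisation regardless of label.
#' @return list with `counts` (named TP/FP/FN), `pairs` (data frame of
#'   matched indices and distances), `unmatched_predicted`,
#'   `unmatched_annotated` (row indices).
#' @export
match_events <- function(predicted, annotated, cfg = match_config(),
                         by_class = TRUE) {
  np <- nrow(predicted); na <- nrow(annotated)
  pairs <- NULL
  if (np > 0 && na > 0) {
    dx <- outer(predicted$x, annotated$x, "-")
    dy <- outer(predicted$y, annotated$y, "-")
    ds <- sqrt(dx^2 + dy^2)
    dt <- abs(outer(predicted$t, annotated$t, "-"))
    ok <- ds <= cfg$spatial_tol & dt <= cfg$temporal_tol
    if (by_class)
      ok <- ok & outer(predicted$class, annotated$class, "==")
    cand <- which(ok, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      o <- order(ds[cand], dt[cand], cand[, 1], cand[, 2])
      cand <- cand[o, , drop = FALSE]
      target <- max_bipartite_tp(cand, np, na)
      usedp <- logical(np); useda <- logical(na)
      keep <- logical(nrow(cand))
      accepted <- 0L
      for (i in seq_len(nrow(cand))) {
        p <- cand[i, 1]; a <- cand[i, 2]
        if (usedp[p] || useda[a]) next
        # accept only if a maximum matching remains reachable afterwards
        rest <- cand[-seq_len(i), , drop = FALSE]
        rest <- rest[!usedp[rest[, 1]] & !useda[rest[, 2]] &
                       rest[, 1] != p & rest[, 2] != a, , drop = FALSE]
        if (accepted + 1L + max_bipartite_tp(rest, np, na) == target) {
          keep[i] <- TRUE; usedp[p] <- TRUE; useda[a] <- TRUE
          accepted <- accepted + 1L
        }
      }
      cand <- cand[keep, , drop = FALSE]
      pairs <- data.frame(predicted = cand[, 1], annotated = cand[, 2],
                          spatial_distance = ds[cand],
                          temporal_distance = dt[cand])
    }
  }
  if (is.null(pairs))
    pairs <- data.frame(predicted = integer(0), annotated = integer(0),
                        spatial_distance = numeric(0),
                        temporal_distance = numeric(0))
  tp <- nrow(pairs)
  list(counts = c(TP = tp, FP = np - tp, FN = na - tp),
       pairs = pairs,
       unmatched_predicted = setdiff(seq_len(np), pairs$predicted),
       unmatched_annotated = setdiff(seq_len(na), pairs$annotated))
}

# maximum-cardinality bipartite matching size (Kuhn's augmenting paths)
# over a candidate edge list (matrix with predicted/annotated columns)
max_bipartite_tp <- function(cand, np, na) {
  if (nrow(cand) == 0L) return(0L)
  adj <- split(cand[, 2], factor(cand[, 1], levels = seq_len(np)))
  match_a <- integer(na)          # annotation -> prediction (0 = free)
  seen <- logical(na)
  try_augment <- function(p) {
    for (a in adj[[p]]) {
      if (seen[a]) next
      seen[a] <<- TRUE
      if (match_a[a] == 0L || try_augment(match_a[a])) {
        match_a[a] <<- p
        return(TRUE)
      }
    }
    FALSE
  }
  size <- 0L
  for (p in unique(cand[, 1])) {
    seen <- logical(na)
    if (try_augment(p)) size <- size + 1L
  }
  size
}

#' Precision, recall, F1 (and optional accuracy) from counts
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `f1 = TP/(TP + (FP+FN)/2)` (identical to the harmonic mean
#' `2PR/(P+R)` whenever defined). Accuracy `(TP+TN)/(TP+TN+FP+FN)` is
#' reported only when TN is supplied, i.e. for window-level classification;
#' true negatives are undefined for point detection. When a denominator is
#' 0 the metric is 0, except that an empty prediction set scored against an
#' empty annotation set gives 1 (nothing to find, nothing found).
#'
#' @param counts named vector/list with TP, FP, FN and optionally TN.
#' @param tolerances optional `epi_match_config` echoed into the report.
#' @return an `epi_metric_report` (named list: precision, recall, f1,
#'   accuracy, counts, tolerances).
#' @export
compute_scores <- function(counts, tolerances = NULL) {
  tp <- as.numeric(counts[["TP"]]); fp <- as.numeric(counts[["FP"]])
  fn <- as.numeric(counts[["FN"]])
  tn <- if ("TN" %in% names(counts)) as.numeric(counts[["TN"]]) else NA_real_
  if (tp == 0 && fp == 0 && fn == 0) {
    precision <- recall <- f1 <- 1
  } else {
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (tp + (fp + fn) / 2 > 0) tp / (tp + (fp + fn) / 2) else 0
  }
  accuracy <- if (is.na(tn)) NA_real_ else (tp + tn) / (tp + tn + fp + fn)
  structure(list(precision = precision, recall = recall, f1 = f1,
                 accuracy = accuracy,
                 counts = c(TP = tp, FP = fp, FN = fn, TN = tn),
                 tolerances = tolerances),
            class = "epi_metric_report")
}

#' @export
print.epi_metric_report <- function(x, ...) {
  cat(sprintf("<epi_metric_report> P %.3f  R %.3f  F1 %.3f%s  (TP %d, FP %d, FN %d)\n",
              x$precision, x$recall, x$f1,
              if (is.na(x$accuracy)) "" else sprintf("  acc %.3f", x$accuracy),
              x$counts[["TP"]], x$counts[["FP"]], x$counts[["FN"]]))
  if (!is.null(x$tolerances))
    cat(sprintf("  tolerances: %g px, %g frames\n", x$tolerances$spatial_tol,
                x$tolerances$temporal_tol))
  invisible(x)
}

#' F1 score from precision and recall
#' @param precision,recall metric values in \[0, 1\].
#' @return harmonic mean `2PR/(P+R)` (0 when both are 0).
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), 0)
}

#' 2D histogram of spatiotemporal distances between detections and annotations
#'
#' Pairs each annotation with detections inside a wide cutoff (one-to-one,
#' via [match_events()] with the cutoff as tolerance), bins the pair
#' distances at 1 px x 1 frame, and reports the marginal histograms and the
#' fraction of pairs inside the matching tolerance box.
#'
#' @param predicted,annotated [event_set()]s in the same scale.
#' @param cfg an [match_config()] defining the tolerance box reported on.
#' @param cutoff_spatial,cutoff_temporal wide pairing cutoffs (px, frames).
#' @return list: `counts` (matrix spatial bin x temporal bin),
#'   `spatial_marginal`, `temporal_marginal`, `fraction_inside`, `n_pairs`.
#' @export
distance_histogram <- function(predicted, annotated, cfg = match_config(),
                               cutoff_spatial = 50, cutoff_temporal = 12) {
  wide <- match_config(cutoff_spatial, cutoff_temporal)
  m <- match_events(predicted, annotated, wide)
  sbr <- 0:ceiling(cutoff_spatial + 1)
  tbr <- 0:ceiling(cutoff_temporal + 1)
  sbin <- pmin(floor(m$pairs$spatial_distance), max(sbr) - 1L)
  tbin <- pmin(floor(m$pairs$temporal_distance), max(tbr) - 1L)
  counts <- matrix(0L, length(sbr) - 1L, length(tbr) - 1L,
                   dimnames = list(utils::head(sbr, -1L), utils::head(tbr, -1L)))
  for (i in seq_along(sbin))
    counts[sbin[i] + 1L, tbin[i] + 1L] <- counts[sbin[i] + 1L, tbin[i] + 1L] + 1L
  inside <- m$pairs$spatial_distance <= cfg$spatial_tol &
            m$pairs$temporal_distance <= cfg$temporal_tol
  list(counts = counts,
       spatial_marginal = rowSums(counts),
       temporal_marginal = colSums(counts),
       fraction_inside = if (nrow(m$pairs) > 0) mean(inside) else NA_real_,
       n_pairs = nrow(m$pairs))
}

#' Cumulative event counts over time and their per-bin difference
#'
#' Computes the cumulative number of events over developmental time for the
#' detections and the annotations, binned every `bin_minutes`, and the mean
#' absolute per-bin difference between the two curves.
#'
#' @param events,annotations [event_set()]s sharing a time origin.
#' @param frame_interval min/frame used to convert frames to minutes.
#' @param bin_minutes bin width in minutes.
#' @return list: `time_min` (bin upper edges), `cumulative_detected`,
#'   `cumulative_annotated`, `abs_difference`, `mean_abs_difference`.
#' @export
cumulative_counts <- function(events, annotations, frame_interval = 5,
                              bin_minutes = 10) {
  tmax <- max(c(events$t, annotations$t, 0)) * frame_interval
  edges <- seq(0, tmax + bin_minutes, by = bin_minutes)
  cum_at <- function(ev) vapply(edges, function(e)
    sum(ev$t * frame_interval <= e), 0L)
  cd <- cum_at(events); ca <- cum_at(annotations)
  list(time_min = edges, cumulative_detected = cd, cumulative_annotated = ca,
       abs_difference = abs(cd - ca),
       mean_abs_difference = mean(abs(cd - ca)))
}

#' Random detection subset for manual review
#'
#' For movies without annotations, precision is estimated by reviewing a
#' random subset of detections by eye. `sample_rois_for_review` draws a
#' uniform subset without replacement; [review_precision()] turns the
#' recorded verdicts into an estimated precision.
#'
#' @param predicted an [event_set()].
#' @param n subset size (at most `nrow(predicted)`).
#' @return an `epi_events` subset of `predicted`.
#' @export
sample_rois_for_review <- function(predicted, n) {
  if (n > nrow(predicted))
    stop_invalid("requested ", n, " of ", nrow(predicted), " detections")
  predicted[sort(sample.int(nrow(predicted), n)), , drop = FALSE]
}

#' @rdname sample_rois_for_review
#' @param verdicts logical vector (or data frame with a `correct` column)
#'   of manual judgements for the reviewed subset.
#' @return `review_precision` returns the estimated precision k/n.
#' @export
review_precision <- function(verdicts) {
  v <- if (is.data.frame(verdicts)) verdicts$correct else verdicts
  if (length(v) == 0L) stop_invalid("no verdicts supplied")
  mean(as.logical(v))
}
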
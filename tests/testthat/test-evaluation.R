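test_that("matching respects the spatiotemporal tolerance box", {
  cfg <- match_config(15, 4)
  pred <- event_set(100, 100, 10, "extrusion")
  annot <- event_set(110, 105, 12, "extrusion")
  m <- match_events(pred, annot, cfg)
  expect_equal(unname(m$counts), c(1, 0, 0))      # sqrt(125) <= 15, dt 2 <= 4
  expect_equal(m$pairs$spatial_distance, sqrt(125))

  far <- event_set(100, 100, 15, "extrusion")
  m2 <- match_events(pred, far, cfg)
  expect_equal(unname(m2$counts), c(0, 1, 1))     # dt 5 > 4

  # class-aware: a division prediction does not match an extrusion annotation
  divp <- event_set(100, 100, 10, "division")
  m3 <- match_events(divp, annot, cfg)
  expect_equal(unname(m3$counts), c(0, 1, 1))
})

test_that("greedy matching is symmetric and equals the exhaustive optimum", {
  cfg <- match_config(15, 4)
  set.seed(40)
  for (rep in 1:200) {
    np <- sample(0:6, 1); na <- sample(0:6, 1)
    pred <- random_events(np, d = c(12, 60, 60))
    annot <- random_events(na, d = c(12, 60, 60))
    m <- match_events(pred, annot, cfg)
    expect_equal(m$counts[["TP"]], optimal_match_tp(pred, annot, cfg))
    swap <- match_events(annot, pred, cfg)
    expect_equal(swap$counts[["TP"]], m$counts[["TP"]])
    expect_equal(swap$counts[["FP"]], m$counts[["FN"]])
    expect_equal(swap$counts[["FN"]], m$counts[["FP"]])
    expect_equal(m$counts[["TP"]] + m$counts[["FP"]], np)
    expect_equal(m$counts[["TP"]] + m$counts[["FN"]], na)
  }
})

test_that("greedy TP never exceeds the optimum on larger instances", {
  cfg <- match_config(15, 4)
  set.seed(41)
  for (rep in 1:20) {
    pred <- random_events(sample(5:20, 1), d = c(10, 40, 40))
    annot <- random_events(sample(5:20, 1), d = c(10, 40, 40))
    m <- match_events(pred, annot, cfg)
    expect_lte(m$counts[["TP"]], min(nrow(pred), nrow(annot)))
  }
})

test_that("score formulas and 0/0 conventions are exact", {
  r <- compute_scores(c(TP = 1, FP = 0, FN = 0))
  expect_equal(c(r$precision, r$recall, r$f1), c(1, 1, 1))
  z <- compute_scores(c(TP = 0, FP = 5, FN = 5))
  expect_equal(c(z$precision, z$recall, z$f1), c(0, 0, 0))
  e <- compute_scores(c(TP = 0, FP = 0, FN = 0))
  expect_equal(c(e$precision, e$recall, e$f1), c(1, 1, 1))

  # both F1 forms agree, and F1 lies between P and R
  set.seed(50)
  for (i in 1:100) {
    tp <- sample(1:30, 1); fp <- sample(0:30, 1); fn <- sample(0:30, 1)
    r <- compute_scores(c(TP = tp, FP = fp, FN = fn))
    expect_equal(r$f1, tp / (tp + (fp + fn) / 2))
    expect_equal(r$f1, f1_score(r$precision, r$recall))
    expect_gte(r$f1, min(r$precision, r$recall) - 1e-12)
    expect_lte(r$f1, max(r$precision, r$recall) + 1e-12)
  }

  # window-level accuracy uses TN; point detection reports none
  wa <- compute_scores(c(TP = 40, TN = 50, FP = 5, FN = 5))
  expect_equal(wa$accuracy, 0.9)
  expect_true(is.na(compute_scores(c(TP = 1, FP = 1, FN = 1))$accuracy))
})

test_that("the published worked example: P 0.72, R 0.86 gives F1 0.78", {
  expect_equal(round(f1_score(0.72, 0.86), 2), 0.78)
})

test_that("distance histograms conserve pairs and count the tolerance box", {
  pred <- event_set(c(10, 50, 90), c(10, 50, 90), c(2, 5, 9), rep("extrusion", 3))
  m <- distance_histogram(pred, pred)
  expect_equal(m$n_pairs, 3)
  expect_equal(sum(m$counts), 3)
  expect_equal(m$counts["0", "0"], 3L)            # all pairs at distance 0
  expect_equal(m$fraction_inside, 1)

  annot <- event_set(c(10, 50, 90), c(14, 50, 90), c(2, 5, 9), rep("extrusion", 3))
  h <- distance_histogram(pred, annot, match_config(3, 4))
  expect_equal(sum(h$counts), h$n_pairs)
  expect_equal(h$fraction_inside, 2 / 3)          # one pair at 4 px > 3 px tol
  expect_equal(sum(h$spatial_marginal), h$n_pairs)
})

test_that("cumulative curves are non-decreasing and end at the set sizes", {
  ev <- random_events(30, d = c(100, 50, 50), seed = 60)
  cc <- cumulative_counts(ev, ev, frame_interval = 5, bin_minutes = 10)
  expect_equal(cc$mean_abs_difference, 0)
  annot <- random_events(20, d = c(100, 50, 50), seed = 61)
  cc2 <- cumulative_counts(ev, annot, frame_interval = 5, bin_minutes = 10)
  expect_true(all(diff(cc2$cumulative_detected) >= 0))
  expect_true(all(diff(cc2$cumulative_annotated) >= 0))
  expect_equal(utils::tail(cc2$cumulative_detected, 1), 30)
  expect_equal(utils::tail(cc2$cumulative_annotated, 1), 20)
  expect_equal(cc2$mean_abs_difference,
               mean(abs(cc2$cumulative_detected - cc2$cumulative_annotated)))
})

test_that("review subsets are reproducible and yield k/n precision", {
  ev <- random_events(40, seed = 70)
  set.seed(5); s1 <- sample_rois_for_review(ev, 10)
  set.seed(5); s2 <- sample_rois_for_review(ev, 10)
  expect_equal(as.data.frame(s1), as.data.frame(s2))
  expect_equal(nrow(sample_rois_for_review(ev, 40)), 40)
  expect_error(sample_rois_for_review(ev, 41),
               class = "epievents_invalid_input")
  expect_equal(review_precision(c(TRUE, TRUE, FALSE, TRUE)), 0.75)
})
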
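# small study fields keep these tests fast; the full-size study conditions
# are exercised by the acceptance suite
small_cfg <- function(seed = 1L, ...) {
  synth_config(image_size = c(128L, 128L), n_frames = 24L, n_extrusions = 2L,
               n_divisions = 1L, min_separation_px = 30,
               min_separation_frames = 8, seed = seed, ...)
}

test_that("epithelium generation is seed-reproducible with bimodal intensities", {
  g1 <- generate_epithelium(small_cfg(5))
  g2 <- generate_epithelium(small_cfg(5))
  expect_identical(g1$movie$frames, g2$movie$frames)
  g3 <- generate_epithelium(small_cfg(6))
  expect_false(identical(g1$movie$frames, g3$movie$frames))

  # junctions bright, interiors dark: clearly separated intensity modes
  fr <- g1$movie$frames[1, , ]
  cfg <- small_cfg(5)
  frac_dark <- mean(fr < (cfg$background + 0.1))
  frac_bright <- mean(fr > (cfg$junction_intensity - 0.15))
  expect_gt(frac_dark, 0.5)      # most pixels are cell interior
  expect_gt(frac_bright, 0.02)   # junction skeleton is present
  expect_lt(mean(fr > cfg$background + 0.1 & fr < cfg$junction_intensity - 0.15),
            frac_dark)
})

test_that("generated cell sizes track the configured diameter", {
  cfg <- small_cfg(7)
  geom <- epievents:::synth_geometry(cfg)
  empty <- data.frame(cell = integer(0), type = character(0),
                      t0 = integer(0), dur = integer(0))
  dyn <- epievents:::build_dynamics(geom, empty)
  lab <- epievents:::synth_labels_frame(dyn, 1, cfg$image_size)
  areas <- as.vector(table(lab))
  mean_diam <- mean(2 * sqrt(areas / pi))
  expect_lt(abs(mean_diam - cfg$cell_diameter) / cfg$cell_diameter, 0.2)
})

test_that("planted events carry exact ground truth", {
  cfg <- small_cfg(9)
  geom <- epievents:::synth_geometry(cfg)
  res <- plant_events(NULL, geom, cfg)
  expect_equal(sum(res$events$class == "extrusion"), 2)
  expect_equal(sum(res$events$class == "division"), 1)
  d <- dim(res$movie$frames)
  expect_true(all(res$events$x >= 0 & res$events$x < d[3]))
  expect_true(all(res$events$t >= 0 & res$events$t < d[1]))

  # an extruding cell's apical area is non-increasing to zero over its span
  sch <- res$schedule
  ext <- sch[sch$type == "extrusion", ][1, ]
  areas <- epievents:::synth_area_trajectories(geom, sch, ext$cell)[, 1]
  span <- (ext$t0 - ext$dur):(ext$t0) + 1L
  expect_true(all(diff(areas[span]) <= 0))
  expect_equal(areas[ext$t0 + 1L], 0)
  expect_true(all(areas[(ext$t0 + 1L):cfg$n_frames] == 0))

  # planting zero events reproduces the plain epithelium exactly
  cfg0 <- small_cfg(9)
  cfg0$n_extrusions <- 0L; cfg0$n_divisions <- 0L
  geom0 <- epievents:::synth_geometry(cfg0)
  base <- generate_epithelium(cfg0)
  planted0 <- plant_events(NULL, geom0, cfg0)
  expect_identical(planted0$movie$frames, base$movie$frames)
  expect_equal(nrow(planted0$events), 0)
})

test_that("confusers are rendered but never annotated", {
  cfg <- small_cfg(11, n_confusers = 2L)
  geom <- epievents:::synth_geometry(cfg)
  res <- plant_events(NULL, geom, cfg)
  expect_equal(sum(res$schedule$type == "confuser"), 2)
  expect_equal(nrow(res$events), 3)   # 2 extrusions + 1 division only
  # the confuser constricts and relaxes: area dips but recovers
  conf <- res$schedule[res$schedule$type == "confuser", ][1, ]
  areas <- epievents:::synth_area_trajectories(geom, res$schedule, conf$cell)[, 1]
  post <- areas[(conf$t0 + 2 * conf$dur):min(length(areas), conf$t0 + 3 * conf$dur)]
  expect_lt(min(areas[conf$t0:(conf$t0 + conf$dur) + 1L]), 0.6 * areas[1])
  expect_gt(max(post), 0.8 * areas[1])
})

test_that("extrusion and division area signatures are discriminable", {
  cfg <- synth_config(image_size = c(128L, 128L), n_frames = 30L,
                      n_extrusions = 4L, n_divisions = 4L,
                      min_separation_px = 30, min_separation_frames = 6,
                      seed = 13)
  feats <- NULL
  for (seed in 13:15) {
    cfg$seed <- seed
    geom <- epievents:::synth_geometry(cfg)
    res <- plant_events(NULL, geom, cfg)
    sch <- res$schedule
    areas <- epievents:::synth_area_trajectories(geom, sch, sch$cell)
    for (r in seq_len(nrow(sch))) {
      tr <- areas[max(1, sch$t0[r] - 5):min(nrow(areas), sch$t0[r] + 5), r]
      a0 <- max(tr[1], 1)
      feats <- rbind(feats,
                     data.frame(type = sch$type[r],
                                min_ratio = min(tr) / a0,
                                final_ratio = utils::tail(tr, 1) / a0))
    }
  }
  # leave-one-out nearest-centroid classification on the two features
  correct <- 0L
  for (i in seq_len(nrow(feats))) {
    tr <- feats[-i, ]; te <- feats[i, ]
    cen <- stats::aggregate(cbind(min_ratio, final_ratio) ~ type, tr, mean)
    dd <- (cen$min_ratio - te$min_ratio)^2 + (cen$final_ratio - te$final_ratio)^2
    if (cen$type[which.min(dd)] == te$type) correct <- correct + 1L
  }
  expect_gt(correct / nrow(feats), 0.9)
})

test_that("datasets carry a manifest and distinct per-movie seeds", {
  d <- withr::local_tempdir()
  ds <- generate_dataset(small_cfg(21), n_movies = 3, dir = d)
  expect_length(ds, 3)
  mf <- utils::read.csv(attr(ds, "manifest"))
  expect_equal(nrow(mf), 3)
  expect_equal(mf$seed, 21:23)
  expect_equal(sum(mf$n_events), sum(vapply(ds, function(x) nrow(x$events), 0)))
  expect_false(identical(ds[[1]]$movie$frames, ds[[2]]$movie$frames))
  # artefacts are readable back
  back <- read_imagej_rois(mf$rois[1])
  expect_equal(nrow(back), nrow(ds[[1]]$events))
  mov <- read_tiff_movie(mf$movie[1], 0.275, 5)
  expect_identical(dim(mov$frames), dim(ds[[1]]$movie$frames))
})
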
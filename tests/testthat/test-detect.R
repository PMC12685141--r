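test_that("pure-noise volumes produce no picks", {
  sp <- scene_spec(pixel_size = 10, shape = c(48L, 48L, 48L), n_particles = 0L,
                   snr = 5, seed = 5)
  v <- generate_tomogram(sp)
  expect_equal(nrow(detect_blobs(v, threshold = 0.5)), 0)
  expect_error(detect_blobs(v, sigma = 5), "voxel")
  expect_error(detect_blobs(v, threshold = 1.5), "threshold")
})

test_that("detection localizes particles to subvoxel precision", {
  sp <- scene_spec(pixel_size = 10, shape = c(48L, 48L, 48L), n_particles = 1L,
                   monomer_fraction = 1, dimer_fraction = 0, snr = Inf,
                   seed = 3, min_center_distance = 0)
  v <- generate_tomogram(sp)
  p <- detect_blobs(v, sigma = 10)
  expect_equal(nrow(p), 1)
  err <- sqrt(sum((unlist(p[1, c("x", "y", "z")]) -
                     unlist(v$truth[1, c("x", "y", "z")]))^2))
  expect_lt(err, 0.5 * 10)
  # a dimer yields two picks one separation apart
  sp2 <- scene_spec(pixel_size = 10, shape = c(48L, 48L, 48L), n_particles = 1L,
                    monomer_fraction = 0, dimer_fraction = 1,
                    dimer_separation_mean = 40, dimer_separation_sd = 0,
                    snr = 5, seed = 4, min_center_distance = 0)
  v2 <- generate_tomogram(sp2)
  p2 <- detect_blobs(v2, sigma = 10)
  expect_equal(nrow(p2), 2)
  expect_equal(as.numeric(stats::dist(p2[, c("x", "y", "z")])), 40, tolerance = 4)
})

test_that("pairing follows the separation window with deterministic tie-breaks", {
  mk <- function(xs) data.frame(x = xs, y = 0, z = 0)
  p1 <- pair_picks(mk(c(0, 40)))
  expect_equal(nrow(p1$pairs), 1)
  expect_length(p1$leftover, 0)
  p2 <- pair_picks(mk(c(0, 60)))
  expect_equal(nrow(p2$pairs), 0)
  expect_length(p2$leftover, 2)
  # three collinear picks at 0/40/80: exactly one pair by tie-break
  p3 <- pair_picks(mk(c(0, 40, 80)))
  expect_equal(nrow(p3$pairs), 1)
  expect_equal(c(p3$pairs$i, p3$pairs$j), c(1, 2))
  expect_equal(p3$leftover, 3L)
  # determinism: same input, same pairing
  expect_identical(pair_picks(mk(c(0, 40, 80))), p3)
})

test_that("classification conserves picks and validates dumbbells", {
  sp <- scene_spec(pixel_size = 10, shape = c(64L, 64L, 64L), n_particles = 6L,
                   monomer_fraction = 0.5, dimer_fraction = 0.5,
                   dimer_separation_mean = 40, dimer_separation_sd = 0,
                   snr = 8, seed = 21, min_center_distance = 80)
  v <- generate_tomogram(sp)
  picks <- detect_blobs(v, sigma = 10)
  pairing <- pair_picks(picks)
  pred <- classify_picks(v, picks, pairing)
  expect_equal(2 * sum(pred$class == "dimer") + sum(pred$class == "monomer"),
               nrow(picks))
  if (any(pred$class == "dimer")) {
    expect_true(all(pred$separation[pred$class == "dimer"] >= 26))
    expect_true(all(pred$dumbbell_score[pred$class == "dimer"] > 0))
  }
})

test_that("evaluation scores perfect and degenerate predictions correctly", {
  truth <- data.frame(id = 1:3, class = c("monomer", "dimer", "monomer"),
                      x = c(100, 300, 500), y = 100, z = 100,
                      axis_x = NA, axis_y = NA, axis_z = NA, separation = NA)
  perfect <- data.frame(class = truth$class, x = truth$x, y = truth$y, z = truth$z)
  expect_equal(evaluate_classification(truth, perfect)$accuracy, 1)
  allmono <- transform(perfect, class = "monomer")
  rep2 <- evaluate_classification(truth, allmono)
  expect_equal(rep2$per_class$dimer[["recall"]], 0)
  expect_equal(rep2$accuracy, 2 / 3)
  # unmatched truth is a miss, unmatched prediction a false positive
  rep3 <- evaluate_classification(truth, perfect[1:2, ])
  expect_equal(rep3$misses, 1)
  rep4 <- evaluate_classification(truth, rbind(perfect,
                                               data.frame(class = "monomer", x = 900, y = 900, z = 900)))
  expect_equal(rep4$false_positives, 1)
  expect_error(evaluate_classification(truth, perfect, match_tolerance = 0))
})
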
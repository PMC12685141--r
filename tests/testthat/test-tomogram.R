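test_that("empty scenes are pure noise and scenes respect spacing", {
  sp0 <- scene_spec(pixel_size = 10, shape = c(40L, 40L, 40L), n_particles = 0L,
                    snr = 5, seed = 5)
  v0 <- generate_tomogram(sp0)
  expect_equal(mean(v0$density), 0, tolerance = 3 * (1 / 5) / sqrt(40^3))
  expect_equal(nrow(v0$truth), 0)

  sp <- scene_spec(pixel_size = 10, shape = c(64L, 64L, 64L), n_particles = 20L,
                   monomer_fraction = 0, dimer_fraction = 1,
                   dimer_separation_mean = 40, dimer_separation_sd = 0,
                   snr = 5, seed = 6, min_center_distance = 100)
  v <- generate_tomogram(sp)
  cen <- as.matrix(v$truth[, c("x", "y", "z")])
  expect_true(min(stats::dist(cen)) >= 100)
  # truth completeness: one record per requested particle, inside bounds
  expect_equal(nrow(v$truth), 20)
  expect_true(all(cen >= 0 & cen <= 630))
})

test_that("unplaceable scenes error with the achieved count", {
  sp <- scene_spec(pixel_size = 10, shape = c(24L, 24L, 24L), n_particles = 50L,
                   snr = 5, seed = 7, min_center_distance = 150)
  expect_error(generate_tomogram(sp, retry_cap = 50L), "placed")
})

test_that("identical spec and seed give bit-identical volumes", {
  sp <- scene_spec(pixel_size = 10, shape = c(32L, 32L, 32L), n_particles = 5L,
                   snr = 5, seed = 123, min_center_distance = 40,
                   tilt_range = c(-48, 48))
  v1 <- generate_tomogram(sp)
  v2 <- generate_tomogram(sp)
  expect_identical(v1$density, v2$density)
  expect_identical(v1$truth, v2$truth)
})

test_that("membrane slabs sit one cleft width apart and confine particles", {
  sp <- scene_spec(pixel_size = 10, shape = c(48L, 48L, 64L), n_particles = 10L,
                   snr = Inf, seed = 9, min_center_distance = 40,
                   membrane_pair = list(cleft_width = 280, restrict_to_cleft = TRUE))
  v <- generate_tomogram(sp)
  mids <- c(v$membranes$presynaptic$point[3], v$membranes$postsynaptic$point[3])
  expect_equal(abs(diff(mids)), 280)
  expect_true(all(v$truth$z > min(mids) & v$truth$z < max(mids)))
  # density shows high-density sheets at both mid-planes
  zprof <- apply(v$density, 3, mean)
  zs <- (seq_along(zprof) - 1) * 10
  sheet_level <- min(zprof[abs(zs - mids[1]) < 15], zprof[abs(zs - mids[2]) < 15])
  cleft_level <- stats::median(zprof[zs > min(mids) + 60 & zs < max(mids) - 60])
  expect_gt(sheet_level, cleft_level + 0.2)
})

test_that("a full tilt range leaves the volume untouched", {
  set.seed(1)
  arr <- array(stats::rnorm(16^3), dim = c(16, 16, 16))
  out <- apply_missing_wedge(arr, -90, 90)
  expect_equal(out, arr, tolerance = 1e-10)
  expect_error(apply_missing_wedge(arr, 30, 30), "strictly")
})

test_that("the missing wedge elongates the point response along z", {
  g <- seq_len(48) - 24.5
  blob <- exp(-outer(outer(g^2, g^2, "+"), g^2, "+") / (2 * 1.5^2))
  out <- apply_missing_wedge(blob, -48, 48)
  expect_true(is.numeric(out))           # Hermitian mask keeps it real
  width <- function(p) {
    p <- pmax(p, 0); x <- seq_along(p)
    m <- sum(x * p) / sum(p)
    sqrt(sum(p * (x - m)^2) / sum(p))
  }
  wz <- width(out[24, 24, ])
  expect_gt(wz, width(out[, 24, 24]))
  expect_gt(wz, width(out[24, , 24]))
})

test_that("wedge blurring weakens the dumbbell dip of z-oriented dimers", {
  sp <- scene_spec(pixel_size = 10, shape = c(48L, 48L, 48L), n_particles = 1L,
                   snr = Inf, seed = 1, min_center_distance = 0)
  ctr <- rep((48 - 1) / 2 * 10, 3)
  score_for <- function(axis) {
    tr <- particle_truth(1L, "dimer", ctr, axis = axis, separation = 40)
    vol <- render_scene(sp, list(tr))
    vol <- apply_missing_wedge(vol, -48, 48)
    sm <- nanodimer:::gaussian_smooth3d(vol$density, 5, 10)
    s <- seq(-50, 50, by = 1)
    pts <- cbind(ctr[1] + s * axis[1], ctr[2] + s * axis[2], ctr[3] + s * axis[3])
    nanodimer:::dumbbell_score_profile(
      data.frame(s = s, intensity = nanodimer:::trilinear(sm, pts / 10 + 1)))
  }
  expect_gt(score_for(c(1, 0, 0)), score_for(c(0, 0, 1)))
})
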
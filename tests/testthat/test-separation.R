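test_that("centroid splitting recovers symmetric dumbbells exactly", {
  spec <- fine_spec()
  m <- split_centroids(class_average(render_projection(centered_dimer(40), spec), 1, 10))
  expect_true(m$accepted)
  expect_equal(m$separation, 40, tolerance = 0.5)
  # centroids at +/- 20 Angstrom along the axis
  expect_equal(abs(m$centroid_b[1] - m$centroid_a[1]), 40, tolerance = 0.5)
  expect_gt(m$dumbbell_score, 0.1)
})

test_that("monomers are rejected for lacking a two-lobe profile", {
  spec <- fine_spec()
  m <- split_centroids(class_average(render_projection(centered_monomer(spec), spec), 1, 10))
  expect_false(m$accepted)
  expect_match(m$reason, "two-lobe")
})

test_that("separation is invariant to in-plane rotation", {
  spec <- fine_spec()
  seps <- vapply(c(0, 0.3, 37 * pi / 180, 1.1, 2.2, 2.9), function(th) {
    split_centroids(class_average(render_projection(centered_dimer(40, th), spec),
                                  1, 10))$separation
  }, numeric(1))
  expect_lt(diff(range(seps)), 0.5)
})

test_that("split centroids agree with an exhaustive two-disc template search", {
  spec <- fine_spec()
  for (true_sep in c(30, 34.8, 40, 44)) {
    img <- render_projection(centered_dimer(true_sep, theta = 0.4), spec)
    m <- split_centroids(class_average(img, 1, 10))
    # brute-force grid oracle: best-fitting rendered separation
    cand <- seq(26, 46, by = 0.25)
    sse <- vapply(cand, function(s) {
      sum((render_projection(centered_dimer(s, theta = 0.4), spec) - img)^2)
    }, numeric(1))
    expect_equal(m$separation, cand[which.min(sse)], tolerance = 0.5)
  }
})

test_that("axis profiles are symmetric with maxima at the lobe centers", {
  spec <- fine_spec()
  img <- render_projection(centered_dimer(40), spec)
  ca <- class_average(img, 1, 10)
  m <- split_centroids(ca)
  prof <- axis_profile(ca, m$centroid_a, m$centroid_b)
  expect_equal(prof$s, seq(-50, 50, by = 1))
  # even about the midpoint
  expect_equal(prof$intensity, rev(prof$intensity), tolerance = 0.02 * max(prof$intensity))
  expect_equal(prof$s[which.max(prof$intensity * (prof$s > 0))], 20, tolerance = 2)
  # constant image gives a constant profile (2 A pixels keep the sampled
  # +/- 50 A window inside the field of view)
  flat <- class_average(matrix(3, 96, 96), 2, 10)
  pf <- axis_profile(flat, c(70, 95), c(120, 95))
  expect_true(all(abs(pf$intensity - 3) < 1e-9))
  expect_error(axis_profile(ca, c(10, 10), c(10, 10)), "coincide")
})

test_that("separation histograms aggregate particle-weighted statistics", {
  mk <- function(sep, n) {
    structure(list(accepted = TRUE, separation = sep, n_particles = as.integer(n)),
              class = "separation_measurement")
  }
  single <- aggregate_separations(list(mk(34.8, 100)))
  expect_equal(single$mean, 34.8)
  expect_equal(single$sd, 0)
  expect_equal(single$counts[findInterval(34.8, seq(26, 46, 2))], 100)
  expect_equal(sum(single$counts), 100)

  two <- aggregate_separations(list(mk(30, 100), mk(40, 300)))
  expect_equal(two$mean, 37.5)
  expect_equal(sum(two$counts), 400)
  # representative defaults to the weighted mean but is overridable
  expect_equal(two$representative, 37.5)
  expect_equal(aggregate_separations(list(mk(30, 100), mk(40, 300)),
                                     representative = 40)$representative, 40)
  expect_warning(out <- aggregate_separations(list(mk(30, 10), mk(50, 5))),
                 "outside")
  expect_equal(out$overflow, 5)
  expect_equal(sum(out$counts), 10)
})

test_that("the class-average pipeline recovers generated separation statistics", {
  spec <- fine_spec(snr = 3, seed = 7)
  cas <- generate_class_set(spec, n_classes = 20, particles_per_class = 1000,
                            class = "dimer")
  h <- aggregate_separations(lapply(cas, split_centroids))
  true_sep <- vapply(cas, function(ca) ca$truth$separation, numeric(1))
  w <- vapply(cas, function(ca) ca$n_particles, integer(1))
  expect_lt(abs(h$mean - sum(true_sep * w) / sum(w)), 0.5)
  expect_lt(abs(h$sd - nanodimer:::weighted_sd(true_sep, w)), 1.0)
  expect_equal(h$n_particles, 20000)
})
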
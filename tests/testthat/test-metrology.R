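test_that("recentering is a fixed point and corrects subpixel offsets", {
  spec <- fine_spec()
  ca <- class_average(render_projection(centered_monomer(spec), spec), 1, 10)
  rc <- recenter(ca)
  expect_equal(rc$image, ca$image, tolerance = 1e-6)
  # disc offset by (3.4, -2.1) px comes back to center within 0.01 px
  off <- particle_truth(1L, "monomer", c(47.5 + 3.4, 47.5 - 2.1))
  ca2 <- class_average(render_projection(off, spec), 1, 10)
  rc2 <- recenter(ca2)
  cen <- nanodimer:::centroid_px(nanodimer:::prepare_image(rc2$image))
  expect_lt(max(abs(cen - (dim(rc2$image) + 1) / 2)), 0.01)
  # pure noise has no reliable centroid
  set.seed(2)
  noise <- class_average(matrix(stats::rnorm(96^2), 96, 96), 1, 10)
  expect_error(recenter(noise), "centroid|intensity")
})

test_that("radial profiles reproduce step and chord-length references", {
  # binary disc: 1 inside radius 10, 0 outside
  d <- matrix(0, 65, 65)
  ctr <- 33
  d[(row(d) - ctr)^2 + (col(d) - ctr)^2 <= 10^2] <- 1
  prof <- radial_profile(class_average(d, 1, 10))
  expect_true(all(prof$mean_intensity[prof$radii <= 8] > 0.99))
  expect_true(all(prof$mean_intensity[prof$radii >= 12] < 0.01))
  # noiseless projected sphere follows the chord profile within 1%
  # (half-Angstrom pixels so annulus averaging stays below the tolerance)
  spec <- scene_spec(pixel_size = 0.5, shape = c(193L, 193L),
                     monomer_radius = 13.2, snr = Inf, seed = 1L)
  img <- render_projection(particle_truth(1L, "monomer", c(48, 48)), spec)
  prof2 <- radial_profile(class_average(img, 0.5, 10))
  r <- prof2$radii
  keep <- r <= 0.9 * 13.2
  expect_lt(max(abs(prof2$mean_intensity[keep] -
                      sqrt(1 - (r[keep] / 13.2)^2))), 0.01)
  # degenerate weights select a single class
  other <- class_average(img * 0.37, 1, 10)
  both <- radial_profile(list(class_average(img, 1, 10), other),
                         weights = c(1000, 0))
  expect_equal(both$mean_intensity, prof2$mean_intensity, tolerance = 1e-12)
  expect_error(radial_profile(list(class_average(img, 1, 10),
                                   class_average(img, 2, 10))),
               "pixel size")
})

test_that("cutoff radii invert a step disc and the projected-sphere chord law", {
  d <- matrix(0, 65, 65)
  d[(row(d) - 33)^2 + (col(d) - 33)^2 <= 10^2] <- 1
  cut <- cutoff_radii(radial_profile(class_average(d, 1, 10)))
  # the half-intensity crossing sits on the edge annulus; lower fractions
  # land in the one-pixel aliasing band of the hard edge
  expect_lt(abs(cut$r["r50"] - 10), 0.5)
  expect_true(all(abs(cut$r - 10) <= 1))
  # projected sphere: r_f = R sqrt(1 - f^2)
  spec <- fine_spec(shape = c(97L, 97L))
  img <- render_projection(particle_truth(1L, "monomer", c(48, 48)), spec)
  cut2 <- cutoff_radii(radial_profile(class_average(img, 1, 10)))
  expected <- 13.2 * sqrt(1 - c(0.5, 0.2, 0.1)^2)
  expect_true(all(abs(cut2$r - expected) <= 0.5 * spec$pixel_size))
  expect_true(cut2$r["r50"] <= cut2$r["r20"])
  expect_true(cut2$r["r20"] <= cut2$r["r10"])
  # a profile that never falls below the fraction errors by name
  flat_prof <- radial_profile(class_average(matrix(1, 33, 33) +
                                              diag(33) * 1e-3, 1, 10))
  expect_error(cutoff_radii(flat_prof, fractions = 0.5), "falls below")
})
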
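test_that("Monte-Carlo pair distance distribution matches the closed-form sphere law", {
  set.seed(42)
  R <- 12.5
  r <- seq(0.25, 30, by = 0.5)
  mc <- pddf_direct(sphere_model(R), r, n_pairs = 5e5)
  analytic <- nanodimer:::sphere_pddf_analytic(r, R)
  expect_lt(sqrt(mean((mc$p_r - analytic)^2)) / max(analytic), 0.02)
  # support ends at the diameter; peak near 0.525 D
  expect_true(all(mc$p_r[r > 2 * R + 0.5] == 0))
  expect_equal(r[which.max(mc$p_r)], 0.525 * 2 * R, tolerance = 0.05)
})

test_that("dimer pair distances span to 2R + d with a lower second peak", {
  set.seed(43)
  r <- seq(0.5, 80, by = 1)
  mc <- pddf_direct(dimer_model(sphere_model(12.5), 40), r, n_pairs = 5e5)
  expect_equal(mc$dmax_true, 65)
  expect_true(all(mc$p_r[r > 66] == 0))
  expect_gt(sum(mc$p_r[r > 63 & r < 66]), 0)  # support reaches ~65
  # two-peak structure: self-distance peak below 25, cross peak near 40
  p1 <- max(mc$p_r[r < 25])
  p2 <- max(mc$p_r[r > 30 & r < 55])
  expect_gt(p2, 0)
  expect_lt(p2, p1)
})

test_that("indirect transform inverts a noiseless sphere profile", {
  prof <- sphere_intensity(sphere_model(12.86), q_default)
  res <- pddf_moore(prof, dmax_scan = seq(15, 60, by = 1))
  # R_g of a homogeneous sphere is sqrt(3/5) R
  expect_equal(res$rg, sqrt(3 / 5) * 12.86, tolerance = 0.01)
  # sine basis pins the endpoints
  expect_equal(res$p_r[1], 0, tolerance = 1e-10)
  expect_equal(res$p_r[length(res$p_r)], 0, tolerance = 1e-10)
  # I0 = 4 pi Int p dr reproduces the forward intensity
  expect_equal(res$i0, sphere_intensity(sphere_model(12.86), c(0, 0.01))$intensity[1],
               tolerance = 0.01)
  # recovered p(r) matches the Monte-Carlo oracle
  set.seed(44)
  mc <- pddf_direct(sphere_model(12.86), seq(0.5, 26, by = 0.5), n_pairs = 5e5)
  pm <- stats::approx(res$r, res$p_r / nanodimer:::trapz(res$r, res$p_r),
                      xout = mc$r, rule = 2)$y
  expect_lt(sqrt(mean((pm - mc$p_r)^2)) / max(mc$p_r), 0.02)
})

test_that("indirect transform recovers dimer geometry and parallel-axis Rg", {
  prof <- dimer_intensity(dimer_model(sphere_model(12.5), 40), q_default)
  res <- pddf_moore(prof, dmax_scan = seq(40, 100, by = 1))
  # parallel-axis law: Rg^2 = Rg_sphere^2 + (d/2)^2
  expect_equal(res$rg, sqrt((sqrt(3 / 5) * 12.5)^2 + 20^2), tolerance = 0.02)
  # two peaks, the second lower, the first near the monomer radius
  peaks <- which(diff(sign(diff(res$p_r))) == -2) + 1
  peaks <- peaks[res$p_r[peaks] > 0.05 * max(res$p_r)]
  expect_gte(length(peaks), 2)
  expect_equal(res$r[peaks[1]], 12.5, tolerance = 0.08)
  expect_lt(res$p_r[peaks[2]], res$p_r[peaks[1]])
  # oracle equivalence on the dimer
  set.seed(45)
  mc <- pddf_direct(dimer_model(sphere_model(12.5), 40), seq(0.5, 65, by = 1),
                    n_pairs = 5e5)
  pm <- stats::approx(res$r, res$p_r / nanodimer:::trapz(res$r, res$p_r),
                      xout = mc$r, rule = 2)$y
  expect_lt(sqrt(mean((pm - mc$p_r)^2)) / max(mc$p_r), 0.02)
})

test_that("noise raises the misfit but leaves D_max stable at high SNR", {
  prof <- dimer_intensity(dimer_model(sphere_model(12.5), 40), q_default)
  clean <- pddf_moore(prof, dmax_scan = seq(45, 90, by = 1))
  dmaxes <- numeric(3)
  for (s in 1:3) {
    set.seed(s)
    noisy <- saxs_profile(prof$q, prof$intensity * (1 + stats::rnorm(length(prof$q), sd = 0.02)),
                          sigma = 0.02 * prof$intensity)
    res <- pddf_moore(noisy, dmax_scan = seq(45, 90, by = 1))
    expect_gt(res$residual, clean$residual)
    dmaxes[s] <- res$dmax
  }
  expect_lt(abs(stats::median(dmaxes) - 65) / 65, 0.05)
})

test_that("degenerate inversion requests fail loudly", {
  prof <- sphere_intensity(sphere_model(12.5), seq(0.01, 0.03, by = 0.01))
  expect_error(pddf_moore(prof, dmax_scan = c(-5, 10)), "positive")
  expect_error(pddf_moore(prof, dmax_scan = 25, n_terms = 2), "at least 3")
})
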
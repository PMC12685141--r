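test_that("plane and mesh distances agree with closed forms", {
  pl <- membrane_plane(c(0, 0, 0), c(0, 0, 1))
  expect_equal(shortest_distance(c(0, 0, 100), pl), 100)
  expect_equal(shortest_distance(c(5, -3, 0), pl), 0)
  # mesh tessellation of the same plane
  vt <- rbind(c(-500, -500, 0), c(500, -500, 0), c(500, 500, 0), c(-500, 500, 0))
  msh <- membrane_mesh(vt, rbind(c(1, 2, 3), c(1, 3, 4)))
  set.seed(1)
  for (i in 1:20) {
    p <- c(stats::runif(2, -400, 400), stats::runif(1, -200, 200))
    expect_equal(shortest_distance(p, msh), shortest_distance(p, pl),
                 tolerance = 1e-6)
  }
  # off-patch points fall back to edge/vertex distances (>= plane distance)
  expect_gte(shortest_distance(c(700, 0, 50), msh),
             shortest_distance(c(700, 0, 50), pl))
  expect_error(membrane_mesh(vt, matrix(c(1, 2, 9), 1)), "indices")
})

test_that("distances are invariant under joint rigid motion", {
  set.seed(3)
  vt <- matrix(stats::runif(12, -100, 100), 4, 3)
  msh <- membrane_mesh(vt, rbind(c(1, 2, 3), c(2, 3, 4)))
  p <- c(10, 20, 150)
  d0 <- shortest_distance(p, msh)
  th <- 0.7
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  shift <- c(40, -25, 13)
  msh2 <- membrane_mesh(t(Rz %*% t(vt)) + rep(shift, each = 4), msh$faces)
  expect_equal(shortest_distance(drop(Rz %*% p) + shift, msh2), d0,
               tolerance = 1e-6)
})

test_that("distance statistics recover the generating distribution", {
  set.seed(11)
  sc <- simulate_label_distances(n = 93)
  st <- distance_stats(sc$centers, sc$membrane, range = c(110, 190))
  se <- 28 / sqrt(93)
  expect_lt(abs(st$mean - 156), 2 * se)
  expect_lt(abs(st$sd - 28) / 28, 0.2)
  # fraction in the reach interval matches the normal-probability oracle
  oracle <- stats::pnorm((190 - 156) / 28) - stats::pnorm((110 - 156) / 28)
  expect_lt(abs(st$fraction_in_range - oracle), 3 * sqrt(oracle * (1 - oracle) / 93))
  # singleton
  one <- distance_stats(matrix(c(0, 0, 150), 1), sc$membrane)
  expect_equal(one$mean, 150)
  expect_equal(one$sd, 0)
  expect_equal(one$n, 1)
})

test_that("replicate scenes center on the generating mean distance", {
  set.seed(12)
  means <- replicate(200, {
    sc <- simulate_label_distances(n = 93)
    mean(distance_stats(sc$centers, sc$membrane)$distances)
  })
  expect_lt(abs(mean(means) - 156), 1)
})

test_that("cleft widths are exact for parallel planes and vary when tilted", {
  pre <- membrane_plane(c(0, 0, 280), c(0, 0, 1))
  post <- membrane_plane(c(0, 0, 0), c(0, 0, 1))
  cw <- cleft_width(pre, post, patch_extent = 100)
  expect_true(all(abs(cw$widths - 280) < 1e-9))
  expect_equal(cw$mean, 280)
  expect_equal(cw$sd, 0)
  # tilting the sampled membrane spreads the shortest-distance widths
  tilted <- membrane_plane(c(0, 0, 0), c(sin(5 * pi / 180), 0, cos(5 * pi / 180)))
  cw2 <- cleft_width(pre, tilted, patch_extent = 100)
  expect_gt(cw2$sd, 0)
  expect_equal(cw2$mean, 280, tolerance = 0.01 * 280)
  # identical membranes: zero width everywhere
  cw3 <- cleft_width(post, post, patch_extent = 50)
  expect_true(all(cw3$widths < 1e-9))
})

test_that("condition comparison has correct null behavior and power", {
  same <- list(widths = rep(280, 50))
  id <- compare_conditions(same, same)
  expect_equal(id$statistic, 0)
  expect_equal(id$p_value, 1)
  # type-I error near the nominal 5% over 1000 null replicates
  set.seed(13)
  rej <- mean(replicate(1000, {
    compare_conditions(list(widths = stats::rnorm(50, 280, 10)),
                       list(widths = stats::rnorm(50, 280, 10)))$p_value < 0.05
  }))
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.07)
  # a 5 nm shift at SD 1 nm is detected overwhelmingly
  set.seed(14)
  p <- compare_conditions(list(widths = stats::rnorm(50, 280, 10)),
                          list(widths = stats::rnorm(50, 330, 10)))$p_value
  expect_lt(p, 1e-10)
  expect_error(compare_conditions(list(widths = 1), same), "at least two")
})
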
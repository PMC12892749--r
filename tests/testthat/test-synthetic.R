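test_that("lead-field columns match a naive evaluation of the sphere formula", {
  hd <- default_head(16)
  lf <- make_lead_field(hd)
  for (q in c(1L, 7L, 16L)) {
    v <- vapply(seq_len(21), function(s)
      naive_sphere_potential(hd$sensor_positions[s, ],
                             hd$source_positions[q, ],
                             hd$source_orientations[q, ]), 0)
    expect_lt(max(abs(v - lf$G[, q])), 1e-8)
  }
})

test_that("central radial dipole produces zero scalp potential", {
  pos <- matrix(0, 1, 3)
  hd <- spherical_head(montage_1020(), pos, radial_orientations(pos))
  lf <- make_lead_field(hd)
  expect_equal(max(abs(lf$G)), 0)
})

test_that("mirror-symmetric sources give mirror-symmetric lead-field columns", {
  # sensors symmetric about x = 0; source pair mirrored through that plane
  sens <- rbind(c(0.6, 0.64, 0.48), c(-0.6, 0.64, 0.48),
                c(0, 0, 1), c(0, -0.8, 0.6))
  sens <- sens / sqrt(rowSums(sens^2))
  pos <- rbind(c(0.4, 0.3, 0.2), c(-0.4, 0.3, 0.2))
  ori <- radial_orientations(pos)
  lf <- make_lead_field(spherical_head(sens, pos, ori))
  # swapping the mirrored sensors maps column 1 onto column 2
  expect_equal(lf$G[c(2, 1, 3, 4), 1], lf$G[, 2], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("sources on or outside the sphere are rejected", {
  expect_error(spherical_head(montage_1020(), matrix(c(1, 0, 0), 1),
                              matrix(c(1, 0, 0), 1)),
               "source on/outside")
})

test_that("zero coupling with white innovations gives uncorrelated regions", {
  scn <- sim_scenario(8, 1, matrix(0, 8, 8),
                      cbind(delta = rep(0, 8), alpha = rep(0, 8)),
                      duration = 60, rate = 256, seed = 5)
  src <- simulate_sources(scn)
  cc <- cor(t(src$x)); diag(cc) <- 0
  expect_lt(max(abs(cc)), 0.05)
})

test_that("a x4 delta drive shows up in an independently computed spectrum", {
  scn <- scenario_preictal(n_regions = 8, driver = 2, delta_gain = 4,
                           duration = 60, rate = 256, seed = 3)
  src <- simulate_sources(scn)
  # independent PSD: stats::spec.pgram, not the package's Welch code
  delta_power <- vapply(seq_len(8), function(i) {
    sp <- stats::spec.pgram(stats::ts(src$x[i, ], frequency = 256),
                            spans = 25, plot = FALSE, taper = 0.1)
    mean(sp$spec[sp$freq >= 1 & sp$freq < 4])
  }, 0)
  expect_gt(delta_power[2], 2 * median(delta_power[-2]))
})

test_that("source simulation is bit-reproducible given the seed", {
  scn <- scenario_preictal(n_regions = 6, duration = 10, seed = 77)
  expect_identical(simulate_sources(scn)$x, simulate_sources(scn)$x)
})

test_that("unstable coupling is rejected with the spectral radius named", {
  C <- diag(1.05, 4)
  expect_error(sim_scenario(4, 1, C, cbind(delta = rep(1, 4),
                                           alpha = rep(1, 4))),
               "spectral radius")
})

test_that("scalp projection respects the requested SNR and the noise-free limit", {
  scn <- sim_scenario(8, 1, matrix(0, 8, 8),
                      cbind(delta = rep(1, 8), alpha = rep(1, 8)),
                      duration = 60, rate = 256, seed = 5)
  src <- simulate_sources(scn)
  lf <- make_lead_field(default_head(8))
  clean <- project_to_scalp(src, lf, snr = Inf)
  expect_equal(clean$samples, lf$G %*% src$x)
  noisy <- project_to_scalp(src, lf, snr = 5, seed = 2)
  noise <- noisy$samples - lf$G %*% src$x
  emp <- mean((lf$G %*% src$x)^2) / mean(noise^2)
  expect_lt(abs(emp - 5) / 5, 0.1)
  zero <- region_ts(matrix(0, 8, 2560), rate = 256)
  pure <- project_to_scalp(zero, lf, snr = Inf)
  expect_equal(max(abs(pure$samples)), 0)
  expect_error(project_to_scalp(src, make_lead_field(default_head(6)), 5),
               "sources")
})

test_that("bistable simulator fixed point, basin of attraction and noise validation", {
  tr <- simulate_bistable(matrix(0, 1, 1), D = 0, t_max = 5, x0 = -1)
  expect_equal(max(abs(tr$x + 1)), 0)
  tr2 <- simulate_bistable(matrix(0, 1, 1), D = 0, t_max = 30, x0 = 0.5)
  expect_equal(tr2$x[1, ncol(tr2$x)], 1, tolerance = 1e-6)
  expect_error(simulate_bistable(matrix(0, 1, 1), D = -0.1), ">= 0")
  t1 <- simulate_bistable(matrix(0, 2, 2), D = 0.2, seed = 4, t_max = 5)
  t2 <- simulate_bistable(matrix(0, 2, 2), D = 0.2, seed = 4, t_max = 5)
  expect_identical(t1$x, t2$x)
})

test_that("single-node stationary density matches the Boltzmann distribution", {
  tr <- simulate_bistable(matrix(0, 1, 1), D = 0.25, seed = 11,
                          t_max = 20000, dt = 0.01)
  xs <- sort(tr$x[1, seq(1, ncol(tr$x), by = 50)])
  V <- function(x) x^4 / 4 - x^2 / 2
  Z <- stats::integrate(function(x) exp(-V(x) / 0.25), -4, 4)$value
  cdf <- vapply(xs, function(q)
    stats::integrate(function(x) exp(-V(x) / 0.25), -4, q)$value / Z, 0)
  ks <- max(abs(seq_along(xs) / length(xs) - cdf))
  expect_lt(ks, 0.05)
})
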
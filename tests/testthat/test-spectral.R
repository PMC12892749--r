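test_that("Welch density integrates to the variance (Parseval)", {
  set.seed(2)
  x <- matrix(rnorm(60 * 256), 1)
  p <- welch_psd(x, window_s = 2, overlap = 0.5, rate = 256)
  expect_lt(abs(sum(p$psd_raw) * diff(p$freqs[1:2]) - 1), 0.1)
})

test_that("a pure tone peaks at its bin and power scales quadratically", {
  rate <- 256
  tone <- matrix(sin(2 * pi * 10 * (0:(20 * rate - 1)) / rate), 1)
  p1 <- welch_psd(tone, rate = rate)
  expect_equal(p1$freqs[which.max(p1$psd_raw[1, ])], 10)
  p2 <- welch_psd(2 * tone, rate = rate)
  expect_equal(p2$psd_raw, 4 * p1$psd_raw, tolerance = 1e-9)
  expect_error(welch_psd(tone[, 1:100, drop = FALSE], window_s = 2,
                         rate = rate), "longer than the signal")
})

test_that("PSD of concatenated identical epochs matches one epoch", {
  set.seed(6)
  ep <- matrix(rnorm(512), 1)
  one <- welch_psd(ep, window_s = 2, overlap = 0, rate = 256)
  many <- welch_psd(cbind(ep, ep, ep, ep), window_s = 2, overlap = 0,
                    rate = 256)
  expect_equal(one$psd_raw, many$psd_raw, tolerance = 1e-9)
})

test_that("band aggregation averages density then converts to dB", {
  fake <- structure(list(psd_raw = matrix(1, 1, 81), freqs = 0:80,
                         rate = 256), class = "band_psd")
  agg <- band_aggregate(fake)
  expect_equal(unname(agg[1, ]), rep(0, 6))  # flat density 1 -> 0 dB/Hz
  # half-open band rule: [1, 4) excludes the 4 Hz bin
  fake2 <- fake; fake2$psd_raw[1, fake$freqs == 4] <- 1e6
  agg2 <- band_aggregate(fake2)
  expect_equal(unname(agg2[1, "delta"]), 0)
  expect_gt(agg2[1, "theta"], 10)
  # empty band errors
  coarse <- structure(list(psd_raw = matrix(1, 1, 9),
                           freqs = seq(0, 80, by = 10), rate = 256),
                      class = "band_psd")
  expect_error(band_aggregate(coarse), "no frequency bins")
})

test_that("delta-dominated signals stand out by > 10 dB in the delta band", {
  scn <- scenario_preictal(n_regions = 4, driver = 1, delta_gain = 50,
                           duration = 60, seed = 9)
  src <- simulate_sources(scn)
  agg <- band_aggregate(welch_psd(src))
  expect_gt(agg[1, "delta"] - max(agg[1, c("beta", "low_gamma")]), 10)
})

test_that("band scheme validates edges and ordering", {
  expect_error(band_scheme(data.frame(name = "a", lo = 4, hi = 2)),
               "lo < hi")
  expect_error(band_scheme(data.frame(name = c("a", "b"), lo = c(1, 3),
                                      hi = c(4, 8))), "overlap")
  sch <- band_scheme()
  expect_equal(sch$lo[sch$name == "delta"], 1)
  expect_equal(sch$hi[sch$name == "delta"], 4)
})

test_that("Hilbert envelope and phase behave as the analytic signal", {
  rate <- 256
  t <- 0:(10 * rate - 1) / rate
  x <- matrix(3 * cos(2 * pi * 8 * t), 1)
  a <- hilbert_analytic(x)
  core <- seq(round(0.05 * length(t)), round(0.95 * length(t)))
  expect_lt(max(abs(a$amplitude[1, core] - 3)) / 3, 0.01)
  # envelope is sign-invariant
  a2 <- hilbert_analytic(-x)
  expect_equal(a2$amplitude, a$amplitude, tolerance = 1e-9)
  # phase advances by 2 pi f / rate per sample
  dphi <- diff(a$phase[1, core])
  dphi <- (dphi + pi) %% (2 * pi) - pi
  expect_lt(median(abs(dphi - 2 * pi * 8 / rate)), 1e-3)
  expect_true(all(a$phase > -pi & a$phase <= pi + 1e-12))
})

test_that("band powers of independent signals stay uncorrelated", {
  # 120 regions keeps the null sampling error of each correlation
  # (~1/sqrt(n)) small enough that the 0.3 bound is a sharp test of
  # independence rather than of luck
  n <- 120
  scn <- sim_scenario(n, 1, matrix(0, n, n),
                      cbind(delta = rep(1, n), alpha = rep(1, n)),
                      duration = 30, rate = 256, seed = 13)
  src <- simulate_sources(scn)
  agg <- band_aggregate(welch_psd(src))
  cc <- cor(agg)
  diag(cc) <- 0
  expect_lt(max(abs(cc)), 0.3)
})
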
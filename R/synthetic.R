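#' Simulation scenario for ground-truthed preictal EEG
#'
#' Describes a synthetic preictal recording with one or more planted
#' "driver" regions: regions with elevated, burst-modulated delta-band
#' (1--4 Hz) source power that exert lagged directed influence on a set of
#' target regions. Downstream stages should recover the driver as the top
#' delta-band outflow hub and the top seizure-index region.
#'
#' Source dynamics are an MVAR(1) recursion
#'   x_t = C x_{t-1} + e_t,
#' where `coupling` C (target row, source column) carries the directed
#' structure, and the innovations e_t are band-shaped: per region, white
#' noise plus AR(2) resonator components for the alpha band (all regions)
#' and the delta band (gain set by `band_profile`). The driver's delta
#' component is multiplied by a slow periodic burst envelope, emulating
#' intermittent preictal rhythmic delta activity; continuous stationary
#' delta would leave the Hilbert-envelope statistics used by the seizure
#' index uninformative (the envelope of a stationary Gaussian process is
#' Rayleigh whatever its power).
#'
#' @param n_regions number of cortical regions (default 68).
#' @param driver_regions integer ids of planted drivers (non-empty).
#' @param coupling n x n lagged coefficient matrix, entry (i, j) = effect
#'   of region j at time t-1 on region i at time t. Spectral radius of the
#'   companion matrix must be < 1.
#' @param band_profile n x 2 matrix (columns `delta`, `alpha`) of power
#'   multipliers for the per-region innovation resonators.
#' @param noise_sd white innovation scale (microvolt-scale units).
#' @param sensor_snr broadband signal-to-noise power ratio at the sensors.
#' @param duration recording length in seconds (default 600, the 10-min
#'   preictal window).
#' @param rate sampling rate, samples/second (default 256).
#' @param burst list with `period` (s) and `depth` in [0, 1): burst
#'   envelope for the driver's delta drive, `1 + depth * cos` shaped.
#' @param seed integer RNG seed.
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(n_regions, driver_regions, coupling, band_profile,
                         noise_sd = 1, sensor_snr = 5, duration = 600,
                         rate = 256, burst = list(period = 10, depth = 0.85),
                         seed = 1L) {
  stopifnot(duration > 0, rate > 0, length(driver_regions) >= 1)
  coupling <- as.matrix(coupling)
  stopifnot(nrow(coupling) == n_regions, ncol(coupling) == n_regions)
  sr <- max(Mod(eigen(coupling, only.values = TRUE)$values))
  if (sr >= 1)
    stop("unstable coupling matrix: spectral radius ", signif(sr, 4),
         " >= 1")
  structure(list(n_regions = n_regions,
                 driver_regions = as.integer(driver_regions),
                 coupling = coupling, band_profile = band_profile,
                 noise_sd = noise_sd, sensor_snr = sensor_snr,
                 duration = duration, rate = rate, burst = burst,
                 seed = as.integer(seed)),
            class = "sim_scenario")
}

#' Default preictal scenario with one planted delta driver
#'
#' Study conditions: 68 regions, 10 min at 256 Hz, one driver region
#' coupled to `n_targets` randomly chosen targets with lag-1 coefficient
#' `coupling_strength`, delta drive `delta_gain` times the background
#' (power), burst-modulated, sensor SNR 5. The reduced profile
#' (`n_regions = 16`, `duration = 60`) is used for fast tests.
#'
#' @param n_regions,duration,rate,sensor_snr,seed see [sim_scenario].
#' @param driver driver region id (default 1).
#' @param n_targets number of regions the driver projects to.
#' @param coupling_strength lag-1 MVAR coefficient driver -> target.
#' @param delta_gain delta-band innovation power multiplier for the driver.
#' @return A [sim_scenario].
#' @export
scenario_preictal <- function(n_regions = 68L, driver = 1L, n_targets = 5L,
                              coupling_strength = 0.35, delta_gain = 8,
                              duration = 600, rate = 256, sensor_snr = 5,
                              seed = 1L) {
  C <- matrix(0, n_regions, n_regions)
  others <- setdiff(seq_len(n_regions), driver)
  set.seed(seed + 104729L)
  targets <- sample(others, min(n_targets, length(others)))
  C[targets, driver] <- coupling_strength
  bp <- cbind(delta = rep(1, n_regions), alpha = rep(1, n_regions))
  bp[driver, "delta"] <- delta_gain
  sim_scenario(n_regions, driver, C, bp, sensor_snr = sensor_snr,
               duration = duration, rate = rate, seed = seed)
}

# AR(2) resonator filter coefficients for a peak at f0 Hz, pole radius rho
resonator_coef <- function(f0, rate, rho) {
  c(2 * rho * cos(2 * pi * f0 / rate), -rho^2)
}

#' Simulate region-level source time series from a scenario
#'
#' Runs the scenario's MVAR recursion with band-shaped innovations (see
#' [sim_scenario]); the first 4 s are discarded as burn-in. Bit-reproducible
#' given the scenario seed.
#'
#' @param scn a [sim_scenario].
#' @return A [region_ts] (regions x time).
#' @export
simulate_sources <- function(scn) {
  stopifnot(inherits(scn, "sim_scenario"))
  n <- scn$n_regions
  rate <- scn$rate
  burn <- 4 * rate
  len <- round(scn$duration * rate) + burn
  set.seed(scn$seed)

  delta_c <- resonator_coef(2.5, rate, 0.98)
  alpha_c <- resonator_coef(10, rate, 0.95)
  # resonator gain normalization so unit-variance input gives roughly
  # unit-variance output (empirical variance of the AR(2) response)
  g_delta <- 1 / sd(stats::filter(rnorm(8192), delta_c, method = "recursive"))
  g_alpha <- 1 / sd(stats::filter(rnorm(8192), alpha_c, method = "recursive"))

  E <- matrix(0, n, len)
  tsec <- seq_len(len) / rate
  burst_env <- 1 + scn$burst$depth * cos(2 * pi * tsec / scn$burst$period)
  for (i in seq_len(n)) {
    white <- rnorm(len, sd = scn$noise_sd)
    dl <- as.numeric(stats::filter(rnorm(len), delta_c,
                                   method = "recursive")) * g_delta
    al <- as.numeric(stats::filter(rnorm(len), alpha_c,
                                   method = "recursive")) * g_alpha
    dgain <- sqrt(scn$band_profile[i, "delta"])
    again <- sqrt(scn$band_profile[i, "alpha"])
    if (i %in% scn$driver_regions) dl <- dl * burst_env
    E[i, ] <- white + dgain * dl + again * al
  }
  X <- matrix(0, n, len)
  X[, 1] <- E[, 1]
  C <- scn$coupling
  if (all(C == 0)) {
    X <- E
  } else {
    for (t in 2:len) X[, t] <- C %*% X[, t - 1] + E[, t]
  }
  region_ts(X[, (burn + 1):len, drop = FALSE], rate = rate)
}

#' Project region sources to the scalp and add sensor noise
#'
#' Sensor signals are `G x` plus white Gaussian sensor noise scaled so that
#' the ratio of mean broadband signal power to noise power (across
#' channels) equals `snr`. `snr = Inf` gives noise-free sensors.
#'
#' @param src a [region_ts] of source signals.
#' @param lf a [lead_field] with one column per region.
#' @param snr signal-to-noise power ratio (> 0 or `Inf`).
#' @param seed RNG seed for the sensor noise.
#' @return An [eeg_recording].
#' @export
project_to_scalp <- function(src, lf, snr = 5, seed = 1L) {
  stopifnot(inherits(src, "region_ts"), inherits(lf, "lead_field"))
  if (ncol(lf$G) != nrow(src$x))
    stop("lead field has ", ncol(lf$G), " sources but ", nrow(src$x),
         " region series supplied")
  Y <- lf$G %*% src$x
  if (is.finite(snr)) {
    stopifnot(snr > 0)
    sig_pow <- mean(Y^2)
    set.seed(seed)
    Y <- Y + matrix(rnorm(length(Y), sd = sqrt(sig_pow / snr)),
                    nrow(Y), ncol(Y))
  }
  eeg_recording(Y, rate = src$rate, channel_names = lf$sensor_names)
}

#' Euler--Maruyama trajectories of the coupled bistable node model
#'
#' Integrates, from all nodes at the resting attractor x = -1,
#'   dx_i = [ x_i - x_i^3 + c * sum_j W[j,i] x_j ] dt + sqrt(2 D_i) dW_i .
#' Each node has the double-well potential V(x) = x^4/4 - x^2/2 (stable
#' states at -1 and +1, barrier at 0). This direct-coupling variant is the
#' generator/oracle used in tests; the seizure-index integrator
#' ([escape_times]) uses diffusive coupling.
#'
#' @param coupling n x n weight matrix, entry (j, i) = weight j -> i; may
#'   be a scalar 0 for uncoupled nodes.
#' @param D per-node noise intensities (>= 0), recycled to n.
#' @param seed integer RNG seed.
#' @param t_max integration horizon, model-time units.
#' @param dt Euler--Maruyama step (default 0.01).
#' @param c coupling gain (default 1).
#' @param x0 initial state, recycled to n (default -1).
#' @param n number of nodes (inferred from `coupling`/`D` if omitted).
#' @return list with `t` (time grid) and `x` (n x length(t) trajectories).
#' @export
simulate_bistable <- function(coupling, D, seed = 1L, t_max = 100,
                              dt = 0.01, c = 1, x0 = -1, n = NULL) {
  if (is.null(n))
    n <- if (is.matrix(coupling)) nrow(coupling) else length(D)
  if (!is.matrix(coupling)) coupling <- matrix(coupling, n, n)
  D <- rep_len(D, n)
  if (any(D < 0)) stop("noise intensities D must be >= 0")
  stopifnot(t_max > dt, dt > 0)
  n_steps <- floor(t_max / dt)
  x <- rep_len(x0, n)
  out <- matrix(0, n, n_steps + 1L)
  out[, 1] <- x
  tW <- t(coupling)
  sig <- sqrt(2 * D * dt)
  set.seed(seed)
  for (k in seq_len(n_steps)) {
    drift <- x - x^3 + c * (tW %*% x)[, 1]
    x <- x + drift * dt + sig * rnorm(n)
    out[, k + 1L] <- x
  }
  list(t = dt * (0:n_steps), x = out)
}
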
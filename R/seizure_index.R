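#' Seizure-index configuration
#'
#' Parameters of the coupled bistable escape-time model. Each region is a
#' particle in the double-well potential V(x) = x^4/4 - x^2/2 (resting
#' attractor -1, seizure attractor +1, barrier at 0) driven by white noise
#' whose intensity comes from the region's Hilbert-envelope variability,
#' and coupled diffusively through the band's DTF network.
#'
#' @param coupling_gain network coupling gain c (default 0.5).
#' @param n_realizations Monte-Carlo realizations R (default 200).
#' @param t_max horizon in model-time units (default 100); realizations
#'   that never escape are censored at t_max.
#' @param dt Euler--Maruyama step (default 0.01).
#' @param seed integer RNG seed (default 1234).
#' @param d0 baseline noise intensity of the envelope-CV map (default 0.1).
#' @param threshold escape threshold on x (default 0.5): the trajectory
#'   has crossed the barrier and committed to the seizure basin. The
#'   attractor itself (+1) is approached only asymptotically (the drift
#'   vanishes there), so first passage to +1 is not a well-defined escape
#'   time.
#' @param cutoff normalized-SI threshold for the epileptogenic set
#'   (default 0.95).
#' @return An object of class `si_config`.
#' @export
si_config <- function(coupling_gain = 0.5, n_realizations = 200L,
                      t_max = 100, dt = 0.01, seed = 1234L, d0 = 0.1,
                      threshold = 0.5, cutoff = 0.95) {
  stopifnot(n_realizations >= 1, dt > 0, t_max > dt)
  structure(list(coupling_gain = coupling_gain,
                 n_realizations = as.integer(n_realizations),
                 t_max = t_max, dt = dt, seed = as.integer(seed),
                 d0 = d0, threshold = threshold, cutoff = cutoff),
            class = "si_config")
}

#' Map Hilbert-envelope variability to per-region noise intensity
#'
#' D_i = d0 * (CV_i / median CV)^2 where CV_i is the coefficient of
#' variation (sd/mean) of region i's envelope; clipped to [1e-4, 1].
#' Regions with bursty, strongly amplitude-modulated activity get larger
#' noise intensity, hence shorter escape times.
#'
#' @param a an `analytic_signal` (envelope of band-filtered region
#'   signals), or an envelope matrix (regions x time).
#' @param d0 baseline noise intensity (default 0.1).
#' @return numeric vector of per-region noise intensities D.
#' @export
estimate_noise <- function(a, d0 = 0.1) {
  amp <- if (inherits(a, "analytic_signal")) a$amplitude else as.matrix(a)
  mu <- rowMeans(amp)
  if (any(mu <= 0)) stop("zero-mean envelope; cannot form CV")
  cv <- apply(amp, 1, sd) / mu
  ref <- median(cv)
  if (ref <= 0) ref <- 1
  pmin(pmax(d0 * (cv / ref)^2, 1e-4), 1)
}

#' Mean escape times of the DTF-coupled bistable model
#'
#' Euler--Maruyama integration of
#'   dx_i = [ x_i - x_i^3 + c * sum_j W[j,i] (x_j - x_i) ] dt
#'          + sqrt(2 D_i) dW_i
#' from all nodes at the resting attractor (-1). Region i's escape time in
#' a realization is the first time x_i >= threshold; realizations with no
#' escape are censored at t_max and enter the mean as t_max (conservative:
#' biases the seizure index downward for stable regions). If the
#' integration diverges (|x| > 10) the step is halved once.
#'
#' @param adj delta-band (or configured band) `adjacency_matrix`,
#'   unthresholded; or a bare weight matrix `W[source, sink]`.
#' @param D per-region noise intensities (from [estimate_noise]).
#' @param cfg an [si_config].
#' @return An object of class `si_result` with `tau_mean`,
#'   `censored_fraction` per region (plus `si`, `normalized`,
#'   `epileptogenic` once [seizure_index] has been applied).
#' @export
escape_times <- function(adj, D, cfg = si_config()) {
  W <- if (inherits(adj, "adjacency_matrix")) adj$W else as.matrix(adj)
  n <- nrow(W)
  D <- rep_len(D, n)
  if (any(D < 0)) stop("noise intensities must be >= 0")
  res <- em_escape(W, D, cfg, cfg$dt)
  if (is.null(res)) {
    res <- em_escape(W, D, cfg, cfg$dt / 2)
    if (is.null(res)) stop("bistable integration diverged even at dt/2")
  }
  structure(list(tau_mean = rowMeans(res$tau),
                 censored_fraction = rowMeans(res$censored),
                 t_max = cfg$t_max, config = cfg),
            class = "si_result")
}

em_escape <- function(W, D, cfg, dt) {
  n <- nrow(W); R <- cfg$n_realizations
  n_steps <- floor(cfg$t_max / dt)
  tW <- t(W)
  cs <- colSums(W)
  c_gain <- cfg$coupling_gain
  sig <- sqrt(2 * D * dt)
  x <- matrix(-1, n, R)
  tau <- matrix(cfg$t_max, n, R)
  esc <- matrix(FALSE, n, R)
  set.seed(cfg$seed)
  for (k in seq_len(n_steps)) {
    drift <- x - x^3 + c_gain * (tW %*% x - cs * x)
    x <- x + drift * dt + sig * matrix(rnorm(n * R), n, R)
    if (max(abs(x)) > 10) return(NULL)
    hit <- !esc & x >= cfg$threshold
    if (any(hit)) { tau[hit] <- k * dt; esc[hit] <- TRUE }
    if (all(esc)) break
  }
  list(tau = tau, censored = !esc)
}

#' Seizure index from escape times
#'
#' SI = 1 / mean escape time; normalized by its maximum; regions with
#' normalized SI >= cutoff are flagged as highly epileptogenic.
#'
#' @param res an `si_result` from [escape_times].
#' @param cutoff normalized-SI threshold (default from the config).
#' @return The `si_result` completed with `si`, `normalized`,
#'   `epileptogenic`.
#' @export
seizure_index <- function(res, cutoff = NULL) {
  stopifnot(inherits(res, "si_result"))
  if (is.null(cutoff)) cutoff <- res$config$cutoff
  res$si <- 1 / res$tau_mean
  res$normalized <- res$si / max(res$si)
  res$epileptogenic <- which(res$normalized >= cutoff)
  if (all(res$censored_fraction == 1))
    warning("no region ever escaped; all regions flagged equally")
  res
}

#' @export
print.si_result <- function(x, ...) {
  cat(sprintf("<si_result> %d regions, t_max %g, mean censoring %.2f\n",
              length(x$tau_mean), x$t_max, mean(x$censored_fraction)))
  if (!is.null(x$epileptogenic))
    cat("  epileptogenic set:", paste(x$epileptogenic, collapse = ", "),
        "\n")
  invisible(x)
}

#' Band-limited seizure index from region time series
#'
#' Pipeline wrapper: band-pass the region signals to the requested band,
#' take the Hilbert envelope, map envelope variability to noise
#' intensities, run the escape-time model on the band's DTF network, and
#' score.
#'
#' @param x a [region_ts].
#' @param adj the band's unthresholded `adjacency_matrix`.
#' @param band band name (default `"delta"`).
#' @param scheme a [band_scheme].
#' @param cfg an [si_config].
#' @return A completed `si_result`.
#' @export
si_pipeline <- function(x, adj, band = "delta", scheme = band_scheme(),
                        cfg = si_config()) {
  row <- which(scheme$name == band)
  if (length(row) != 1L) stop("unknown band: ", band)
  rec <- eeg_recording(x$x, x$rate,
                       channel_names = sprintf("R%03d", seq_len(nrow(x$x))))
  filt <- bandpass(rec, scheme$lo[row], scheme$hi[row])
  env <- hilbert_analytic(filt$samples)
  D <- estimate_noise(env, d0 = cfg$d0)
  seizure_index(escape_times(adj, D, cfg))
}
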
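#' Frequency-band scheme
#'
#' The six conventional EEG bands. Delta is 1--4 Hz; the gamma range is
#' split around the 48--52 Hz mains notch, so low gamma ends at 48 Hz and
#' high gamma starts at 52 Hz. Band membership of a frequency bin uses the
#' half-open rule lo <= f < hi.
#'
#' @param bands data.frame with columns `name`, `lo`, `hi`; default the
#'   six-band scheme delta 1--4, theta 4--8, alpha 8--13, beta 13--30,
#'   low_gamma 30--48, high_gamma 52--80 Hz.
#' @return An object of class `band_scheme`.
#' @export
band_scheme <- function(bands = NULL) {
  if (is.null(bands))
    bands <- data.frame(
      name = c("delta", "theta", "alpha", "beta", "low_gamma", "high_gamma"),
      lo = c(1, 4, 8, 13, 30, 52),
      hi = c(4, 8, 13, 30, 48, 80))
  stopifnot(all(c("name", "lo", "hi") %in% colnames(bands)))
  if (any(bands$lo >= bands$hi)) stop("band edges must satisfy lo < hi")
  if (is.unsorted(bands$lo)) stop("bands must be in increasing order")
  if (any(utils::head(bands$hi, -1) > utils::tail(bands$lo, -1)))
    stop("bands must not overlap")
  structure(bands, class = c("band_scheme", "data.frame"))
}

#' Welch power spectral density of region time series
#'
#' Averaged modified periodograms: sliding windows of `window_s` seconds
#' (default 2, Hann taper, 50\% overlap), one-sided density on a grid with
#' resolution 1/window_s Hz, normalized so that the integral of the
#' density over frequency equals the signal variance (Parseval).
#'
#' @param x a [region_ts] (or a numeric matrix rows = series with `rate`).
#' @param window_s window length in seconds (default 2).
#' @param overlap fractional overlap in [0, 1) (default 0.5).
#' @param rate sampling rate, required when `x` is a bare matrix.
#' @return An object of class `band_psd` with `psd_raw`
#'   (region x frequency, density units), `freqs` (Hz), `rate`.
#' @export
welch_psd <- function(x, window_s = 2, overlap = 0.5, rate = NULL) {
  if (inherits(x, "region_ts")) { rate <- x$rate; x <- x$x }
  x <- as.matrix(x)
  stopifnot(!is.null(rate), overlap >= 0, overlap < 1)
  nw <- round(window_s * rate)
  if (nw < 8) stop("window too short: needs >= 8 samples")
  if (nw > ncol(x)) stop("window longer than the signal")
  step <- max(1L, round(nw * (1 - overlap)))
  starts <- seq(1L, ncol(x) - nw + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nw - 1)) / (nw - 1))   # Hann
  U <- sum(w^2)
  n_freq <- nw %/% 2 + 1L
  freqs <- (0:(n_freq - 1L)) * rate / nw
  psd <- matrix(0, nrow(x), n_freq)
  for (s0 in starts) {
    seg <- x[, s0:(s0 + nw - 1L), drop = FALSE] *
      rep(w, each = nrow(x))
    ft <- t(apply(seg, 1, fft))
    if (nrow(x) == 1L) ft <- matrix(fft(seg[1, ]), 1)
    p <- Mod(ft[, seq_len(n_freq), drop = FALSE])^2 / (U * rate)
    # one-sided: double everything except DC and (for even nw) Nyquist
    dbl <- rep(2, n_freq); dbl[1] <- 1
    if (nw %% 2 == 0) dbl[n_freq] <- 1
    psd <- psd + p * rep(dbl, each = nrow(x))
  }
  psd <- psd / length(starts)
  structure(list(psd_raw = psd, freqs = freqs, rate = rate),
            class = "band_psd")
}

#' Aggregate a PSD into frequency bands (dB/Hz)
#'
#' Mean raw density over the in-band bins (half-open rule lo <= f < hi),
#' then 10 log10, giving band power density in dB/Hz.
#'
#' @param psd a `band_psd` from [welch_psd].
#' @param scheme a [band_scheme].
#' @return region x band matrix of dB/Hz values (columns = band names).
#' @export
band_aggregate <- function(psd, scheme = band_scheme()) {
  stopifnot(inherits(psd, "band_psd"), inherits(scheme, "band_scheme"))
  out <- matrix(NA_real_, nrow(psd$psd_raw), nrow(scheme))
  colnames(out) <- scheme$name
  for (b in seq_len(nrow(scheme))) {
    sel <- psd$freqs >= scheme$lo[b] & psd$freqs < scheme$hi[b]
    if (!any(sel))
      stop("band '", scheme$name[b], "' contains no frequency bins ",
           "(grid resolution ", signif(diff(psd$freqs[1:2]), 3), " Hz)")
    out[, b] <- 10 * log10(rowMeans(psd$psd_raw[, sel, drop = FALSE]))
  }
  out
}

#' Analytic signal via the FFT Hilbert transform
#'
#' Returns the instantaneous amplitude (envelope) and wrapped phase in
#' (-pi, pi] per region.
#'
#' @param x a [region_ts] or numeric matrix (rows = series).
#' @return An object of class `analytic_signal` with `amplitude` and
#'   `phase` matrices of the input shape.
#' @export
hilbert_analytic <- function(x) {
  if (inherits(x, "region_ts")) x <- x$x
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("signals must be finite")
  n <- ncol(x)
  h <- rep(0, n)
  h[1] <- 1
  if (n %% 2 == 0) { h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else h[2:((n + 1) / 2)] <- 2
  amp <- phase <- matrix(0, nrow(x), n)
  for (i in seq_len(nrow(x))) {
    z <- fft(fft(x[i, ]) * h, inverse = TRUE) / n
    amp[i, ] <- Mod(z)
    phase[i, ] <- Arg(z)
  }
  structure(list(amplitude = amp, phase = phase), class = "analytic_signal")
}
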
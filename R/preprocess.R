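#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth band-pass applied forward-backward (zero phase)
#' per channel; the DC component is removed before filtering. Defaults
#' follow the clinical conditioning chain: 0.5--80 Hz.
#'
#' @param rec an [eeg_recording].
#' @param lo,hi band edges in Hz, 0 < lo < hi < rate/2.
#' @param order Butterworth order per pass (default 4).
#' @return Filtered [eeg_recording].
#' @export
bandpass <- function(rec, lo = 0.5, hi = 80, order = 4L) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$rate / 2
  if (!(lo > 0 && lo < hi)) stop("need 0 < lo < hi")
  if (hi >= nyq)
    stop("upper edge ", hi, " Hz >= Nyquist (", nyq, " Hz)")
  bf <- signal::butter(order, c(lo, hi) / nyq, type = "pass")
  out <- rec$samples - rowMeans(rec$samples)
  for (ch in seq_len(nrow(out)))
    out[ch, ] <- signal::filtfilt(bf, out[ch, ])
  eeg_recording(out, rec$rate, rec$channel_names, rec$onset_marker)
}

#' Zero-phase notch (band-stop) filter for line noise
#'
#' Butterworth band-stop covering `freq` +/- `halfwidth` (default
#' 48--52 Hz for 50 Hz mains), applied forward-backward per channel.
#'
#' @param rec an [eeg_recording].
#' @param freq line frequency in Hz (default 50).
#' @param halfwidth stop-band half width in Hz (default 2).
#' @param order Butterworth order per pass (default 4).
#' @return Filtered [eeg_recording].
#' @export
notch <- function(rec, freq = 50, halfwidth = 2, order = 4L) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$rate / 2
  if (freq >= nyq) stop("notch frequency >= Nyquist")
  bf <- signal::butter(order, c(freq - halfwidth, freq + halfwidth) / nyq,
                       type = "stop")
  out <- rec$samples
  for (ch in seq_len(nrow(out)))
    out[ch, ] <- signal::filtfilt(bf, out[ch, ])
  eeg_recording(out, rec$rate, rec$channel_names, rec$onset_marker)
}

#' Select the preictal window
#'
#' Returns exactly the `minutes`-long window ending at (and excluding) the
#' seizure onset marker: samples in [onset - minutes*60*rate, onset).
#'
#' @param rec an [eeg_recording] with `onset_marker` set.
#' @param minutes window length in minutes (default 10).
#' @return An [eeg_recording] of exactly `minutes * 60 * rate` samples.
#' @export
select_preictal <- function(rec, minutes = 10) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.null(rec$onset_marker))
    stop("recording has no seizure onset marker")
  n_want <- round(minutes * 60 * rec$rate)
  first <- rec$onset_marker - n_want
  if (first < 1L)
    stop("recording too short: only ",
         signif((rec$onset_marker - 1) / rec$rate / 60, 3),
         " min available before onset, need ", minutes, " min")
  eeg_recording(rec$samples[, first:(rec$onset_marker - 1L), drop = FALSE],
                rec$rate, rec$channel_names)
}

#' Segment a recording into fixed-length epochs
#'
#' Non-overlapping, contiguous epochs of `length_s` seconds; a trailing
#' remainder shorter than one epoch is dropped (with a message).
#'
#' @param rec an [eeg_recording].
#' @param length_s epoch length in seconds (default 2).
#' @return An object of class `epoch_set` with fields `epochs`
#'   (epoch x channel x time array), `rate`, `epoch_length`.
#' @export
epoch_recording <- function(rec, length_s = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (length_s <= 0) stop("epoch length must be > 0")
  n_ep_samp <- round(length_s * rec$rate)
  n <- ncol(rec$samples)
  if (n < n_ep_samp) stop("recording shorter than one epoch")
  n_ep <- n %/% n_ep_samp
  dropped <- n - n_ep * n_ep_samp
  if (dropped > 0)
    message("epoching dropped trailing ", signif(dropped / rec$rate, 3),
            " s (", dropped, " samples)")
  arr <- array(0, dim = c(n_ep, nrow(rec$samples), n_ep_samp))
  for (e in seq_len(n_ep))
    arr[e, , ] <- rec$samples[, ((e - 1L) * n_ep_samp + 1L):(e * n_ep_samp)]
  structure(list(epochs = arr, rate = rec$rate, epoch_length = length_s,
                 channel_names = rec$channel_names),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples (%g s @ %g Hz)\n",
              dim(x$epochs)[1], dim(x$epochs)[2], dim(x$epochs)[3],
              x$epoch_length, x$rate))
  invisible(x)
}

#' Common-average re-reference
#'
#' Subtracts the instantaneous mean across channels. Off by default in the
#' pipeline (the inverse operator applies its own average-reference
#' projection when configured).
#'
#' @param rec an [eeg_recording].
#' @return Re-referenced [eeg_recording].
#' @export
common_average <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  out <- sweep(rec$samples, 2, colMeans(rec$samples))
  eeg_recording(out, rec$rate, rec$channel_names, rec$onset_marker)
}
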
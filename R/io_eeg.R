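#' Multichannel scalp EEG recording
#'
#' Container for a scalp EEG recording. Samples are stored channels x time
#' in microvolts; channel names follow the 10--20 montage where applicable.
#'
#' @param samples numeric matrix, channels x time, in microvolts.
#' @param rate sampling rate in samples/second (> 0).
#' @param channel_names character vector of unique channel labels, one per
#'   row of `samples`.
#' @param onset_marker optional sample index (1-based) of electrographic
#'   seizure onset.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, rate, channel_names, onset_marker = NULL) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples)) stop("samples must be numeric")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("rate must be a single positive number")
  channel_names <- as.character(channel_names)
  if (length(channel_names) != nrow(samples))
    stop("channel count (", nrow(samples), ") != number of channel names (",
         length(channel_names), ")")
  if (anyDuplicated(channel_names))
    stop("duplicate channel names: ",
         paste(unique(channel_names[duplicated(channel_names)]), collapse = ", "))
  if (!is.null(onset_marker)) {
    onset_marker <- as.integer(onset_marker)
    if (onset_marker < 1L || onset_marker > ncol(samples))
      stop("onset_marker outside recording")
  }
  rownames(samples) <- channel_names
  structure(list(samples = samples, rate = rate,
                 channel_names = channel_names, onset_marker = onset_marker),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$rate,
              ncol(x$samples) / x$rate))
  if (!is.null(x$onset_marker))
    cat(sprintf("  seizure onset at sample %d (%.1f s)\n",
                x$onset_marker, x$onset_marker / x$rate))
  invisible(x)
}

#' Read an EEG recording from EDF or TSV
#'
#' TSV layout: first row channel names, subsequent rows one time sample per
#' row (columns = channels); the sampling rate must be supplied since TSV
#' carries no metadata. EDF (European Data Format) files carry their own
#' rate and labels; values whose physical dimension is declared as mV or V
#' are converted to microvolts.
#'
#' @param path file path.
#' @param format `"edf"` or `"tsv"`; default guesses from the extension.
#' @param rate sampling rate (required for TSV, ignored for EDF).
#' @param onset_marker optional onset sample index attached to the result.
#' @return An [eeg_recording].
#' @export
read_eeg <- function(path, format = c("auto", "edf", "tsv"), rate = NULL,
                     onset_marker = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read EEG file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "tsv"
  if (format == "tsv") {
    if (is.null(rate)) stop("rate must be given for TSV input")
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             check.names = FALSE)
    eeg_recording(t(as.matrix(tab)), rate = rate,
                  channel_names = colnames(tab), onset_marker = onset_marker)
  } else {
    read_edf(path, onset_marker = onset_marker)
  }
}

#' Write an EEG recording to EDF or TSV
#'
#' The TSV writer emits the canonical text dialect (tab-delimited, UTF-8,
#' '.' decimal): header row of channel names, one time sample per row. The
#' EDF writer stores 16-bit samples with per-channel physical scaling in
#' microvolts and 1-s data records; recordings whose length is not a whole
#' number of seconds are zero-padded to the next record (with a warning).
#'
#' @param rec an [eeg_recording].
#' @param path output file path.
#' @param format `"edf"` or `"tsv"`; default guesses from the extension.
#' @return `path`, invisibly.
#' @export
write_eeg <- function(rec, path, format = c("auto", "edf", "tsv")) {
  stopifnot(inherits(rec, "eeg_recording"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "tsv"
  if (format == "tsv") {
    tab <- as.data.frame(t(rec$samples))
    colnames(tab) <- rec$channel_names
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  } else {
    write_edf(rec, path)
  }
  invisible(path)
}

# ---- EDF (European Data Format), continuous recordings -----------------
# 256-byte fixed header + 256 bytes per signal (field-major), then data
# records of interleaved int16 little-endian samples. Physical scaling is
# linear per channel between (phys_min, phys_max) and (dig_min, dig_max).

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

write_edf <- function(rec, path) {
  ns <- nrow(rec$samples)
  rate <- rec$rate
  if (abs(rate - round(rate)) > 1e-9)
    stop("EDF writer requires an integer sampling rate")
  rate <- as.integer(round(rate))
  n <- ncol(rec$samples)
  n_rec <- ceiling(n / rate)
  if (n_rec * rate != n) {
    warning("recording length is not a whole number of seconds; ",
            "zero-padding final EDF record")
    pad <- matrix(0, ns, n_rec * rate - n)
    samples <- cbind(rec$samples, pad)
  } else samples <- rec$samples

  phys_min <- apply(samples, 1, min)
  phys_max <- apply(samples, 1, max)
  flat <- phys_max - phys_min < 1e-12
  phys_min[flat] <- phys_min[flat] - 1
  phys_max[flat] <- phys_max[flat] + 1
  dig_min <- -32768; dig_max <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),                       # version
    edf_pad("X X X X", 80),                # patient id (anonymous)
    edf_pad("Startdate X X X X", 80),      # recording id
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256L * (1L + ns), 8),          # header bytes
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_pad("1", 8),                       # record duration, seconds
    edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(values, width)
    writeChar(paste0(vapply(values, edf_pad, "", width = width),
                     collapse = ""), con, eos = NULL)
  field(rec$channel_names, 16)
  field(rep("", ns), 80)                   # transducer
  field(rep("uV", ns), 8)                  # physical dimension
  field(formatC(phys_min, format = "g", digits = 7), 8)
  field(formatC(phys_max, format = "g", digits = 7), 8)
  field(rep(dig_min, ns), 8)
  field(rep(dig_max, ns), 8)
  field(rep("", ns), 80)                   # prefiltering
  field(rep(rate, ns), 8)                  # samples per record
  field(rep("", ns), 32)

  scale <- (dig_max - dig_min) / (phys_max - phys_min)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * rate + 1L):(r * rate)
    for (ch in seq_len(ns)) {
      dig <- round((samples[ch, idx] - phys_min[ch]) * scale[ch] + dig_min)
      writeBin(as.integer(pmin(pmax(dig, dig_min), dig_max)), con,
               size = 2L, endian = "little")
    }
  }
  invisible(path)
}

read_edf <- function(path, onset_marker = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) {
    trimws(rawToChar(readBin(con, "raw", width)))
  }
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                    # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fields <- function(width)
    vapply(seq_len(ns), function(i) rd(width), "")
  labels <- fields(16)
  fields(80)
  dims <- fields(8)
  phys_min <- as.numeric(fields(8))
  phys_max <- as.numeric(fields(8))
  dig_min <- as.numeric(fields(8))
  dig_max <- as.numeric(fields(8))
  fields(80)
  spr <- as.integer(fields(8))
  fields(32)
  if (length(unique(spr)) != 1L)
    stop("EDF reader supports equal sampling rates across signals only")
  rate <- spr[1] / rec_dur

  out <- matrix(0, ns, n_rec * spr[1])
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", spr[ch], size = 2L, signed = TRUE,
                     endian = "little")
      out[ch, idx] <- (dig - dig_min[ch]) * gain[ch] + phys_min[ch]
    }
  }
  # convert to microvolts where the physical dimension declares units
  unit_scale <- ifelse(tolower(dims) == "mv", 1e3,
                       ifelse(tolower(dims) == "v", 1e6, 1))
  out <- out * unit_scale
  eeg_recording(out, rate = rate, channel_names = labels,
                onset_marker = onset_marker)
}
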
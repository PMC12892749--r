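#' Region-level source time series
#'
#' @param x regions x time numeric matrix.
#' @param rate sampling rate in Hz.
#' @param region_ids integer region labels (default 1..n).
#' @return An object of class `region_ts`.
#' @export
region_ts <- function(x, rate, region_ids = NULL) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("region time series must be finite")
  if (is.null(region_ids)) region_ids <- seq_len(nrow(x))
  structure(list(x = x, rate = rate, region_ids = as.integer(region_ids)),
            class = "region_ts")
}

#' @export
print.region_ts <- function(x, ...) {
  cat(sprintf("<region_ts> %d regions x %d samples @ %g Hz\n",
              nrow(x$x), ncol(x$x), x$rate))
  invisible(x)
}

# Moore-Penrose pseudo-inverse via SVD
pinv <- function(M, tol = NULL) {
  s <- svd(M)
  if (is.null(tol)) tol <- max(dim(M)) * max(s$d) * .Machine$double.eps
  keep <- s$d > tol
  if (!any(keep)) return(matrix(0, ncol(M), nrow(M)))
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Build the sLORETA inverse operator
#'
#' Minimum-norm kernel T = G' (G G' + alpha I)^+ with an average-reference
#' projector applied to the lead field first when `avg_ref`, plus the
#' sLORETA standardization factors R_jj = (T G)_jj (the resolution-derived
#' variance of each standardized source, assuming identity noise and
#' source covariance). `alpha = "auto"` uses the conventional
#' trace(G G') / (n_sensors * snr^2).
#'
#' @param lf a [lead_field].
#' @param alpha regularization scalar >= 0, or `"auto"`.
#' @param snr assumed amplitude SNR for auto regularization (default 3).
#' @param avg_ref apply the average-reference projector (default TRUE).
#' @return An object of class `inverse_operator` with fields `T_kernel`,
#'   `R_diag`, `alpha`, `avg_ref`, `sensor_names`, `source_ids`.
#' @export
build_inverse <- function(lf, alpha = "auto", snr = 3, avg_ref = TRUE) {
  stopifnot(inherits(lf, "lead_field"))
  G <- lf$G
  if (all(G == 0)) stop("zero lead field")
  m <- nrow(G)
  if (avg_ref) {
    H <- diag(m) - matrix(1 / m, m, m)
    G <- H %*% G
  }
  GGt <- G %*% t(G)
  if (identical(alpha, "auto"))
    alpha <- sum(diag(GGt)) / (m * snr^2)
  if (!is.numeric(alpha) || alpha < 0) stop("alpha must be >= 0")
  T_kernel <- t(G) %*% pinv(GGt + alpha * diag(m))
  R_diag <- rowSums(T_kernel * t(G))   # diag(T G)
  if (any(R_diag <= 0))
    stop("non-positive standardization factor; lead field column ",
         paste(which(R_diag <= 0), collapse = ", "),
         " carries no signal")
  structure(list(T_kernel = T_kernel, R_diag = R_diag, alpha = alpha,
                 avg_ref = avg_ref, sensor_names = lf$sensor_names,
                 source_ids = lf$source_ids),
            class = "inverse_operator")
}

#' Apply the sLORETA inverse to an EEG recording
#'
#' Standardized current-density estimate per source:
#' s_j(t) = (T y(t))_j / sqrt(R_jj). Channel order must match the inverse
#' operator's sensors; the average-reference projection is applied to the
#' data when the operator was built with `avg_ref`.
#'
#' @param inv an `inverse_operator` from [build_inverse].
#' @param rec an [eeg_recording].
#' @return An object of class `source_estimate` (fields `s_hat`
#'   sources x time, `rate`, `source_ids`).
#' @export
apply_sloreta <- function(inv, rec) {
  stopifnot(inherits(inv, "inverse_operator"), inherits(rec, "eeg_recording"))
  if (!identical(as.character(rec$channel_names),
                 as.character(inv$sensor_names))) {
    missing <- setdiff(inv$sensor_names, rec$channel_names)
    extra <- setdiff(rec$channel_names, inv$sensor_names)
    if (length(missing) || length(extra))
      stop("channel mismatch; missing: [",
           paste(missing, collapse = ", "), "] unexpected: [",
           paste(extra, collapse = ", "), "]")
    # same set, different order: align
    rec$samples <- rec$samples[match(inv$sensor_names, rec$channel_names), ,
                               drop = FALSE]
  }
  Y <- rec$samples
  if (inv$avg_ref) Y <- sweep(Y, 2, colMeans(Y))
  s <- (inv$T_kernel %*% Y) / sqrt(inv$R_diag)
  structure(list(s_hat = s, rate = rec$rate, source_ids = inv$source_ids),
            class = "source_estimate")
}

#' Extract region-level time series from a source estimate
#'
#' Per region: each member vertex series is sign-aligned to the region's
#' first member (flipped when the correlation is negative -- source
#' orientations are defined only up to sign), then averaged.
#'
#' @param src a `source_estimate`.
#' @param parc a [parcellation_table] whose vertices index source rows.
#' @return A [region_ts] with one row per region.
#' @export
extract_regions <- function(src, parc) {
  stopifnot(inherits(src, "source_estimate"),
            inherits(parc, "parcellation_table"))
  n_src <- nrow(src$s_hat)
  out <- matrix(0, length(parc$region_id), ncol(src$s_hat))
  for (r in seq_along(parc$region_id)) {
    v <- parc$vertex_ids[[r]]
    if (any(v < 1L | v > n_src))
      stop("region ", parc$region_id[r], " references vertex outside the ",
           "source grid (1..", n_src, ")")
    ref <- src$s_hat[v[1], ]
    acc <- ref
    if (length(v) > 1L) {
      for (vi in v[-1]) {
        series <- src$s_hat[vi, ]
        flip <- suppressWarnings(cor(ref, series))
        if (!is.na(flip) && flip < 0) series <- -series
        acc <- acc + series
      }
    }
    out[r, ] <- acc / length(v)
  }
  region_ts(out, rate = src$rate, region_ids = parc$region_id)
}
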
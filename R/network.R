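#' Fit a multivariate autoregressive (MVAR) model
#'
#' Ridge-regularized multichannel least squares. An `epoch_set`-style
#' input (regions x time per epoch) is pooled: each epoch contributes its
#' own lagged design rows, so epoch boundaries never mix. With
#' `p = "auto"` the order minimizing BIC over 1..`max_order` is chosen.
#' The ridge penalty is trace-scaled: lambda = ridge * mean diagonal of
#' the design Gram matrix, so `ridge` is unitless.
#'
#' @param x a [region_ts], a list of regions x time matrices (epochs), or
#'   an `epoch_set` whose channels are regions.
#' @param p model order (>= 1) or `"auto"`.
#' @param ridge unitless ridge penalty (default 1e-3). 0 requires a
#'   well-conditioned design.
#' @param max_order largest order tried for `p = "auto"` (default 10).
#' @param rate sampling rate, required if `x` is a bare matrix/list.
#' @return An object of class `mvar_model`: coefficient array `A`
#'   (d x d x p, `A[i, j, k]` = effect of region j at lag k on region i),
#'   innovation covariance `Sigma`, `p`, `rate`, `stable` flag.
#' @export
fit_mvar <- function(x, p = "auto", ridge = 1e-3, max_order = 10L,
                     rate = NULL) {
  epochs <- mvar_epoch_list(x)
  if (is.null(rate)) rate <- attr(epochs, "rate")
  if (is.null(rate)) stop("sampling rate unknown; pass rate=")
  d <- nrow(epochs[[1]])
  if (identical(p, "auto")) {
    max_order <- min(max_order, ncol(epochs[[1]]) - 1L)
    bic <- vapply(seq_len(max_order), function(ord)
      mvar_fit_order(epochs, ord, ridge)$bic, 0)
    p <- which.min(bic)
  }
  stopifnot(is.numeric(p), p >= 1)
  fit <- mvar_fit_order(epochs, as.integer(p), ridge)
  sr <- companion_radius(fit$A)
  stable <- sr < 1
  if (!stable)
    warning("fitted MVAR is unstable (companion spectral radius ",
            signif(sr, 4), "); returned with stable = FALSE")
  structure(list(A = fit$A, Sigma = fit$Sigma, p = as.integer(p),
                 rate = rate, ridge = ridge, stable = stable,
                 spectral_radius = sr),
            class = "mvar_model")
}

mvar_epoch_list <- function(x) {
  if (inherits(x, "region_ts")) {
    out <- list(x$x); attr(out, "rate") <- x$rate; return(out)
  }
  if (inherits(x, "epoch_set")) {
    out <- lapply(seq_len(dim(x$epochs)[1]), function(e)
      matrix(x$epochs[e, , ], dim(x$epochs)[2], dim(x$epochs)[3]))
    attr(out, "rate") <- x$rate
    return(out)
  }
  if (is.matrix(x)) return(list(x))
  if (is.list(x)) return(lapply(x, as.matrix))
  stop("unsupported input to fit_mvar")
}

mvar_fit_order <- function(epochs, p, ridge) {
  d <- nrow(epochs[[1]])
  XtX <- matrix(0, d * p, d * p)
  XtY <- matrix(0, d * p, d)
  n_rows <- 0L
  for (ep in epochs) {
    Tn <- ncol(ep)
    if (Tn <= p) next
    rows <- (p + 1L):Tn
    X <- do.call(cbind, lapply(seq_len(p), function(k) t(ep[, rows - k,
                                                            drop = FALSE])))
    Y <- t(ep[, rows, drop = FALSE])
    XtX <- XtX + crossprod(X)
    XtY <- XtY + crossprod(X, Y)
    n_rows <- n_rows + length(rows)
  }
  if (n_rows == 0L) stop("not enough samples for order ", p)
  lambda <- ridge * mean(diag(XtX))
  M <- XtX + lambda * diag(d * p)
  B <- tryCatch(solve(M, XtY), error = function(e)
    stop("singular MVAR design; increase ridge > 0 (", conditionMessage(e),
         ")"))
  # B rows: lag blocks [lag1 (d cols of predictors)...]; B is (d*p) x d,
  # column i = coefficients predicting region i
  A <- array(0, dim = c(d, d, p))
  for (k in seq_len(p))
    A[, , k] <- t(B[((k - 1L) * d + 1L):(k * d), , drop = FALSE])
  # residual covariance
  rss <- matrix(0, d, d)
  for (ep in epochs) {
    Tn <- ncol(ep)
    if (Tn <= p) next
    rows <- (p + 1L):Tn
    pred <- matrix(0, d, length(rows))
    for (k in seq_len(p))
      pred <- pred + A[, , k] %*% ep[, rows - k, drop = FALSE]
    res <- ep[, rows, drop = FALSE] - pred
    rss <- rss + res %*% t(res)
  }
  Sigma <- rss / n_rows
  # BIC with a jittered log-determinant for near-singular residuals
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  ld <- sum(log(pmax(ev, max(ev) * 1e-12)))
  bic <- n_rows * ld + p * d^2 * log(n_rows)
  list(A = A, Sigma = Sigma, bic = bic)
}

companion_radius <- function(A) {
  d <- dim(A)[1]; p <- dim(A)[3]
  comp <- matrix(0, d * p, d * p)
  for (k in seq_len(p)) comp[1:d, ((k - 1) * d + 1):(k * d)] <- A[, , k]
  if (p > 1)
    comp[(d + 1):(d * p), 1:(d * (p - 1))] <- diag(d * (p - 1))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Directed transfer function of an MVAR model
#'
#' For each frequency f the transfer matrix
#' H(f) = (I - sum_k A_k exp(-i 2 pi f k / rate))^{-1} is evaluated and
#' normalized per sink row (Kaminski--Blinowska):
#' gamma2[i, j, f] = |H_ij|^2 / sum_m |H_im|^2, the fraction of inflow
#' into sink i originating from source j. Rows sum to 1 at every
#' frequency.
#'
#' @param m an `mvar_model`.
#' @param freqs frequency grid in Hz (default 1..Nyquist-1 at 1 Hz).
#' @return An object of class `dtf_tensor`: `gamma2` array
#'   (sink x source x frequency), `freqs`.
#' @export
compute_dtf <- function(m, freqs = NULL) {
  stopifnot(inherits(m, "mvar_model"))
  d <- dim(m$A)[1]
  if (is.null(freqs)) freqs <- seq(1, m$rate / 2 - 1, by = 1)
  gamma2 <- array(0, dim = c(d, d, length(freqs)))
  for (fi in seq_along(freqs)) {
    Af <- diag(d) + 0i
    for (k in seq_len(m$p))
      Af <- Af - m$A[, , k] * exp(-2i * pi * freqs[fi] * k / m$rate)
    H <- tryCatch(solve(Af), error = function(e)
      stop("MVAR spectral matrix singular at ", freqs[fi], " Hz"))
    h2 <- Mod(H)^2
    gamma2[, , fi] <- h2 / rowSums(h2)
  }
  structure(list(gamma2 = gamma2, freqs = freqs), class = "dtf_tensor")
}

#' Band-averaged directed adjacency matrix
#'
#' Averages the DTF over the in-band frequencies (half-open lo <= f < hi)
#' and transposes to the source -> sink weight convention
#' `W[source, sink]`, so out-degree is a row sum. The diagonal is zeroed.
#'
#' @param dtf a `dtf_tensor`.
#' @param scheme a [band_scheme].
#' @param band band name present in `scheme`.
#' @return An object of class `adjacency_matrix`: `W`, `band`, `density`.
#' @export
band_network <- function(dtf, scheme = band_scheme(), band = "delta") {
  stopifnot(inherits(dtf, "dtf_tensor"))
  row <- which(scheme$name == band)
  if (length(row) != 1L) stop("unknown band: ", band)
  sel <- dtf$freqs >= scheme$lo[row] & dtf$freqs < scheme$hi[row]
  if (!any(sel)) stop("band '", band, "' contains no DTF frequencies")
  M <- apply(dtf$gamma2[, , sel, drop = FALSE], c(1, 2), mean)
  W <- t(M)                      # W[source, sink]
  diag(W) <- 0
  adjacency_matrix(W, band = band)
}

#' Directed adjacency container
#' @param W non-negative weights, `W[source, sink]`, zero diagonal.
#' @param band band name label.
#' @param density retained-edge fraction (1 if unthresholded).
#' @return An object of class `adjacency_matrix`.
#' @export
adjacency_matrix <- function(W, band = "", density = 1) {
  W <- as.matrix(W)
  if (any(W < 0)) stop("adjacency weights must be non-negative")
  if (any(diag(W) != 0)) stop("adjacency diagonal must be zero")
  structure(list(W = W, band = band, density = density),
            class = "adjacency_matrix")
}

#' Proportional sparsity threshold
#'
#' Keeps the `ceiling(density * n(n-1))` largest off-diagonal weights
#' (ties broken deterministically by source-then-sink index order), zeroes
#' the rest, and retains the surviving weights (weighted analysis, no
#' binarization).
#'
#' @param adj an `adjacency_matrix`.
#' @param density fraction of off-diagonal edges to keep, in (0, 1].
#' @return Thresholded `adjacency_matrix` with `density` recorded.
#' @export
sparsity_threshold <- function(adj, density) {
  stopifnot(inherits(adj, "adjacency_matrix"), density > 0, density <= 1)
  W <- adj$W
  n <- nrow(W)
  off <- which(row(W) != col(W))
  k <- ceiling(density * length(off))
  ord <- off[order(-W[off], row(W)[off], col(W)[off])]
  drop <- ord[-seq_len(k)]
  W[drop] <- 0
  adjacency_matrix(W, band = adj$band, density = density)
}

#' Weighted degree centralities of a directed network
#'
#' Out-degree dc_out_i = sum_j W[i, j], in-degree dc_in_i = sum_j W[j, i],
#' total dc = dc_in + dc_out (counts/sums of edge weights; with 0/1
#' weights these are connection counts).
#'
#' @param adj an `adjacency_matrix` (or bare non-negative matrix with zero
#'   diagonal, `W[source, sink]`).
#' @return list with numeric vectors `dc`, `dc_in`, `dc_out`.
#' @export
degree_metrics <- function(adj) {
  W <- if (inherits(adj, "adjacency_matrix")) adj$W else as.matrix(adj)
  if (any(W < 0)) stop("negative edge weight")
  dc_out <- rowSums(W)
  dc_in <- colSums(W)
  list(dc = dc_in + dc_out, dc_in = dc_in, dc_out = dc_out)
}

#' Degree centralities integrated over a sparsity-threshold sweep
#'
#' Computes dc/dc_in/dc_out at each density of the grid and integrates
#' each metric over density by the trapezoidal rule, giving a
#' threshold-free per-region score.
#'
#' @param adj an unthresholded `adjacency_matrix`.
#' @param densities density grid (>= 2 points; sorted internally with a
#'   notice if needed).
#' @return list of numeric vectors `dc`, `dc_in`, `dc_out` (AUC per
#'   region).
#' @export
auc_over_thresholds <- function(adj, densities = seq(0.05, 0.5, by = 0.05)) {
  stopifnot(inherits(adj, "adjacency_matrix"), length(densities) >= 2)
  if (is.unsorted(densities)) {
    message("density grid unsorted; sorting")
    densities <- sort(densities)
  }
  per <- lapply(densities, function(d)
    degree_metrics(sparsity_threshold(adj, d)))
  out <- list()
  for (metric in c("dc", "dc_in", "dc_out")) {
    vals <- vapply(per, `[[`, numeric(nrow(adj$W)), metric)
    if (is.null(dim(vals))) vals <- matrix(vals, 1)
    # trapezoid over the density grid, per region
    dx <- diff(densities)
    out[[metric]] <- as.numeric((vals[, -ncol(vals), drop = FALSE] +
                                 vals[, -1, drop = FALSE]) %*% dx / 2)
  }
  out
}

#' Normalize scores and detect hubs
#'
#' normalized = score / max(score); regions with normalized >= `cutoff`
#' (default 0.95) are hubs. All-zero scores yield an empty hub set with a
#' warning.
#'
#' @param scores non-negative per-region scores.
#' @param cutoff hub threshold on the normalized score (default 0.95).
#' @return list with `normalized` and integer `hubs`.
#' @export
normalize_and_hub <- function(scores, cutoff = 0.95) {
  if (all(scores == 0)) {
    warning("all scores zero; no hubs")
    return(list(normalized = scores, hubs = integer()))
  }
  normalized <- scores / max(scores)
  list(normalized = normalized, hubs = which(normalized >= cutoff))
}

#' Per-region network metrics with threshold-sweep AUC and hubs
#'
#' Convenience wrapper: AUC of dc/dc_in/dc_out over the density grid,
#' normalization, and hub sets.
#'
#' @inheritParams auc_over_thresholds
#' @param cutoff hub threshold (default 0.95).
#' @return An object of class `node_metrics`: `auc`, `normalized`, `hubs`
#'   (each a list over the three metrics), `band`, `densities`.
#' @export
node_metrics <- function(adj, densities = seq(0.05, 0.5, by = 0.05),
                         cutoff = 0.95) {
  auc <- auc_over_thresholds(adj, densities)
  norm <- lapply(auc, normalize_and_hub, cutoff = cutoff)
  structure(list(auc = auc,
                 normalized = lapply(norm, `[[`, "normalized"),
                 hubs = lapply(norm, `[[`, "hubs"),
                 band = adj$band, densities = densities, cutoff = cutoff),
            class = "node_metrics")
}

#' @export
print.node_metrics <- function(x, ...) {
  cat(sprintf("<node_metrics> band '%s', %d regions, densities %g..%g\n",
              x$band, length(x$auc$dc), min(x$densities), max(x$densities)))
  for (m in c("dc", "dc_in", "dc_out"))
    cat(sprintf("  %-6s hubs: %s\n", m,
                paste(x$hubs[[m]], collapse = ", ")))
  invisible(x)
}
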
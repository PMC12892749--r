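# Independent oracles used across the suite. These re-derive quantities
# with naive scalar code (or a different algorithm) and must never call the
# implementation paths they check.

# Surface potential of a dipole in a homogeneous conducting unit sphere:
# naive scalar Legendre-series evaluation, one sensor at a time.
naive_sphere_potential <- function(sensor, pos, mom, sigma = 0.33, N = 300) {
  b <- sqrt(sum(pos^2))
  if (sum(mom^2) < 1e-300) return(0)
  if (b < 1e-12) return(3 * sum(sensor * mom) / (4 * pi * sigma))
  rq <- pos / b
  mr <- sum(mom * rq)
  tv <- mom - mr * rq
  mt <- sqrt(sum(tv^2))
  th <- if (mt > 1e-14) tv / mt else c(0, 0, 0)
  c0 <- max(min(sum(sensor * rq), 1), -1)
  perp <- sensor - c0 * rq
  pn <- sqrt(sum(perp^2))
  cph <- if (pn > 1e-14) sum(perp * th) / pn else 0
  s0 <- sqrt(max(1 - c0^2, 0))
  tot <- 0
  Pm1 <- 1; P <- c0
  for (n in 1:N) {
    if (n >= 2) {
      Pn <- ((2 * n - 1) * c0 * P - (n - 1) * Pm1) / n
      Pm1 <- P; P <- Pn
    }
    Pn1 <- if (s0 > 1e-12) n * (Pm1 - c0 * P) / s0 else 0
    tot <- tot + (2 * n + 1) / n * b^(n - 1) * (n * mr * P + mt * Pn1 * cph)
  }
  tot / (4 * pi * sigma)
}

# Brute-force DTF of an MVAR coefficient array at one frequency.
naive_dtf <- function(A, f, rate) {
  d <- dim(A)[1]; p <- dim(A)[3]
  Af <- diag(d) + 0i
  for (k in seq_len(p)) Af <- Af - A[, , k] * exp(-2i * pi * f * k / rate)
  H <- solve(Af)
  h2 <- Mod(H)^2
  h2 / rowSums(h2)
}

# Naive trapezoidal integral.
naive_trapz <- function(x, y) {
  s <- 0
  for (i in seq_len(length(x) - 1))
    s <- s + (x[i + 1] - x[i]) * (y[i] + y[i + 1]) / 2
  s
}

# Two-sided Fisher exact p for a 2x2 table by exhaustive hypergeometric
# enumeration with the point-probability rule.
naive_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(a)
    exp(lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(r1 + r2, c1)), 0)
  p_obs <- probs[tab[1, 1] - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Random stable MVAR coefficient array (rejection sampling on the
# companion spectral radius).
random_stable_mvar <- function(d, p, seed, scale = 0.4) {
  set.seed(seed)
  repeat {
    A <- array(rnorm(d * d * p, sd = scale / sqrt(d * p)), c(d, d, p))
    comp <- matrix(0, d * p, d * p)
    for (k in seq_len(p)) comp[1:d, ((k - 1) * d + 1):(k * d)] <- A[, , k]
    if (p > 1) comp[(d + 1):(d * p), 1:(d * (p - 1))] <- diag(d * (p - 1))
    if (max(Mod(eigen(comp, only.values = TRUE)$values)) < 0.95) return(A)
  }
}

# Small deterministic EEG recording fixture.
toy_recording <- function(n_ch = 4, n = 1024, rate = 256, seed = 1) {
  set.seed(seed)
  eeg_recording(matrix(rnorm(n_ch * n), n_ch, n), rate,
                sprintf("CH%d", seq_len(n_ch)))
}

# Reduced-profile pipeline config used by the fast end-to-end tests.
reduced_config <- function(seed) {
  cfg <- default_config(seed = seed)
  cfg$scenario$n_regions <- 16L
  cfg$scenario$duration <- 60
  cfg
}
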
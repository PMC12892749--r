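test_that("MVAR fit on white noise finds (near) zero coefficients", {
  set.seed(1)
  x <- region_ts(matrix(rnorm(5 * 5000), 5), rate = 256)
  fit <- fit_mvar(x, p = 2, ridge = 1e-3)
  expect_lt(max(abs(fit$A)), 0.05)
  expect_true(fit$stable)
})

test_that("MVAR recovers known VAR(2) coefficients from pooled epochs", {
  A <- random_stable_mvar(6, 2, seed = 14, scale = 0.8)
  set.seed(15)
  n <- 40 * 512 + 200
  X <- matrix(0, 6, n); E <- matrix(rnorm(6 * n), 6, n)
  for (t in 3:n) X[, t] <- A[, , 1] %*% X[, t - 1] + A[, , 2] %*% X[, t - 2] + E[, t]
  X <- X[, 201:n]
  eps <- lapply(1:40, function(e) X[, ((e - 1) * 512 + 1):(e * 512)])
  fit <- fit_mvar(eps, p = 2, ridge = 1e-3, rate = 256)
  expect_lt(sqrt(mean((fit$A - A)^2)), 0.05)
  # auto order lands on 2 for this process
  fit_auto <- fit_mvar(eps, p = "auto", max_order = 5, rate = 256)
  expect_equal(fit_auto$p, 2L)
})

test_that("increasing ridge monotonically shrinks the coefficients", {
  set.seed(16)
  x <- list(matrix(rnorm(4 * 2000), 4))
  norms <- vapply(c(1e-4, 1e-2, 1, 100), function(r)
    sqrt(sum(fit_mvar(x, p = 2, ridge = r, rate = 100)$A^2)), 0)
  expect_true(all(diff(norms) < 0))
})

test_that("DTF of a diagonal MVAR is the identity flow pattern", {
  A <- array(0, c(3, 3, 1)); diag(A[, , 1]) <- c(0.5, -0.3, 0.7)
  m <- structure(list(A = A, p = 1L, rate = 256, Sigma = diag(3),
                      stable = TRUE), class = "mvar_model")
  d <- compute_dtf(m, freqs = c(2, 10, 40))
  for (fi in 1:3) {
    expect_equal(diag(d$gamma2[, , fi]), rep(1, 3), tolerance = 1e-12)
    expect_equal(max(abs(d$gamma2[, , fi] - diag(3))), 0, tolerance = 1e-12)
  }
})

test_that("unidirectional coupling produces one-way DTF flow", {
  A <- array(0, c(2, 2, 1))
  A[1, 1, 1] <- 0.5; A[2, 2, 1] <- 0.3; A[2, 1, 1] <- 0.4  # 1 -> 2 only
  m <- structure(list(A = A, p = 1L, rate = 256, Sigma = diag(2),
                      stable = TRUE), class = "mvar_model")
  d <- compute_dtf(m, freqs = 1:100)
  expect_equal(max(d$gamma2[1, 2, ]), 0)        # nothing flows 2 -> 1
  expect_true(all(d$gamma2[2, 1, ] > 0))        # 1 -> 2 at every frequency
  W <- band_network(d, band = "alpha")$W
  expect_equal(sum(W > 0), 1L)
  expect_gt(W[1, 2], 0)                         # source 1 -> sink 2
})

test_that("DTF matches a brute-force evaluation and normalizes per sink", {
  A <- array(0, c(2, 2, 1))
  A[, , 1] <- matrix(c(0.5, 0.25, -0.2, 0.4), 2, 2, byrow = TRUE)
  m <- structure(list(A = A, p = 1L, rate = 256, Sigma = diag(2),
                      stable = TRUE), class = "mvar_model")
  d <- compute_dtf(m, freqs = 10)
  expect_equal(d$gamma2[, , 1], naive_dtf(A, 10, 256), tolerance = 1e-10)

  for (s in 1:20) {
    A <- random_stable_mvar(4, 2, seed = 100 + s)
    m <- structure(list(A = A, p = 2L, rate = 256, Sigma = diag(4),
                        stable = TRUE), class = "mvar_model")
    d <- compute_dtf(m, freqs = c(3, 11, 27))
    sums <- apply(d$gamma2, c(1, 3), sum)
    expect_lt(max(abs(sums - 1)), 1e-8)
  }
})

test_that("band network inherits normalization bookkeeping", {
  # frequency-constant DTF -> W equals that constant off-diagonal
  g <- matrix(c(0.6, 0.4, 0.3, 0.7), 2, 2, byrow = TRUE)
  d <- structure(list(gamma2 = array(rep(g, 3), c(2, 2, 3)),
                      freqs = c(1.5, 2.5, 3.5)), class = "dtf_tensor")
  W <- band_network(d, band = "delta")$W
  expect_equal(W[2, 1], 0.4)  # source 2 -> sink 1 = gamma2[1, 2]
  expect_equal(W[1, 2], 0.3)  # source 1 -> sink 2 = gamma2[2, 1]
  expect_equal(diag(W), rep(0, 2))
  # after diagonal removal, inflow sums are <= 1
  expect_true(all(colSums(W) <= 1 + 1e-12))
})

test_that("sparsity threshold keeps the largest edges with a deterministic tie rule", {
  set.seed(17)
  W <- matrix(runif(16), 4, 4); diag(W) <- 0
  adj <- adjacency_matrix(W)
  expect_equal(sparsity_threshold(adj, 1)$W, W)
  th <- sparsity_threshold(adj, 0.25)$W
  off <- W[row(W) != col(W)]
  kept <- sort(off, decreasing = TRUE)[1:3]
  expect_equal(sum(th > 0), 3L)
  expect_setequal(th[th > 0], kept)
  # all-equal weights: lowest-index (source-major) edges survive
  We <- matrix(1, 3, 3); diag(We) <- 0
  the <- sparsity_threshold(adjacency_matrix(We), 0.5)$W
  expect_equal(sum(the > 0), 3L)
  expect_equal(which(t(the) > 0), c(2L, 3L, 4L))  # row-major positions 1,2 then 2,1
})

test_that("degree metrics reproduce the toy-graph worked example", {
  # node 1: two incoming unit edges (2->1, 3->1), one outgoing (1->4)
  W <- matrix(0, 4, 4)
  W[2, 1] <- 1; W[3, 1] <- 1; W[1, 4] <- 1
  dm <- degree_metrics(adjacency_matrix(W))
  expect_equal(dm$dc_in[1], 2)
  expect_equal(dm$dc_out[1], 1)
  expect_equal(dm$dc[1], 3)
  # empty graph
  dm0 <- degree_metrics(adjacency_matrix(matrix(0, 3, 3)))
  expect_equal(unlist(dm0), rep(0, 9), ignore_attr = TRUE)
  # weighted 3-cycle 1->2 (0.2), 2->3 (0.3), 3->1 (0.5)
  Wc <- matrix(0, 3, 3); Wc[1, 2] <- 0.2; Wc[2, 3] <- 0.3; Wc[3, 1] <- 0.5
  dmc <- degree_metrics(adjacency_matrix(Wc))
  expect_equal(dmc$dc_out, c(0.2, 0.3, 0.5))
  expect_equal(dmc$dc_in, c(0.5, 0.2, 0.3))
  expect_equal(dmc$dc, c(0.7, 0.5, 0.8))
  expect_error(degree_metrics(matrix(c(0, -1, 0, 0), 2)), "negative")
})

test_that("dc = dc_in + dc_out on random graphs and under relabeling", {
  for (s in 1:50) {
    set.seed(s)
    n <- sample(3:10, 1)
    W <- matrix(runif(n * n), n, n); diag(W) <- 0
    dm <- degree_metrics(adjacency_matrix(W))
    expect_equal(dm$dc, dm$dc_in + dm$dc_out)
    perm <- sample(n)
    dmp <- degree_metrics(adjacency_matrix(W[perm, perm]))
    expect_equal(dmp$dc, dm$dc[perm])
    expect_equal(dmp$dc_out, dm$dc_out[perm])
  }
})

test_that("threshold-sweep AUC matches naive trapezoid integration", {
  # constant metric c over grid [0.1, 0.5]: AUC = 0.4 c
  W <- matrix(1, 3, 3); diag(W) <- 0   # full graph survives any threshold
  adj <- adjacency_matrix(W)
  grid <- seq(0.99, 1, length.out = 5)  # densities where nothing is cut
  auc <- auc_over_thresholds(adj, densities = c(0.99, 1))
  expect_equal(auc$dc_out, rep(2 * 0.01, 3), tolerance = 1e-12)

  set.seed(18)
  W <- matrix(runif(36), 6, 6); diag(W) <- 0
  adj <- adjacency_matrix(W)
  grid <- seq(0.1, 0.9, by = 0.1)
  auc <- auc_over_thresholds(adj, densities = grid)
  per <- sapply(grid, function(d)
    degree_metrics(sparsity_threshold(adj, d))$dc_out)
  for (i in 1:6)
    expect_equal(auc$dc_out[i], naive_trapz(grid, per[i, ]),
                 tolerance = 1e-12)
  expect_message(auc_over_thresholds(adj, densities = rev(grid)),
                 "sorting")
})

test_that("normalization and the 0.95 hub rule", {
  nh <- normalize_and_hub(c(1, 2, 4))
  expect_equal(nh$normalized, c(0.25, 0.5, 1))
  expect_equal(nh$hubs, 3L)
  nh2 <- normalize_and_hub(c(4, 3.9, 1))
  expect_equal(nh2$hubs, c(1L, 2L))   # 3.9/4 = 0.975 >= 0.95
  nh3 <- normalize_and_hub(rep(2, 5))
  expect_equal(nh3$hubs, 1:5)
  expect_warning(nh0 <- normalize_and_hub(c(0, 0)), "no hubs")
  expect_length(nh0$hubs, 0)
})
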
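test_that("input weights are uniform, fixed by seed, in range", {
  w <- init_input_weights(5, 100, seed = 3)
  expect_equal(dim(w), c(100L, 5L))
  expect_true(all(w > -0.5 & w < 0.5))
  expect_identical(init_input_weights(5, 100, seed = 3), w)
  # distribution check: mean of 1e6 U(-0.5, 0.5) draws within 3 sigma/sqrt(n)
  big <- init_input_weights(1000, 1000, seed = 4)
  expect_lt(abs(mean(big)), 3 * sqrt(1 / 12) / 1000)
  # polarity-constrained mode: one sign per dendrite
  wp <- init_input_weights(4, 50, seed = 5, polarity = "per_dendrite")
  signs <- apply(wp, 1, function(row) length(unique(sign(row))))
  expect_true(all(signs == 1))
  expect_error(init_input_weights(0, 5), "L")
  expect_error(init_input_weights(5, 5, low = 1, high = 0), "low")
})

test_that("summed input superposes weight columns at spike times", {
  w1 <- init_input_weights(3, 6, seed = 1)
  r0 <- spike_raster(NULL, 3, 10)
  expect_equal(summed_input(r0, w1), matrix(0, 6, 10))
  # one-hot: a single spike copies that channel's weight column
  r1 <- spike_raster(cbind(4, 1), 3, 10)
  u <- summed_input(r1, w1)
  expect_equal(u[, 5], w1[, 2])
  expect_equal(u[, -5], matrix(0, 6, 9))
  # superposition: simultaneous spikes add their weight columns
  r2 <- spike_raster(cbind(c(4, 4), c(0, 2)), 3, 10)
  expect_equal(summed_input(r2, w1)[, 5], w1[, 1] + w1[, 3])
  expect_error(summed_input(spike_raster(cbind(0, 0), 2, 5), w1), "channels")
})

test_that("dendritic activations match a literal per-spike oracle", {
  r <- random_raster(3, 120, 18, seed = 21)
  w1 <- init_input_weights(3, 6, seed = 22)
  kb <- sample_kernel_bank(6, "alpha", t_max = 60, seed = 23)
  A <- dendritic_activations(summed_input(r, w1), kb)
  expect_equal(A, forward_per_spike(r, w1, kb), tolerance = 1e-6)
  # zero input -> zero activations (compress(0) = 0)
  A0 <- dendritic_activations(matrix(0, 6, 50), kb)
  expect_equal(A0, matrix(0, 6, 50))
  expect_error(dendritic_activations(matrix(0, 4, 50), kb), "kernel count")
})

test_that("a single spike produces the compressed scaled alpha response", {
  ks <- kernel_spec("alpha", ts = 10)
  w1 <- matrix(0.4, 1, 1)
  r <- spike_raster(cbind(5, 0), 1, 40)
  A <- dendritic_activations(summed_input(r, w1), list(ks))
  expect_equal(A[1, 16], compress(0.4 * exp(-1), 5), tolerance = 1e-9)
})

test_that("a second close spike is compressed more (depressive adaptation)", {
  ks <- kernel_spec("alpha", ts = 10)
  w1 <- matrix(0.4, 1, 1)
  single <- dendritic_activations(
    summed_input(spike_raster(cbind(5, 0), 1, 80), w1), list(ks))
  double <- dendritic_activations(
    summed_input(spike_raster(cbind(c(5, 8), c(0, 0)), 1, 80), w1), list(ks))
  expect_lt(max(double), 2 * max(single))
})

test_that("activations are bounded and causal", {
  # dense input: every cell spikes; logistic keeps |a| <= 0.5, touching
  # 0.5 only where the potential saturates past double precision
  K <- 300
  ev <- cbind(rep(0:(K - 1), each = 2), rep(0:1, K))
  r <- spike_raster(ev, 2, K)
  w1 <- matrix(0.5 - 1e-6, 8, 2)
  kb <- sample_kernel_bank(8, "alpha", t_max = 100, seed = 31)
  A <- dendritic_activations(summed_input(r, w1), kb)
  expect_true(all(abs(A) <= 0.5))
  # at realistic spike density the bound is strict
  r2 <- random_raster(2, K, 40, seed = 33)
  A2 <- dendritic_activations(summed_input(r2, w1), kb)
  expect_true(all(abs(A2) < 0.5))
  # causality: truncating the raster after step t leaves columns <= t intact
  r_full <- random_raster(2, 200, 30, seed = 32)
  t_cut <- 120L
  keep <- r_full$events[, "timestep"] < t_cut
  r_cut <- spike_raster(r_full$events[keep, , drop = FALSE], 2, 200)
  Af <- dendritic_activations(summed_input(r_full, w1), kb)
  Ac <- dendritic_activations(summed_input(r_cut, w1), kb)
  expect_equal(Af[, 1:t_cut], Ac[, 1:t_cut], tolerance = 1e-12)
})

test_that("soma is an exact linear map (triple-loop oracle)", {
  set.seed(41)
  A <- matrix(rnorm(7 * 20), 7, 20)
  W <- matrix(rnorm(3 * 7), 3, 7)
  y <- soma(A, W)
  y_oracle <- matrix(0, 3, 20)
  for (n in 1:3) for (t in 1:20) for (j in 1:7)
    y_oracle[n, t] <- y_oracle[n, t] + W[n, j] * A[j, t]
  expect_equal(y, y_oracle, tolerance = 1e-12)
  expect_equal(soma(A, matrix(0, 2, 7)), matrix(0, 2, 20))
  # one-hot output weights select a dendrite row
  Wh <- matrix(0, 1, 7); Wh[1, 4] <- 1
  expect_equal(drop(soma(A, Wh)), A[4, ])
  expect_error(soma(A, matrix(0, 1, 6)), "columns")
})

test_that("thresholding emits one spike per rising edge", {
  y <- rep(0.1, 50)
  expect_equal(n_events(threshold_spikes(y, 0.25)), 0L)
  # unit square pulse: exactly one spike at the pulse onset
  y[21:30] <- 1
  sp <- threshold_spikes(y, 0.25)
  expect_equal(unname(sp$events[, "timestep"]), 20L)
  # two separated pulses -> two spikes
  y[41:44] <- 0.9
  expect_equal(unname(threshold_spikes(y, 0.25)$events[, "timestep"]),
               c(20L, 40L))
  # supra-threshold from t = 0 spikes at t = 0
  expect_equal(unname(threshold_spikes(rep(1, 5), 0.25)$events[, "timestep"]),
               0L)
  expect_error(threshold_spikes(y, 0), "theta")
})

test_that("the forward pass is a pure function of raster and model", {
  task <- list(r = random_raster(4, 500, 60, seed = 51))
  m <- skim_model(init_input_weights(4, 10, seed = 52),
                  sample_kernel_bank(10, "alpha", 100, seed = 53),
                  matrix(stats::rnorm(10), 1, 10), threshold = 0.25)
  out1 <- skim_run(m, task$r, return_trace = TRUE)
  out2 <- skim_run(m, task$r, return_trace = TRUE)
  expect_identical(out1$y, out2$y)
  expect_identical(out1$spikes$events, out2$spikes$events)
  expect_equal(out1$y, soma(out1$A, m$output_weights))
})

test_that("soma reset zeroes dendritic state after an output spike", {
  # two identical input volleys; weights chosen so the first fires the soma
  ks <- sample_kernel_bank(3, "alpha", 40, seed = 61)
  w1 <- matrix(c(0.45, 0.4, 0.35), 3, 1)
  w2 <- matrix(1, 1, 3)
  m <- skim_model(w1, ks, w2, threshold = 0.25)
  r <- spike_raster(cbind(c(5, 12), c(0, 0)), 1, 120)
  no_reset <- skim_run(m, r, reset = FALSE, return_trace = TRUE)
  with_reset <- skim_run(m, r, reset = TRUE, return_trace = TRUE)
  # before any firing the two traces agree
  first_fire <- min(which(no_reset$y[1, ] >= 0.25))
  expect_equal(with_reset$y[1, 1:first_fire], no_reset$y[1, 1:first_fire],
               tolerance = 1e-9)
  # immediately after firing, the reset trace collapses toward zero
  expect_lt(with_reset$y[1, first_fire + 1], no_reset$y[1, first_fire + 1])
  expect_lt(abs(with_reset$y[1, first_fire + 1]), 1e-9)
})

test_that("the alternate order compresses amplitudes before filtering", {
  # contract: a_j = h_j * compress(u_j), each event scaled independently
  r <- random_raster(3, 150, 20, seed = 71)
  w1 <- init_input_weights(3, 5, seed = 72)
  kb <- sample_kernel_bank(5, "alpha", t_max = 60, seed = 73)
  u <- summed_input(r, w1)
  A_alt <- dendritic_activations(u, kb, order = "nonlinearity_then_filter")
  for (j in 1:5) {
    h <- impulse_response(kb[[j]])
    v <- numeric(150)
    for (t0 in which(u[j, ] != 0)) {
      idx <- t0:min(150, t0 + length(h) - 1L)
      v[idx] <- v[idx] + compress(u[j, t0], kb[[j]]$k) * h[seq_along(idx)]
    }
    expect_equal(A_alt[j, ], v, tolerance = 1e-9)
  }
  # with no compression the two orders coincide (both are linear)
  kb_lin <- lapply(kb, function(k) { k$compression <- "none"; k })
  expect_equal(dendritic_activations(u, kb_lin),
               dendritic_activations(u, kb_lin,
                                     order = "nonlinearity_then_filter"),
               tolerance = 1e-9)
  # with compression they differ as soon as spike responses overlap:
  # the default order adapts to spike history, the alternate does not
  A_def <- dendritic_activations(u, kb)
  expect_gt(max(abs(A_def - A_alt)), 1e-4)
})
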
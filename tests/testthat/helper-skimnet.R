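# Shared fixtures and independent oracles for the test suite.

random_raster <- function(L, K, n, seed) {
  with_seed_test(seed, {
    cells <- sample.int(L * K, n)
    spike_raster(cbind(timestep = (cells - 1L) %/% L,
                       channel = (cells - 1L) %% L),
                 n_channels = L, n_steps = K)
  })
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

# Literal per-spike forward pass: superpose each spike's scaled impulse
# response (no convolution, no truncation beyond K), then compress.
forward_per_spike <- function(raster, w1, kernels) {
  M <- nrow(w1); K <- raster$n_steps
  A <- matrix(0, M, K)
  for (j in seq_len(M)) {
    f <- skimnet:::kernel_fun(kernels[[j]])
    v <- numeric(K)
    for (i in seq_len(nrow(raster$events))) {
      t0 <- raster$events[i, 1L]; ch <- raster$events[i, 2L]
      tt <- seq.int(0L, K - 1L - t0)
      v[(t0 + 1L):K] <- v[(t0 + 1L):K] + w1[j, ch + 1L] * f(tt)
    }
    A[j, ] <- compress(v, kernels[[j]]$k, kernels[[j]]$compression)
  }
  A
}

# Ridge normal-equation brute force: W = Z A' (A A' + ridge I)^-1.
solve_normal_equations <- function(A, Z, ridge) {
  Z %*% t(A) %*% solve(A %*% t(A) + ridge * diag(nrow(A)))
}

rel_frob <- function(X, Y) sqrt(sum((X - Y)^2)) / max(sqrt(sum(Y^2)),
                                                      .Machine$double.eps)

# Exhaustive window-by-window detection scorer (independent of
# match_detections internals): explicit loop over merged positives and
# complement tiles.
score_windows_brute <- function(spikes, windows, K) {
  win <- skimnet:::merge_windows(windows, K)
  len <- max(1L, round(mean(windows[, 2] - windows[, 1])))
  inside <- function(s, e) sum(spikes >= s & spikes < e) > 0
  tp <- 0L; fn <- 0L; fp <- 0L; tn <- 0L
  for (i in seq_len(nrow(win)))
    if (inside(win[i, 1], win[i, 2])) tp <- tp + 1L else fn <- fn + 1L
  covered <- rep(FALSE, K)
  for (i in seq_len(nrow(win)))
    if (win[i, 2] > win[i, 1]) covered[(win[i, 1] + 1):win[i, 2]] <- TRUE
  gap_start <- which(!covered & !c(FALSE, !covered[-K]))
  for (g in gap_start) {
    g_end <- g
    while (g_end < K && !covered[g_end + 1]) g_end <- g_end + 1
    s <- g - 1
    while (s < g_end) {
      e <- min(s + len, g_end)
      if (inside(s, e)) fp <- fp + 1L else tn <- tn + 1L
      s <- e
    }
  }
  list(tp = tp, fn = fn, fp = fp, tn = tn)
}

# Small benchmark task shared by slower tests.
toy_task <- function(seed, K = 2e4, rate = 300 / 1e5, M = 60,
                     noise_ratio = 1) {
  pat <- make_pattern(seed = seed)
  train <- embed_pattern(pat, K = K, presentation_rate = rate,
                         noise_ratio = noise_ratio, seed = seed + 1000)
  test <- embed_pattern(pat, K = K, presentation_rate = rate,
                        noise_ratio = noise_ratio, seed = seed + 2000)
  model <- skim_train(train$raster, train$presentation_end_times, M = M,
                      seed = seed + 3000)
  list(pattern = pat, train = train, test = test, model = model)
}
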
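#' Analog training target from desired spike times
#'
#' Builds the target soma signal `Z` used to solve the output weights.
#' Because single-timestep targets carry almost no energy, each desired
#' output spike is widened to a square pulse: for every pattern end time
#' `e` the half-open window `[e + delay, e + delay + width)` is set to
#' `amplitude` (default: width 10, delayed 10 timesteps after the end of
#' the input pattern, so the dendritic kernel responses have peaked).
#' Overlapping windows are merged; windows are clipped at `K`.
#'
#' @param pattern_end_times numeric vector of pattern end timesteps for a
#'   single output, or a list of such vectors (one per output neuron).
#' @param K sequence length in timesteps.
#' @param width pulse width in timesteps (>= 1, default 10).
#' @param delay displacement after the pattern end (>= 0, default 10).
#' @param amplitude pulse height (default 1).
#' @return An object of class `target_signal` with fields `values`
#'   (`N x K` matrix), `spike_windows` (per-output matrix of half-open
#'   `[start, end)` intervals) and `amplitude`.
#' @examples
#' z <- build_target(100, K = 200)      # ones on [110, 120)
#' sum(z$values)                        # 10
#' @export
build_target <- function(pattern_end_times, K, width = 10, delay = 10,
                         amplitude = 1.0) {
  K <- check_count(K, "K")
  if (width < 1) stop_config("`width` must be >= 1")
  if (delay < 0) stop_config("`delay` must be >= 0")
  if (!is.list(pattern_end_times)) pattern_end_times <- list(pattern_end_times)
  N <- length(pattern_end_times)
  values <- matrix(0, N, K)
  windows <- vector("list", N)
  for (n in seq_len(N)) {
    e <- sort(as.numeric(pattern_end_times[[n]]))
    w <- merge_windows(cbind(e + delay, e + delay + width), K)
    windows[[n]] <- w
    for (i in seq_len(nrow(w)))
      values[n, (w[i, 1L] + 1L):w[i, 2L]] <- amplitude
  }
  structure(list(values = values, spike_windows = windows,
                 amplitude = amplitude),
            class = "target_signal")
}

# Merge overlapping/abutting half-open [start, end) windows, clip to [0, K).
merge_windows <- function(w, K) {
  if (is.null(w) || nrow(w) == 0L)
    return(matrix(numeric(), 0L, 2L, dimnames = list(NULL, c("start", "end"))))
  w[, 1L] <- pmax(w[, 1L], 0); w[, 2L] <- pmin(w[, 2L], K)
  w <- w[w[, 2L] > w[, 1L], , drop = FALSE]
  if (nrow(w) == 0L)
    return(matrix(numeric(), 0L, 2L, dimnames = list(NULL, c("start", "end"))))
  w <- w[order(w[, 1L]), , drop = FALSE]
  out <- w[1L, , drop = FALSE]
  for (i in seq_len(nrow(w))[-1L]) {
    if (w[i, 1L] <= out[nrow(out), 2L]) {
      out[nrow(out), 2L] <- max(out[nrow(out), 2L], w[i, 2L])
    } else out <- rbind(out, w[i, ])
  }
  dimnames(out) <- list(NULL, c("start", "end"))
  out
}

#' @export
print.target_signal <- function(x, ...) {
  cat(sprintf("<target_signal> %d output(s) x %d steps, amplitude %g, %s window(s)\n",
              nrow(x$values), ncol(x$values), x$amplitude,
              paste(vapply(x$spike_windows, nrow, 0L), collapse = "/")))
  invisible(x)
}

as_target_matrix <- function(Z) {
  if (inherits(Z, "target_signal")) Z$values
  else if (is.vector(Z)) matrix(Z, 1L) else Z
}

#' Solve output weights by regularized least squares
#'
#' Finds the dendrite-to-soma weights `W` minimizing
#' \eqn{\|WA - Z\|_F^2 + \lambda \|W\|_F^2} — the single-step linear
#' solution that constitutes training.  With `ridge > 0` (default 1e-8,
#' for numerical stability with rank-deficient activation matrices) the
#' solution is computed by QR factorization of the ridge-augmented
#' system; with `ridge = 0` it is the exact Moore-Penrose pseudoinverse
#' solution \eqn{W = Z A^+} via SVD, with singular values below
#' `sv_tol` (relative to the largest) discarded.
#'
#' @param A `M x K` activation matrix (dendrites x timesteps).
#' @param Z `N x K` target matrix, or a [build_target()] result.
#' @param ridge regularization \eqn{\lambda \ge 0} (default 1e-8).
#' @param sv_tol relative singular-value cutoff for the `ridge = 0` path
#'   (default: machine-precision based).
#' @return `N x M` weight matrix.  If `K < M` the system is
#'   underdetermined; a warning is issued and the minimum-norm solution
#'   returned.
#' @export
solve_batch <- function(A, Z, ridge = 1e-8, sv_tol = NULL) {
  Z <- as_target_matrix(Z)
  stopifnot(is.matrix(A), is.matrix(Z))
  M <- nrow(A); K <- ncol(A); N <- nrow(Z)
  if (ncol(Z) != K)
    stop_config("A and Z must have the same number of timesteps")
  if (ridge < 0) stop_config("`ridge` must be >= 0")
  if (K < M)
    warning("fewer timesteps (", K, ") than dendrites (", M,
            "): system is underdetermined; returning the minimum-norm solution",
            call. = FALSE)
  if (ridge > 0 && K >= M) {
    X <- rbind(t(A), sqrt(ridge) * diag(M))
    Y <- rbind(t(Z), matrix(0, M, N))
    Wt <- qr.coef(qr(X, LAPACK = TRUE), Y)
    t(Wt)
  } else {
    # SVD pseudoinverse (also used when K < M, where it is minimum-norm)
    s <- svd(A)
    if (is.null(sv_tol)) sv_tol <- max(M, K) * .Machine$double.eps
    keep <- s$d > sv_tol * max(s$d, 0)
    if (!any(keep)) return(matrix(0, N, M))
    d <- s$d[keep]
    filt <- if (ridge > 0) d / (d^2 + ridge) else 1 / d
    ZV <- Z %*% s$v[, keep, drop = FALSE]
    sweep(ZV, 2L, filt, `*`) %*% t(s$u[, keep, drop = FALSE])
  }
}

#' Solve output weights by recursive least squares
#'
#' Online counterpart of [solve_batch()]: processes the timestep samples
#' `(a_t, z_t)` one at a time, maintaining a rank-one-updated inverse
#' correlation matrix (initialized as `(1/ridge) I`).  After all samples
#' the result matches the batch ridge solution on the concatenated data;
#' since least squares is order-free, so is the stream order.
#'
#' @param A `M x K` activation matrix whose columns are the sample stream.
#' @param Z `N x K` target matrix (or [build_target()] result).
#' @param ridge initialization regularizer (> 0, default 1e-8).
#' @return `N x M` weight matrix.
#' @export
solve_incremental <- function(A, Z, ridge = 1e-8) {
  Z <- as_target_matrix(Z)
  stopifnot(is.matrix(A), is.matrix(Z))
  M <- nrow(A); K <- ncol(A); N <- nrow(Z)
  if (ncol(Z) != K)
    stop_config("A and Z must have the same number of timesteps")
  if (K < 1L) stop_config("at least one sample is required")
  if (ridge <= 0) stop_config("`ridge` must be > 0 for the incremental solver")
  P <- diag(M) / ridge
  W <- matrix(0, N, M)
  for (t in seq_len(K)) {
    a <- A[, t]
    Pa <- P %*% a
    g <- Pa / (1 + sum(a * Pa))
    W <- W + (Z[, t, drop = FALSE] - W %*% a) %*% t(g)
    P <- P - g %*% t(Pa)
    P <- (P + t(P)) / 2            # keep the state symmetric
  }
  W
}

#' Firing threshold from target amplitude
#'
#' The optimum output threshold is usually below half the target pulse
#' amplitude; a threshold of 25% of spike amplitude is the recommended
#' guideline and the default.
#'
#' @param amplitude target pulse amplitude.
#' @param fraction threshold fraction in (0, 1), default 0.25.
#' @return `fraction * amplitude`.
#' @export
choose_threshold <- function(amplitude, fraction = 0.25) {
  if (fraction <= 0 || fraction >= 1)
    stop_config("`fraction` must be in (0, 1)")
  fraction * amplitude
}

#' Synthesize (train) a SKIM network in a single pass
#'
#' Composes the full synthesis: draw fixed random input weights, sample a
#' kernel bank, run the forward projection on the training raster, build
#' the widened target signal from the pattern end times, solve the output
#' weights by regularized least squares, and set the firing threshold as
#' a fraction of the target amplitude.  There is no iteration — training
#' is one linear solve.
#'
#' @param raster training input [spike_raster()].
#' @param end_times pattern end timesteps (vector for one output, or list
#'   of vectors for several outputs).
#' @param M number of dendrites (default 100).
#' @param family kernel family (default `"alpha"`).
#' @param t_max pattern memory length in timesteps (default 200).
#' @param seed integer seed controlling all randomness of the synthesis.
#' @param ridge least-squares regularizer (default 1e-8).
#' @param width,delay,amplitude target-pulse shape, see [build_target()].
#' @param threshold_fraction threshold as a fraction of `amplitude`
#'   (default 0.25).
#' @param k,compression compression settings, see [kernel_spec()].
#' @param w_low,w_high,polarity input-weight settings, see
#'   [init_input_weights()].
#' @param ts_mode kernel time-constant sampling, see [sample_kernel_bank()].
#' @param order forward-pass order, see [dendritic_activations()].
#' @param solver `"batch"` (default) or `"incremental"`.
#' @return A [skim_model()]; its `config` field records the synthesis
#'   settings so the model can be pruned or extended later.
#' @export
skim_train <- function(raster, end_times, M = 100, family = "alpha",
                       t_max = 200, seed = NULL, ridge = 1e-8,
                       width = 10, delay = 10, amplitude = 1.0,
                       threshold_fraction = 0.25, k = 5,
                       compression = "logistic",
                       w_low = -0.5, w_high = 0.5, polarity = "mixed",
                       ts_mode = "uniform",
                       order = "filter_then_nonlinearity",
                       solver = c("batch", "incremental")) {
  solver <- match.arg(solver)
  stopifnot(inherits(raster, "spike_raster"))
  L <- raster$n_channels; K <- raster$n_steps
  pieces <- with_seed(seed, {
    w1 <- init_input_weights(L, M, low = w_low, high = w_high,
                             polarity = polarity)
    kb <- sample_kernel_bank(M, family = family, t_max = t_max, k = k,
                             compression = compression, ts_mode = ts_mode)
    list(w1 = w1, kb = kb)
  })
  u <- summed_input(raster, pieces$w1)
  A <- dendritic_activations(u, pieces$kb, order = order)
  Zt <- build_target(end_times, K, width = width, delay = delay,
                     amplitude = amplitude)
  W <- if (solver == "batch") solve_batch(A, Zt, ridge = ridge)
       else solve_incremental(A, Zt, ridge = ridge)
  model <- skim_model(input_weights = pieces$w1, kernels = pieces$kb,
                      output_weights = W,
                      threshold = choose_threshold(amplitude,
                                                   threshold_fraction),
                      target_amplitude = amplitude,
                      seed = if (is.null(seed)) NA_integer_ else seed,
                      dt = raster$dt, order = order)
  model$config <- list(family = family, t_max = t_max, ridge = ridge,
                       width = width, delay = delay, amplitude = amplitude,
                       threshold_fraction = threshold_fraction, k = k,
                       compression = compression, w_low = w_low,
                       w_high = w_high, polarity = polarity,
                       ts_mode = ts_mode)
  model
}

#' Training residual of a model
#'
#' Frobenius-norm residual \eqn{\|WA - Z\|_F} of the solved linear system
#' on a given input/target pair; the quantity pruning strategies compare.
#'
#' @param model a [skim_model()].
#' @param raster input [spike_raster()].
#' @param target a [build_target()] result (or `N x K` matrix).
#' @return Non-negative scalar.
#' @export
training_residual <- function(model, raster, target) {
  Z <- as_target_matrix(target)
  fw <- skim_run(model, raster, return_trace = TRUE)
  sqrt(sum((fw$y - Z)^2))
}
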
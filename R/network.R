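#' Initialize fixed random input weights
#'
#' The first-layer synaptic weights \eqn{w^{(1)}} project `L` input
#' channels onto `M` dendritic branches.  They are drawn i.i.d. uniform —
#' by default on (-0.5, 0.5) — and are never modified afterwards: together
#' with the kernel nonlinearity they form the random projection to a
#' higher-dimensional space, and only the dendrite-to-soma weights are
#' solved.  `polarity = "per_dendrite"` instead gives every weight within
#' one dendrite a common random sign (magnitudes uniform on `(0, high)`),
#' for settings where synapses must be purely excitatory or inhibitory.
#'
#' @param L number of input channels (> 0).
#' @param M number of dendrites (> 0).
#' @param low,high uniform range (default -0.5, 0.5); `low < high`.
#' @param seed integer seed; the matrix is deterministic given it.
#' @param polarity `"mixed"` (default) or `"per_dendrite"`.
#' @return `M x L` numeric matrix.
#' @export
init_input_weights <- function(L, M, low = -0.5, high = 0.5, seed = NULL,
                               polarity = c("mixed", "per_dendrite")) {
  L <- check_count(L, "L"); M <- check_count(M, "M")
  polarity <- match.arg(polarity)
  if (low >= high) stop_config("`low` must be < `high`")
  with_seed(seed, {
    if (polarity == "mixed") {
      matrix(stats::runif(M * L, low, high), M, L)
    } else {
      signs <- sample(c(-1, 1), M, replace = TRUE)
      signs * matrix(stats::runif(M * L, 0, high), M, L)
    }
  })
}

#' Weighted spike sum per dendrite
#'
#' Computes \eqn{u_{j,t} = \sum_i w^{(1)}_{ji} x_{i,t}}: the instantaneous
#' weighted sum of input spikes arriving at each dendrite.  Columns with
#' no input spike are exactly zero.
#'
#' @param raster input [spike_raster()] with `n_channels == ncol(input_weights)`.
#' @param input_weights `M x L` matrix from [init_input_weights()].
#' @return `M x K` numeric matrix.
#' @export
summed_input <- function(raster, input_weights) {
  stopifnot(inherits(raster, "spike_raster"), is.matrix(input_weights))
  if (ncol(input_weights) != raster$n_channels)
    stop_config("input_weights has ", ncol(input_weights),
                " columns but raster has ", raster$n_channels, " channels")
  M <- nrow(input_weights); K <- raster$n_steps
  u <- matrix(0, M, K)
  ev <- raster$events
  if (nrow(ev)) {
    # accumulate weight columns at the event timesteps (spikes superpose)
    for (t0 in unique(ev[, 1L])) {
      ch <- ev[ev[, 1L] == t0, 2L] + 1L
      u[, t0 + 1L] <- rowSums(input_weights[, ch, drop = FALSE])
    }
  }
  u
}

#' Dendritic activation matrix
#'
#' Converts the weighted spike sums into the design matrix `A` of
#' dendritic activations.  In the default order each dendrite's signal is
#' convolved with its truncated kernel impulse response (spike responses
#' superpose additively) and the compressive nonlinearity is applied to
#' the superposition — so a spike arriving on the tail of an earlier one
#' is compressed more, giving the synapse depressive adaptation.  The
#' alternate order `"nonlinearity_then_filter"` applies the compression
#' to the scaled spike impulses themselves before filtering, so every
#' event is scaled independently of spike history; it is supported for
#' comparison but loses the history-dependent adaptation and with it
#' computational power.
#'
#' @param u `M x K` matrix from [summed_input()].
#' @param kernels list of `M` [kernel_spec()] objects.
#' @return `M x K` activation matrix.  Column t depends only on spikes at
#'   timesteps <= t; under the default order with logistic or tanh
#'   compression all entries also lie strictly in (-0.5, 0.5) (up to
#'   floating-point saturation at the +/-0.5 asymptotes).
#' @param order `"filter_then_nonlinearity"` (default) or
#'   `"nonlinearity_then_filter"`.
#' @export
dendritic_activations <- function(u, kernels,
                                  order = c("filter_then_nonlinearity",
                                            "nonlinearity_then_filter")) {
  order <- match.arg(order)
  stopifnot(is.matrix(u))
  M <- nrow(u); K <- ncol(u)
  if (length(kernels) != M)
    stop_config("kernel count (", length(kernels),
                ") does not match dendrite count (", M, ")")
  Lh <- max(vapply(kernels, function(ks) ks$truncation, 0L))
  H <- matrix(0, Lh, M)
  for (j in seq_len(M))
    H[seq_len(kernels[[j]]$truncation), j] <- impulse_response(kernels[[j]])
  if (order == "filter_then_nonlinearity") {
    v <- t(conv_columns(t(u), H))          # M x K linear potentials
    a <- v
    for (j in seq_len(M))
      a[j, ] <- compress(v[j, ], kernels[[j]]$k, kernels[[j]]$compression)
    a
  } else {
    cu <- u
    for (j in seq_len(M))                  # compress the spike amplitudes
      cu[j, ] <- compress(u[j, ], kernels[[j]]$k, kernels[[j]]$compression)
    t(conv_columns(t(cu), H))
  }
}

#' Linear soma potentials
#'
#' The soma of each output neuron is a purely linear summing element:
#' \eqn{y = w^{(2)} A}, with no nonlinearity before thresholding.
#'
#' @param A `M x K` activation matrix.
#' @param output_weights `N x M` solved weight matrix.
#' @return `N x K` matrix of pre-threshold soma potentials.
#' @export
soma <- function(A, output_weights) {
  stopifnot(is.matrix(A), is.matrix(output_weights))
  if (ncol(output_weights) != nrow(A))
    stop_config("output_weights has ", ncol(output_weights),
                " columns but A has ", nrow(A), " rows")
  output_weights %*% A
}

#' Threshold soma potentials into output spikes
#'
#' An output spike is emitted at each rising-edge crossing: a timestep
#' where the soma potential reaches `theta` from below.  A sustained
#' supra-threshold plateau therefore emits exactly one spike at its onset
#' (closely overlapping recognitions merge into one event).
#'
#' @param y `N x K` matrix of soma potentials (or a vector for N = 1).
#' @param theta spike threshold (> 0).
#' @param dt milliseconds per timestep for the returned raster.
#' @return A [spike_raster()] with `N` channels.
#' @export
threshold_spikes <- function(y, theta, dt = 1.0) {
  if (is.vector(y)) y <- matrix(y, 1L)
  if (theta <= 0) stop_config("`theta` must be > 0")
  N <- nrow(y); K <- ncol(y)
  ev <- NULL
  for (n in seq_len(N)) {
    above <- y[n, ] >= theta
    rising <- above & !c(FALSE, above[-K])
    t0 <- which(rising) - 1L
    if (length(t0)) ev <- rbind(ev, cbind(t0, n - 1L))
  }
  spike_raster(ev, n_channels = N, n_steps = K, dt = dt)
}

# Stepwise forward pass with soma reset: pending kernel contributions are
# kept in a ring buffer and zeroed whenever any output fires, emulating
# hyperpolarization of the whole dendritic tree after a spike.
forward_stepwise_reset <- function(model, raster) {
  u_events <- summed_input(raster, model$input_weights)  # M x K, sparse cols
  M <- model$M; K <- raster$n_steps; N <- model$N
  Lh <- max(vapply(model$kernels, function(ks) ks$truncation, 0L))
  H <- matrix(0, Lh, M)
  for (j in seq_len(M))
    H[seq_len(model$kernels[[j]]$truncation), j] <-
      impulse_response(model$kernels[[j]])
  kk <- vapply(model$kernels, function(ks) ks$k, 0)
  kind <- vapply(model$kernels, function(ks) ks$compression, "")
  same_kind <- length(unique(kind)) == 1L
  P <- matrix(0, M, Lh)                    # ring buffer of pending potentials
  y <- matrix(0, N, K)
  A <- matrix(0, M, K)
  prev_above <- rep(FALSE, N)
  for (t in seq_len(K) - 1L) {
    amp <- u_events[, t + 1L]
    if (any(amp != 0)) {
      cols <- ((t + seq_len(Lh) - 1L) %% Lh) + 1L
      P[, cols] <- P[, cols] + amp * t(H)
    }
    idx <- (t %% Lh) + 1L
    v <- P[, idx]
    # per-dendrite compression (vectorized over the common case)
    if (same_kind) {
      a <- compress(kk * v, k = 1, kind = kind[1L])
    } else {
      a <- numeric(M)
      for (j in seq_len(M)) a[j] <- compress(v[j], kk[j], kind[j])
    }
    A[, t + 1L] <- a
    yt <- drop(model$output_weights %*% a)
    y[, t + 1L] <- yt
    above <- yt >= model$threshold
    if (any(above & !prev_above)) P[] <- 0  # reset all dendritic potentials
    prev_above <- above
    P[, idx] <- 0                            # consume the current slot
  }
  list(A = A, y = y)
}

#' Run the forward pass of a SKIM model
#'
#' Applies the full forward computation — random input projection,
#' synaptic kernel filtering, compression, linear soma summation and
#' thresholding — to an input raster.  The pass is a pure function of
#' `(raster, model)`.  With `reset = TRUE` the network is simulated
#' stepwise and all dendritic potentials are forced to zero after any
#' output fires (soma hyperpolarization); this rarely changes results and
#' is off by default.
#'
#' @param model a [skim_model()].
#' @param raster input [spike_raster()] with `model$L` channels.
#' @param reset zero dendritic state after an output spike (default FALSE).
#' @param return_trace also return the activation matrix and soma trace.
#' @return A [spike_raster()] of output spikes, or (with
#'   `return_trace = TRUE`) a list with elements `spikes`, `A` (`M x K`)
#'   and `y` (`N x K`).
#' @export
skim_run <- function(model, raster, reset = FALSE, return_trace = FALSE) {
  stopifnot(inherits(model, "skim_model"), inherits(raster, "spike_raster"))
  if (raster$n_channels != model$L)
    stop_config("raster has ", raster$n_channels,
                " channels but model expects ", model$L)
  if (reset) {
    fw <- forward_stepwise_reset(model, raster)
    A <- fw$A; y <- fw$y
  } else {
    u <- summed_input(raster, model$input_weights)
    A <- dendritic_activations(u, model$kernels, order = model$order)
    y <- soma(A, model$output_weights)
  }
  spikes <- threshold_spikes(y, model$threshold, dt = raster$dt)
  if (return_trace) list(spikes = spikes, A = A, y = y) else spikes
}
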
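#' Synaptic kernel specification
#'
#' A `kernel_spec` describes one dendrite's synaptic kernel: the linear
#' impulse response that converts a presynaptic spike into a persistent
#' continuous signal, plus the compressive nonlinearity applied after
#' superposition.  Supported families (response to a unit spike at t = 0,
#' before compression):
#'
#' * `alpha`: \eqn{r(t) = (t/\tau_s) e^{-t/\tau_s}} — rises then decays,
#'   peaking at \eqn{t = \tau_s} with value \eqn{1/e}; the standard model of
#'   a postsynaptic current.
#' * `leaky`: \eqn{r(t) = e^{-t/\tau_s}} — leaky integration, equivalent to
#'   a stable recurrent self-connection.
#' * `resonant`: \eqn{r(t) = e^{-t/\tau_s} \sin(\omega t)} — damped
#'   resonance.
#' * `delayed_alpha`: alpha function shifted by a synaptic/dendritic delay
#'   \eqn{\Delta T}; zero for \eqn{t < \Delta T}.
#' * `delayed_gaussian`: \eqn{r(t) = e^{-(t-\Delta T)^2 / 2\sigma^2}} for
#'   \eqn{t \ge \Delta T}, zero before the delay — narrow widths give high
#'   temporal precision at the cost of time-warp robustness.
#' * `custom`: a tabulated impulse response (values at integer timesteps
#'   starting from t = 0).
#'
#' `truncation` is the finite support length used for convolution; the
#' default is long enough that the dropped tail is below 1e-6 of the peak
#' in magnitude and below 1e-4 of the response in L1 mass.
#'
#' @param family kernel family, one of `"alpha"`, `"leaky"`, `"resonant"`,
#'   `"delayed_alpha"`, `"delayed_gaussian"`, `"custom"`.
#' @param ts time constant \eqn{\tau_s} in timesteps (families using it).
#' @param delay delay \eqn{\Delta T} in timesteps (0 for undelayed families).
#' @param omega angular frequency per timestep (`resonant` only).
#' @param sigma Gaussian width in timesteps (`delayed_gaussian` only).
#' @param custom_table numeric vector of impulse-response values at
#'   timesteps 0, 1, ... (`custom` only).
#' @param k compression gain (default 5).
#' @param compression `"logistic"` (default), `"tanh"` or `"none"`.
#' @param truncation support length in timesteps; `NULL` for the default.
#' @return An object of class `kernel_spec`.
#' @examples
#' ks <- kernel_spec("alpha", ts = 10)
#' impulse_response(ks, 11)[11]  # peak value 1/e at t = ts
#' @export
kernel_spec <- function(family = c("alpha", "leaky", "resonant",
                                   "delayed_alpha", "delayed_gaussian",
                                   "custom"),
                        ts = NULL, delay = 0, omega = NULL, sigma = NULL,
                        custom_table = NULL, k = 5,
                        compression = c("logistic", "tanh", "none"),
                        truncation = NULL) {
  family <- match.arg(family)
  compression <- match.arg(compression)
  if (k <= 0) stop_config("compression gain `k` must be > 0")
  if (delay < 0) stop_config("`delay` must be >= 0")
  needs_ts <- family %in% c("alpha", "leaky", "resonant", "delayed_alpha")
  if (needs_ts) {
    if (is.null(ts) || !is.numeric(ts) || ts <= 0)
      stop_config("family '", family, "' requires time constant `ts` > 0")
  } else ts <- NULL
  if (family == "resonant") {
    if (is.null(omega) || omega <= 0)
      stop_config("family 'resonant' requires `omega` > 0")
  } else omega <- NULL
  if (family == "delayed_gaussian") {
    if (is.null(sigma) || !is.numeric(sigma) || sigma <= 0)
      stop_config("family 'delayed_gaussian' requires `sigma` > 0")
  } else sigma <- NULL
  if (family == "custom") {
    if (is.null(custom_table) || !is.numeric(custom_table) ||
        length(custom_table) < 1L || anyNA(custom_table))
      stop_config("family 'custom' requires a numeric `custom_table`")
  } else custom_table <- NULL
  if (!family %in% c("delayed_alpha", "delayed_gaussian") && delay != 0)
    stop_config("`delay` is only meaningful for delayed families")
  spec <- structure(list(family = family, ts = ts, delay = delay,
                         omega = omega, sigma = sigma,
                         custom_table = custom_table, k = k,
                         compression = compression, truncation = NULL),
                    class = "kernel_spec")
  if (is.null(truncation)) truncation <- default_truncation(spec)
  truncation <- check_count(truncation, "truncation")
  spec$truncation <- truncation
  spec
}

# Support length keeping the dropped tail < 1e-6 x peak in magnitude and
# < 1e-4 of the L1 mass (alpha tail at 18 tau: (1+18)e^{-18} of total mass).
default_truncation <- function(spec) {
  switch(spec$family,
         alpha = ,
         leaky = ,
         resonant = ceiling(18 * spec$ts),
         delayed_alpha = ceiling(spec$delay + 18 * spec$ts),
         delayed_gaussian = ceiling(spec$delay + 11 * spec$sigma),
         custom = length(spec$custom_table))
}

#' @export
print.kernel_spec <- function(x, ...) {
  pars <- c(ts = x$ts, delay = if (x$delay > 0) x$delay, omega = x$omega,
            sigma = x$sigma)
  cat(sprintf("<kernel_spec> %s(%s), compression %s (k = %g), support %d\n",
              x$family,
              paste(names(pars), signif(pars, 4), sep = "=", collapse = ", "),
              x$compression, x$k, x$truncation))
  invisible(x)
}

# Continuous-time impulse response r(t), vectorized over t (timesteps).
kernel_fun <- function(spec) {
  switch(spec$family,
    alpha = function(t) ifelse(t >= 0, (t / spec$ts) * exp(-t / spec$ts), 0),
    leaky = function(t) ifelse(t >= 0, exp(-t / spec$ts), 0),
    resonant = function(t)
      ifelse(t >= 0, exp(-t / spec$ts) * sin(spec$omega * t), 0),
    delayed_alpha = function(t) {
      u <- t - spec$delay
      ifelse(u >= 0, (u / spec$ts) * exp(-u / spec$ts), 0)
    },
    delayed_gaussian = function(t) {
      # full Gaussian bump centred 5 sigma past the hard delay, so the
      # response is causal (exactly 0 before delay, < 4e-6 of peak at the
      # cut) yet keeps the standard 2*sigma*sqrt(2 ln 2) width at half max
      u <- t - spec$delay - 5 * spec$sigma
      ifelse(t >= spec$delay, exp(-u^2 / (2 * spec$sigma^2)), 0)
    },
    custom = {
      tab <- spec$custom_table
      f <- stats::approxfun(seq_along(tab) - 1, tab, rule = 2, yleft = 0)
      function(t) ifelse(t >= 0 & t <= length(tab) - 1, f(pmax(t, 0)), 0)
    })
}

#' Kernel impulse response on the timestep grid
#'
#' Returns the linear (uncompressed) response of a kernel to a unit spike
#' at timestep 0, sampled at timesteps `0, 1, ..., length - 1`.
#'
#' @param spec a [kernel_spec()].
#' @param length number of timesteps to return (default: the kernel's
#'   truncation length).
#' @return Numeric vector of the given length.
#' @export
impulse_response <- function(spec, length = spec$truncation) {
  stopifnot(inherits(spec, "kernel_spec"))
  length <- check_count(length, "length")
  kernel_fun(spec)(seq_len(length) - 1)
}

#' Compressive nonlinearity
#'
#' The saturating nonlinearity applied to dendritic potentials:
#' `logistic` maps v to \eqn{1/(1+e^{-kv}) - 1/2}, `tanh` to
#' \eqn{\tanh(kv)/2}, `none` is the identity.  Logistic and tanh outputs
#' lie strictly in (-0.5, 0.5), are odd-symmetric and monotone increasing;
#' this compression is what gives the synapse depressive adaptation (a
#' second spike riding on the tail of a first is compressed more).
#'
#' @param v numeric vector of pre-compression potentials.
#' @param k gain (> 0, default 5).
#' @param kind `"logistic"`, `"tanh"` or `"none"`.
#' @return Numeric vector, same length as `v`.
#' @examples
#' compress(1, k = 5)          # 1/(1 + exp(-5)) - 0.5
#' compress(0, k = 5)          # exactly 0
#' @export
compress <- function(v, k = 5, kind = c("logistic", "tanh", "none")) {
  kind <- match.arg(kind)
  if (k <= 0) stop_config("`k` must be > 0")
  switch(kind,
         logistic = 1 / (1 + exp(-k * v)) - 0.5,
         tanh = tanh(k * v) / 2,
         none = v)
}

# Locate the global maximum of the uncompressed response on [0, truncation]
# and verify unimodality: no second local maximum above half the peak.
kernel_peak <- function(spec, grid_step = 1e-3) {
  f <- kernel_fun(spec)
  tt <- seq(0, spec$truncation, by = grid_step)
  v <- f(tt)
  i <- which.max(v)
  peak_t <- tt[i]; peak_v <- v[i]
  if (peak_v <= 0) stop_config("kernel has non-positive peak")
  # interior local maxima above half height, other than the global one
  int <- which(diff(sign(diff(v))) == -2) + 1L
  rival <- int[v[int] > peak_v / 2 & abs(tt[int] - peak_t) > 10 * grid_step]
  if (length(rival) > 0L)
    stop_config("kernel response is multimodal; FWHM/preferred delay undefined")
  # refine off-grid unless the peak sits on the boundary
  if (i > 1L && i < length(tt)) {
    opt <- stats::optimize(f, lower = tt[i - 1L], upper = tt[i + 1L],
                           maximum = TRUE, tol = 1e-9)
    peak_t <- opt$maximum; peak_v <- opt$objective
  }
  list(t = peak_t, value = peak_v, grid_t = tt, grid_v = v)
}

#' Full width at half maximum of a kernel
#'
#' Width, in timesteps, between the two crossings of half the peak value
#' of the uncompressed impulse response.  Crossings are bracketed on a
#' fine grid (1e-3 timestep) and refined by root bisection; for kernels
#' that peak at t = 0 (e.g. `leaky`) the left crossing clamps to 0.
#' The FWHM sets the tolerance of a detector to spike jitter and linear
#' time warping: for the alpha kernel it is 244.6% of the time constant,
#' so pass windows widen linearly with \eqn{\tau_s}.
#'
#' @param spec a [kernel_spec()]; the response must have a single maximum
#'   over its support (verified numerically; multimodal kernels error).
#' @return FWHM in timesteps, accurate to better than 1e-2 timestep.
#' @examples
#' kernel_fwhm(kernel_spec("alpha", ts = 10))   # ~24.46
#' @export
kernel_fwhm <- function(spec) {
  stopifnot(inherits(spec, "kernel_spec"))
  pk <- kernel_peak(spec)
  f <- kernel_fun(spec)
  half <- pk$value / 2
  g <- function(t) f(t) - half
  tt <- pk$grid_t; v <- pk$grid_v
  below_l <- which(tt < pk$t & v < half)
  left <- if (length(below_l)) {
    i <- max(below_l)
    stats::uniroot(g, lower = tt[i], upper = pk$t, tol = 1e-9)$root
  } else 0
  below_r <- which(tt > pk$t & v < half)
  if (!length(below_r))
    stop_config("response does not fall below half maximum within support")
  i <- min(below_r)
  right <- stats::uniroot(g, lower = pk$t, upper = tt[i], tol = 1e-9)$root
  right - left
}

#' Preferred delay of a kernel
#'
#' The time of maximum amplitude of the uncompressed impulse response —
#' the delay at which a spike routed through this dendrite contributes
#' most strongly to the soma, i.e. the pathway's preferred delay.
#'
#' @inheritParams kernel_fwhm
#' @return Argmax time in timesteps.
#' @examples
#' preferred_delay(kernel_spec("alpha", ts = 10))  # 10
#' @export
preferred_delay <- function(spec) {
  stopifnot(inherits(spec, "kernel_spec"))
  kernel_peak(spec)$t
}

#' Sample a random bank of synaptic kernels
#'
#' Draws `M` kernels of one family with randomized timing parameters, the
#' mechanism by which the dendrites form a diverse (non-orthogonal) basis
#' of temporal features.  For `alpha`/`leaky`/`resonant`, time constants
#' are uniform on `(1, t_max/2]` — `t_max` being the longest interval over
#' which spikes must be remembered, and `ts ~ t_max/2` the useful
#' heuristic; `ts_mode = "heuristic"` instead fixes every `ts` at
#' `t_max/2`.  Delayed families draw `delay ~ Uniform(0, t_max)` with a
#' fixed shape parameter.
#'
#' @param M number of kernels (dendrites).
#' @param family kernel family (see [kernel_spec()]; not `custom`).
#' @param t_max pattern memory length in timesteps (>= 2).
#' @param seed integer seed; the bank is a deterministic function of it.
#' @param k,compression compression settings shared by the bank.
#' @param ts_mode `"uniform"` (default) or `"heuristic"`.
#' @param omega resonant angular frequency (default `2*pi/t_max`).
#' @param ts shape time constant for `delayed_alpha` (default `t_max/20`).
#' @param sigma Gaussian width for `delayed_gaussian` (default `t_max/40`).
#' @return List of `M` [kernel_spec()] objects.
#' @export
sample_kernel_bank <- function(M, family = "alpha", t_max, seed = NULL,
                               k = 5, compression = "logistic",
                               ts_mode = c("uniform", "heuristic"),
                               omega = NULL, ts = NULL, sigma = NULL) {
  M <- check_count(M, "M")
  t_max <- check_count(t_max, "t_max", min = 2L)
  ts_mode <- match.arg(ts_mode)
  if (!family %in% c("alpha", "leaky", "resonant", "delayed_alpha",
                     "delayed_gaussian"))
    stop_config("unknown kernel family for bank sampling: ", family)
  with_seed(seed, {
    if (family %in% c("alpha", "leaky", "resonant")) {
      tsv <- if (ts_mode == "heuristic") rep(t_max / 2, M)
             else stats::runif(M, 1, t_max / 2)
      if (family == "resonant") {
        if (is.null(omega)) omega <- 2 * pi / t_max
        lapply(tsv, function(t1)
          kernel_spec("resonant", ts = t1, omega = omega, k = k,
                      compression = compression))
      } else {
        lapply(tsv, function(t1)
          kernel_spec(family, ts = t1, k = k, compression = compression))
      }
    } else {
      delays <- stats::runif(M, 0, t_max)
      if (family == "delayed_alpha") {
        if (is.null(ts)) ts <- t_max / 20
        lapply(delays, function(d)
          kernel_spec("delayed_alpha", ts = ts, delay = d, k = k,
                      compression = compression))
      } else {
        if (is.null(sigma)) sigma <- t_max / 40
        lapply(delays, function(d)
          kernel_spec("delayed_gaussian", sigma = sigma, delay = d, k = k,
                      compression = compression))
      }
    }
  })
}

#' Read a custom kernel table from CSV
#'
#' Two-column CSV with header `timestep,value`; timesteps must be
#' consecutive integers starting at 0.
#'
#' @param path file to read.
#' @param ... further arguments passed to [kernel_spec()] (e.g. `k`,
#'   `compression`).
#' @return A `custom` [kernel_spec()].
#' @export
read_kernel_table <- function(path, ...) {
  tab <- utils::read.csv(path)
  if (!identical(names(tab), c("timestep", "value")))
    stop_config("kernel table must have header 'timestep,value'")
  if (!identical(as.integer(tab$timestep), seq_len(nrow(tab)) - 1L))
    stop_config("kernel table timesteps must be 0, 1, 2, ...")
  kernel_spec("custom", custom_table = as.numeric(tab$value), ...)
}
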
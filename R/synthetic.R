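#' Random spatio-temporal spike pattern
#'
#' Draws the fixed pattern a network is synthesized to detect: `n_spikes`
#' spikes placed uniformly at random (without duplicates) over
#' `L` channels x `duration` timesteps.  A channel may carry zero, one or
#' several spikes.  The defaults reproduce the toy recognition task: nine
#' spikes over five channels in a 200-step window.
#'
#' @param L number of input channels (default 5).
#' @param n_spikes number of spikes in the pattern (default 9).
#' @param duration pattern window length in timesteps (default 200).
#' @param seed integer seed; the pattern is deterministic given it.
#' @param max_per_channel optional cap on spikes per channel (e.g. 3);
#'   `NULL` (default) leaves placement unconstrained.
#' @return An object of class `pattern_spec` with fields `spikes`
#'   (matrix with columns `channel`, `offset`, 0-based), `n_channels`,
#'   `duration`, `seed`.
#' @export
make_pattern <- function(L = 5, n_spikes = 9, duration = 200, seed = NULL,
                         max_per_channel = NULL) {
  L <- check_count(L, "L")
  n_spikes <- check_count(n_spikes, "n_spikes")
  duration <- check_count(duration, "duration")
  if (n_spikes > L * duration)
    stop_config("n_spikes (", n_spikes, ") exceeds the ", L * duration,
                " available (channel, offset) cells")
  if (!is.null(max_per_channel) && n_spikes > L * max_per_channel)
    stop_config("n_spikes exceeds L * max_per_channel")
  with_seed(seed, {
    if (is.null(max_per_channel)) {
      cells <- sample.int(L * duration, n_spikes)
      ch <- (cells - 1L) %% L
      off <- (cells - 1L) %/% L
    } else {
      ch <- integer(0); off <- integer(0)
      count <- integer(L)
      while (length(ch) < n_spikes) {
        c1 <- sample.int(L, 1L) - 1L
        if (count[c1 + 1L] >= max_per_channel) next
        o1 <- sample.int(duration, 1L) - 1L
        if (any(ch == c1 & off == o1)) next
        ch <- c(ch, c1); off <- c(off, o1)
        count[c1 + 1L] <- count[c1 + 1L] + 1L
      }
    }
    ord <- order(off, ch)
    structure(list(spikes = cbind(channel = as.integer(ch[ord]),
                                  offset = as.integer(off[ord])),
                   n_channels = L, duration = duration,
                   seed = if (is.null(seed)) NA_integer_ else
                     as.integer(seed)),
              class = "pattern_spec")
  })
}

#' @export
print.pattern_spec <- function(x, ...) {
  cat(sprintf("<pattern_spec> %d spikes on %d channels over %d steps\n",
              nrow(x$spikes), x$n_channels, x$duration))
  invisible(x)
}

#' Uniformly time-warp a pattern
#'
#' Scales all spike offsets (and the duration) by `factor`, rounding to
#' the nearest timestep — the model of variable speech cadence, e.g.
#' warps drawn between 76% and 124% of the original.  Channel identities
#' and spike count are unchanged.
#'
#' @param pattern a [make_pattern()] result.
#' @param factor warp factor (> 0); 1 is the identity.
#' @return A warped `pattern_spec`.
#' @export
time_warp <- function(pattern, factor) {
  stopifnot(inherits(pattern, "pattern_spec"))
  if (factor <= 0) stop_config("`factor` must be > 0")
  duration <- max(1L, as.integer(round(pattern$duration * factor)))
  off <- pmin(as.integer(round(pattern$spikes[, "offset"] * factor)),
              duration - 1L)
  out <- pattern
  out$duration <- duration
  out$spikes <- cbind(channel = pattern$spikes[, "channel"], offset = off)
  ord <- order(out$spikes[, "offset"], out$spikes[, "channel"])
  out$spikes <- out$spikes[ord, , drop = FALSE]
  out
}

#' Jitter a pattern's spike times
#'
#' Perturbs each offset by rounded zero-mean Gaussian noise of standard
#' deviation `sd` timesteps, clipped to `[0, duration)`.
#'
#' @param pattern a [make_pattern()] result.
#' @param sd jitter standard deviation in timesteps (>= 0).
#' @param seed integer seed.
#' @return A jittered `pattern_spec`.
#' @export
jitter_pattern <- function(pattern, sd, seed = NULL) {
  stopifnot(inherits(pattern, "pattern_spec"))
  if (sd < 0) stop_config("`sd` must be >= 0")
  if (sd == 0) return(pattern)
  with_seed(seed, {
    off <- pattern$spikes[, "offset"] +
      as.integer(round(stats::rnorm(nrow(pattern$spikes), 0, sd)))
    off <- pmin(pmax(off, 0L), pattern$duration - 1L)
    out <- pattern
    out$spikes <- cbind(channel = pattern$spikes[, "channel"],
                        offset = as.integer(off))
    ord <- order(out$spikes[, "offset"], out$spikes[, "channel"])
    out$spikes <- out$spikes[ord, , drop = FALSE]
    out
  })
}

#' Embed pattern presentations in Poisson noise
#'
#' Builds a long input sequence in which exact copies of the pattern
#' (optionally warped/jittered per presentation) occur as a Poisson
#' process, overlapping freely, on top of independent uniform Poisson
#' noise spikes.  By default the expected number of noise spikes equals
#' the expected number of pattern spikes (`noise_ratio = 1`).  Collisions
#' resolve by OR — the raster is binary.  The reference task uses ~580
#' presentations of a 9-spike pattern in 1e5 timesteps.
#'
#' @param pattern a [make_pattern()] result.
#' @param K sequence length in timesteps (>= `pattern$duration`).
#' @param presentation_rate expected presentations per timestep
#'   (default `580 / 1e5`).
#' @param noise_ratio expected noise spikes per expected pattern spike
#'   (>= 0, default 1).
#' @param seed integer seed.
#' @param warp_range optional length-2 vector; each presentation is
#'   time-warped by a factor drawn uniformly from this range.
#' @param jitter_sd optional per-presentation spike jitter (timesteps).
#' @return An object of class `embedded_sequence`: list with `raster`
#'   (the [spike_raster()]), `presentation_end_times` (sorted, one per
#'   embedded copy: the timestep one past the copy's last input spike —
#'   the end of its input sequence, which training targets are placed
#'   relative to), `n_pattern_spikes` and `n_noise_spikes` (distinct
#'   raster cells attributable to each).
#' @export
embed_pattern <- function(pattern, K, presentation_rate = 580 / 1e5,
                          noise_ratio = 1.0, seed = NULL,
                          warp_range = NULL, jitter_sd = 0) {
  stopifnot(inherits(pattern, "pattern_spec"))
  K <- check_count(K, "K")
  if (K < pattern$duration)
    stop_config("K must be at least the pattern duration")
  if (noise_ratio < 0) stop_config("`noise_ratio` must be >= 0")
  with_seed(seed, {
    L <- pattern$n_channels
    span <- K - pattern$duration + 1L   # admissible start positions
    n_pres <- stats::rpois(1L, presentation_rate * span)
    starts <- sort(sample.int(span, n_pres, replace = TRUE) - 1L)
    ev <- matrix(integer(), 0L, 2L)
    ends <- integer(0)
    n_placed <- 0L
    for (s in starts) {
      p <- pattern
      if (!is.null(warp_range))
        p <- time_warp(p, stats::runif(1L, warp_range[1L], warp_range[2L]))
      if (jitter_sd > 0)
        p <- jitter_pattern(p, jitter_sd)
      if (s + p$duration > K) next      # warped copy no longer fits
      ev <- rbind(ev, cbind(s + p$spikes[, "offset"], p$spikes[, "channel"]))
      # a presentation "ends" one step past its last input spike: targets
      # are placed relative to the end of the input sequence, not the
      # nominal pattern window
      ends <- c(ends, s + max(p$spikes[, "offset"]) + 1L)
      n_placed <- n_placed + nrow(p$spikes)
    }
    pat_cells <- unique(ev)
    expected_pattern_spikes <- presentation_rate * span * nrow(pattern$spikes)
    n_noise <- stats::rpois(1L, noise_ratio * expected_pattern_spikes)
    noise <- cbind(sample.int(K, n_noise, replace = TRUE) - 1L,
                   sample.int(L, n_noise, replace = TRUE) - 1L)
    all_ev <- rbind(pat_cells, noise)
    raster <- spike_raster(all_ev, n_channels = L, n_steps = K)
    structure(list(raster = raster,
                   presentation_end_times = sort(ends),
                   n_pattern_spikes = nrow(pat_cells),
                   n_noise_spikes = n_events(raster) - nrow(pat_cells)),
              class = "embedded_sequence")
  })
}

#' @export
print.embedded_sequence <- function(x, ...) {
  cat(sprintf(paste0("<embedded_sequence> %d presentations in %d steps; ",
                     "%d pattern + %d noise spike cells\n"),
              length(x$presentation_end_times), x$raster$n_steps,
              x$n_pattern_spikes, x$n_noise_spikes))
  invisible(x)
}
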
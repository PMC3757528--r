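#' Score output spikes against ground-truth windows
#'
#' Windowed detection scoring for continuous sequences.  Overlapping
#' truth windows are merged first.  A truth window containing at least
#' one output spike is a true positive, otherwise a false negative.  The
#' complement of the truth windows is tiled into negative windows of the
#' nominal truth-window length (a shorter remainder tile closes each
#' gap); a negative window containing an output spike is a false
#' positive, otherwise a true negative.
#'
#' @param output a [spike_raster()] of output spikes (channel 0 is
#'   scored), or a vector of 0-based spike timesteps.
#' @param truth_windows two-column matrix of half-open `[start, end)`
#'   timestep intervals (e.g. `build_target(...)$spike_windows[[1]]`).
#' @param K sequence length; windows must lie within `[0, K)`.
#' @param channel which output channel to score when `output` is a
#'   raster (0-based, default 0).
#' @return An object of class `eval_counts`: list with `tp`, `fp`, `tn`,
#'   `fn`, `n_positive_windows`, `n_negative_windows`
#'   (`tp + fn = n_positive_windows`, `fp + tn = n_negative_windows`).
#' @export
match_detections <- function(output, truth_windows, K, channel = 0L) {
  K <- check_count(K, "K")
  if (inherits(output, "spike_raster")) {
    ev <- output$events
    spikes <- ev[ev[, "channel"] == channel, "timestep"]
  } else spikes <- as.numeric(output)
  if (any(spikes < 0 | spikes >= K)) stop_config("spikes outside [0, K)")
  if (is.null(dim(truth_windows)))
    truth_windows <- matrix(truth_windows, ncol = 2L)
  if (nrow(truth_windows) &&
      (any(truth_windows < 0) || any(truth_windows > K)))
    stop_config("truth windows outside [0, K)")
  len <- if (nrow(truth_windows))
    round(mean(truth_windows[, 2L] - truth_windows[, 1L])) else K
  len <- max(1L, len)
  win <- merge_windows(truth_windows, K)
  has_spike <- function(s, e) any(spikes >= s & spikes < e)
  tp <- 0L; fn <- 0L
  for (i in seq_len(nrow(win))) {
    if (has_spike(win[i, 1L], win[i, 2L])) tp <- tp + 1L else fn <- fn + 1L
  }
  # tile the complement into windows of the nominal length
  gaps <- if (nrow(win) == 0L) matrix(c(0, K), 1L) else {
    starts <- c(0, win[, 2L]); ends <- c(win[, 1L], K)
    cbind(starts, ends)[starts < ends, , drop = FALSE]
  }
  fp <- 0L; tn <- 0L
  for (i in seq_len(nrow(gaps))) {
    s <- gaps[i, 1L]
    while (s < gaps[i, 2L]) {
      e <- min(s + len, gaps[i, 2L])
      if (has_spike(s, e)) fp <- fp + 1L else tn <- tn + 1L
      s <- e
    }
  }
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 n_positive_windows = tp + fn,
                 n_negative_windows = fp + tn),
            class = "eval_counts")
}

#' @export
print.eval_counts <- function(x, ...) {
  cat(sprintf("<eval_counts> tp %d / fn %d (of %d positive), fp %d / tn %d (of %d negative)\n",
              x$tp, x$fn, x$n_positive_windows,
              x$fp, x$tn, x$n_negative_windows))
  invisible(x)
}

#' Detection error (sum of miss and false-alarm rates)
#'
#' The challenge scoring metric: the false-negative term plus the
#' false-positive term.  Under the default `"ground_truth"` reading the
#' denominators are the ground-truth positive and negative counts,
#' `fn / n_positive + fp / n_negative` — bounded in `[0, 2]`, zero iff
#' detection is perfect, and well-defined even when nothing is detected.
#' The `"detected"` reading divides by the detected counts (`fn / tp +
#' fp / tn`) and errors when either denominator is zero.
#'
#' @param counts an `eval_counts` object from [match_detections()] (or a
#'   list with fields `tp`, `fp`, `tn`, `fn`, `n_positive_windows`,
#'   `n_negative_windows`).
#' @param interpretation `"ground_truth"` (default) or `"detected"`.
#' @return Non-negative scalar error.
#' @examples
#' error_metric(list(tp = 45, fn = 5, fp = 10, tn = 440,
#'                   n_positive_windows = 50, n_negative_windows = 450))
#' @export
error_metric <- function(counts,
                         interpretation = c("ground_truth", "detected")) {
  interpretation <- match.arg(interpretation)
  if (interpretation == "ground_truth") {
    if (counts$n_positive_windows <= 0 || counts$n_negative_windows <= 0)
      stop_config("error metric undefined: zero positive or negative windows")
    counts$fn / counts$n_positive_windows +
      counts$fp / counts$n_negative_windows
  } else {
    if (counts$tp <= 0 || counts$tn <= 0)
      stop_config("error metric undefined: zero true positives or negatives")
    counts$fn / counts$tp + counts$fp / counts$tn
  }
}

#' Evaluate a model on a spike sequence
#'
#' Runs the forward pass on a test sequence and scores the output against
#' detection windows derived from the ground-truth pattern end times.
#' Each presentation ending at `e` is scored over a window of length
#' `window` centred on the middle of its trained target pulse
#' (`e + delay + width/2`) — the continuous-sequence analogue of
#' per-utterance scoring, with the default window equal to one nominal
#' pattern duration (200 timesteps).
#'
#' Two detection semantics are available.  `"state"` (default) scores a
#' window as detected if the soma is in the spiking state (potential at
#' or above threshold) at any point inside it: a broad supra-threshold
#' event spanning two overlapping presentations then counts for both,
#' matching how merged output events are read off the soma trace.
#' `"edge"` requires a discrete rising-edge spike (see
#' [threshold_spikes()]) inside the window, so a merged event counts only
#' toward the window holding its onset.
#'
#' @param model a [skim_model()].
#' @param raster test input [spike_raster()].
#' @param end_times ground-truth pattern end timesteps.
#' @param window scoring window length in timesteps (default 200).
#' @param semantics `"state"` (default) or `"edge"`, as above.
#' @param interpretation denominator reading for [error_metric()].
#' @return List with `counts` (an `eval_counts`), `error`, and `spikes`
#'   (the rising-edge output [spike_raster()]).
#' @export
skim_evaluate <- function(model, raster, end_times, window = 200,
                          semantics = c("state", "edge"),
                          interpretation = "ground_truth") {
  stopifnot(inherits(model, "skim_model"))
  semantics <- match.arg(semantics)
  if (is.null(window)) window <- 200
  fw <- skim_run(model, raster, return_trace = TRUE)
  d <- model$config$delay %||% 10; w <- model$config$width %||% 10
  ctr <- sort(as.numeric(end_times)) + d + w / 2
  K <- raster$n_steps
  win <- cbind(pmax(ctr - window / 2, 0), pmin(ctr + window / 2, K))
  win <- win[win[, 2L] > win[, 1L], , drop = FALSE]
  detect <- if (semantics == "state") {
    which(fw$y[1L, ] >= model$threshold) - 1L
  } else fw$spikes
  counts <- match_detections(detect, win, K = K)
  list(counts = counts,
       error = error_metric(counts, interpretation = interpretation),
       spikes = fw$spikes)
}
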
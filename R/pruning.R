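# Dendrite importance: summed |w2| across output neurons, so pruning works
# for multi-output models on a scale-fair aggregate.
dendrite_importance <- function(output_weights)
  colSums(abs(output_weights))

#' Cumulative weight-concentration curve
#'
#' For one output neuron, sorts the solved dendritic weights by absolute
#' magnitude (descending) and returns the cumulative share of the total
#' absolute weight mass contributed by the top-1, top-2, ... top-M
#' dendrites.  In typical solutions the mass is strongly concentrated —
#' about a quarter of the dendrites carry half the solution and half of
#' them carry ~80% — which is what makes magnitude-based pruning viable.
#'
#' @param output_weights `N x M` solved weight matrix (or a [skim_model()]).
#' @param output which output neuron's row to analyse (1-based, default 1).
#' @return An object of class `concentration_curve`: a list with
#'   `fractions` (length-M non-decreasing concave sequence ending at 1)
#'   and `order` (dendrite indices sorted by descending `|weight|`).
#' @examples
#' weight_concentration(matrix(c(3, 1, 0, 0), 1))$fractions  # 0.75 1 1 1
#' @export
weight_concentration <- function(output_weights, output = 1L) {
  if (inherits(output_weights, "skim_model"))
    output_weights <- output_weights$output_weights
  stopifnot(is.matrix(output_weights))
  w <- abs(output_weights[output, ])
  total <- sum(w)
  if (total <= 0)
    stop_config("output row ", output, " has zero total absolute weight")
  ord <- order(w, decreasing = TRUE)
  structure(list(fractions = cumsum(w[ord]) / total, order = ord),
            class = "concentration_curve")
}

#' @export
print.concentration_curve <- function(x, ...) {
  M <- length(x$fractions)
  probe <- unique(pmax(1L, round(M * c(0.25, 0.5, 1))))
  cat(sprintf("<concentration_curve> M = %d; share at top %s: %s\n", M,
              paste0(probe, collapse = "/"),
              paste0(sprintf("%.1f%%", 100 * x$fractions[probe]),
                     collapse = "/")))
  invisible(x)
}

# Rebuild a model from a subset (or replacement set) of dendrites and a
# freshly solved weight matrix.
subset_model <- function(model, idx, W) {
  m <- skim_model(input_weights = model$input_weights[idx, , drop = FALSE],
                  kernels = model$kernels[idx],
                  output_weights = W, threshold = model$threshold,
                  target_amplitude = model$target_amplitude,
                  seed = model$seed, dt = model$dt, order = model$order)
  m$config <- model$config
  m
}

#' Two-pass synaptic pruning
#'
#' Over-provision, train, prune, re-solve: keeps the `keep` dendrites with
#' the largest summed absolute output weight, discards the rest (their
#' input weights and kernels are removed from the model), and re-solves
#' the output weights on the same training data.  Re-solving is mandatory
#' — the surviving dendrites' old weights are no longer optimal once
#' their companions are gone.  Starting from a network ~10x larger than
#' the final size, this typically beats a same-size network trained once.
#'
#' @param model trained [skim_model()].
#' @param raster training input [spike_raster()].
#' @param target training [build_target()] result (or `N x K` matrix).
#' @param keep number of dendrites to retain (1 <= keep <= M).
#' @param ridge regularizer for the re-solve (default: the model's
#'   training ridge).
#' @return A [skim_model()] with `keep` dendrites and re-solved weights.
#' @export
prune_two_pass <- function(model, raster, target, keep,
                           ridge = NULL) {
  stopifnot(inherits(model, "skim_model"))
  keep <- check_count(keep, "keep")
  if (keep > model$M)
    stop_config("`keep` (", keep, ") exceeds dendrite count (", model$M, ")")
  if (is.null(ridge)) ridge <- model$config$ridge %||% 1e-8
  imp <- dendrite_importance(model$output_weights)
  idx <- sort(order(imp, decreasing = TRUE)[seq_len(keep)])
  u <- summed_input(raster, model$input_weights[idx, , drop = FALSE])
  A <- dendritic_activations(u, model$kernels[idx], order = model$order)
  W <- solve_batch(A, as_target_matrix(target), ridge = ridge)
  subset_model(model, idx, W)
}

#' Iterative discard-and-replace pruning
#'
#' Keeps the network at a constant size `n_keep` while repeatedly
#' discarding the `n_replace` dendrites with the lowest solved weight
#' magnitude, sampling that many fresh random dendrites (input weights
#' and kernels drawn as at synthesis), and re-solving.  Over iterations
#' the dendrite pool drifts toward features that matter for the task,
#' typically ending below the residual of a same-size network trained
#' once.
#'
#' @inheritParams prune_two_pass
#' @param n_keep network size (must equal the model's dendrite count).
#' @param n_replace dendrites replaced per round (< `n_keep`).
#' @param iterations number of discard/replace/re-solve rounds (>= 1).
#' @param seed integer seed for the fresh dendrites (deterministic).
#' @return A [skim_model()] with `n_keep` dendrites and freshly solved
#'   weights.
#' @export
prune_iterative <- function(model, raster, target, n_keep, n_replace,
                            iterations, seed = NULL, ridge = NULL) {
  stopifnot(inherits(model, "skim_model"))
  n_keep <- check_count(n_keep, "n_keep")
  n_replace <- check_count(n_replace, "n_replace", min = 0L)
  iterations <- check_count(iterations, "iterations")
  if (model$M != n_keep)
    stop_config("model has ", model$M, " dendrites; expected n_keep = ", n_keep)
  if (n_replace >= n_keep)
    stop_config("`n_replace` must be < `n_keep`")
  if (is.null(ridge)) ridge <- model$config$ridge %||% 1e-8
  cfg <- model$config
  if (is.null(cfg$family))
    stop_config("model carries no synthesis config; train with skim_train()")
  Z <- as_target_matrix(target)
  X <- as_dense(raster)
  w1 <- model$input_weights
  kb <- model$kernels
  A <- dendritic_activations(w1 %*% X, kb, order = model$order)
  W <- solve_batch(A, Z, ridge = ridge)
  with_seed(seed, {
    for (it in seq_len(iterations)) {
      if (n_replace > 0L) {
        drop_idx <- order(dendrite_importance(W))[seq_len(n_replace)]
        w_new <- init_input_weights(raster$n_channels, n_replace,
                                    low = cfg$w_low %||% -0.5,
                                    high = cfg$w_high %||% 0.5,
                                    polarity = cfg$polarity %||% "mixed")
        k_new <- sample_kernel_bank(n_replace, family = cfg$family,
                                    t_max = cfg$t_max,
                                    k = cfg$k %||% 5,
                                    compression = cfg$compression %||%
                                      "logistic",
                                    ts_mode = cfg$ts_mode %||% "uniform")
        w1[drop_idx, ] <- w_new
        kb[drop_idx] <- k_new
        A[drop_idx, ] <- dendritic_activations(w_new %*% X, k_new,
                                               order = model$order)
      }
      W <- solve_batch(A, Z, ridge = ridge)
    }
  })
  out <- skim_model(input_weights = w1, kernels = kb, output_weights = W,
                    threshold = model$threshold,
                    target_amplitude = model$target_amplitude,
                    seed = model$seed, dt = model$dt, order = model$order)
  out$config <- cfg
  out
}
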
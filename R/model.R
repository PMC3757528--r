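#' SKIM network model
#'
#' The complete description of a synthesized network: `L` input neurons
#' fan out through fixed random weights \eqn{w^{(1)}} (`M x L`) to `M`
#' dendritic branches, each with its own synaptic kernel; the solved
#' linear weights \eqn{w^{(2)}} (`N x M`) connect the dendrites to `N`
#' linear soma elements, and the axon hillock emits a spike whenever a
#' soma potential crosses `threshold` from below.
#'
#' @param input_weights `M x L` fixed random weight matrix.
#' @param kernels list of `M` [kernel_spec()] objects.
#' @param output_weights `N x M` solved weight matrix.
#' @param threshold firing threshold \eqn{\theta > 0}.
#' @param target_amplitude amplitude of the training target pulse
#'   (default 1); `threshold` is usually a fraction of it.
#' @param seed integer seed the network was built from (metadata).
#' @param dt milliseconds per timestep (metadata, default 1).
#' @param order forward-pass order, `"filter_then_nonlinearity"` (default)
#'   or `"nonlinearity_then_filter"`.
#' @return An object of class `skim_model` with fields `L`, `M`, `N`,
#'   `input_weights`, `kernels`, `output_weights`, `threshold`,
#'   `target_amplitude`, `seed`, `dt`, `order`.
#' @export
skim_model <- function(input_weights, kernels, output_weights,
                       threshold, target_amplitude = 1.0, seed = NA_integer_,
                       dt = 1.0, order = "filter_then_nonlinearity") {
  stopifnot(is.matrix(input_weights), is.matrix(output_weights))
  M <- nrow(input_weights); L <- ncol(input_weights)
  N <- nrow(output_weights)
  if (ncol(output_weights) != M)
    stop_config("output_weights must be N x M with M = ", M,
                " (got ", ncol(output_weights), " columns)")
  if (length(kernels) != M)
    stop_config("kernels must have exactly M = ", M, " entries")
  if (!all(vapply(kernels, inherits, TRUE, "kernel_spec")))
    stop_config("all kernels must be kernel_spec objects")
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop_config("`threshold` must be a single value > 0")
  if (!order %in% c("filter_then_nonlinearity", "nonlinearity_then_filter"))
    stop_config("unknown forward-pass order: ", order)
  structure(list(L = L, M = M, N = N,
                 input_weights = input_weights, kernels = kernels,
                 output_weights = output_weights, threshold = threshold,
                 target_amplitude = target_amplitude,
                 seed = as.integer(seed), dt = dt, order = order),
            class = "skim_model")
}

#' @export
print.skim_model <- function(x, ...) {
  fam <- table(vapply(x$kernels, function(ks) ks$family, ""))
  cat(sprintf("<skim_model> L = %d inputs, M = %d dendrites, N = %d outputs\n",
              x$L, x$M, x$N))
  cat(sprintf("  kernels: %s\n",
              paste(sprintf("%s x%d", names(fam), fam), collapse = ", ")))
  cat(sprintf("  threshold = %g (target amplitude %g), dt = %g ms, seed = %s\n",
              x$threshold, x$target_amplitude, x$dt,
              ifelse(is.na(x$seed), "NA", x$seed)))
  invisible(x)
}

MODEL_FORMAT_VERSION <- 1L

kernels_to_table <- function(kernels) {
  num <- function(x) if (is.null(x)) NA_real_ else x
  data.frame(
    family = vapply(kernels, function(k) k$family, ""),
    ts = vapply(kernels, function(k) num(k$ts), 0),
    delay = vapply(kernels, function(k) k$delay, 0),
    omega = vapply(kernels, function(k) num(k$omega), 0),
    sigma = vapply(kernels, function(k) num(k$sigma), 0),
    k = vapply(kernels, function(k) k$k, 0),
    compression = vapply(kernels, function(k) k$compression, ""),
    truncation = vapply(kernels, function(k) k$truncation, 0L),
    stringsAsFactors = FALSE)
}

kernels_from_table <- function(tab, custom_tables) {
  opt <- function(x) if (is.na(x)) NULL else x
  lapply(seq_len(nrow(tab)), function(i) {
    kernel_spec(tab$family[i], ts = opt(tab$ts[i]), delay = tab$delay[i],
                omega = opt(tab$omega[i]), sigma = opt(tab$sigma[i]),
                custom_table = if (tab$family[i] == "custom")
                  custom_tables[[as.character(i)]] else NULL,
                k = tab$k[i], compression = tab$compression[i],
                truncation = tab$truncation[i])
  })
}

#' Save / load a SKIM model
#'
#' Serializes the full model — weight matrices, kernel parameter table and
#' scalar attributes (`L`, `M`, `N`, `threshold`, `seed`, `dt`,
#' `format_version`) — to a JSON container at full numeric precision, so
#' that `load_model(save_model(m))` reproduces every field exactly.
#'
#' @param model a [skim_model()].
#' @param path destination (`save_model`) or source (`load_model`) file.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   reconstructed [skim_model()].  A file missing a required dataset or
#'   written by a different format version raises a format error.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "skim_model"))
  custom <- list()
  for (i in seq_along(model$kernels))
    if (model$kernels[[i]]$family == "custom")
      custom[[as.character(i)]] <- model$kernels[[i]]$custom_table
  obj <- list(
    format_version = MODEL_FORMAT_VERSION,
    L = model$L, M = model$M, N = model$N,
    threshold = model$threshold,
    target_amplitude = model$target_amplitude,
    seed = model$seed, dt = model$dt, order = model$order,
    input_weights = model$input_weights,
    output_weights = model$output_weights,
    kernel_table = kernels_to_table(model$kernels),
    custom_tables = custom)
  # digits = I(17): full IEEE double precision, so reload is bit-exact
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       na = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop_config("model file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("format_version", "L", "M", "N", "threshold", "seed", "dt",
                "input_weights", "output_weights", "kernel_table")
  missing <- setdiff(required, names(obj))
  if (length(missing))
    stop_config("model format error: missing dataset(s) ",
                paste(missing, collapse = ", "), " in ", path)
  if (obj$format_version != MODEL_FORMAT_VERSION)
    stop_config("model format error: version ", obj$format_version,
                " (expected ", MODEL_FORMAT_VERSION, ")")
  iw <- matrix(as.numeric(obj$input_weights), obj$M, obj$L)
  ow <- matrix(as.numeric(obj$output_weights), obj$N, obj$M)
  custom <- lapply(obj$custom_tables, as.numeric)
  skim_model(input_weights = iw,
             kernels = kernels_from_table(obj$kernel_table, custom),
             output_weights = ow, threshold = obj$threshold,
             target_amplitude = obj$target_amplitude %||% 1.0,
             seed = obj$seed, dt = obj$dt,
             order = obj$order %||% "filter_then_nonlinearity")
}
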
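# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

stop_config <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x != floor(x))
    stop_config(sprintf("`%s` must be a single integer >= %d", name, min))
  as.integer(x)
}

# Linear convolution of each column of `u` (time down the rows) with the
# matching column of `h`, truncated to the first nrow(u) samples.  FFT with
# power-of-two padding; columns are processed in blocks to bound memory.
conv_columns <- function(u, h, block = 128L) {
  K <- nrow(u); Lh <- nrow(h); M <- ncol(u)
  stopifnot(ncol(h) == M)
  n <- 2^ceiling(log2(K + Lh - 1))
  out <- matrix(0, K, M)
  for (j0 in seq(1L, M, by = block)) {
    j1 <- min(j0 + block - 1L, M)
    Up <- rbind(u[, j0:j1, drop = FALSE], matrix(0, n - K, j1 - j0 + 1L))
    Hp <- rbind(h[, j0:j1, drop = FALSE], matrix(0, n - Lh, j1 - j0 + 1L))
    out[, j0:j1] <- Re(mvfft(mvfft(Up) * mvfft(Hp), inverse = TRUE))[seq_len(K), ] / n
  }
  out
}
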
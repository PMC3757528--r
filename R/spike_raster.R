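#' Multichannel spike raster
#'
#' A `spike_raster` holds discrete-time spike events for a set of channels:
#' a set of `(timestep, channel)` pairs on a grid of `n_steps` timesteps.
#' Timesteps and channels are 0-based; at most one event may occupy a
#' `(timestep, channel)` cell (duplicates are collapsed).  `dt` records the
#' physical duration of one timestep in milliseconds and is metadata only:
#' all computations run on the integer grid.
#'
#' @param events two-column matrix or data frame with columns
#'   `timestep` and `channel` (0-based integers); may have zero rows.
#' @param n_channels number of channels (L for inputs, N for outputs).
#' @param n_steps number of timesteps K; every event must satisfy
#'   `0 <= timestep < n_steps`.
#' @param dt milliseconds per timestep (metadata, default 1).
#'
#' @return An object of class `spike_raster` with fields `events`
#'   (integer matrix, sorted by timestep then channel), `n_channels`,
#'   `n_steps`, `dt`.
#' @examples
#' r <- spike_raster(cbind(timestep = c(7, 5), channel = c(3, 0)),
#'                   n_channels = 5, n_steps = 10)
#' n_events(r)
#' @export
spike_raster <- function(events, n_channels, n_steps, dt = 1.0) {
  n_channels <- check_count(n_channels, "n_channels")
  n_steps <- check_count(n_steps, "n_steps")
  if (is.data.frame(events)) events <- as.matrix(events)
  if (is.null(events) || length(events) == 0L)
    events <- matrix(integer(), 0L, 2L)
  if (!is.matrix(events) || ncol(events) != 2L)
    stop_config("`events` must be a two-column (timestep, channel) matrix")
  storage.mode(events) <- "integer"
  colnames(events) <- c("timestep", "channel")
  if (nrow(events)) {
    if (anyNA(events)) stop_config("`events` contains missing values")
    if (any(events[, 1L] < 0L) || any(events[, 1L] >= n_steps))
      stop_config("event timestep outside [0, n_steps)")
    if (any(events[, 2L] < 0L) || any(events[, 2L] >= n_channels))
      stop_config("event channel outside [0, n_channels)")
    events <- events[!duplicated(events), , drop = FALSE]
    events <- events[order(events[, 1L], events[, 2L]), , drop = FALSE]
  }
  structure(list(events = events, n_channels = n_channels,
                 n_steps = n_steps, dt = dt),
            class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("<spike_raster> %d channels x %d steps, %d events (dt = %g ms)\n",
              x$n_channels, x$n_steps, nrow(x$events), x$dt))
  invisible(x)
}

#' Number of spike events in a raster
#' @param raster a [spike_raster()].
#' @return Integer event count.
#' @export
n_events <- function(raster) nrow(raster$events)

#' Dense 0/1 matrix view of a raster
#'
#' @param raster a [spike_raster()].
#' @return `n_channels x n_steps` numeric matrix with ones at event cells.
#' @export
as_dense <- function(raster) {
  x <- matrix(0, raster$n_channels, raster$n_steps)
  if (nrow(raster$events))
    x[cbind(raster$events[, 2L] + 1L, raster$events[, 1L] + 1L)] <- 1
  x
}

#' Read a spike raster from CSV
#'
#' The file format is a CSV with header `timestep,channel` and one event
#' per row, 0-based integers.  Duplicate rows collapse to a single event.
#'
#' @param path file to read.
#' @param n_channels,n_steps declared raster dimensions; events outside
#'   these bounds are an error.
#' @param dt milliseconds per timestep (metadata).
#' @return A [spike_raster()].
#' @export
read_raster <- function(path, n_channels, n_steps, dt = 1.0) {
  if (!file.exists(path)) stop_config("spike file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0L || trimws(lines[1L]) != "timestep,channel")
    stop_config("line 1: expected header 'timestep,channel' in ", path)
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  if (!length(body))
    return(spike_raster(NULL, n_channels, n_steps, dt))
  parts <- strsplit(body, ",", fixed = TRUE)
  bad <- which(vapply(parts, length, 0L) != 2L)
  ts <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
  ch <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
  bad <- sort(unique(c(bad, which(is.na(ts) | is.na(ch)))))
  if (length(bad))
    stop_config(sprintf("line %d: malformed event row '%s' in %s",
                        bad[1L] + 1L, body[bad[1L]], path))
  spike_raster(cbind(timestep = ts, channel = ch), n_channels, n_steps, dt)
}

#' Write a spike raster to CSV
#'
#' Events are written sorted by `(timestep, channel)` under the header
#' `timestep,channel`; `write_raster` followed by [read_raster()] is the
#' identity on the event set.
#'
#' @param raster a [spike_raster()].
#' @param path destination file.
#' @return Invisibly, `path`.
#' @export
write_raster <- function(raster, path) {
  stopifnot(inherits(raster, "spike_raster"))
  ev <- raster$events  # constructor already sorted and de-duplicated
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("timestep,channel", con)
  if (nrow(ev))
    writeLines(paste(ev[, 1L], ev[, 2L], sep = ","), con)
  invisible(path)
}
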
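#' Spike raster objects
#'
#' A `spike_raster` holds per-neuron, per-bin spike counts (rows = neurons,
#' columns = time bins) together with the bin width `dt` in seconds. It is the
#' universal input of the pipeline: every downstream analysis (population
#' activity, avalanches, branching-parameter estimation, covariance
#' statistics) consumes either a raster or the population activity series
#' derived from one.
#'
#' @param counts integer matrix of non-negative spike counts, neurons as rows.
#'   Non-integer entries within `1e-9` of an integer are rounded; anything
#'   else is rejected.
#' @param dt bin width in seconds (> 0).
#' @param neuron_ids optional unique labels, one per row.
#' @param meta free-form provenance list (source file, seed, ...).
#'
#' @return An object of class `spike_raster` with elements `counts`, `dt`,
#'   `neuron_ids`, `meta`.
#' @export
spike_raster <- function(counts, dt, neuron_ids = NULL, meta = list()) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop("counts must be numeric")
  if (ncol(counts) < 2L) stop("raster needs at least 2 time bins")
  counts <- check_integer_counts(counts)
  check_dt(dt)
  if (!is.null(neuron_ids)) {
    if (length(neuron_ids) != nrow(counts))
      stop("neuron_ids must match the number of rows")
    if (anyDuplicated(neuron_ids)) stop("neuron_ids must be unique")
  }
  structure(
    list(counts = counts, dt = as.numeric(dt), neuron_ids = neuron_ids,
         meta = meta),
    class = "spike_raster"
  )
}

#' Population activity series
#'
#' An `activity_series` is the population-summed activity \eqn{A_t}: the total
#' number of spikes across all recorded neurons in each time bin. The driven
#' branching-process model acts on this series, \eqn{\langle A_{t+1} | A_t
#' \rangle = m A_t + h}.
#'
#' @param values non-negative integer vector, one entry per bin (length >= 2).
#' @param dt bin width in seconds.
#' @return An object of class `activity_series` with elements `values`, `dt`.
#' @export
activity_series <- function(values, dt) {
  values <- as.vector(values, mode = "numeric")
  if (length(values) < 2L) stop("activity series needs at least 2 bins")
  values <- drop(check_integer_counts(matrix(values, nrow = 1)))
  check_dt(dt)
  structure(list(values = values, dt = as.numeric(dt)),
            class = "activity_series")
}

check_dt <- function(dt) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("dt must be a single positive number (seconds)")
  invisible(dt)
}

check_integer_counts <- function(x) {
  if (anyNA(x)) stop("counts contain missing values")
  r <- round(x)
  if (any(abs(x - r) > 1e-9)) stop("non-integer count entries")
  if (any(r < 0)) stop("negative count entries")
  r
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("<spike_raster> %d neurons x %d bins, dt = %g s (%.1f s total)\n",
              nrow(x$counts), ncol(x$counts), x$dt, ncol(x$counts) * x$dt))
  invisible(x)
}

#' @export
print.activity_series <- function(x, ...) {
  cat(sprintf("<activity_series> %d bins, dt = %g s, mean activity %.3f\n",
              length(x$values), x$dt, mean(x$values)))
  invisible(x)
}

#' @export
dim.spike_raster <- function(x) dim(x$counts)

#' @export
length.activity_series <- function(x) length(x$values)

#' Load a spike raster from disk
#'
#' Reads a rectangular matrix of spike counts from delimited text
#' (comma/tab/whitespace, auto-sniffed) or from an RDS file storing a dense
#' matrix. Delimited files are neurons-as-rows by default; `transpose = TRUE`
#' flips a bins-as-rows layout. Lines starting with `#` are treated as a
#' sidecar header of `key=value` pairs; a `dt` entry there is used when the
#' `dt` argument is missing.
#'
#' @param path file path.
#' @param dt bin width in seconds; overrides any header value.
#' @param format `"delimited"` or `"dense-matrix"` (RDS).
#' @param transpose transpose the on-disk matrix after reading.
#' @return A [spike_raster()].
#' @export
load_raster <- function(path, dt = NULL, format = c("delimited", "dense-matrix"),
                        transpose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  header_dt <- NULL
  if (format == "delimited") {
    first <- readLines(path, n = 50L)
    n_hdr <- match(FALSE, startsWith(first, "#"), nomatch = length(first) + 1L) - 1L
    if (n_hdr > 0L) {
      kv <- sub("^#\\s*", "", first[seq_len(n_hdr)])
      dt_line <- grep("^dt\\s*=", kv, value = TRUE)
      if (length(dt_line))
        header_dt <- as.numeric(sub("^dt\\s*=\\s*", "", dt_line[1]))
    }
    m <- tryCatch(
      as.matrix(data.table::fread(path, header = FALSE, data.table = FALSE,
                                  skip = n_hdr)),
      error = function(e) stop("failed to parse delimited raster: ",
                               conditionMessage(e))
    )
    if (!is.numeric(m)) stop("raster file contains non-numeric entries")
  } else {
    m <- readRDS(path)
    if (!is.matrix(m)) stop("dense-matrix file does not contain a matrix")
  }
  if (transpose) m <- t(m)
  if (is.null(dt)) dt <- header_dt
  if (is.null(dt)) stop("dt must be given (argument or '# dt=' header line)")
  spike_raster(m, dt, meta = list(source = path, format = format))
}

#' Write a spike raster to delimited text
#'
#' Emits tab-separated counts, neurons as rows, preceded by a `# dt=<seconds>`
#' header line so the file round-trips through [load_raster()] without
#' external metadata.
#'
#' @param raster a [spike_raster()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(raster, path) {
  stopifnot(inherits(raster, "spike_raster"))
  writeLines(sprintf("# dt=%.17g", raster$dt), path)
  data.table::fwrite(as.data.frame(raster$counts), path, sep = "\t",
                     col.names = FALSE, append = TRUE)
  invisible(path)
}

#' Population activity of a raster
#'
#' Sums spike counts across neurons in each time bin, yielding the population
#' activity \eqn{A_t} that the branching-process analyses act on.
#'
#' @param raster a [spike_raster()].
#' @return An [activity_series()] with the same `dt`.
#' @export
population_activity <- function(raster) {
  stopifnot(inherits(raster, "spike_raster"))
  activity_series(colSums(raster$counts), raster$dt)
}

#' Temporal coarse-graining
#'
#' Reduces the sampling rate by an integer `factor` in one of two modes that
#' bracket what real acquisition does. `"skip"` keeps the last bin of each
#' block of `factor` consecutive bins and discards the rest (classical
#' temporal subsampling). `"sum"` replaces each block by the sum of its bins
#' (temporal summation: what slow-indicator spike inference effectively
#' measures, since spikes between frames are still captured). A trailing
#' incomplete block is discarded in both modes, and `dt` is multiplied by
#' `factor`.
#'
#' @param x a [spike_raster()] or [activity_series()].
#' @param factor integer >= 1.
#' @param mode `"sum"` or `"skip"`.
#' @return An object of the same class as `x`.
#' @export
temporal_coarsen <- function(x, factor, mode = c("sum", "skip")) {
  UseMethod("temporal_coarsen")
}

coarsen_matrix <- function(m, factor, mode) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("factor must be an integer >= 1")
  n <- ncol(m)
  if (factor > n) stop("factor exceeds the number of bins")
  if (factor == 1L) return(m)
  nblock <- n %/% factor
  m <- m[, seq_len(nblock * factor), drop = FALSE]
  if (mode == "skip") {
    m[, seq_len(nblock) * factor, drop = FALSE]
  } else {
    grp <- rep(seq_len(nblock), each = factor)
    t(rowsum(t(m), grp))
  }
}

#' @export
temporal_coarsen.spike_raster <- function(x, factor, mode = c("sum", "skip")) {
  mode <- match.arg(mode)
  out <- coarsen_matrix(x$counts, factor, mode)
  if (ncol(out) < 2L) stop("coarsening left fewer than 2 bins")
  spike_raster(out, x$dt * as.integer(factor), neuron_ids = x$neuron_ids,
               meta = x$meta)
}

#' @export
temporal_coarsen.activity_series <- function(x, factor, mode = c("sum", "skip")) {
  mode <- match.arg(mode)
  out <- coarsen_matrix(matrix(x$values, nrow = 1), factor, mode)
  if (ncol(out) < 2L) stop("coarsening left fewer than 2 bins")
  activity_series(drop(out), x$dt * as.integer(factor))
}

#' Per-neuron firing rates and population summary
#'
#' @param raster a [spike_raster()].
#' @return A list with `rates` (spikes/second per neuron), `mean` and `sd`
#'   over neurons, and `n_neurons`.
#' @export
firing_rate_stats <- function(raster) {
  stopifnot(inherits(raster, "spike_raster"))
  duration <- ncol(raster$counts) * raster$dt
  rates <- rowSums(raster$counts) / duration
  names(rates) <- raster$neuron_ids
  list(rates = rates, mean = mean(rates), sd = sd(rates),
       n_neurons = length(rates))
}
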
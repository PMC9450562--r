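#' Simulate a driven branching process
#'
#' Generates population activity from the linear branching model
#' \eqn{\langle A_{t+1} | A_t \rangle = m A_t + h}: each of the \eqn{A_t}
#' current events produces a Poisson(\eqn{m}) number of next-bin events and an
#' external drive contributes an independent Poisson(\eqn{h}) count per bin.
#' The subcritical stationary mean is \eqn{h / (1 - m)}. The process starts at
#' that mean (rounded) unless `init` is given, and a burn-in is discarded so
#' the returned series is stationary.
#'
#' @param m branching parameter in \[0, 1.05\]. `m = 0` is Poisson
#'   (asynchronous) activity, `m = 1` the critical point, values just below 1
#'   the reverberating regime.
#' @param h mean external drive per bin; must be positive when `m < 1`
#'   (otherwise the process is absorbed at zero).
#' @param steps number of bins returned (>= 100).
#' @param dt bin width in seconds attached to the result.
#' @param seed optional integer seed (`set.seed`).
#' @param init initial activity; default `round(h / (1 - m))` for `m < 1`.
#' @param burn_in bins discarded before recording (default 1000).
#' @return An [activity_series()].
#' @export
simulate_branching <- function(m, h, steps, dt = 1, seed = NULL, init = NULL,
                               burn_in = 1000L) {
  stopifnot(is.numeric(m), length(m) == 1L, m >= 0, m <= 1.05,
            is.numeric(h), length(h) == 1L, h >= 0)
  steps <- as.integer(steps)
  if (steps < 100L) stop("steps must be >= 100")
  if (h <= 0 && m < 1)
    stop("h must be > 0 when m < 1 (the process would be absorbed at 0)")
  if (is.null(init)) {
    init <- if (m < 1) round(h / (1 - m)) else max(1, round(h))
  }
  if (!is.null(seed)) set.seed(seed)
  values <- branching_core(steps, m, h, init, as.integer(burn_in))
  activity_series(values, dt)
}

#' Simulate a 4-neighbour lattice branching network
#'
#' Units sit on a periodic 2-D square lattice, each connected to its four
#' nearest neighbours. Every event at a unit independently triggers an event
#' at each neighbour in the next bin with probability `p_transmit`, so the
#' implied branching ratio is `4 * p_transmit`; supplying `m` sets
#' `p_transmit = m / 4`. Each unit additionally receives independent Poisson
#' drive at rate `h_unit` per bin. Unit counts are event tallies and may
#' exceed 1 per bin. Unlike the well-mixed branching process, activity here
#' is spatially clustered, which is what makes systematic neuron subsampling
#' (as opposed to binomial spike subsampling) biased.
#'
#' @param n_units number of lattice units; must be a perfect square >= 100.
#' @param m implied branching ratio (`p_transmit = m / 4`); give either `m`
#'   or `p_transmit`.
#' @param p_transmit per-edge transmission probability.
#' @param h_unit per-unit drive rate per bin.
#' @param steps recorded bins.
#' @param dt bin width in seconds.
#' @param seed optional integer seed.
#' @param burn_in bins discarded before recording (default 1000).
#' @param record optional integer vector of unit indices (1-based) to record;
#'   default all units. Recording a subset is the memory-friendly way to
#'   emulate measuring only part of the network.
#' @return A [spike_raster()] with `length(record)` rows.
#' @export
simulate_lattice <- function(n_units, m = NULL, p_transmit = NULL, h_unit,
                             steps, dt = 1, seed = NULL, burn_in = 1000L,
                             record = NULL) {
  n_units <- as.integer(n_units)
  side <- as.integer(round(sqrt(n_units)))
  if (side * side != n_units) stop("n_units must be a perfect square")
  if (n_units < 100L) stop("n_units must be >= 100")
  if (is.null(p_transmit)) {
    if (is.null(m)) stop("give either m or p_transmit")
    p_transmit <- m / 4
  }
  m_implied <- 4 * p_transmit
  if (p_transmit < 0 || p_transmit > 1 || m_implied > 1.05)
    stop("implied branching ratio 4 * p_transmit must be in [0, 1.05]")
  stopifnot(h_unit >= 0)
  if (m_implied == 0 && h_unit == 0)
    stop("need either transmission or drive")
  steps <- as.integer(steps)
  if (is.null(record)) record <- seq_len(n_units)
  record <- as.integer(record)
  if (any(record < 1L) || any(record > n_units)) stop("record out of range")
  init_total <- if (m_implied < 1) {
    round(n_units * h_unit / (1 - m_implied))
  } else {
    max(1, round(n_units * h_unit))
  }
  if (!is.null(seed)) set.seed(seed)
  counts <- lattice_core(side, p_transmit, h_unit, steps,
                         as.integer(burn_in), record - 1L,
                         as.integer(init_total))
  spike_raster(counts, dt,
               meta = list(model = "lattice", n_units = n_units,
                           p_transmit = p_transmit, h_unit = h_unit,
                           recorded = record, seed = seed))
}

#' Binomial spike subsampling
#'
#' Emulates spatial subsampling in which every spike is observed
#' independently with probability `q` ("each spike has an equal probability
#' of being skipped"). The MR branching-parameter estimator is provably
#' invariant under this operator: it rescales the regression slopes
#' \eqn{r_k} by a constant \eqn{b} without changing the decay rate \eqn{m}.
#'
#' @param x a [spike_raster()] or [activity_series()].
#' @param q keep probability in \[0, 1\].
#' @param seed optional integer seed.
#' @return Same class as `x`.
#' @export
subsample_spikes_binomial <- function(x, q, seed = NULL) {
  if (!is.numeric(q) || length(q) != 1L || q < 0 || q > 1)
    stop("q must be a probability in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  if (inherits(x, "spike_raster")) {
    thinned <- rbinom(length(x$counts), as.integer(x$counts), q)
    m <- matrix(thinned, nrow = nrow(x$counts))
    spike_raster(m, x$dt, neuron_ids = x$neuron_ids, meta = x$meta)
  } else if (inherits(x, "activity_series")) {
    activity_series(rbinom(length(x$values), as.integer(x$values), q), x$dt)
  } else {
    stop("x must be a spike_raster or activity_series")
  }
}

#' Systematic neuron subsampling
#'
#' Keeps a uniformly random subset of neurons (rows), without replacement and
#' with row order preserved — the experimental situation where only some
#' neurons are measured at all, every spike of a measured neuron being seen.
#'
#' @param raster a [spike_raster()].
#' @param keep number of neurons to keep (`keep >= 1`) or a fraction in
#'   (0, 1). `keep = 1` means a single neuron.
#' @param seed optional integer seed.
#' @return A [spike_raster()] with the kept rows.
#' @export
subsample_neurons <- function(raster, keep, seed = NULL) {
  stopifnot(inherits(raster, "spike_raster"))
  n <- nrow(raster$counts)
  if (keep > 0 && keep < 1) keep <- round(keep * n)
  keep <- as.integer(keep)
  if (is.na(keep) || keep < 1L || keep > n) stop("keep out of range")
  if (!is.null(seed)) set.seed(seed)
  idx <- sort(sample.int(n, keep))
  spike_raster(raster$counts[idx, , drop = FALSE], raster$dt,
               neuron_ids = raster$neuron_ids[idx], meta = raster$meta)
}

#' Time-shuffled surrogate
#'
#' Destroys temporal structure while conserving totals exactly: for a raster,
#' each neuron's time bins are independently permuted; for an activity
#' series, the whole series is permuted. The surrogate of any temporally
#' correlated process is Poisson-like (regression slopes \eqn{r_k \approx 0}),
#' which is the null the stationarity battery's Poisson tests identify.
#'
#' @param x a [spike_raster()] or [activity_series()].
#' @param seed optional integer seed.
#' @return Same class as `x`.
#' @export
shuffle_time <- function(x, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(x, "spike_raster")) {
    nb <- ncol(x$counts)
    m <- t(apply(x$counts, 1L, function(row) row[sample.int(nb)]))
    spike_raster(m, x$dt, neuron_ids = x$neuron_ids, meta = x$meta)
  } else if (inherits(x, "activity_series")) {
    n <- length(x$values)
    v <- if (n == 1L) x$values else x$values[sample.int(n)]
    activity_series(v, x$dt)
  } else {
    stop("x must be a spike_raster or activity_series")
  }
}

#' Sample a discrete power law by inverse CDF
#'
#' Draws from \eqn{P(X = x) \propto x^{-\alpha}} on integers `x >= xmin`,
#' using an exact cumulative table up to `cap` and a continuous-approximation
#' tail beyond it (tail mass is well below 1e-3 for the exponents used here).
#' This is the generator-side oracle for the distribution-fitting machinery.
#'
#' @param n number of samples.
#' @param exponent power-law exponent \eqn{\alpha > 1}.
#' @param xmin lower cutoff (integer >= 1).
#' @param seed optional integer seed.
#' @param cap upper bound of the exact CDF table.
#' @return Integer vector of length `n`.
#' @export
rpowerlaw_discrete <- function(n, exponent, xmin = 1L, seed = NULL,
                               cap = 1e6) {
  stopifnot(exponent > 1, xmin >= 1)
  if (!is.null(seed)) set.seed(seed)
  xmin <- as.integer(xmin)
  xs <- seq.int(xmin, cap)
  z <- hurwitz_zeta(exponent, xmin)
  cdf <- cumsum(xs^(-exponent)) / z
  u <- runif(n)
  out <- xs[pmin(findInterval(u, cdf) + 1L, length(xs))]
  in_tail <- u > cdf[length(cdf)]
  if (any(in_tail)) {
    # continuous-approximation inverse CCDF for the rare beyond-cap draws
    s <- 1 - u[in_tail]
    out[in_tail] <- floor((s * (exponent - 1) * z)^(-1 / (exponent - 1)) + 0.5)
  }
  out
}
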
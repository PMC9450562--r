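#' Extract neuronal avalanches from population activity
#'
#' A neuronal avalanche is a maximal run of consecutive time bins with
#' nonzero population activity, bounded by silent (zero-activity) bins. Its
#' size `S` is the total spike count across the run and its duration `T` the
#' number of bins. Runs touching the first or last bin of the recording are
#' censored (their true extent is unknown) and are flagged `edge_truncated`;
#' distribution fits exclude them by default.
#'
#' @param series an [activity_series()].
#' @return An object of class `avalanche_set`: `sizes`, `durations`,
#'   `profiles` (list of per-bin activity vectors), `edge_truncated`
#'   (logical), `dt`, and `no_silent_bins` (TRUE when the series never goes
#'   silent — then no avalanche can be delimited at all, as happens when the
#'   sampling is too slow for the population ever to appear quiet).
#' @export
extract_avalanches <- function(series) {
  stopifnot(inherits(series, "activity_series"))
  v <- series$values
  active <- v > 0
  no_silent <- all(active)
  if (no_silent) {
    warning("no silent bins: the series never reaches zero activity, ",
            "so no avalanche can be delimited")
    return(structure(list(sizes = integer(0), durations = integer(0),
                          profiles = list(), edge_truncated = logical(0),
                          dt = series$dt, no_silent_bins = TRUE),
                     class = "avalanche_set"))
  }
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  starts <- starts[keep]; ends <- ends[keep]
  profiles <- lapply(seq_along(starts),
                     function(i) v[starts[i]:ends[i]])
  truncated <- (starts == 1L) | (ends == length(v))
  structure(list(
    sizes = vapply(profiles, sum, 0),
    durations = ends - starts + 1L,
    profiles = profiles,
    edge_truncated = truncated,
    dt = series$dt,
    no_silent_bins = FALSE
  ), class = "avalanche_set")
}

#' @export
print.avalanche_set <- function(x, ...) {
  cat(sprintf("<avalanche_set> %d avalanches (%d edge-truncated), dt = %g s\n",
              length(x$sizes), sum(x$edge_truncated), x$dt))
  invisible(x)
}

# avalanches usable for distribution fits
av_fit_subset <- function(av, include_truncated = FALSE) {
  if (include_truncated) seq_along(av$sizes) else which(!av$edge_truncated)
}

#' Mean size given duration exponent
#'
#' Fits \eqn{\langle S \rangle(T) \sim T^{\beta}} by ordinary least squares
#' of \eqn{\log \langle S \rangle} on \eqn{\log T} over the distinct
#' durations (mean size per duration first, then the regression — the
#' quantity is a conditional mean, not a probability distribution).
#'
#' @param av an `avalanche_set` from [extract_avalanches()].
#' @param include_truncated include edge-truncated avalanches.
#' @return A list: `beta`, `intercept`, `r_squared`, `durations`,
#'   `mean_sizes`.
#' @export
fit_size_given_duration <- function(av, include_truncated = FALSE) {
  idx <- av_fit_subset(av, include_truncated)
  if (length(idx) == 0L) stop("no avalanches to fit")
  Tv <- av$durations[idx]
  Sv <- av$sizes[idx]
  mean_s <- tapply(Sv, Tv, mean)
  Tu <- as.numeric(names(mean_s))
  if (length(Tu) < 2L) stop("fewer than 2 distinct durations")
  y <- log(as.numeric(mean_s))
  fit <- lm(y ~ log(Tu))
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(fit$residuals^2) / sst else 1
  list(beta = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r2,
       durations = Tu, mean_sizes = as.numeric(mean_s))
}

#' Avalanche shape collapse
#'
#' Tests the self-similarity prediction \eqn{s(t, T) \propto T^{\gamma}
#' F(t/T)}: if the system is critical, mean temporal profiles of avalanches
#' of every duration collapse onto one universal curve after rescaling time
#' to \[0, 1\] and amplitude by \eqn{T^{-\gamma}}. The procedure: (1) drop
#' avalanches shorter than `min_duration` bins and durations with fewer than
#' `min_count` avalanches; (2) average the profiles within each remaining
#' duration; (3) rescale each mean profile's time axis to \[0, 1\] and
#' linearly interpolate it at `n_points` points; (4) for a candidate
#' \eqn{\gamma}, scale profiles by \eqn{T^{-\gamma}} and score the collapse
#' as the mean over interpolation points of the across-duration variance,
#' divided by the squared span (max minus min over all scaled profiles and
#' points); (5) minimize over \eqn{\gamma \in [0, 5]} by a coarse-to-fine
#' grid (steps 0.1, then 0.01 around the optimum, then 0.001).
#'
#' @param av an `avalanche_set`.
#' @param min_duration shortest duration kept (default 5 bins).
#' @param min_count minimum avalanches per duration (default 3).
#' @param n_points interpolation points (default 1000).
#' @param gamma_range search interval (default \[0, 5\]).
#' @param include_truncated include edge-truncated avalanches.
#' @return A list: `gamma`, `collapse_error`, `durations`,
#'   `mean_profiles` (durations x n_points matrix of the unscaled
#'   interpolated mean profiles), `grid` (the rescaled time axis).
#' @export
shape_collapse <- function(av, min_duration = 5L, min_count = 3L,
                           n_points = 1000L, gamma_range = c(0, 5),
                           include_truncated = FALSE) {
  idx <- av_fit_subset(av, include_truncated)
  idx <- idx[av$durations[idx] >= min_duration]
  if (!length(idx)) stop("no avalanches survive the duration exclusion")
  durs <- av$durations[idx]
  tab <- table(durs)
  keep_durs <- as.integer(names(tab)[tab >= min_count])
  if (length(keep_durs) < 2L)
    stop("fewer than 2 distinct durations survive the exclusions")
  grid <- seq(0, 1, length.out = n_points)
  mean_profiles <- t(vapply(keep_durs, function(Td) {
    ps <- av$profiles[idx[durs == Td]]
    mp <- Reduce(`+`, ps) / length(ps)
    stats::approx(seq(0, 1, length.out = Td), mp, xout = grid)$y
  }, numeric(n_points)))

  err_fun <- function(gamma) {
    scaled <- mean_profiles * keep_durs^(-gamma)
    centered <- sweep(scaled, 2, colMeans(scaled))
    v <- colMeans(centered^2)                     # population variance
    span <- max(scaled) - min(scaled)
    mean(v) / span^2
  }
  grid_min <- function(gammas) {
    errs <- vapply(gammas, err_fun, 0)
    i <- which.min(errs)
    list(gamma = gammas[i], err = errs[i])
  }
  lo <- gamma_range[1]; hi <- gamma_range[2]
  s1 <- grid_min(seq(lo, hi, by = 0.1))
  s2 <- grid_min(seq(max(lo, s1$gamma - 0.1), min(hi, s1$gamma + 0.1),
                     by = 0.01))
  s3 <- grid_min(seq(max(lo, s2$gamma - 0.01), min(hi, s2$gamma + 0.01),
                     by = 0.001))
  list(gamma = s3$gamma, collapse_error = s3$err, durations = keep_durs,
       mean_profiles = mean_profiles, grid = grid)
}

#' Crackling-noise consistency residual
#'
#' At criticality the collapse exponent and the size-given-duration exponent
#' are tied by \eqn{\gamma = \beta - 1}; the residual \eqn{\gamma - (\beta -
#' 1)} should be zero. A large residual is evidence against critical
#' avalanching even when individual fits look reasonable.
#'
#' @param beta slope of \eqn{\log\langle S \rangle(T)} vs \eqn{\log T}.
#' @param gamma shape-collapse exponent.
#' @return `gamma - (beta - 1)`.
#' @export
crackling_residual <- function(beta, gamma) {
  stopifnot(is.finite(beta), is.finite(gamma))
  gamma - (beta - 1)
}
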
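#' Spike count matrix
#'
#' Divides a recording into `N` contiguous windows ("subsets") and totals
#' each neuron's spikes within each window, giving the neuron-by-subset
#' count matrix \eqn{n_i^p} on which the covariance and dimensionality
#' statistics operate. Window widths convert to an integer number of bins by
#' flooring (at least 1); a trailing partial window is dropped.
#'
#' @param raster a [spike_raster()].
#' @param width window width in seconds (mode `"fixed_seconds"`), or the
#'   multiplier applied to `tau` (mode `"tau_multiple"`).
#' @param mode `"fixed_seconds"` (default) or `"tau_multiple"`, the latter
#'   sizing windows by the recording's own autocorrelation time.
#' @param tau autocorrelation time in seconds; required for
#'   `"tau_multiple"`.
#' @return An object of class `spike_count_matrix`: `counts` (neurons x
#'   subsets), `window_width` (seconds actually used), `n_subsets`.
#' @export
spike_count_matrix <- function(raster, width,
                               mode = c("fixed_seconds", "tau_multiple"),
                               tau = NULL) {
  stopifnot(inherits(raster, "spike_raster"))
  mode <- match.arg(mode)
  if (mode == "tau_multiple") {
    if (is.null(tau) || !is.finite(tau) || tau <= 0)
      stop("tau_multiple mode needs a positive tau")
    width <- width * tau
  }
  if (width < raster$dt) stop("window width smaller than the bin width")
  wbins <- max(1L, floor(width / raster$dt))
  nsub <- ncol(raster$counts) %/% wbins
  if (nsub < 2L) stop("recording spans fewer than 2 windows")
  m <- raster$counts[, seq_len(nsub * wbins), drop = FALSE]
  grp <- rep(seq_len(nsub), each = wbins)
  counts <- t(rowsum(t(m), grp))
  structure(list(counts = counts, window_width = wbins * raster$dt,
                 n_subsets = nsub),
            class = "spike_count_matrix")
}

#' Spike-count covariance statistics
#'
#' Unbiased pairwise covariances \eqn{\hat c_{ij} = \frac{1}{N-1} \sum_p
#' (n_i^p - \bar n_i)(n_j^p - \bar n_j)} over subsets, plus the summary
#' statistics that discriminate dynamical regimes: the mean \eqn{\mu} and SD
#' \eqn{\sigma} of the off-diagonal covariances, the mean single-neuron
#' variance \eqn{\bar c_{ii}}, and the normalized width \eqn{\Delta = \sigma
#' / \bar c_{ii}}. Critical avalanching predicts a covariance distribution
#' with large mean and small width; the balanced/asynchronous regime the
#' opposite (\eqn{|\mu| \ll \sigma}). Correlations are reported for neurons
#' with nonzero variance (zero-variance neurons are excluded from the
#' correlation list but kept in the covariances, with their indices
#' flagged). A jackknife-over-subsets bias-corrected \eqn{\Delta} is
#' reported alongside the naive value; it is a labelled surrogate, not the
#' canonical correction from the covariance literature.
#'
#' @param scm a [spike_count_matrix()].
#' @return A list of class `popstats_cov`: `cov` (matrix), `cov_offdiag`,
#'   `var`, `corr_offdiag`, `mean_cov`, `width_cov`, `mean_var`, `Delta`,
#'   `Delta_jackknife`, `zero_variance_neurons`, `n_subsets`.
#' @export
count_covariance_stats <- function(scm) {
  stopifnot(inherits(scm, "spike_count_matrix"))
  if (scm$n_subsets < 2L) stop("need at least 2 subsets")
  X <- t(scm$counts)            # subsets x neurons
  C <- cov(X)                   # unbiased, 1/(N-1)
  off <- C[upper.tri(C)]
  vars <- diag(C)
  zero_var <- which(vars == 0)
  corr <- NULL
  if (length(zero_var) < nrow(C) - 1L) {
    keep <- setdiff(seq_len(nrow(C)), zero_var)
    Ck <- C[keep, keep, drop = FALSE]
    R <- Ck / sqrt(outer(diag(Ck), diag(Ck)))
    corr <- R[upper.tri(R)]
  }
  delta_of <- function(counts) {
    Cc <- cov(t(counts))
    sd(Cc[upper.tri(Cc)]) / mean(diag(Cc))
  }
  Delta <- sd(off) / mean(vars)
  N <- scm$n_subsets
  loo <- vapply(seq_len(N), function(p) delta_of(scm$counts[, -p, drop = FALSE]), 0)
  Delta_jack <- N * Delta - (N - 1) * mean(loo)
  structure(list(cov = C, cov_offdiag = off, var = vars,
                 corr_offdiag = corr, mean_cov = mean(off),
                 width_cov = sd(off), mean_var = mean(vars), Delta = Delta,
                 Delta_jackknife = Delta_jack,
                 zero_variance_neurons = zero_var, n_subsets = N),
            class = "popstats_cov")
}

#' Participation ratio dimensionality
#'
#' PCA of the spike count matrix (neurons as variables, subsets as
#' observations, per-neuron mean removed, no variance scaling) gives
#' explained-variance ratios \eqn{\tilde\lambda_k}; the effective
#' dimensionality is the participation ratio \eqn{N_{eff} = (\sum_k
#' \tilde\lambda_k^2)^{-1}}. Critical avalanching implies a single dominant
#' mode with near-uniform loadings, \eqn{N_{eff} \approx 1}; multidimensional
#' activity gives \eqn{N_{eff} \gg 1} with heterogeneous loadings.
#'
#' @param scm a [spike_count_matrix()].
#' @return A list: `evr` (explained-variance ratios, summing to 1), `N_eff`,
#'   `loadings` (principal-component coefficient vectors, columns).
#' @export
participation_ratio <- function(scm) {
  stopifnot(inherits(scm, "spike_count_matrix"))
  if (nrow(scm$counts) < 2L || scm$n_subsets < 2L)
    stop("need at least 2 neurons and 2 subsets")
  X <- t(scm$counts)
  if (all(apply(X, 2, var) == 0)) stop("degenerate all-constant count matrix")
  p <- prcomp(X, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2
  evr <- ev / sum(ev)
  list(evr = evr, N_eff = 1 / sum(evr^2), loadings = p$rotation)
}

#' Distance to the dynamically balanced critical point
#'
#' From the normalized covariance width \eqn{\Delta} the largest eigenvalue
#' of the effective network connectivity is \eqn{\lambda_{max} = 1 - 1 / (1 +
#' N \Delta^2)}, where `N` is the underlying network size (not the number of
#' recorded neurons). \eqn{\lambda_{max} = 1} marks the edge-of-chaos
#' critical point of the balanced state.
#'
#' @param Delta normalized covariance width (>= 0), from
#'   [count_covariance_stats()].
#' @param network_size assumed full network size (default 1500, the larval
#'   zebrafish habenula scale).
#' @return \eqn{\lambda_{max}} in \[0, 1).
#' @export
lambda_max <- function(Delta, network_size = 1500) {
  if (any(Delta < 0)) stop("Delta must be >= 0")
  stopifnot(network_size >= 1)
  1 - 1 / (1 + network_size * Delta^2)
}
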
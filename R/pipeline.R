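#' Run the full diagnostics pipeline over one or many datasets
#'
#' For each dataset and each temporal coarsening factor: population activity
#' is formed (rasters are summed over neurons), avalanches are extracted and
#' their scaling summarized when silent bins exist, the MR regression slopes
#' are computed and screened by the stationarity battery, and the branching
#' parameter and autocorrelation time are reported only for accepted runs.
#' Rasters additionally get the covariance/dimensionality statistics.
#' Accepted (dt, m_hat) pairs across datasets and factors feed the
#' timescale-conversion fit \eqn{\hat m = \phi^{\Delta t}}. Stage errors are
#' captured per dataset and the pipeline continues.
#'
#' @param datasets named list of [spike_raster()] / [activity_series()]
#'   objects.
#' @param coarsen_factors integer vector of temporal coarsening factors
#'   (default 1).
#' @param coarsen_mode `"sum"` or `"skip"`.
#' @param policy acceptance policy, `"lenient"` or `"strict"` (see
#'   [accept_dataset()]).
#' @param k_max lag count for [regression_slopes()], `NULL` for the default.
#' @param window_seconds window for [spike_count_matrix()] (default 2 s).
#' @param network_size assumed network size for [lambda_max()].
#' @return An object of class `analysis_report`: `datasets` (per-run
#'   results), `sweep` (data frame: dataset, factor, dt, m_hat, tau,
#'   verdict, accepted), `phi_fit` (or `NULL`), `config`, `errors`.
#' @export
run_pipeline <- function(datasets, coarsen_factors = 1L,
                         coarsen_mode = c("sum", "skip"),
                         policy = c("lenient", "strict"), k_max = NULL,
                         window_seconds = 2, network_size = 1500) {
  coarsen_mode <- match.arg(coarsen_mode)
  policy <- match.arg(policy)
  if (!length(datasets)) stop("no datasets")
  if (is.null(names(datasets)) || any(names(datasets) == ""))
    names(datasets) <- paste0("dataset_", seq_along(datasets))

  results <- list()
  errors <- list()
  sweep <- list()
  for (nm in names(datasets)) {
    for (f in as.integer(coarsen_factors)) {
      run_id <- if (f == 1L) nm else sprintf("%s.x%d", nm, f)
      res <- tryCatch({
        x <- datasets[[nm]]
        if (f > 1L) x <- temporal_coarsen(x, f, coarsen_mode)
        is_raster <- inherits(x, "spike_raster")
        series <- if (is_raster) population_activity(x) else x

        aval <- NULL
        if (any(series$values == 0)) {
          av <- extract_avalanches(series)
          aval <- list(n_avalanches = length(av$sizes),
                       n_truncated = sum(av$edge_truncated))
          usable <- av$sizes[!av$edge_truncated]
          if (length(usable) >= 10L && length(unique(usable)) >= 2L) {
            aval$size_fit <- tryCatch(
              compare_power_law_exponential(usable), error = function(e) NULL)
            aval$beta_fit <- tryCatch(
              fit_size_given_duration(av), error = function(e) NULL)
          }
        }

        r_k <- regression_slopes(series, k_max)
        report <- stationarity_battery(r_k, series$dt)
        acc <- accept_dataset(report, policy)
        mr <- fit_branching_parameter(r_k, series$dt)

        pop <- NULL
        if (is_raster) {
          pop <- tryCatch({
            scm <- spike_count_matrix(x, window_seconds)
            cs <- count_covariance_stats(scm)
            pr <- participation_ratio(scm)
            list(Delta = cs$Delta, mean_cov = cs$mean_cov,
                 width_cov = cs$width_cov, N_eff = pr$N_eff,
                 lambda_max = lambda_max(cs$Delta, network_size))
          }, error = function(e) NULL)
        }

        m_head <- if (!acc$accepted) NA_real_
          else if (report$verdict == "accepted_poisson") 0 else mr$m_hat
        list(dataset = nm, factor = f, dt = series$dt, mr = mr,
             report = report, accepted = acc$accepted, reason = acc$reason,
             m_hat = m_head,
             tau = if (acc$accepted && report$verdict != "accepted_poisson")
               mr$tau else NA_real_,
             avalanches = aval, popstats = pop)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        errors[[run_id]] <- conditionMessage(res)
      } else {
        results[[run_id]] <- res
        sweep[[run_id]] <- data.frame(
          dataset = nm, factor = f, dt = res$dt, m_hat = res$m_hat,
          tau = res$tau, verdict = res$report$verdict,
          accepted = res$accepted, stringsAsFactors = FALSE)
      }
    }
  }
  sweep <- if (length(sweep)) do.call(rbind, c(sweep, make.row.names = FALSE)) else NULL

  phi_fit <- NULL
  if (!is.null(sweep)) {
    ok <- sweep[sweep$accepted & is.finite(sweep$m_hat) & sweep$m_hat > 0, ]
    if (nrow(ok) >= 3L)
      phi_fit <- tryCatch(fit_phi(data.frame(dt = ok$dt, m_hat = ok$m_hat)),
                          error = function(e) NULL)
  }
  structure(list(datasets = results, sweep = sweep, phi_fit = phi_fit,
                 config = list(coarsen_factors = coarsen_factors,
                               coarsen_mode = coarsen_mode, policy = policy,
                               k_max = k_max, window_seconds = window_seconds,
                               network_size = network_size,
                               version = as.character(utils::packageVersion("spikedyn"))),
                 errors = errors),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> %d runs, %d errors\n",
              length(x$datasets), length(x$errors)))
  if (!is.null(x$sweep)) print(x$sweep)
  if (!is.null(x$phi_fit))
    cat(sprintf("phi fit: phi = %.4g\n", x$phi_fit$phi))
  invisible(x)
}

#' Write a synthetic dataset (raster/series plus manifest) to disk
#'
#' Wraps the simulators for fixture generation: simulates a branching
#' process or lattice network, optionally applies binomial spike
#' subsampling, neuron subsampling and temporal coarsening, writes the
#' result as delimited text via [write_raster()] (activity series are stored
#' as single-row rasters) and records the ground-truth parameters — including
#' the effective branching parameter after coarsening,
#' \eqn{m_{true}^{factor}} — in a JSON manifest for parameter-recovery
#' tests. Identical spec and seed give byte-identical files.
#'
#' @param spec list describing the dataset. Required: `model`
#'   (`"branching"` or `"lattice"`) and the model's parameters (`m`, `h`,
#'   `steps`, `dt` for branching; `n_units`, `m`, `h_unit`, `steps`, `dt`,
#'   optional `record` count for lattice). Optional: `subsample_q` (binomial
#'   spike keep probability), `keep_neurons`, `coarsen` (factor),
#'   `coarsen_mode`.
#' @param dir output directory (created if needed).
#' @param name basename for the two files (`<name>.tsv`,
#'   `<name>_manifest.json`).
#' @param seed integer seed governing every random stage.
#' @return Invisibly, a list with `data_path`, `manifest_path`, `manifest`.
#' @export
make_synthetic_dataset <- function(spec, dir, name = "synthetic", seed = 1L) {
  stopifnot(is.list(spec), !is.null(spec$model))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  dt <- if (is.null(spec$dt)) 1 else spec$dt
  if (spec$model == "branching") {
    x <- simulate_branching(spec$m, spec$h, spec$steps, dt = dt)
    m_true <- spec$m
  } else if (spec$model == "lattice") {
    record <- if (!is.null(spec$record)) {
      sort(sample.int(spec$n_units, spec$record))
    } else NULL
    x <- simulate_lattice(spec$n_units, m = spec$m, h_unit = spec$h_unit,
                          steps = spec$steps, dt = dt, record = record)
    m_true <- spec$m
  } else {
    stop("unknown model: ", spec$model)
  }
  if (!is.null(spec$subsample_q)) x <- subsample_spikes_binomial(x, spec$subsample_q)
  if (!is.null(spec$keep_neurons)) x <- subsample_neurons(x, spec$keep_neurons)
  factor <- if (is.null(spec$coarsen)) 1L else as.integer(spec$coarsen)
  mode <- if (is.null(spec$coarsen_mode)) "sum" else spec$coarsen_mode
  if (factor > 1L) x <- temporal_coarsen(x, factor, mode)

  raster <- if (inherits(x, "activity_series")) {
    spike_raster(matrix(x$values, nrow = 1), x$dt)
  } else x
  data_path <- file.path(dir, paste0(name, ".tsv"))
  write_raster(raster, data_path)
  manifest <- list(name = name, model = spec$model, seed = seed,
                   dt_native = dt, dt_effective = x$dt,
                   m_true = m_true, coarsen = factor, coarsen_mode = mode,
                   m_effective = if (m_true > 0)
                     timescale_convert(m_true, factor) else 0,
                   spec = spec)
  manifest_path <- file.path(dir, paste0(name, "_manifest.json"))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(data_path = data_path, manifest_path = manifest_path,
                 manifest = manifest))
}
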
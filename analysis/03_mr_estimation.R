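#!/usr/bin/env Rscript

# MR branching-parameter estimation with the stationarity battery across the
# simulated spectrum, a temporal-coarsening sweep, and the timescale-
# conversion fit m_hat = phi^dt across accepted (dt, m_hat) pairs. Shuffled
# surrogates are run through the same pipeline to confirm they register as
# Poisson.

suppressPackageStartupMessages(library(spikedyn))
dir.create("results/mr", recursive = TRUE, showWarnings = FALSE)

files <- Sys.glob("results/data/branching_m*.tsv")
if (!length(files)) stop("run analysis/01_simulate.R first")

datasets <- list()
for (f in files) {
  name <- sub("\\.tsv$", "", basename(f))
  datasets[[name]] <- population_activity(load_raster(f))
}
datasets[["shuffled_m0p9"]] <- shuffle_time(datasets[["branching_m0p9"]],
                                            seed = 303)

report <- run_pipeline(datasets, coarsen_factors = c(1, 2, 5, 10))
print(report$sweep)
utils::write.csv(report$sweep, "results/mr/sweep_temporal.csv",
                 row.names = FALSE)

# conversion law m_hat = phi^dt fitted per dataset (phi is a property of
# one underlying system observed at several sampling timescales)
cat("\nconversion-law fits per dataset:\n")
for (nm in unique(report$sweep$dataset)) {
  rows <- report$sweep[report$sweep$dataset == nm & report$sweep$accepted &
                         is.finite(report$sweep$m_hat) &
                         report$sweep$m_hat > 0, ]
  if (nrow(rows) >= 3) {
    phi <- fit_phi(data.frame(dt = rows$dt, m_hat = rows$m_hat))
    cat(sprintf("  %-22s phi = %.3f (m at native dt: %.3f)\n", nm, phi$phi,
                predict(phi, 1)))
  } else {
    cat(sprintf("  %-22s too few accepted sweep points\n", nm))
  }
}

# the m = 0.9 dataset in detail: the r_k decay and its fit
mr <- report$datasets[["branching_m0p9"]]$mr
cat(sprintf("\nm = 0.9 dataset: m_hat = %.3f, tau = %.1f bins, verdict %s\n",
            mr$m_hat, mr$tau,
            report$datasets[["branching_m0p9"]]$report$verdict))
utils::write.csv(data.frame(k = seq_along(mr$r_k), r_k = mr$r_k,
                            fit = mr$b_hat * mr$m_hat^seq_along(mr$r_k)),
                 "results/mr/rk_m0p9.csv", row.names = FALSE)
cat("wrote results/mr/sweep_temporal.csv and results/mr/rk_m0p9.csv\n")
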
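#!/usr/bin/env Rscript

# Generate the synthetic datasets used by the downstream analysis steps:
# driven branching processes spanning the asynchronous-reverberating-critical
# spectrum (m = 0, 0.5, 0.9, 0.985, 0.9999) and two lattice networks in the
# regimes matched to the coarse-timescale branching values 0.7972 and 0.9985.
# Every dataset is written with a JSON manifest holding its ground truth.

suppressPackageStartupMessages(library(spikedyn))
out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

ms <- c(0, 0.5, 0.9, 0.985, 0.9999)
for (i in seq_along(ms)) {
  m <- ms[i]
  h <- if (m < 1) (1 - m) * 10 else 0.001      # stationary mean ~10
  name <- sprintf("branching_m%s", sub("\\.", "p", format(m)))
  out <- make_synthetic_dataset(
    list(model = "branching", m = m, h = max(h, 0.001), steps = 13000, dt = 1),
    out_dir, name = name, seed = 100 + i)
  cat("wrote", out$data_path, "\n")
}

# Lattice networks at the fine (4 ms) timescale; recorded subset of 250 units
for (m_fine in c(0.985, 0.9999)) {
  h_unit <- if (m_fine == 0.985) 5e-4 * (1 - m_fine) else 4e-4
  name <- sprintf("lattice_m%s", sub("\\.", "p", format(m_fine)))
  out <- make_synthetic_dataset(
    list(model = "lattice", n_units = 2500, m = m_fine, h_unit = h_unit,
         steps = 45000, dt = 0.004, record = 250),
    out_dir, name = name, seed = 200)
  cat("wrote", out$data_path, "\n")
}
cat("done: all ground truths recorded in the *_manifest.json files\n")
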
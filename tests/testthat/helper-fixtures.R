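# Build an avalanche_set directly from profiles (bypassing extraction) for
# tests of the scaling analyses.
make_avalanche_set <- function(profiles, dt = 1) {
  structure(list(
    sizes = vapply(profiles, sum, 0),
    durations = vapply(profiles, length, 0L),
    profiles = profiles,
    edge_truncated = rep(FALSE, length(profiles)),
    dt = dt,
    no_silent_bins = FALSE
  ), class = "avalanche_set")
}

# Parabolic avalanche profiles s(x) = T^gamma * 4 x (1 - x) sampled at each
# duration's own rescaled time grid; the canonical mean-field avalanche shape.
parabolic_profiles <- function(durations, gamma = 1, copies = 1, scale = 1) {
  profs <- lapply(durations, function(Td) {
    x <- seq(0, 1, length.out = Td)
    scale * Td^gamma * 4 * x * (1 - x)
  })
  rep(profs, each = copies)
}

# Spike-count matrix object built straight from a count matrix.
make_scm <- function(counts, window_width = 1) {
  structure(list(counts = counts, window_width = window_width,
                 n_subsets = ncol(counts)),
            class = "spike_count_matrix")
}
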
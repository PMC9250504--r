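# Shared fixtures, built once per test run. Forward/inverse pairs share the
# electrode layout (same `seed`) but use disjoint source grids
# (`source_seed`) so inversion never happens on the generating grid.

fix <- local({
  lf16 <- build_spherical_leadfield(16, 40, seed = 42)
  lf_fwd32 <- build_spherical_leadfield(32, 300, seed = 7, source_seed = 71)
  lf_inv32 <- build_spherical_leadfield(32, 150, seed = 7, source_seed = 72)
  list(lf16 = lf16, lf_fwd32 = lf_fwd32, lf_inv32 = lf_inv32,
       regions32 = make_region_sets(lf_fwd32))
})

# One noisy (0 dB) and one noiseless trial on the 32-channel pair.
fix$trial_noisy <- simulate_trial(fix$lf_fwd32, fix$regions32,
                                  default_sim_config(), seed = 101)
fix$trial_clean <- local({
  cfg <- default_sim_config()
  cfg$snr_db <- NULL
  simulate_trial(fix$lf_fwd32, fix$regions32, cfg, seed = 101)
})

# Independent brute-force non-dominated sort: repeated full scans using the
# pairwise definition only.
brute_fronts <- function(obj) {
  remaining <- seq_len(nrow(obj))
  fronts <- list()
  while (length(remaining) > 0) {
    nd <- remaining[vapply(remaining, function(i) {
      !any(vapply(remaining, function(j)
        j != i && dominates(obj[j, ], obj[i, ]), logical(1)))
    }, logical(1))]
    fronts[[length(fronts) + 1]] <- nd
    remaining <- setdiff(remaining, nd)
  }
  fronts
}

# Canonical form for comparing front partitions.
front_sets <- function(fronts) lapply(fronts, sort)
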
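# Small simulation configurations used across tests. Cohort sizes are kept
# modest where the property under test does not need the full design.

small_cfg <- function(n = 10L, seed = 1L, ...) {
  sim_config(n_dat = n, n_bvftd = n, seed = seed, ...)
}

# cohort with balanced disinhibition across both diagnosis groups
balanced_cfg <- function(n = 10L, seed = 1L, ...) {
  sim_config(n_dat = n, n_bvftd = n, seed = seed,
             disinhibition_rate = c(DAT = 0.5, bvFTD = 0.5), ...)
}

fixture_atlas <- function() load_atlas()

# rescale a vector to have an exact sample mean and SD
with_moments <- function(x, mean, sd) {
  (x - mean(x)) / sd(x) * sd + mean
}
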
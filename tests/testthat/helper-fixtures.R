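# Shared small fixtures; all generated in code.

small_phantom <- function(seed = 1, ..., grid = c(16, 16, 10)) {
  phantom_config(grid_shape = grid, seed = seed, ...)
}

noiseless_phantom <- function(seed = 1, grid = c(16, 16, 10), ...) {
  phantom_config(grid_shape = grid, seed = seed,
                 dwi_noise_sd = 0, dce_noise_sd = 0, ...)
}

tiny_cohort_config <- function(n = 8, seed = 3,
                               missing_sequence_fractions = list(dwi = 0,
                                                                 dce = 0),
                               ...) {
  cohort_config(n_patients = n, seed = seed,
                phantom = phantom_config(grid_shape = c(14, 14, 8)),
                missing_sequence_fractions = missing_sequence_fractions, ...)
}
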
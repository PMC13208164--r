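# Shared fixtures, all built in code.

# Day-unit rate constants of the default configuration.
K1_DAY <- 2.59e-7 * 86400
K2_DAY <- 5.13e-5 * 86400

# A noiseless count triplet for a given mixture on a given grid.
noiseless_triplet <- function(concentrations, grid = 300:400, width = 25,
                              counts_at_reference = 48000) {
  simulate_count_triplet(
    source_model(grid = grid, counts_at_reference = counts_at_reference),
    mixture_sample(concentrations),
    default_lake_curves(grid = grid, width = width),
    noise_model("none")
  )
}

# Constant-count spectra are handy for arithmetic checks.
flat_counts <- function(grid, value) {
  tibble::tibble(wavelength = grid, counts = rep(value, length(grid)))
}

# A small lake configuration that runs in well under a second.
quick_lake <- function(depth = 0.05, ...) {
  lake_config(depth = depth, horizon = 50, record_every = 5, ...)
}

# Flat attenuation curves across both bands (one value everywhere), used to
# build columns with a prescribed uniform optical depth.
flat_curves <- function(grid, eps_ferro, eps_nitro = 0) {
  dplyr::bind_rows(
    tibble::tibble(wavelength = as.numeric(grid), epsilon = eps_ferro,
                   species = "ferrocyanide"),
    tibble::tibble(wavelength = as.numeric(grid), epsilon = eps_nitro,
                   species = "nitroprusside")
  )
}
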
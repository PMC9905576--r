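# Shared fixtures. Small-grid models (140 points = one pooling block) keep
# the training-related tests fast; the acceptance tests build full-size
# problems and cache expensive fits for re-use across test blocks.

small_grid <- function() make_wavelength_grid(350, 489, 140)

small_dataset <- function(scenario = "N01", n = 20, seed = 42, noise_sd = 5) {
  synthesize_dataset(
    scenario_config(scenario, n_samples = n, noise_sd = noise_sd, seed = seed),
    small_grid()
  )
}

# memoised store for fits shared between acceptance tests
.fit_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fit_cache)) assign(key, expr, envir = .fit_cache)
  get(key, envir = .fit_cache)
}
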
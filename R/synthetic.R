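#' Gaussian peak parameters
#'
#' One emission peak of a reference spectrum: amplitude \eqn{I_k} (a.u.),
#' centre \eqn{\lambda_k} (nm) and width \eqn{\sigma_k} (nm). Note the width
#' convention used throughout the benchmarks: the peak profile is
#' \eqn{I_k \exp(-(\lambda-\lambda_k)^2 / (2\sigma_k)^2)}, i.e. the
#' denominator is the square of \eqn{2\sigma_k}, not \eqn{2\sigma_k^2}.
#'
#' @param amplitude peak amplitude (a.u.), non-negative.
#' @param center peak centre (nm).
#' @param width peak width parameter \eqn{\sigma_k} (nm), positive.
#' @return A `peak_params` object.
#' @export
peak_params <- function(amplitude, center, width) {
  if (amplitude < 0) stop_invalid("peak amplitude must be non-negative")
  if (width <= 0) stop_invalid("peak width must be positive")
  structure(list(amplitude = amplitude, center = center, width = width),
            class = "peak_params")
}

#' Evaluate a multi-peak reference spectrum
#'
#' The reference spectrum of one agent at unit concentration is a sum of
#' Gaussian peaks,
#' \deqn{I_0(\lambda) = \sum_k I_k \exp\!\big(-(\lambda-\lambda_k)^2 / (2\sigma_k)^2\big),}
#' evaluated pointwise on the grid.
#'
#' @param peaks a single [peak_params()] or a list of them.
#' @param grid a [make_wavelength_grid()] object or numeric wavelength
#'   vector.
#' @return A [spectrum()].
#' @examples
#' g <- default_grid()
#' ref <- reference_spectrum(list(peak_params(180, 656.3, 2),
#'                                peak_params(60, 486.1, 2)), g)
#' @export
reference_spectrum <- function(peaks, grid) {
  if (inherits(peaks, "peak_params")) peaks <- list(peaks)
  if (!length(peaks) || !all(vapply(peaks, inherits, logical(1), "peak_params")))
    stop_invalid("'peaks' must be peak_params objects")
  grid <- as_wavelength_grid(grid)
  w <- grid$values
  y <- 0
  for (p in peaks)
    y <- y + p$amplitude * exp(-((w - p$center)^2) / (2 * p$width)^2)
  spectrum(w, y)
}

# Peak tables of the six benchmark scenarios. N01-N05 are one-agent cases
# sharing amplitudes 180/60 and centres 656.3/486.1 nm; N05 widens the peaks
# (sigma 45/40 nm) so that the reference is no longer sharply peaked. N06
# has two agents with interleaved peaks.
scenario_peak_table <- function(scenario) {
  switch(scenario,
    N01 = ,
    N02 = ,
    N03 = ,
    N04 = list(list(peak_params(180, 656.3, 2), peak_params(60, 486.1, 2))),
    N05 = list(list(peak_params(180, 656.3, 45), peak_params(60, 486.1, 40))),
    N06 = list(
      list(peak_params(180, 656.3, 2), peak_params(60, 486.1, 2)),
      list(peak_params(240, 587.5, 2), peak_params(100, 480.0, 2))
    ),
    stop_invalid("unknown scenario: ", scenario)
  )
}

#' Reference spectra of a benchmark scenario
#'
#' @param scenario one of `"N01"` to `"N06"`.
#' @param grid wavelength grid (defaults to [default_grid()]).
#' @return A numeric matrix with one column per agent (length-of-grid rows),
#'   with the grid attached as attribute `wavelength`. N01-N05 have one
#'   agent, N06 has two.
#' @export
scenario_references <- function(scenario, grid = default_grid()) {
  grid <- as_wavelength_grid(grid)
  specs <- scenario_peak_table(scenario)
  refs <- vapply(specs, function(p) reference_spectrum(p, grid)$intensity,
                 numeric(length(grid$values)))
  refs <- matrix(refs, nrow = length(grid$values))
  colnames(refs) <- paste0("agent_", seq_len(ncol(refs)))
  attr(refs, "wavelength") <- grid$values
  refs
}

#' Benchmark scenario configuration
#'
#' Describes one of the six synthetic benchmark families:
#' \describe{
#'   \item{N01}{peaked reference, steady constant background (10 a.u.);}
#'   \item{N02}{peaked reference, unsteady constant background
#'     \eqn{10\varepsilon}, \eqn{\varepsilon \sim U[1,6]};}
#'   \item{N03}{peaked reference, steady shaped background
#'     \eqn{50\exp(-(\lambda-500)^2/(2\cdot75^2))};}
#'   \item{N04}{peaked reference, unsteady shaped background
#'     \eqn{50\varepsilon_1\exp(-(\lambda-500-200\varepsilon_2)^2/(2\cdot75^2))},
#'     \eqn{\varepsilon_1 \sim U[1,6]}, \eqn{\varepsilon_2 \sim U[0,1]};}
#'   \item{N05}{as N04 but with a broad, non-peaked reference;}
#'   \item{N06}{as N04 with two agents and independent concentrations.}
#' }
#' One \eqn{(\varepsilon, \varepsilon_1, \varepsilon_2)} draw applies per
#' spectrum, shared across its wavelengths. Noise is i.i.d. zero-mean
#' Gaussian per wavelength with standard deviation `noise_sd` (default 5
#' a.u.), and concentrations are uniform on `conc_range` (default 0 to 2).
#'
#' @param scenario one of `"N01"` to `"N06"`.
#' @param n_samples number of spectra to generate (default 1000).
#' @param conc_range concentration interval, lower bound non-negative.
#' @param noise_sd noise standard deviation (a.u.), non-negative.
#' @param seed integer seed making the generated dataset reproducible, or
#'   `NULL` to draw from the current RNG stream.
#' @return A `scenario_config` object.
#' @export
scenario_config <- function(scenario, n_samples = 1000, conc_range = c(0, 2),
                            noise_sd = 5, seed = 1) {
  scenario <- match.arg(scenario, paste0("N0", 1:6))
  if (n_samples < 1) stop_invalid("'n_samples' must be at least 1")
  if (length(conc_range) != 2 || conc_range[1] < 0 || conc_range[2] <= conc_range[1])
    stop_invalid("'conc_range' must be an increasing interval with lower bound >= 0")
  if (noise_sd < 0) stop_invalid("'noise_sd' must be non-negative")
  structure(list(scenario = scenario, n_samples = as.integer(n_samples),
                 conc_range = as.numeric(conc_range), noise_sd = noise_sd,
                 seed = seed),
            class = "scenario_config")
}

# Background intensities for given nuisance draws; eps1/eps2 may be vectors
# (one spectrum per element). Returns a matrix n x length(grid).
background_matrix <- function(scenario, grid, eps1, eps2) {
  w <- as_wavelength_grid(grid)$values
  n <- max(length(eps1), length(eps2), 1L)
  switch(scenario,
    N01 = matrix(10, n, length(w)),
    N02 = matrix(10 * eps1, n, length(w)),
    N03 = matrix(rep(50 * exp(-(w - 500)^2 / (2 * 75^2)), each = n), n, length(w)),
    N04 = ,
    N05 = ,
    N06 = {
      centres <- 500 + 200 * eps2
      t(vapply(seq_len(n), function(i)
        50 * eps1[i] * exp(-(w - centres[i])^2 / (2 * 75^2)),
        numeric(length(w))))
    },
    stop_invalid("unknown scenario: ", scenario)
  )
}

#' Draw one background spectrum of a scenario
#'
#' Draws the scenario's nuisance parameters (\eqn{\varepsilon} on 1 to 6
#' and/or \eqn{\varepsilon_2} on 0 to 1, one draw shared across all
#' wavelengths) from the current RNG stream and evaluates the background.
#'
#' @param config a [scenario_config()] (its seed is *not* applied here; seed
#'   externally or via [synthesize_dataset()]).
#' @param grid wavelength grid.
#' @return A [spectrum()]; the draws are attached as attributes `eps1` and
#'   `eps2`.
#' @export
background_sample <- function(config, grid = default_grid()) {
  stopifnot(inherits(config, "scenario_config"))
  eps <- switch(config$scenario,
    N01 = ,
    N03 = list(eps1 = 1, eps2 = 0),
    N02 = list(eps1 = runif(1, 1, 6), eps2 = 0),
    list(eps1 = runif(1, 1, 6), eps2 = runif(1, 0, 1))
  )
  bg <- background_matrix(config$scenario, grid, eps$eps1, eps$eps2)
  s <- spectrum(grid, bg[1, ])
  attr(s, "eps1") <- eps$eps1
  attr(s, "eps2") <- eps$eps2
  s
}

#' Draw a noise spectrum
#'
#' Independent zero-mean Gaussian noise per wavelength, drawn from the
#' current RNG stream.
#'
#' @param grid wavelength grid.
#' @param sd noise standard deviation (a.u.), non-negative.
#' @return A [spectrum()].
#' @export
noise_sample <- function(grid = default_grid(), sd = 5) {
  if (sd < 0) stop_invalid("'sd' must be non-negative")
  grid <- as_wavelength_grid(grid)
  spectrum(grid, rnorm(length(grid$values), 0, sd))
}

#' Generate a labelled benchmark dataset
#'
#' Builds `n_samples` measured spectra of the configured scenario: each is
#' the sum of the concentration-scaled reference spectra, a background draw
#' and a noise draw. Concentrations, nuisance draws and the three generating
#' components are retained so that downstream code can be tested against the
#' exact truth; they are never consulted by [train_pinn()].
#'
#' With a non-`NULL` `config$seed`, runs are bit-reproducible and the
#' caller's RNG state is left untouched.
#'
#' @param config a [scenario_config()].
#' @param grid wavelength grid (defaults to [default_grid()]).
#' @param keep_components retain the generating agent/background/noise
#'   matrices (default `TRUE`).
#' @return A `pinn_dataset`: list with `wavelength` (grid values), `spectra`
#'   (n x L matrix of measurements), `concentrations` (n x N matrix),
#'   `references` (L x N matrix), `components` (list of n x L matrices
#'   `agent`, `background`, `noise`, or `NULL`), `eps` (data frame of
#'   nuisance draws), plus the scenario metadata.
#' @examples
#' ds <- synthesize_dataset(scenario_config("N01", n_samples = 5, seed = 42))
#' dim(ds$spectra)
#' @export
synthesize_dataset <- function(config, grid = default_grid(),
                               keep_components = TRUE) {
  stopifnot(inherits(config, "scenario_config"))
  grid <- as_wavelength_grid(grid)
  w <- grid$values
  L <- length(w)
  n <- config$n_samples
  refs <- scenario_references(config$scenario, grid)
  N <- ncol(refs)

  with_seed(config$seed, {
    conc <- matrix(runif(n * N, config$conc_range[1], config$conc_range[2]), n, N)
    eps1 <- switch(config$scenario, N01 = , N03 = rep(1, n), runif(n, 1, 6))
    eps2 <- switch(config$scenario, N01 = , N02 = , N03 = rep(0, n), runif(n, 0, 1))
    noise <- matrix(rnorm(n * L, 0, config$noise_sd), n, L)

    agent <- conc %*% t(refs)
    bg <- background_matrix(config$scenario, grid, eps1, eps2)
    measured <- agent + bg + noise

    structure(list(
      wavelength = w,
      spectra = measured,
      concentrations = conc,
      references = refs,
      components = if (keep_components)
        list(agent = agent, background = bg, noise = noise) else NULL,
      eps = data.frame(eps1 = eps1, eps2 = eps2),
      scenario = config$scenario,
      seed = config$seed,
      noise_sd = config$noise_sd,
      conc_range = config$conc_range
    ), class = "pinn_dataset")
  })
}

#' @export
print.pinn_dataset <- function(x, ...) {
  cat(sprintf("<pinn_dataset> scenario %s: %d spectra x %d wavelengths, %d agent(s)%s\n",
              x$scenario, nrow(x$spectra), ncol(x$spectra), ncol(x$concentrations),
              if (is.null(x$components)) " (measurements only)" else ""))
  invisible(x)
}
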
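test_that("wavelength grids are uniform, inclusive and validated", {
  g <- make_wavelength_grid(350, 1049, 700)
  expect_equal(g$spacing, 1.0)
  expect_equal(length(g$values), 700)
  expect_equal(g$values[c(1, 700)], c(350, 1049))

  expect_equal(make_wavelength_grid(0, 2, 3)$values, c(0, 1, 2))
  expect_error(make_wavelength_grid(500, 400, 10), class = "pinncal_invalid")
  expect_error(make_wavelength_grid(0, 1, 1), class = "pinncal_invalid")
  expect_error(as_wavelength_grid(c(1, 3, 2)), class = "pinncal_invalid")
})

test_that("reference spectrum matches hand-evaluated Gaussian values", {
  # evaluate on a grid holding the exact peak wavelength and offsets
  w <- c(486.1, 656.3, 660.3)
  ref <- reference_spectrum(list(peak_params(180, 656.3, 2),
                                 peak_params(60, 486.1, 2)), w)
  at <- function(x) ref$intensity[match(x, w)]
  # at the first peak centre the second term is ~exp(-1810), i.e. 0
  i6563 <- 180 + 60 * exp(-(656.3 - 486.1)^2 / 16)
  expect_equal(at(656.3), i6563, tolerance = 1e-12)
  expect_equal(at(656.3), 180, tolerance = 1e-12)
  # two width parameters away from the centre: amplitude * exp(-1)
  expect_equal(at(660.3), 180 * exp(-1), tolerance = 1e-6)

  # single peak is symmetric about its centre
  single <- reference_spectrum(peak_params(1, 0, 3), seq(-10, 10, by = 0.5))
  expect_equal(single$intensity, rev(single$intensity))

  expect_error(peak_params(1, 500, 0), class = "pinncal_invalid")
  expect_error(peak_params(-1, 500, 1), class = "pinncal_invalid")
})

test_that("reference argmax sits on the grid point nearest the main peak", {
  refs <- scenario_references("N01")
  w <- attr(refs, "wavelength")
  expect_equal(w[which.max(refs[, 1])], w[which.min(abs(w - 656.3))])
})

test_that("scenario backgrounds follow their generating formulas", {
  g <- default_grid()
  w <- g$values
  # steady scenarios are deterministic
  expect_equal(unname(pinncal:::background_matrix("N01", g, 1, 0)[1, ]),
               rep(10, 700))
  n03 <- pinncal:::background_matrix("N03", g, 1, 0)[1, ]
  expect_equal(n03[which(w == 500)], 50)
  expect_equal(n03, 50 * exp(-(w - 500)^2 / (2 * 75^2)))
  # unsteady shaped: hand evaluation at the shifted centre
  n04 <- pinncal:::background_matrix("N04", g, eps1 = 2, eps2 = 0.5)[1, ]
  expect_equal(n04[which(w == 600)], 100)
  # constant unsteady: 10 * eps
  n02 <- pinncal:::background_matrix("N02", g, eps1 = 3.7, eps2 = 0)[1, ]
  expect_equal(n02, rep(37, 700))
})

test_that("background draws stay in the stated nuisance ranges", {
  cfg <- scenario_config("N04", n_samples = 200, seed = 7)
  ds <- synthesize_dataset(cfg)
  expect_true(all(ds$eps$eps1 >= 1 & ds$eps$eps1 <= 6))
  expect_true(all(ds$eps$eps2 >= 0 & ds$eps$eps2 <= 1))
  # one draw per spectrum: each background row matches its eps exactly
  w <- ds$wavelength
  for (i in c(1, 57, 200)) {
    expect_equal(ds$components$background[i, ],
                 50 * ds$eps$eps1[i] *
                   exp(-(w - 500 - 200 * ds$eps$eps2[i])^2 / (2 * 75^2)))
  }
})

test_that("a noiseless unsteady background is exactly recoverable", {
  # family membership: fitting the log-background recovers eps1 and eps2
  ds <- synthesize_dataset(scenario_config("N04", n_samples = 5, seed = 3))
  w <- ds$wavelength
  for (i in 1:5) {
    bg <- ds$components$background[i, ]
    centre <- w[which.max(bg)]
    # refine by quadratic interpolation of log-intensity
    fit <- stats::lm(log(bg) ~ poly(w, 2, raw = TRUE))
    co <- coef(fit)
    centre_hat <- -co[2] / (2 * co[3])
    eps2_hat <- (centre_hat - 500) / 200
    eps1_hat <- exp(co[1] - co[2]^2 / (4 * co[3])) / 50
    expect_equal(eps2_hat, ds$eps$eps2[i], tolerance = 1e-6,
                 ignore_attr = TRUE)
    expect_equal(eps1_hat, ds$eps$eps1[i], tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("noise generator has the configured moments", {
  g <- default_grid()
  set.seed(99)
  draws <- unlist(replicate(143, noise_sample(g, sd = 5)$intensity,
                            simplify = FALSE))  # ~1e5 draws
  n <- length(draws)
  expect_gt(n, 1e5 - 1)
  expect_lt(abs(mean(draws)), 3 * 5 / sqrt(n))
  expect_equal(sd(draws), 5, tolerance = 0.02)
  expect_equal(noise_sample(g, sd = 0)$intensity, rep(0, 700))
  expect_error(noise_sample(g, sd = -1), class = "pinncal_invalid")
})

test_that("measured spectra are the exact sum of their components", {
  for (sc in c("N01", "N04", "N06")) {
    ds <- synthesize_dataset(scenario_config(sc, n_samples = 10, seed = 5),
                             small_grid())
    recon <- ds$components$agent + ds$components$background + ds$components$noise
    expect_equal(ds$spectra, recon)
    expect_equal(ds$components$agent,
                 ds$concentrations %*% t(ds$references))
    expect_true(all(ds$concentrations >= 0 & ds$concentrations <= 2))
  }
})

test_that("N06 uses two reference spectra with independent concentrations", {
  ds <- synthesize_dataset(scenario_config("N06", n_samples = 400, seed = 8),
                           small_grid())
  expect_equal(ncol(ds$concentrations), 2)
  expect_equal(ncol(ds$references), 2)
  # independence: sample correlation of the two concentration draws is small
  expect_lt(abs(cor(ds$concentrations[, 1], ds$concentrations[, 2])), 0.15)
  # peak positions of the two agents (on the default grid they differ)
  refs <- scenario_references("N06")
  w <- attr(refs, "wavelength")
  expect_equal(w[which.max(refs[, 1])], 656)        # nearest grid point to 656.3
  expect_true(w[which.max(refs[, 2])] %in% c(587, 588))  # 587.5 falls mid-cell
  expect_equal(max(refs[, 1]), 180, tolerance = 0.02)
  expect_equal(max(refs[, 2]), 240, tolerance = 0.02)
})

test_that("zero-noise, unit-concentration N01 reduces to reference plus offset", {
  cfg <- scenario_config("N01", n_samples = 3, conc_range = c(1, 1 + 1e-12),
                         noise_sd = 0, seed = 2)
  ds <- synthesize_dataset(cfg)
  ref <- scenario_references("N01")[, 1]
  for (i in 1:3)
    expect_equal(ds$spectra[i, ], ref + 10, tolerance = 1e-9,
                 ignore_attr = TRUE)
})

test_that("generation is seed-reproducible byte for byte", {
  cfg <- scenario_config("N05", n_samples = 15, seed = 123)
  d1 <- synthesize_dataset(cfg, small_grid())
  d2 <- synthesize_dataset(cfg, small_grid())
  expect_identical(serialize(d1, NULL), serialize(d2, NULL))
  d3 <- synthesize_dataset(scenario_config("N05", n_samples = 15, seed = 124),
                           small_grid())
  expect_false(identical(d1$spectra, d3$spectra))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(77)
  a <- runif(1)
  set.seed(77)
  invisible(synthesize_dataset(scenario_config("N01", n_samples = 2, seed = 1),
                               small_grid()))
  expect_identical(runif(1), a)
})
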
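# Single-pass brute-force metric oracles (independent of the implementations).
brute_r2 <- function(t, p) {
  num <- 0; den <- 0; tb <- sum(t) / length(t)
  for (i in seq_along(t)) {
    num <- num + (t[i] - p[i])^2
    den <- den + (t[i] - tb)^2
  }
  1 - num / den
}

brute_mre <- function(t, p, floor) {
  acc <- 0; k <- 0
  for (i in seq_along(t)) if (t[i] >= floor) {
    acc <- acc + abs(p[i] - t[i]) / t[i]
    k <- k + 1
  }
  100 * acc / k
}

test_that("metrics match hand values and the brute-force oracle", {
  expect_equal(r_squared(c(0, 1, 2), c(0, 1, 1)), 0.5)
  expect_equal(r_squared(1:5, 1:5), 1)
  expect_equal(r_squared(c(1, 2, 3), rep(2, 3)), 0)
  expect_equal(mean_relative_error(c(1, 2), c(1.01, 2.02)), 1)
  expect_equal(mean_relative_error(1:4, 1:4), 0)

  set.seed(6)
  for (rep in 1:5) {
    t <- runif(8, 0, 2); p <- t + rnorm(8, 0, 0.1)
    expect_equal(r_squared(t, p), brute_r2(t, p), tolerance = 1e-12)
    expect_equal(mean_relative_error(t, p, 0.3), brute_mre(t, p, 0.3),
                 tolerance = 1e-12)
  }

  expect_error(r_squared(rep(1, 5), rep(1, 5)), class = "pinncal_degenerate")
  expect_error(r_squared(1:3, 1:4), class = "pinncal_invalid")
  expect_error(mean_relative_error(c(0.01, 0.05), c(1, 1), floor = 0.1),
               class = "pinncal_degenerate")
})

test_that("evaluation reports cover each agent separately", {
  set.seed(10)
  t <- matrix(runif(40, 0, 2), 20, 2)
  p <- t + matrix(rnorm(40, 0, 0.02), 20, 2)
  ev <- evaluate_predictions(t, p)
  expect_length(ev$r_squared, 2)
  expect_length(ev$mean_relative_error, 2)
  expect_true(all(ev$r_squared <= 1))
  expect_true(all(ev$mean_relative_error >= 0))
  expect_equal(ev$n, 20)
  expect_output(print(ev), "agent 2")
})

test_that("wavelength cuts keep strictly larger wavelengths only", {
  g <- make_wavelength_grid(180, 874, 348)
  s <- spectrum(g, rep(1, 348))
  cut <- cut_wavelengths(s, 400)
  expect_true(all(cut$wavelength > 400))
  expect_equal(length(cut$wavelength),
               sum(g$values > 400))
  # cutting below the grid is the identity
  expect_equal(cut_wavelengths(s, 100)$wavelength, s$wavelength)
  expect_error(cut_wavelengths(s, 1000), class = "pinncal_degenerate")
})

test_that("spectrum averaging reduces noise as 1/sqrt(n)", {
  g <- small_grid()
  s <- spectrum(g, sin(g$values / 30))
  expect_equal(average_spectra(list(s))$intensity, s$intensity)
  neg <- spectrum(g, -s$intensity)
  expect_equal(average_spectra(list(s, neg))$intensity, rep(0, 140))

  ref <- scenario_references("N01", g)[, 1]
  set.seed(21)
  noisy <- replicate(10, spectrum(g, ref + rnorm(140, 0, 5)),
                     simplify = FALSE)
  avg <- average_spectra(noisy)
  resid_sd <- sd(avg$intensity - ref)
  expect_equal(resid_sd, 5 / sqrt(10), tolerance = 0.35)

  other <- spectrum(make_wavelength_grid(0, 139, 140), rep(1, 140))
  expect_error(average_spectra(list(s, other)), class = "pinncal_invalid")
})

test_that("spectrum files round-trip to 12 significant digits", {
  ds <- small_dataset(n = 1, seed = 14)
  s <- spectrum(ds$wavelength, ds$spectra[1, ],
                comments = c("scenario N01", "units a.u."))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum(s, path)
  back <- read_spectrum(path)
  expect_equal(back$wavelength, s$wavelength, tolerance = 1e-12)
  expect_equal(back$intensity, s$intensity, tolerance = 1e-12)
  expect_equal(back$comments, s$comments)
})

test_that("spectrum reader reports malformed input precisely", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# ok", "1\t2", "2\t3\t4", "3\t4"), path)
  err <- tryCatch(read_spectrum(path), error = identity)
  expect_s3_class(err, "pinncal_invalid")
  expect_match(conditionMessage(err), "line 3")

  writeLines(c("1\t2", "2\tx"), path)
  expect_error(read_spectrum(path), class = "pinncal_invalid")

  writeLines(c("1\t2", "3\t5", "2\t4"), path)  # non-monotone wavelengths
  expect_error(read_spectrum(path), class = "pinncal_invalid")

  expect_error(read_spectrum(file.path(tempdir(), "absent.tsv")),
               class = "pinncal_not_found")
})

test_that("dataset export and import preserve measurements and labels", {
  ds <- small_dataset("N04", n = 7, seed = 33)
  base <- withr::local_tempfile(fileext = ".tsv")
  write_dataset(ds, base)
  back <- read_dataset(base)
  expect_equal(back$spectra, ds$spectra, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$concentrations, ds$concentrations, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$references, ds$references, tolerance = 1e-12)
  expect_equal(back$scenario, ds$scenario)
  expect_equal(back$components$background, ds$components$background,
               tolerance = 1e-12, ignore_attr = TRUE)

  # measurements-only export strips the components
  base2 <- withr::local_tempfile(fileext = ".tsv")
  write_dataset(ds, base2, include_components = FALSE)
  expect_null(read_dataset(base2)$components)
})

test_that("least-squares baseline recovers exact mixtures", {
  # noiseless constant background: recovery is exact
  cfg <- scenario_config("N01", n_samples = 6, noise_sd = 0, seed = 3)
  ds <- synthesize_dataset(cfg, small_grid())
  chat <- lsq_concentrations(ds)
  expect_equal(chat, ds$concentrations, tolerance = 1e-9,
               ignore_attr = TRUE)

  # with noise the residual error scales like the theory value
  cfgn <- scenario_config("N01", n_samples = 200, seed = 4)
  dsn <- synthesize_dataset(cfgn)
  chat_n <- lsq_concentrations(dsn)
  sigma_c <- 5 / sqrt(sum((scenario_references("N01")[, 1] -
                             mean(scenario_references("N01")[, 1]))^2))
  expect_equal(sd(chat_n - dsn$concentrations), sigma_c, tolerance = 0.2)
})
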
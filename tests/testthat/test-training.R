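# Training tests run on the 140-point grid so each one stays in the
# seconds range; the full-size behaviour is covered by the acceptance
# tests.

test_that("training drives the loss down on a degenerate noiseless set", {
  g <- small_grid()
  ref <- scenario_references("N01", g)
  # measured = reference exactly: c = 1, no background, no noise
  X <- matrix(rep(ref[, 1], 10), 10, 140, byrow = TRUE)
  m <- pinn_model(pinn_config(140), init_seed = 2)
  fit <- train_pinn(m, X, ref,
                    train_config(epochs = 150, batch_size = 5, seed = 1))
  h <- fit$history
  expect_lte(h$L_tot[nrow(h)], 0.1 * h$L_tot[1])
})

test_that("alpha 'auto' resolves to the heuristic before the first step", {
  ds <- small_dataset(n = 8, seed = 3)
  m <- pinn_model(pinn_config(140), init_seed = 1)
  fit <- train_pinn(m, ds, config = train_config(epochs = 1, seed = 1))
  expect_equal(fit$alpha,
               alpha_heuristic(ds$references, ds$wavelength, delta = "step"))
  fit_span <- train_pinn(m, ds, config = train_config(epochs = 1, seed = 1,
                                                      alpha = "auto-span"))
  expect_equal(fit_span$alpha,
               alpha_heuristic(ds$references, ds$wavelength, delta = "span"))
  fit2 <- train_pinn(m, ds, config = train_config(epochs = 1, seed = 1,
                                                  alpha = 0.37))
  expect_equal(fit2$alpha, 0.37)
})

test_that("training is unsupervised: labels never influence the weights", {
  ds <- small_dataset(n = 12, seed = 4)
  shuffled <- ds
  shuffled$concentrations <- ds$concentrations[sample(12), , drop = FALSE]
  m <- pinn_model(pinn_config(140), init_seed = 5)
  cfg <- train_config(epochs = 30, batch_size = 6, seed = 9)
  f1 <- train_pinn(m, ds, config = cfg)
  f2 <- train_pinn(m, shuffled, config = cfg)
  expect_identical(f1$par, f2$par)
})

test_that("identical seeds give identical weights; seeds matter", {
  ds <- small_dataset(n = 10, seed = 6)
  m <- pinn_model(pinn_config(140), init_seed = 1)
  cfg <- train_config(epochs = 25, batch_size = 5, seed = 31)
  f1 <- train_pinn(m, ds, config = cfg)
  f2 <- train_pinn(m, ds, config = cfg)
  expect_identical(f1$par, f2$par)
  f3 <- train_pinn(m, ds, config = train_config(epochs = 25, batch_size = 5,
                                                seed = 32))
  expect_false(identical(f1$par, f3$par))
})

test_that("split training plus resume equals one continuous run", {
  ds <- small_dataset(n = 10, seed = 7)
  m <- pinn_model(pinn_config(140), init_seed = 3)
  cfg100 <- train_config(epochs = 100, batch_size = 5, seed = 17)
  full <- train_pinn(m, ds, config = cfg100)

  half <- train_pinn(m, ds, config = train_config(epochs = 50, batch_size = 5,
                                                  seed = 17))
  rest <- resume_pinn(half, ds, config = train_config(epochs = 50,
                                                      batch_size = 5))
  expect_identical(rest$par, full$par)
  expect_equal(rest$epochs_trained, 100L)
  expect_equal(nrow(rest$history), 100)

  # resuming for zero additional epochs is a no-op
  same <- resume_pinn(half, ds, config = train_config(epochs = 0))
  expect_identical(same$par, half$par)
})

test_that("checkpoints round-trip bit-exactly and reject corruption", {
  ds <- small_dataset(n = 6, seed = 8)
  m <- pinn_model(pinn_config(140), init_seed = 4)
  fit <- train_pinn(m, ds, config = train_config(epochs = 5, batch_size = 3,
                                                 seed = 2))
  path <- withr::local_tempfile(fileext = ".rds")
  save_pinn(fit, path)
  back <- load_pinn(path)
  expect_identical(back$par, fit$par)
  expect_identical(back$config, fit$config)

  writeLines("not a checkpoint", path)
  expect_error(load_pinn(path), class = "pinncal_invalid")
  expect_error(load_pinn(file.path(tempdir(), "nowhere.rds")),
               class = "pinncal_not_found")
})

test_that("periodic checkpointing writes a loadable snapshot", {
  ds <- small_dataset(n = 6, seed = 9)
  m <- pinn_model(pinn_config(140), init_seed = 6)
  path <- withr::local_tempfile(fileext = ".rds")
  fit <- train_pinn(m, ds, config = train_config(
    epochs = 10, batch_size = 3, seed = 3,
    checkpoint_interval = 5, checkpoint_path = path))
  snap <- load_pinn(path)
  expect_equal(snap$epochs_trained, 10L)
  expect_identical(snap$par, fit$par)
})

test_that("training validates inputs", {
  m <- pinn_model(pinn_config(140), init_seed = 1)
  ds <- small_dataset(n = 4, seed = 10)
  expect_error(train_pinn(m, matrix(0, 2, 139), ds$references),
               class = "pinncal_invalid")
  expect_error(train_pinn(m, ds$spectra, references = NULL),
               class = "pinncal_invalid")
  um <- pinn_model(pinn_config(140), init_seed = 2)
  expect_error(resume_pinn(um, ds), class = "pinncal_invalid")
})

test_that("training does not perturb the caller's RNG stream", {
  ds <- small_dataset(n = 4, seed = 11)
  m <- pinn_model(pinn_config(140), init_seed = 1)
  set.seed(55)
  a <- runif(1)
  set.seed(55)
  invisible(train_pinn(m, ds, config = train_config(epochs = 2, seed = 1)))
  expect_identical(runif(1), a)
})

test_that("the autoencoder recovers a steady shaped background without noise", {
  # noiseless spectra: predicted background should match the true Gaussian
  # background to within a few percent of its peak after a short run
  train <- synthesize_dataset(scenario_config("N03", n_samples = 100,
                                              noise_sd = 0, seed = 5))
  fit <- train_pinn(pinn_model(pinn_config(700, input_scale = 200),
                               init_seed = 1),
                    train, config = train_config(epochs = 800, seed = 1))
  pr <- predict(fit, train)
  rmsd <- sqrt(mean((pr$background - train$components$background)^2))
  expect_lt(rmsd, 0.05 * 50)  # 5% of the background peak amplitude
})
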
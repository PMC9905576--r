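#' Training configuration
#'
#' Unsupervised training minimises the physics-informed loss with ADAM.
#' Benchmark-scale runs use 5e3 epochs for the one-agent scenarios and 5e4
#' for the two-agent one; the default here is 5e3. `batch_size` defaults to
#' 100 and the learning rate to 1e-3 (the conventional ADAM step size).
#'
#' @param epochs number of passes over the training spectra, >= 1.
#' @param batch_size mini-batch size, >= 1.
#' @param lr ADAM learning rate, > 0.
#' @param alpha regularisation weight; `"auto"` applies [alpha_heuristic()]
#'   to the reference spectra before the first step, using the step reading
#'   of the wavelength interval (`delta = "step"`) — the reading under
#'   which the heuristic actually balances the two loss terms on the
#'   benchmark families (see the methods vignette); `"auto-span"` uses the
#'   span reading.
#' @param seed integer seed controlling batch shuffling (and any other
#'   training randomness); `NULL` uses the current RNG stream.
#' @param shuffle reshuffle the sample order every epoch (default `TRUE`).
#' @param checkpoint_interval write a checkpoint every this many epochs
#'   (0 = never); requires `checkpoint_path`.
#' @param checkpoint_path file the periodic checkpoint is written to.
#' @return A `train_config` object.
#' @export
train_config <- function(epochs = 5000, batch_size = 100, lr = 1e-3,
                         alpha = "auto", seed = 1, shuffle = TRUE,
                         checkpoint_interval = 0, checkpoint_path = NULL) {
  if (epochs < 0) stop_invalid("'epochs' must be non-negative")
  if (batch_size < 1) stop_invalid("'batch_size' must be at least 1")
  if (lr <= 0) stop_invalid("'lr' must be positive")
  if (!identical(alpha, "auto") && !identical(alpha, "auto-span") &&
      (!is.numeric(alpha) || alpha < 0))
    stop_invalid("'alpha' must be \"auto\", \"auto-span\" or a non-negative number")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, alpha = alpha, seed = seed, shuffle = isTRUE(shuffle),
                 checkpoint_interval = as.integer(checkpoint_interval),
                 checkpoint_path = checkpoint_path),
            class = "train_config")
}

# One ADAM state: first/second moment vectors and step counter.
adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(opt, par, grad, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  opt$m <- beta1 * opt$m + (1 - beta1) * grad
  opt$v <- beta2 * opt$v + (1 - beta2) * grad^2
  mhat <- opt$m / (1 - beta1^opt$t)
  vhat <- opt$v / (1 - beta2^opt$t)
  list(opt = opt, par = par - lr * mhat / (sqrt(vhat) + eps))
}

# Shared inner loop of train_pinn()/resume_pinn(). Assumes the RNG state is
# already set up by the caller; leaves the post-training state in
# model$rng_state so a resumed run continues the same stream.
run_training <- function(model, X, refs, alpha, spacing, config, epochs) {
  n <- ncol(X)
  cfg <- unclass(model$config)
  par <- model$par
  opt <- if (is.null(model$opt)) adam_init(length(par)) else model$opt
  hist <- vector("list", epochs)
  epoch0 <- model$epochs_trained

  for (ep in seq_len(epochs)) {
    t0 <- proc.time()[["elapsed"]]
    ord <- if (config$shuffle) sample.int(n) else seq_len(n)
    starts <- seq(1, n, by = config$batch_size)
    lrec <- lreg <- ltot <- 0
    for (s in starts) {
      idx <- ord[s:min(s + config$batch_size - 1, n)]
      out <- .pinn_core(par, cfg, X[, idx, drop = FALSE], refs,
                        alpha, spacing, TRUE)
      st <- adam_step(opt, par, out$grad, config$lr)
      opt <- st$opt
      par <- st$par
      lrec <- lrec + out$L_rec; lreg <- lreg + out$L_reg; ltot <- ltot + out$L_tot
    }
    nb <- length(starts)
    hist[[ep]] <- c(epoch = epoch0 + ep, L_rec = lrec / nb, L_reg = lreg / nb,
                    L_tot = ltot / nb,
                    seconds = proc.time()[["elapsed"]] - t0)
    if (config$checkpoint_interval > 0 && !is.null(config$checkpoint_path) &&
        ep %% config$checkpoint_interval == 0) {
      snap <- model
      snap$par <- par; snap$opt <- opt
      snap$epochs_trained <- epoch0 + ep
      snap$history <- rbind(model$history, as.data.frame(do.call(rbind, hist[seq_len(ep)])))
      snap$rng_state <- get0(".Random.seed", globalenv(), inherits = FALSE)
      save_pinn(snap, config$checkpoint_path)
    }
  }

  model$par <- par
  model$opt <- opt
  model$alpha <- alpha
  model$spacing <- spacing
  model$epochs_trained <- epoch0 + epochs
  model$history <- rbind(model$history, as.data.frame(do.call(rbind, hist)))
  model$rng_state <- get0(".Random.seed", globalenv(), inherits = FALSE)
  model
}

resolve_training_inputs <- function(model, data, references, spacing) {
  if (inherits(data, "pinn_dataset")) {
    if (is.null(references)) references <- data$references
    if (is.na(spacing)) spacing <- grid_spacing(data$wavelength)
  }
  if (is.null(references)) stop_invalid("'references' is required")
  if (is.na(spacing)) spacing <- 1
  refs <- as_reference_matrix(references)
  X <- as_input_batch(data, model$config$input_length)
  if (ncol(X) < 1) stop_invalid("the training set is empty")
  if (nrow(refs) != model$config$input_length ||
      ncol(refs) != model$config$n_outputs)
    stop_invalid("reference set does not match the model grid or output width")
  list(X = X, refs = refs, spacing = spacing)
}

#' Train the calibration network (unsupervised)
#'
#' Minimises the physics-informed loss
#' \eqn{L_{tot} = L_{rec} + \alpha L_{reg}} over the training spectra with
#' mini-batch ADAM. Training is unsupervised: concentration labels that may
#' be stored in a `pinn_dataset` are never read. With a non-`NULL`
#' `config$seed`, single-threaded runs are reproducible: the same seed,
#' configuration and data give identical final weights.
#'
#' @param model a [pinn_model()].
#' @param data training spectra: a `pinn_dataset` or an n x L matrix.
#' @param references L x N reference matrix; defaults to the dataset's.
#' @param config a [train_config()].
#' @param spacing grid step (nm) for the smoothness term; defaults to the
#'   dataset's grid spacing, or 1 for bare matrices.
#' @return The trained `pinn_model`, with `$history` (a data frame of
#'   per-epoch `L_rec`, `L_reg`, `L_tot` and wall seconds), `$alpha` and the
#'   ADAM state (so training can be resumed with [resume_pinn()]).
#' @seealso [resume_pinn()], [predict.pinn_model()]
#' @export
train_pinn <- function(model, data, references = NULL,
                       config = train_config(), spacing = NA_real_) {
  stopifnot(inherits(model, "pinn_model"), inherits(config, "train_config"))
  inp <- resolve_training_inputs(model, data, references, spacing)
  alpha <- if (is.character(config$alpha)) {
    alpha_heuristic(inp$refs,
                    seq(0, by = inp$spacing, length.out = nrow(inp$refs)),
                    delta = if (identical(config$alpha, "auto-span"))
                      "span" else "step")
  } else config$alpha

  if (config$epochs == 0L) return(model)
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  if (!is.null(config$seed)) set.seed(config$seed)
  run_training(model, inp$X, inp$refs, alpha, inp$spacing, config,
               config$epochs)
}

#' Resume training from a model or checkpoint
#'
#' Continues optimisation exactly where it stopped: the ADAM moments, the
#' loss weight and the training RNG stream are all restored, so (on one
#' thread) training for `n1` epochs and resuming for `n2` is identical to
#' one `n1 + n2`-epoch run. Histories concatenate.
#'
#' @param model a trained [pinn_model()] or a checkpoint path written by
#'   [save_pinn()].
#' @param data training spectra (as in [train_pinn()]).
#' @param references reference matrix; defaults to the dataset's.
#' @param config a [train_config()]; `epochs` counts the *additional*
#'   epochs. `alpha = "auto"` re-uses the weight stored in the model.
#' @return The further-trained `pinn_model`.
#' @export
resume_pinn <- function(model, data, references = NULL,
                        config = train_config(), spacing = NA_real_) {
  if (is.character(model)) model <- load_pinn(model)
  stopifnot(inherits(model, "pinn_model"), inherits(config, "train_config"))
  if (model$epochs_trained == 0L)
    stop_invalid("the model has not been trained; use train_pinn()")
  inp <- resolve_training_inputs(model, data, references, spacing)
  alpha <- if (is.character(config$alpha)) {
    if (is.na(model$alpha))
      stop_invalid("no stored alpha to resume with; give a numeric alpha")
    model$alpha
  } else config$alpha
  if (config$epochs == 0L) return(model)

  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  if (!is.null(model$rng_state)) {
    assign(".Random.seed", model$rng_state, envir = globalenv())
  } else if (!is.null(config$seed)) {
    set.seed(config$seed)
  }
  run_training(model, inp$X, inp$refs, alpha, inp$spacing, config,
               config$epochs)
}

#' Save and load model checkpoints
#'
#' A checkpoint is a single versioned file holding the architecture, the
#' flat weight vector, the optimiser state, the training history and the
#' RNG state, and round-trips bit-exactly.
#'
#' @param model a [pinn_model()].
#' @param path file path.
#' @return `load_pinn()` returns the `pinn_model`; `save_pinn()` returns
#'   `path` invisibly.
#' @export
save_pinn <- function(model, path) {
  stopifnot(inherits(model, "pinn_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_pinn
#' @export
load_pinn <- function(path) {
  if (!file.exists(path))
    stop(errorCondition(paste0("checkpoint not found: ", path),
                        class = c("pinncal_not_found", "error")))
  model <- tryCatch(readRDS(path), error = function(e)
    stop_invalid("cannot read checkpoint ", path, ": ", conditionMessage(e)))
  if (!inherits(model, "pinn_model") || is.null(model$par) ||
      is.null(model$config) ||
      length(model$par) != .pinn_n_params(unclass(model$config)))
    stop_invalid("file is not a valid model checkpoint: ", path)
  model
}
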
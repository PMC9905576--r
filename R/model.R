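#' Network architecture configuration
#'
#' The calibration network has two parts. A convolutional autoencoder maps
#' the measured spectrum to a predicted background: two conv+ReLU layers,
#' each followed by a max-pool that remembers its argmax indices; the
#' decoder un-pools through the stored indices and applies two further
#' convolutions, the last one linear and single-channel. The background is
#' subtracted from the input and a concentration head (conv+ReLU, max-pool,
#' a ReLU fully-connected layer and a linear output layer) predicts the
#' `n_outputs` concentrations.
#'
#' All convolutions are 1-D along wavelength with "same" zero padding, so
#' the pooling strides alone control the lengths; `input_length` must be
#' divisible by `pool1 * pool2`. With the defaults a 700-point spectrum is
#' compressed to a 7-channel x 5-position code.
#'
#' The head pool advances by `head_pool_stride` (default 100) with windows
#' of `head_pool_size` (default 50), so with the defaults half of the head
#' positions are skipped; set `head_pool_stride = 50` for contiguous
#' windows.
#'
#' @param input_length number of grid points of the input spectra.
#' @param n_outputs number of concentrations to predict (agents), >= 1.
#' @param kernel convolution kernel length (all conv layers).
#' @param enc_filters filter counts of the two encoder convolutions.
#' @param pool pool sizes (= strides) of the two encoder pools.
#' @param head_filters filter count of the head convolution.
#' @param head_pool_size,head_pool_stride head max-pool geometry.
#' @param fc_width width of the hidden fully-connected layer.
#' @param input_scale affine input scaling: the convolutional stack consumes
#'   `I/input_scale` while the loss stays on raw intensities (the predicted
#'   background is rescaled before it enters the reconstruction). `1`
#'   disables scaling.
#' @return A `pinn_config` list.
#' @examples
#' cfg <- pinn_config(700)
#' @export
pinn_config <- function(input_length, n_outputs = 1, kernel = 20,
                        enc_filters = c(20, 7), pool = c(10, 14),
                        head_filters = 5, head_pool_size = 50,
                        head_pool_stride = 100, fc_width = 10,
                        input_scale = 1) {
  input_length <- as.integer(input_length)
  if (n_outputs < 1) stop_invalid("'n_outputs' must be at least 1")
  block <- prod(pool)
  if (input_length %% block != 0) {
    lo <- (input_length %/% block) * block
    hi <- lo + block
    stop_invalid("input length ", input_length, " is not divisible by the ",
                 "pooling strides (", pool[1], " x ", pool[2], "); nearest ",
                 "compatible lengths are ", lo, " and ", hi)
  }
  if (input_length < head_pool_size)
    stop_invalid("input length is shorter than the head pool window")
  structure(list(
    input_length = input_length,
    n_outputs = as.integer(n_outputs),
    kernel = as.integer(kernel),
    enc_filters1 = as.integer(enc_filters[1]),
    enc_filters2 = as.integer(enc_filters[2]),
    pool1 = as.integer(pool[1]),
    pool2 = as.integer(pool[2]),
    head_filters = as.integer(head_filters),
    head_pool_size = as.integer(head_pool_size),
    head_pool_stride = as.integer(head_pool_stride),
    fc_width = as.integer(fc_width),
    input_scale = as.numeric(input_scale)
  ), class = "pinn_config")
}

# Sizes of the weight/bias blocks in the flat parameter vector, in the
# order the compiled core unpacks them. fan_in/fan_out drive the scaled
# random initialisation.
pinn_param_layout <- function(config) {
  c <- config
  NW <- (c$input_length - c$head_pool_size) %/% c$head_pool_stride + 1L
  F <- c$head_filters * NW
  list(
    W1  = list(dim = c(c$enc_filters1, c$kernel), fan_in = c$kernel, relu = TRUE),
    b1  = list(dim = c$enc_filters1),
    W2  = list(dim = c(c$enc_filters2, c$enc_filters1 * c$kernel),
               fan_in = c$enc_filters1 * c$kernel, relu = TRUE),
    b2  = list(dim = c$enc_filters2),
    Wd1 = list(dim = c(c$enc_filters1, c$enc_filters2 * c$kernel),
               fan_in = c$enc_filters2 * c$kernel, relu = TRUE),
    bd1 = list(dim = c$enc_filters1),
    Wd2 = list(dim = c(1, c$enc_filters1 * c$kernel),
               fan_in = c$enc_filters1 * c$kernel, relu = FALSE),
    bd2 = list(dim = 1),
    Wh  = list(dim = c(c$head_filters, c$kernel), fan_in = c$kernel, relu = TRUE),
    bh  = list(dim = c$head_filters),
    Wf1 = list(dim = c(c$fc_width, F), fan_in = F, relu = TRUE),
    bf1 = list(dim = c$fc_width),
    Wf2 = list(dim = c(c$n_outputs, c$fc_width), fan_in = c$fc_width, relu = FALSE),
    bf2 = list(dim = c$n_outputs)
  )
}

#' Build an untrained calibration network
#'
#' Creates a network with the given architecture and randomly initialised
#' weights: He-scaled normal draws (`sd = sqrt(2/fan_in)`) for the
#' ReLU-activated layers, Glorot-scaled (`sd = sqrt(2/(fan_in+fan_out))`)
#' for the two linear output layers, zero biases.
#'
#' @param config a [pinn_config()].
#' @param init_seed integer seed for the weight draws, or `NULL` to use the
#'   current RNG stream.
#' @return A `pinn_model` object (untrained).
#' @export
pinn_model <- function(config, init_seed = 1) {
  stopifnot(inherits(config, "pinn_config"))
  layout <- pinn_param_layout(config)
  par <- with_seed(init_seed, {
    unlist(lapply(layout, function(blk) {
      if (length(blk$dim) == 1) return(numeric(blk$dim))  # biases start at 0
      n <- prod(blk$dim)
      sd <- if (isTRUE(blk$relu)) sqrt(2 / blk$fan_in)
            else sqrt(2 / (blk$fan_in + blk$dim[1]))
      rnorm(n, 0, sd)
    }), use.names = FALSE)
  })
  stopifnot(length(par) == .pinn_n_params(unclass(config)))
  structure(list(config = config, par = par, opt = NULL,
                 epochs_trained = 0L, alpha = NA_real_, spacing = NA_real_,
                 history = NULL, version = 1L),
            class = "pinn_model")
}

#' @export
print.pinn_model <- function(x, ...) {
  code <- .pinn_code_shape(unclass(x$config))
  cat(sprintf(paste0("<pinn_model> input %d, %d output(s), code %d x %d, ",
                     "%d parameters, %d epoch(s) trained\n"),
              x$config$input_length, x$config$n_outputs, code[1], code[2],
              length(x$par), x$epochs_trained))
  invisible(x)
}

# Coerce prediction/training input to an L x B matrix (wavelength in rows).
as_input_batch <- function(spectra, input_length) {
  if (inherits(spectra, "pinn_dataset")) spectra <- spectra$spectra
  if (inherits(spectra, "spectrum")) spectra <- matrix(spectra$intensity, nrow = 1)
  if (is.null(dim(spectra))) spectra <- matrix(spectra, nrow = 1)
  if (ncol(spectra) != input_length)
    stop_invalid("spectra have ", ncol(spectra), " points but the model ",
                 "expects ", input_length)
  t(as.matrix(spectra))
}

#' Predict concentrations and background for new spectra
#'
#' Runs the network forward. Besides the concentrations, the predicted
#' background and the implied agent spectrum
#' \eqn{I_{p,d} = \sum_j c_{p,j} I_{0,j}} are returned, so the measurement
#' can be decomposed into its three parts.
#'
#' @param object a [pinn_model()].
#' @param spectra an n x L matrix of spectra, a single [spectrum()], a
#'   numeric vector, or a `pinn_dataset`.
#' @param references L x N matrix of reference spectra; defaults to the
#'   dataset's own references when `spectra` is a `pinn_dataset`.
#' @param ... unused.
#' @return A `pinn_prediction`: list with `concentrations` (n x N),
#'   `background` (n x L) and `agent` (n x L).
#' @export
predict.pinn_model <- function(object, spectra, references = NULL, ...) {
  if (inherits(spectra, "pinn_dataset") && is.null(references))
    references <- spectra$references
  if (is.null(references))
    stop_invalid("'references' is required")
  refs <- as_reference_matrix(references)
  X <- as_input_batch(spectra, object$config$input_length)
  if (nrow(refs) != object$config$input_length ||
      ncol(refs) != object$config$n_outputs)
    stop_invalid("reference set does not match the model grid or output width")
  out <- .pinn_core(object$par, unclass(object$config), X, refs,
                    0, 1, FALSE)
  conc <- t(out$concentrations)
  colnames(conc) <- colnames(refs)
  structure(list(concentrations = conc,
                 background = t(out$background),
                 agent = conc %*% t(refs)),
            class = "pinn_prediction")
}

#' @export
print.pinn_prediction <- function(x, ...) {
  cat(sprintf("<pinn_prediction> %d spectra, %d agent(s); c_p in [%.4g, %.4g]\n",
              nrow(x$concentrations), ncol(x$concentrations),
              min(x$concentrations), max(x$concentrations)))
  invisible(x)
}
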
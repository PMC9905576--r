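## Physics-informed loss terms.
##
## These R implementations are the package's reference definitions of the
## loss; the compiled training core computes the same quantities and is
## tested against them. All sums run over wavelengths within a spectrum and
## batches are averaged, so the balance between the two terms (and hence the
## meaning of alpha) does not depend on the batch size.

# Coerce measured/background inputs to an n x L matrix.
as_batch <- function(x, L = NULL) {
  if (inherits(x, "spectrum")) x <- x$intensity
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (!is.null(L) && ncol(x) != L)
    stop_invalid("spectra have ", ncol(x), " points but ", L, " were expected")
  x
}

# Coerce concentrations to an n x N matrix.
conform_conc <- function(conc, n, N) {
  if (is.null(dim(conc))) {
    if (n == 1 && length(conc) == N) conc <- matrix(conc, 1, N)
    else if (N == 1 && length(conc) == n) conc <- matrix(conc, n, 1)
    else stop_invalid("'conc' has length ", length(conc),
                      " but ", n, " x ", N, " values are needed")
  } else {
    conc <- as.matrix(conc)
  }
  if (nrow(conc) != n || ncol(conc) != N)
    stop_invalid("'conc' must be an n x N concentration matrix")
  conc
}

as_reference_matrix <- function(references) {
  if (inherits(references, "spectrum"))
    references <- matrix(references$intensity, ncol = 1)
  if (is.null(dim(references))) references <- matrix(references, ncol = 1)
  as.matrix(references)
}

#' Reconstruction loss
#'
#' The squared mismatch between each measured spectrum and the sum of the
#' predicted agent contribution and the predicted background,
#' \deqn{L_{rec} = \sum_\lambda \Big(I(\lambda) - \sum_j c_{p,j} I_{0,j}(\lambda)
#'   - I_{p,b}(\lambda)\Big)^2,}
#' summed over wavelengths and averaged over the batch.
#'
#' @param measured an n x L matrix of measured spectra (or a single
#'   [spectrum()] / numeric vector).
#' @param conc an n x N matrix of predicted concentrations (or a length-N
#'   vector for a single spectrum).
#' @param references L x N matrix of reference spectra (columns = agents).
#' @param background an n x L matrix (or vector / [spectrum()]) of predicted
#'   backgrounds.
#' @return Scalar loss (a.u. squared).
#' @export
reconstruction_loss <- function(measured, conc, references, background) {
  refs <- as_reference_matrix(references)
  L <- nrow(refs)
  measured <- as_batch(measured, L)
  background <- as_batch(background, L)
  if (nrow(background) != nrow(measured))
    stop_invalid("'measured' and 'background' must have the same number of spectra")
  conc <- conform_conc(conc, nrow(measured), ncol(refs))
  resid <- measured - conc %*% t(refs) - background
  sum(resid^2) / nrow(measured)
}

#' Background smoothness loss
#'
#' Penalises wavelength-to-wavelength variation of the predicted background,
#' \deqn{L_{reg} = \sum_i \left(\frac{I_{p,b}(\lambda_{i+1}) -
#'   I_{p,b}(\lambda_i)}{\Delta\lambda_{step}}\right)^2,}
#' with forward differences on a uniform grid, summed over adjacent pairs
#' and averaged over the batch. It breaks the degeneracy of the
#' reconstruction term, which the network could otherwise satisfy by
#' declaring the whole measurement to be background.
#'
#' @param background n x L matrix, numeric vector or [spectrum()].
#' @param spacing grid step (nm); taken from the spectrum's grid when a
#'   [spectrum()] is given.
#' @return Scalar loss.
#' @export
smoothness_loss <- function(background, spacing = 1) {
  if (inherits(background, "spectrum")) {
    spacing <- grid_spacing(background$wavelength)
    background <- matrix(background$intensity, nrow = 1)
  }
  background <- as_batch(background)
  if (ncol(background) < 2)
    stop_invalid("the background needs at least 2 points")
  d <- t(diff(t(background))) / spacing
  sum(d^2) / nrow(background)
}

#' Total physics-informed loss
#'
#' \eqn{L_{tot} = L_{rec} + \alpha L_{reg}}. When `response` is supplied,
#' the linear agent term \eqn{\sum_j c_{p,j} I_{0,j}(\lambda)} in the
#' reconstruction is replaced by the non-linear forward model
#' \eqn{\sum_j g_j(c_{p,j}, \lambda)}; each \eqn{g_j} must satisfy
#' \eqn{g_j(0, \lambda) = 0} (no agent, no signal).
#'
#' @inheritParams reconstruction_loss
#' @param alpha non-negative regularisation weight (see
#'   [alpha_heuristic()]).
#' @param spacing grid step (nm) used by the smoothness term.
#' @param wavelengths wavelength vector passed to `response` (required when
#'   `response` is given).
#' @param response optional non-linear response: a function `g(c, lambda)`
#'   for one agent, or a list of such functions, one per agent.
#' @return A `loss_breakdown`: list with `L_rec`, `L_reg`, `L_tot`, `alpha`.
#' @export
total_loss <- function(measured, conc, references, background, alpha,
                       spacing = 1, wavelengths = NULL, response = NULL) {
  if (alpha < 0) stop_invalid("'alpha' must be non-negative")
  refs <- as_reference_matrix(references)
  if (is.null(response)) {
    L_rec <- reconstruction_loss(measured, conc, references, background)
  } else {
    if (is.function(response)) response <- list(response)
    if (length(response) != ncol(refs))
      stop_invalid("'response' needs one function per agent")
    if (is.null(wavelengths))
      stop_invalid("'wavelengths' is required with a non-linear response")
    measured <- as_batch(measured, nrow(refs))
    background <- as_batch(background, nrow(refs))
    conc <- conform_conc(conc, nrow(measured), ncol(refs))
    for (j in seq_along(response)) {
      g0 <- response[[j]](0, wavelengths)
      if (any(abs(g0) > 1e-9))
        stop_invalid("response ", j, " violates g(0, lambda) = 0")
    }
    agent <- matrix(0, nrow(measured), nrow(refs))
    for (i in seq_len(nrow(measured)))
      for (j in seq_along(response))
        agent[i, ] <- agent[i, ] + response[[j]](conc[i, j], wavelengths)
    resid <- measured - agent - background
    L_rec <- sum(resid^2) / nrow(measured)
  }
  L_reg <- smoothness_loss(background, spacing)
  structure(list(L_rec = L_rec, L_reg = L_reg,
                 L_tot = L_rec + alpha * L_reg, alpha = alpha),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("L_rec = %.6g, L_reg = %.6g, alpha = %.6g, L_tot = %.6g\n",
              x$L_rec, x$L_reg, x$alpha, x$L_tot))
  invisible(x)
}

#' Heuristic regularisation weight
#'
#' Balances reconstruction fidelity against background smoothness from the
#' reference spectrum alone:
#' \deqn{\alpha = \frac{1}{\Delta\lambda} \frac{\sum_\lambda I_0}
#'   {\sum_\lambda \left|\partial I_0 / \partial\lambda\right|},}
#' where \eqn{\Delta\lambda = \lambda_{max} - \lambda_{min}} is the grid
#' span and the derivative is taken by forward differences divided by the
#' grid step. The ratio is invariant to rescaling the reference intensity,
#' and decreases when the reference gets sharper (larger derivative sum),
#' i.e. smoothness is enforced more strongly exactly when it discriminates
#' background from agent. For several agents the per-agent values are
#' averaged.
#'
#' @param references L x N matrix of reference spectra, a [spectrum()] or a
#'   numeric vector.
#' @param wavelengths wavelength vector; defaults to the `wavelength`
#'   attribute of `references` or the spectrum's own grid.
#' @param delta reading of \eqn{\Delta\lambda}: `"span"` (the default,
#'   \eqn{\lambda_{max}-\lambda_{min}}) or `"step"` (the grid step). The
#'   formula leaves this genuinely ambiguous; see the methods vignette for
#'   the empirical comparison behind the default.
#' @return Scalar weight \eqn{\alpha}.
#' @examples
#' alpha_heuristic(c(0, 1, 0), c(0, 1, 2))  # 0.25
#' @export
alpha_heuristic <- function(references, wavelengths = NULL,
                            delta = c("span", "step")) {
  delta <- match.arg(delta)
  if (inherits(references, "spectrum")) {
    wavelengths <- references$wavelength
    references <- matrix(references$intensity, ncol = 1)
  }
  if (is.null(wavelengths)) wavelengths <- attr(references, "wavelength")
  if (is.null(wavelengths))
    stop_invalid("'wavelengths' must be supplied")
  refs <- as_reference_matrix(references)
  if (nrow(refs) != length(wavelengths))
    stop_invalid("references and wavelengths differ in length")
  steps <- diff(wavelengths)
  span <- if (delta == "span") max(wavelengths) - min(wavelengths)
          else mean(steps)
  per_class <- apply(refs, 2, function(I0) {
    deriv_sum <- sum(abs(diff(I0) / steps))
    if (deriv_sum == 0)
      stop_degenerate("constant reference spectrum: the heuristic is undefined")
    sum(I0) / deriv_sum / span
  })
  mean(per_class)
}
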
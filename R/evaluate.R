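#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - \sum(t - p)^2 / \sum(t - \bar t)^2} between target and
#' predicted concentrations.
#'
#' @param targets numeric vector of true values (non-constant, length >= 2).
#' @param predictions numeric vector of predictions, same length.
#' @return Scalar \eqn{R^2} (at most 1; can be negative for predictions
#'   worse than the mean).
#' @export
r_squared <- function(targets, predictions) {
  if (length(targets) != length(predictions))
    stop_invalid("'targets' and 'predictions' differ in length")
  if (length(targets) < 2)
    stop_invalid("at least 2 pairs are required")
  ss_tot <- sum((targets - mean(targets))^2)
  if (ss_tot == 0)
    stop_degenerate("constant targets: R-squared is undefined")
  1 - sum((targets - predictions)^2) / ss_tot
}

#' Mean relative prediction error
#'
#' Mean of \eqn{|p - t| / t} over the samples with \eqn{t \ge} `floor`,
#' expressed as a percentage. The floor excludes near-zero targets, where
#' the relative error diverges; report absolute errors for those instead.
#'
#' @param targets,predictions numeric vectors of equal length.
#' @param floor smallest target included (default 0.1, must be positive).
#' @return Mean relative error in percent.
#' @examples
#' mean_relative_error(c(1, 2), c(1.01, 2.02))  # 1
#' @export
mean_relative_error <- function(targets, predictions, floor = 0.1) {
  if (length(targets) != length(predictions))
    stop_invalid("'targets' and 'predictions' differ in length")
  if (floor <= 0) stop_invalid("'floor' must be positive")
  keep <- targets >= floor
  if (!any(keep))
    stop_degenerate("no targets at or above the floor of ", floor)
  100 * mean(abs(predictions[keep] - targets[keep]) / targets[keep])
}

#' Summarise prediction quality
#'
#' Per-agent \eqn{R^2}, mean relative error (targets above `floor`) and mean
#' absolute error (all samples).
#'
#' @param targets n x N matrix (or vector) of true concentrations.
#' @param predictions n x N matrix (or vector) of predicted concentrations,
#'   e.g. `predict(model, ...)$concentrations`.
#' @param floor relative-error floor, see [mean_relative_error()].
#' @return A `pinn_evaluation`: list with per-class vectors `r_squared`,
#'   `mean_relative_error` (percent), `mean_absolute_error`, the sample
#'   count `n`, and the `pairs` (targets, predictions) used.
#' @export
evaluate_predictions <- function(targets, predictions, floor = 0.1) {
  t_m <- if (is.null(dim(targets))) matrix(targets, ncol = 1) else as.matrix(targets)
  p_m <- if (is.null(dim(predictions))) matrix(predictions, ncol = 1) else as.matrix(predictions)
  if (!all(dim(t_m) == dim(p_m)))
    stop_invalid("'targets' and 'predictions' must have matching dimensions")
  structure(list(
    r_squared = vapply(seq_len(ncol(t_m)),
                       function(j) r_squared(t_m[, j], p_m[, j]), numeric(1)),
    mean_relative_error = vapply(seq_len(ncol(t_m)),
                                 function(j) mean_relative_error(t_m[, j], p_m[, j], floor),
                                 numeric(1)),
    mean_absolute_error = vapply(seq_len(ncol(t_m)),
                                 function(j) mean(abs(p_m[, j] - t_m[, j])), numeric(1)),
    n = nrow(t_m),
    floor = floor,
    pairs = list(targets = t_m, predictions = p_m)
  ), class = "pinn_evaluation")
}

#' @export
print.pinn_evaluation <- function(x, ...) {
  cat(sprintf("<pinn_evaluation> %d samples, %d agent(s)\n", x$n,
              length(x$r_squared)))
  for (j in seq_along(x$r_squared))
    cat(sprintf("  agent %d: R^2 = %.4f, mean rel. error (c >= %g) = %.3f%%, mean abs. error = %.4g\n",
                j, x$r_squared[j], x$floor, x$mean_relative_error[j],
                x$mean_absolute_error[j]))
  invisible(x)
}

#' Per-spectrum least-squares baseline
#'
#' The classical alternative to the network for constant backgrounds: each
#' spectrum is regressed on the reference spectra plus (optionally) a
#' constant offset, and the fitted coefficients are the concentrations.
#' For scenarios whose background really is constant per spectrum this is
#' the statistically optimal linear estimator, which makes it a natural
#' yardstick for the network.
#'
#' @param spectra n x L matrix of measured spectra (or a `pinn_dataset`).
#' @param references L x N reference matrix; defaults to the dataset's.
#' @param offset include a constant background term (default `TRUE`).
#' @return n x N matrix of estimated concentrations.
#' @export
lsq_concentrations <- function(spectra, references = NULL, offset = TRUE) {
  if (inherits(spectra, "pinn_dataset")) {
    if (is.null(references)) references <- spectra$references
    spectra <- spectra$spectra
  }
  if (is.null(references)) stop_invalid("'references' is required")
  refs <- as_reference_matrix(references)
  if (is.null(dim(spectra))) spectra <- matrix(spectra, nrow = 1)
  if (ncol(spectra) != nrow(refs))
    stop_invalid("spectra and references are on different grids")
  A <- if (offset) cbind(refs, 1) else refs
  coef <- qr.solve(A, t(spectra))            # (N [+1]) x n
  out <- t(coef[seq_len(ncol(refs)), , drop = FALSE])
  colnames(out) <- colnames(refs)
  out
}

#' Write and read benchmark datasets
#'
#' The on-disk form is plain text: one wide tab-separated table with columns
#' `sample_id`, `c_1..c_N`, then one intensity column per grid point, plus a
#' sidecar `key value` metadata file (`<file>.meta`) recording the scenario,
#' seed, grid and noise level. With `include_components = TRUE` the
#' generating agent/background/noise matrices are written to
#' `<file>.agent`, `<file>.background` and `<file>.noise` in the same wide
#' layout; `include_components = FALSE` is the "measurements only" export.
#'
#' @param x a `pinn_dataset` from [synthesize_dataset()].
#' @param file path of the main table; sidecar files add suffixes.
#' @param include_components also write the stored components.
#' @return `write_dataset()` returns `file` invisibly; `read_dataset()`
#'   returns a `pinn_dataset` (references are rebuilt from the scenario and
#'   grid recorded in the metadata).
#' @export
write_dataset <- function(x, file, include_components = TRUE) {
  stopifnot(inherits(x, "pinn_dataset"))
  N <- ncol(x$concentrations)
  tab <- data.frame(sample_id = seq_len(nrow(x$spectra)))
  for (j in seq_len(N)) tab[[paste0("c_", j)]] <- x$concentrations[, j]
  int <- as.data.frame(x$spectra)
  names(int) <- sprintf("wl_%.6g", x$wavelength)
  write.table(cbind(tab, int), file, sep = "\t", row.names = FALSE,
              quote = FALSE)
  meta <- c(scenario = x$scenario,
            seed = if (is.null(x$seed)) "NA" else format(x$seed),
            n_samples = nrow(x$spectra),
            noise_sd = format(x$noise_sd, digits = 12),
            conc_min = format(x$conc_range[1], digits = 12),
            conc_max = format(x$conc_range[2], digits = 12),
            grid_start = format(min(x$wavelength), digits = 12),
            grid_stop = format(max(x$wavelength), digits = 12),
            grid_points = length(x$wavelength))
  writeLines(paste(names(meta), meta), paste0(file, ".meta"))
  if (include_components && !is.null(x$components)) {
    for (part in names(x$components)) {
      m <- as.data.frame(x$components[[part]])
      names(m) <- names(int)
      write.table(cbind(sample_id = tab$sample_id, m),
                  paste0(file, ".", part), sep = "\t", row.names = FALSE,
                  quote = FALSE)
    }
  }
  invisible(file)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(file) {
  if (!file.exists(file) || !file.exists(paste0(file, ".meta")))
    stop(errorCondition(paste0("dataset files not found at: ", file),
                        class = c("pinncal_not_found", "error")))
  meta_lines <- readLines(paste0(file, ".meta"))
  kv <- do.call(rbind, strsplit(meta_lines, " ", fixed = TRUE))
  meta <- stats::setNames(kv[, 2], kv[, 1])
  grid <- make_wavelength_grid(as.numeric(meta["grid_start"]),
                               as.numeric(meta["grid_stop"]),
                               as.integer(meta["grid_points"]))
  tab <- read.table(file, header = TRUE, sep = "\t", check.names = FALSE)
  conc_cols <- grep("^c_[0-9]+$", names(tab))
  int_cols <- grep("^wl_", names(tab))
  components <- NULL
  parts <- c("agent", "background", "noise")
  have <- file.exists(paste0(file, ".", parts))
  if (all(have)) {
    components <- lapply(parts, function(part) {
      m <- read.table(paste0(file, ".", part), header = TRUE, sep = "\t",
                      check.names = FALSE)
      as.matrix(m[, grep("^wl_", names(m))])
    })
    names(components) <- parts
  }
  structure(list(
    wavelength = grid$values,
    spectra = as.matrix(tab[, int_cols]),
    concentrations = as.matrix(tab[, conc_cols, drop = FALSE]),
    references = scenario_references(meta[["scenario"]], grid),
    components = components,
    eps = NULL,
    scenario = meta[["scenario"]],
    seed = if (identical(meta[["seed"]], "NA")) NULL else as.integer(meta[["seed"]]),
    noise_sd = as.numeric(meta["noise_sd"]),
    conc_range = c(as.numeric(meta["conc_min"]), as.numeric(meta["conc_max"]))
  ), class = "pinn_dataset")
}
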
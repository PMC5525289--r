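#' Mean residue ellipticity
#'
#' Converts a raw circular-dichroism ellipticity reading into mean residue
#' ellipticity, `MRE = theta * 100 / (c * d * AA)`, the per-residue CD
#' signal in deg cm^2 dmol^-1. Units follow the CD convention used for
#' protein far-UV spectra: `theta` in degrees, `c` in dmol/mL, `d` (cuvette
#' path length) in cm, `AA` the number of amino-acid residues.
#'
#' @param theta Measured ellipticity in degrees. May be a vector (a spectrum).
#' @param c Protein concentration in dmol per mL. Must be positive.
#' @param d Cuvette path length in cm. Must be positive.
#' @param AA Number of amino-acid residues in the protein. Must be positive.
#' @return Mean residue ellipticity, same length as `theta`.
#' @examples
#' mean_residue_ellipticity(1, c = 1, d = 1, AA = 100)
#' @export
mean_residue_ellipticity <- function(theta, c, d, AA) {
  if (!is.numeric(theta)) stop("'theta' must be numeric")
  for (nm in c("c", "d", "AA")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single positive number", nm))
  }
  theta * 100 / (c * d * AA)
}

#' Fit a linear standard curve
#'
#' Ordinary least-squares fit of `signal = slope * concentration + intercept`
#' for assay quantification (e.g. Ellman thiol assays calibrated with
#' cysteine standards, or silicomolybdate silica assays calibrated with
#' silicate standards). Unknowns are then quantified by inverting the line
#' with [quantify()].
#'
#' @param concentration Numeric vector of standard concentrations
#'   (at least two distinct values).
#' @param signal Numeric vector of measured signals, same length.
#' @return An object of class `standard_curve` with elements `slope`,
#'   `intercept`, `residual_sd`, `r_squared` and the standard `points`.
#' @seealso [quantify()]
#' @examples
#' sc <- fit_standard_curve(c(0, 50, 100), c(0, 0.5, 1.0))
#' quantify(sc, 0.52)
#' @export
fit_standard_curve <- function(concentration, signal) {
  if (length(concentration) != length(signal))
    stop("'concentration' and 'signal' must have the same length")
  if (length(unique(concentration)) < 2L)
    stop("need at least two distinct standard concentrations")
  fit <- stats::lm(signal ~ concentration)
  cf <- stats::coef(fit)
  slope <- unname(cf["concentration"])
  if (!is.finite(slope) || slope == 0)
    stop("singular standard-curve fit: slope is zero")
  res <- stats::residuals(fit)
  n <- length(res)
  structure(
    list(
      slope = slope,
      intercept = unname(cf["(Intercept)"]),
      residual_sd = if (n > 2L) sqrt(sum(res^2) / (n - 2L)) else 0,
      r_squared = if (stats::var(signal) > 0)
        1 - sum(res^2) / sum((signal - mean(signal))^2) else 1,
      points = data.frame(concentration = concentration, signal = signal)
    ),
    class = "standard_curve"
  )
}

#' Quantify a sample against a standard curve
#'
#' Inverts a fitted standard curve: `concentration = (signal - intercept) / slope`.
#'
#' @param curve A `standard_curve` from [fit_standard_curve()].
#' @param signal Measured signal(s) of the unknown sample(s).
#' @return Estimated concentration(s), in the units of the standards.
#' @export
quantify <- function(curve, signal) {
  if (!inherits(curve, "standard_curve"))
    stop("'curve' must be a standard_curve object")
  (signal - curve$intercept) / curve$slope
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("Linear standard curve: signal =",
      format(x$slope, digits = 6), "* conc +",
      format(x$intercept, digits = 6), "\n")
  cat(sprintf("  %d standards, residual SD %.4g, R^2 %.4f\n",
              nrow(x$points), x$residual_sd, x$r_squared))
  invisible(x)
}

#' Silica-formation synergy folds
#'
#' Fold enhancements of silica formation by a protein--polyamine mixture
#' over its single components and over a polyamine--phosphate reference:
#' `mix/protein`, `mix/lcpa` and `mix/lcpa_phosphate`. Uncertainties, when
#' supplied, are propagated by the first-order ratio rule
#' `sd(a/b) = (a/b) * sqrt((sd_a/a)^2 + (sd_b/b)^2)`.
#'
#' @param yields Named numeric vector with elements `protein`, `lcpa`,
#'   `mix` and `lcpa_phosphate`: silica yields (e.g. nmol SiO2). All
#'   denominators must be positive.
#' @param sds Optional named numeric vector of the same names with
#'   measurement standard deviations.
#' @return A data frame with columns `comparison`, `fold` and (if `sds`
#'   given) `fold_sd`.
#' @examples
#' synergy_folds(c(protein = 20, lcpa = 15, mix = 104, lcpa_phosphate = 50))
#' @export
synergy_folds <- function(yields, sds = NULL) {
  need <- c("protein", "lcpa", "mix", "lcpa_phosphate")
  if (!all(need %in% names(yields)))
    stop("'yields' must be named with: ", paste(need, collapse = ", "))
  yields <- yields[need]
  if (any(!is.finite(yields)) || any(yields < 0))
    stop("yields must be finite and non-negative")
  denom <- c("protein", "lcpa", "lcpa_phosphate")
  if (any(yields[denom] == 0)) stop("zero denominator yield")
  folds <- unname(yields["mix"] / yields[denom])
  out <- data.frame(
    comparison = paste0("mix/", denom),
    fold = folds,
    stringsAsFactors = FALSE
  )
  if (!is.null(sds)) {
    if (!all(need %in% names(sds)))
      stop("'sds' must be named with: ", paste(need, collapse = ", "))
    rel <- function(a) sds[a] / yields[a]
    out$fold_sd <- signif(
      folds * sqrt(rel("mix")^2 + unname(rel(denom))^2), 2)
  }
  out
}
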
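#' Fit a linear standard curve
#'
#' Ordinary least-squares fit of signal (absorbance) against concentration,
#' as used for maltose quantification in the alpha-amylase assay and for
#' NaNO2 in the Griess assay.  Replicate signals at the same concentration
#' are averaged before fitting.
#'
#' @param concentration Numeric vector of standard concentrations.
#' @param signal Numeric vector of measured signals, same length.
#' @param unit Concentration unit label (e.g. `"mg maltose"` or
#'   `"uM NaNO2"`).
#' @return An object of class `standard_curve` with elements `slope`,
#'   `intercept`, `unit`, `fit_range` and the underlying `lm` fit.
#' @examples
#' std <- fit_standard_curve(c(0, 1, 2), c(0.1, 2.1, 4.1))
#' std$slope
#' @export
fit_standard_curve <- function(concentration, signal, unit = "mg maltose") {
  stopifnot(length(concentration) == length(signal),
            length(concentration) >= 2)
  mean_sig <- tapply(signal, concentration, mean)
  conc <- as.numeric(names(mean_sig))
  if (length(conc) < 2) {
    stop("standard curve needs at least two distinct concentrations")
  }
  fit <- stats::lm(y ~ x, data = data.frame(x = conc, y = as.vector(mean_sig)))
  slope <- unname(stats::coef(fit)[2])
  if (slope == 0) stop("degenerate standard curve: zero slope")
  structure(
    list(slope = slope,
         intercept = unname(stats::coef(fit)[1]),
         unit = unit,
         fit_range = range(conc),
         fit = fit),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve> signal = %.6g * conc + %.6g  (%s, range %g-%g)\n",
              x$slope, x$intercept, x$unit, x$fit_range[1], x$fit_range[2]))
  invisible(x)
}

#' Evaluate a standard curve at given concentrations
#'
#' @param curve A `standard_curve`.
#' @param concentration Numeric vector.
#' @return Predicted signal.
#' @export
evaluate_curve <- function(curve, concentration) {
  stopifnot(inherits(curve, "standard_curve"))
  curve$intercept + curve$slope * concentration
}

#' Invert a standard curve
#'
#' Converts measured signals back into concentrations.  Inversion is the
#' exact inverse of [evaluate_curve()] inside the fitted range; values
#' falling outside the range are still returned but flagged via the
#' `extrapolated` attribute.
#'
#' @param curve A `standard_curve`.
#' @param signal Numeric vector of measured signals.
#' @return Numeric vector of concentrations with a logical attribute
#'   `extrapolated` marking out-of-range results.
#' @export
invert_curve <- function(curve, signal) {
  stopifnot(inherits(curve, "standard_curve"))
  conc <- (signal - curve$intercept) / curve$slope
  attr(conc, "extrapolated") <-
    conc < curve$fit_range[1] | conc > curve$fit_range[2]
  conc
}

#' Percent alpha-amylase inhibition
#'
#' Computes `100 - 100 * (maltose_sample - maltose_blank) /
#' maltose_negative_control`: the blank-corrected maltose released in the
#' presence of the sample, as a percentage of the uninhibited negative
#' control, subtracted from 100.  A sample releasing no maltose beyond its
#' blank scores 100% inhibition; a sample releasing as much as the control
#' scores 0%.  Values may be negative (activation) or exceed 100.
#'
#' @param maltose_sample Maltose equivalents (mg) released with sample.
#' @param maltose_blank Maltose equivalents (mg) of the sample blank.
#' @param maltose_negative_control Maltose equivalents (mg) of the
#'   uninhibited control; must be positive.
#' @return Percent inhibition (full precision; report to 1 decimal).
#' @examples
#' inhibition_percent(0.5, 0.1, 0.8)
#' @export
inhibition_percent <- function(maltose_sample, maltose_blank,
                               maltose_negative_control) {
  if (any(maltose_negative_control <= 0)) {
    stop("maltose_negative_control must be positive")
  }
  100 - (maltose_sample - maltose_blank) * 100 / maltose_negative_control
}

#' Nitrite concentration from a Griess reading
#'
#' Inverse-evaluates the NaNO2 standard curve at the measured absorbance.
#' Readings that invert outside the fitted concentration range (for the
#' study's curve, 3.125-100 uM) are flagged as extrapolated.
#'
#' @param signal Absorbance reading(s).
#' @param curve A `standard_curve` fitted on NaNO2 standards.
#' @return Concentration(s) in the curve's unit, with the `extrapolated`
#'   attribute of [invert_curve()].
#' @export
nitrite_concentration <- function(signal, curve) {
  invert_curve(curve, signal)
}

#' Compute an inhibition report from a plate table
#'
#' Input is a long-format plate table with columns `well`, `role`
#' (`standard`, `sample`, `blank`, `negative_control`), `concentration`
#' (standards only; samples may carry a dose label here) and `absorbance`.
#' Standards are fitted into a maltose curve, all other absorbances are
#' converted to maltose equivalents, replicate readings are averaged per
#' role/concentration, and percent inhibition is computed per sample dose
#' against the mean blank and mean negative control.
#'
#' @param plate Data frame as described above (e.g. from
#'   [utils::read.delim()]).
#' @return Data frame with one row per sample dose: `concentration`,
#'   `maltose_mg` and `inhibition_pct` (rounded to 1 decimal).
#' @export
amylase_inhibition_report <- function(plate) {
  need <- c("role", "concentration", "absorbance")
  if (!all(need %in% names(plate))) {
    stop("plate table must have columns: ", paste(need, collapse = ", "))
  }
  std <- plate[plate$role == "standard", ]
  if (nrow(std) < 2) stop("plate table needs at least two standard wells")
  curve <- fit_standard_curve(std$concentration, std$absorbance)
  to_mg <- function(a) as.numeric(invert_curve(curve, a))
  blank <- mean(to_mg(plate$absorbance[plate$role == "blank"]))
  ctrl <- mean(to_mg(plate$absorbance[plate$role == "negative_control"]))
  samples <- plate[plate$role == "sample", ]
  if (nrow(samples) == 0) stop("plate table contains no sample wells")
  mg <- tapply(to_mg(samples$absorbance), samples$concentration, mean)
  data.frame(
    concentration = as.numeric(names(mg)),
    maltose_mg = as.vector(mg),
    inhibition_pct = round(inhibition_percent(as.vector(mg), blank, ctrl), 1),
    row.names = NULL
  )
}
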
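## Digital single-molecule immunoassay measurement model.
##
## In the digital regime each counted microwell holds at most one bead, and
## the number of labelled immunocomplexes on a bead is Poisson distributed.
## A well is "on" when its bead carries at least one complex, so the expected
## on-fraction at per-bead mean load lambda is 1 - exp(-lambda). Measurement
## therefore reduces to counting on-wells and inverting that occupancy map.

#' Poisson occupancy correction: AEB from the fraction of "on" wells
#'
#' Computes the average number of enzymes (labelled immunocomplexes) per bead
#' from the observed fraction of fluorescent wells, assuming a Poisson load
#' per bead: \code{aeb = -log(1 - fOn)}. This is the exact inverse of the
#' occupancy map \code{fOn = 1 - exp(-aeb)}.
#'
#' @param fOn Fraction of "on" wells, in \code{[0, 1)}. Vectorised.
#' @return Non-negative AEB value(s); strictly increasing in \code{fOn} and
#'   0 exactly at \code{fOn = 0}.
#' @examples
#' aebFromFractionOn(0)            # 0
#' aebFromFractionOn(1 - exp(-1))  # 1
#' aebFromFractionOn(0.1)          # -log(0.9)
#' @export
aebFromFractionOn <- function(fOn) {
  if (!is.numeric(fOn) || any(!is.finite(fOn)))
    evDomainError("fOn must be finite numeric")
  if (any(fOn < 0))
    evDomainError("fOn must be >= 0")
  if (any(fOn >= 1))
    evDomainError("fOn >= 1: array saturated, AEB undefined")
  -log1p(-fOn)
}

#' @rdname aebFromFractionOn
#' @param aeb Mean enzymes per bead (>= 0). Vectorised.
#' @return \code{fractionOnFromAeb} returns the expected "on" fraction
#'   \code{1 - exp(-aeb)}.
#' @export
fractionOnFromAeb <- function(aeb) {
  if (any(aeb < 0)) evDomainError("aeb must be >= 0")
  -expm1(-aeb)
}

#' Simulate a digital well-array readout
#'
#' Given a true sample concentration, the per-bead Poisson mean is
#' \code{lambda = captureEfficiency * trueConc / dilutionFactor +
#' backgroundAeb}; each counted well is "on" independently with probability
#' \code{1 - exp(-lambda)}, and the number of on-wells is binomial over the
#' loaded wells. Deterministic given \code{seed}.
#'
#' @param trueConc True (neat-sample) analyte concentration in pM, >= 0.
#' @param params A \code{\link{BeadAssayParams}} object.
#' @param seed Integer RNG seed.
#' @return A \code{\link{WellArrayReading-class}} object.
#' @export
simulateDigitalReadout <- function(trueConc, params, seed) {
  stopifnot(is(params, "BeadAssayParams"))
  if (!isScalarNumber(trueConc) || trueConc < 0)
    evDomainError("trueConc must be a non-negative number")
  lambda <- params@captureEfficiency * trueConc / params@dilutionFactor +
    params@backgroundAeb
  pOn <- -expm1(-lambda)
  nOn <- withSeed(seed, stats::rbinom(1L, size = as.integer(params@nWellsLoaded),
                                      prob = pOn))
  WellArrayReading(nOn = nOn, nTotal = params@nWellsLoaded)
}

#' Fit a four-parameter logistic calibration curve
#'
#' Fits mean AEB against standard concentration with the monotone Hill-type
#' four-parameter logistic \code{aeb(c) = lower + (upper - lower) * c^s /
#' (c^s + midpoint^s)} using Levenberg-Marquardt least squares. Standards must
#' include a blank (zero concentration) and at least four distinct
#' concentrations. Fits that are non-monotone (non-positive slope or
#' collapsed asymptotes) are refused.
#'
#' @param standards A data.frame with columns \code{marker},
#'   \code{concentration_pM} and \code{aeb} (one row per replicate reading),
#'   containing a single marker.
#' @return A \code{\link{CalibrationCurve-class}} object.
#' @seealso \code{\link{concentrationFromReading}},
#'   \code{\link{fitCalibrationCurves}} for multi-marker tables.
#' @export
fitCalibration <- function(standards) {
  req <- c("marker", "concentration_pM", "aeb")
  if (!is.data.frame(standards) || !all(req %in% names(standards)))
    evConfigError("standards must have columns marker, concentration_pM, aeb")
  mk <- unique(standards$marker)
  if (length(mk) != 1L)
    evConfigError("fitCalibration expects a single marker; use fitCalibrationCurves")
  conc <- standards$concentration_pM
  if (any(conc < 0)) evConfigError("standard concentrations must be >= 0")
  if (any(!is.finite(standards$aeb)))
    evConfigError(sprintf(
      "marker %s: non-finite AEB in standards (saturated array?)", mk))
  if (!any(conc == 0))
    evConfigError(sprintf("marker %s: calibration requires a blank standard", mk))
  if (length(unique(conc)) < 4L)
    evConfigError(sprintf("marker %s: need >= 4 distinct standard concentrations", mk))

  agg <- stats::aggregate(aeb ~ concentration_pM, data = standards, FUN = mean)
  x <- agg$concentration_pM
  y <- agg$aeb
  if (max(y) - min(y) <= .Machine$double.eps * max(1, max(abs(y))))
    evFitError(sprintf("marker %s: degenerate standards (no response variation)", mk))

  lower0 <- min(y)
  upper0 <- max(y) * 1.05 + 1e-9
  pos <- x[x > 0]
  half <- lower0 + (max(y) - lower0) / 2
  mid0 <- pos[which.min(abs(y[x > 0] - half))]
  start <- list(lower = lower0, upper = upper0, midpoint = mid0, slope = 1)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ lower + (upper - lower) * ifelse(x > 0, x^slope / (x^slope + midpoint^slope), 0),
      start = start,
      lower = c(lower = 0, upper = 1e-12, midpoint = min(pos) / 100, slope = 0.05),
      upper = c(lower = max(y), upper = max(y) * 100 + 1, midpoint = max(pos) * 100,
                slope = 20),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)
    ),
    error = function(e) evFitError(sprintf(
      "marker %s: calibration fit did not converge (%s)", mk, conditionMessage(e)))
  )
  cf <- stats::coef(fit)
  if (cf[["upper"]] <= cf[["lower"]] || cf[["slope"]] <= 0)
    evFitError(sprintf("marker %s: fitted curve is not monotone increasing", mk))

  new("CalibrationCurve", marker = mk,
      lower = unname(cf[["lower"]]), upper = unname(cf[["upper"]]),
      midpoint = unname(cf[["midpoint"]]), slope = unname(cf[["slope"]]),
      validRange = range(pos),
      fitResidual = sqrt(mean(stats::resid(fit)^2)))
}

#' @rdname fitCalibration
#' @return \code{fitCalibrationCurves} returns a named list of curves, one
#'   per marker present in the table.
#' @export
fitCalibrationCurves <- function(standards) {
  mks <- unique(standards$marker)
  stats::setNames(lapply(mks, function(m)
    fitCalibration(standards[standards$marker == m, , drop = FALSE])), mks)
}

#' Predict AEB from concentration under a calibration curve
#'
#' @param curve A \code{\link{CalibrationCurve-class}} object.
#' @param conc Concentration(s) in pM at assay scale.
#' @return Predicted AEB value(s).
#' @export
predictAeb <- function(curve, conc) {
  stopifnot(is(curve, "CalibrationCurve"))
  ifelse(conc > 0,
         curve@lower + (curve@upper - curve@lower) *
           conc^curve@slope / (conc^curve@slope + curve@midpoint^curve@slope),
         curve@lower)
}

## Inverse of the 4PL on the open interval (lower, upper).
invertCalibration <- function(curve, aebValue) {
  curve@midpoint *
    ((aebValue - curve@lower) / (curve@upper - aebValue))^(1 / curve@slope)
}

#' Back-calculate concentration from a well-array reading
#'
#' Inverts the calibration curve at the reading's AEB and multiplies by the
#' dilution factor, reporting a neat-sample-equivalent concentration.
#' Readings outside the curve are clamped, never extrapolated: AEB at or
#' below the lower asymptote gives 0 pM with a \code{blank_level} flag; AEB
#' at or above the upper asymptote (including saturated arrays) is clamped to
#' the top of the valid range with an \code{above_curve} flag; inverted
#' concentrations outside the standard range are clamped to the range
#' boundary and flagged \code{below_curve} / \code{above_curve}.
#'
#' @param reading A \code{\link{WellArrayReading-class}} object.
#' @param curve A \code{\link{CalibrationCurve-class}} object.
#' @param dilutionFactor Fold dilution applied before measurement.
#' @return A \code{\link{ConcentrationEstimate-class}} object (cv = 0; see
#'   \code{\link{averageTechnicalReplicates}}).
#' @export
concentrationFromReading <- function(reading, curve, dilutionFactor = 1) {
  stopifnot(is(reading, "WellArrayReading"), is(curve, "CalibrationCurve"))
  if (dilutionFactor < 1) evDomainError("dilutionFactor must be >= 1")
  a <- reading@aeb
  flags <- character()
  if (a <= curve@lower) {
    value <- 0
    flags <- "blank_level"
  } else if (a >= curve@upper) {
    value <- curve@validRange[2]
    flags <- "above_curve"
  } else {
    value <- invertCalibration(curve, a)
    if (value < curve@validRange[1]) {
      value <- curve@validRange[1]
      flags <- "below_curve"
    } else if (value > curve@validRange[2]) {
      value <- curve@validRange[2]
      flags <- "above_curve"
    }
  }
  ConcentrationEstimate(marker = curve@marker,
                        valuePM = value * dilutionFactor, flags = flags)
}

#' Average technical replicates of a concentration estimate
#'
#' Arithmetic mean of the replicate values with the replicate coefficient of
#' variation (sample sd / mean; 0 for a single replicate or zero mean).
#' Flags are pooled across replicates.
#'
#' @param estimates A list of \code{\link{ConcentrationEstimate-class}}
#'   objects for the same marker.
#' @return A single \code{\link{ConcentrationEstimate-class}}.
#' @export
averageTechnicalReplicates <- function(estimates) {
  if (!length(estimates)) evConfigError("need at least one estimate")
  mks <- unique(vapply(estimates, function(e) e@marker, ""))
  if (length(mks) != 1L)
    evConfigError(sprintf("cannot average mixed markers: %s",
                          paste(mks, collapse = ", ")))
  vals <- vapply(estimates, function(e) e@valuePM, 0)
  m <- mean(vals)
  cv <- if (length(vals) >= 2L && m > 0) stats::sd(vals) / m else 0
  ConcentrationEstimate(
    marker = mks, valuePM = m, cv = cv,
    flags = unique(unlist(lapply(estimates, function(e) e@flags)))
  )
}
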
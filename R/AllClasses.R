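## S4 class definitions for the assay, chromatography, and comparison layers.

## ---------------------------------------------------------------------------
## Digital immunoassay
## ---------------------------------------------------------------------------

#' Digital bead-assay parameters
#'
#' Parameters of the single-molecule bead-array measurement model: beads are
#' incubated with sample, immunocomplexes form on beads at a rate proportional
#' to analyte concentration, and a subset of beads is loaded into femtoliter
#' wells (at most one bead per well) and read out as fluorescent "on" wells.
#'
#' @slot nBeads Number of beads incubated per technical replicate.
#' @slot nWellsLoaded Number of beads counted in the well array
#'   (\code{<= nBeads}).
#' @slot captureEfficiency Expected captured immunocomplexes per bead per pM
#'   of analyte at the assay (post-dilution) concentration, in 1/pM.
#' @slot backgroundAeb Mean enzymes per bead at zero analyte (non-specific
#'   binding), entering additively on the per-bead Poisson mean.
#' @slot dilutionFactor Fold dilution applied to the sample before
#'   measurement (4x for tetraspanins, 20x for albumin by default in the
#'   presets).
#'
#' @export
setClass("BeadAssayParams",
  representation(
    nBeads = "numeric",
    nWellsLoaded = "numeric",
    captureEfficiency = "numeric",
    backgroundAeb = "numeric",
    dilutionFactor = "numeric"
  )
)

setValidity("BeadAssayParams", function(object) {
  msg <- character()
  if (!isScalarNumber(object@nBeads) || object@nBeads < 1 ||
      object@nBeads != round(object@nBeads))
    msg <- c(msg, "nBeads must be a positive integer")
  if (!isScalarNumber(object@nWellsLoaded) || object@nWellsLoaded < 1 ||
      object@nWellsLoaded != round(object@nWellsLoaded))
    msg <- c(msg, "nWellsLoaded must be a positive integer")
  if (isScalarNumber(object@nBeads) && isScalarNumber(object@nWellsLoaded) &&
      object@nWellsLoaded > object@nBeads)
    msg <- c(msg, "nWellsLoaded must not exceed nBeads")
  if (!isScalarNumber(object@captureEfficiency) ||
      object@captureEfficiency <= 0)
    msg <- c(msg, "captureEfficiency must be > 0")
  if (!isScalarNumber(object@backgroundAeb) || object@backgroundAeb < 0)
    msg <- c(msg, "backgroundAeb must be >= 0")
  if (!isScalarNumber(object@dilutionFactor) || object@dilutionFactor < 1)
    msg <- c(msg, "dilutionFactor must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @param nBeads,nWellsLoaded,captureEfficiency,backgroundAeb,dilutionFactor
#'   See slot descriptions.
#' @return \code{BeadAssayParams()} returns a validated
#'   \code{BeadAssayParams} object.
#' @rdname BeadAssayParams-class
#' @export
BeadAssayParams <- function(nBeads = 500000, nWellsLoaded = 50000,
                            captureEfficiency = 0.1, backgroundAeb = 0.01,
                            dilutionFactor = 1) {
  new("BeadAssayParams", nBeads = nBeads, nWellsLoaded = nWellsLoaded,
      captureEfficiency = captureEfficiency, backgroundAeb = backgroundAeb,
      dilutionFactor = dilutionFactor)
}

#' Single well-array reading
#'
#' The outcome of counting one bead array: the number of fluorescent "on"
#' wells among all counted bead-bearing wells, the occupied fraction, and the
#' Poisson-corrected average enzymes per bead (AEB). Readings with an "on"
#' fraction of 0.7 or more are flagged saturated: the digital counting regime
#' no longer holds there and values should not be trusted quantitatively.
#'
#' @slot nOn Number of "on" wells.
#' @slot nTotal Number of bead-bearing wells counted.
#' @slot fractionOn \code{nOn / nTotal}.
#' @slot aeb Poisson-corrected mean enzymes per bead; \code{Inf} when every
#'   well is on.
#' @slot saturated Logical saturation flag (\code{fractionOn >= 0.7}).
#'
#' @export
setClass("WellArrayReading",
  representation(
    nOn = "numeric",
    nTotal = "numeric",
    fractionOn = "numeric",
    aeb = "numeric",
    saturated = "logical"
  )
)

setValidity("WellArrayReading", function(object) {
  msg <- character()
  if (object@nOn < 0 || object@nOn != round(object@nOn))
    msg <- c(msg, "nOn must be a non-negative integer")
  if (object@nTotal < 1 || object@nTotal != round(object@nTotal))
    msg <- c(msg, "nTotal must be a positive integer")
  if (object@nOn > object@nTotal)
    msg <- c(msg, "nOn must not exceed nTotal")
  if (abs(object@fractionOn - object@nOn / object@nTotal) > 1e-12)
    msg <- c(msg, "fractionOn must equal nOn / nTotal")
  if ((object@aeb == 0) != (object@nOn == 0))
    msg <- c(msg, "aeb must be zero exactly when nOn is zero")
  if (length(msg)) msg else TRUE
})

WellArrayReading <- function(nOn, nTotal) {
  fOn <- nOn / nTotal
  aeb <- if (nOn == nTotal) Inf else -log1p(-fOn)
  new("WellArrayReading", nOn = as.numeric(nOn), nTotal = as.numeric(nTotal),
      fractionOn = fOn, aeb = aeb, saturated = fOn >= 0.7)
}

#' Four-parameter logistic calibration curve
#'
#' Fitted sigmoid response of AEB against analyte concentration for one
#' marker: \code{aeb(c) = lower + (upper - lower) * c^slope /
#' (c^slope + midpoint^slope)}. The curve is strictly increasing for
#' \code{slope > 0} and \code{upper > lower}; inversion is defined only for
#' AEB strictly between the asymptotes.
#'
#' @slot marker Marker identifier.
#' @slot lower,upper Lower/upper AEB asymptotes.
#' @slot midpoint Concentration (pM) of half-maximal response.
#' @slot slope Hill slope (dimensionless, > 0).
#' @slot validRange Concentration range (pM) spanned by the non-blank
#'   standards; estimates outside it are clamped and flagged.
#' @slot fitResidual Root-mean-square residual of the fit on the AEB scale.
#'
#' @export
setClass("CalibrationCurve",
  representation(
    marker = "character",
    lower = "numeric",
    upper = "numeric",
    midpoint = "numeric",
    slope = "numeric",
    validRange = "numeric",
    fitResidual = "numeric"
  )
)

setValidity("CalibrationCurve", function(object) {
  msg <- character()
  if (object@upper <= object@lower)
    msg <- c(msg, "upper asymptote must exceed lower asymptote")
  if (object@slope <= 0)
    msg <- c(msg, "slope must be > 0 (monotone increasing response)")
  if (object@midpoint <= 0)
    msg <- c(msg, "midpoint must be > 0")
  if (length(object@validRange) != 2L ||
      object@validRange[1] < 0 || diff(object@validRange) <= 0)
    msg <- c(msg, "validRange must be an increasing pair of concentrations")
  if (object@fitResidual < 0)
    msg <- c(msg, "fitResidual must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Concentration estimate for one marker
#'
#' @slot marker Marker identifier.
#' @slot valuePM Estimated concentration in pM (dilution-corrected, i.e.
#'   neat-sample equivalent).
#' @slot cv Coefficient of variation across technical replicates (0 when a
#'   single replicate).
#' @slot flags Character vector drawn from \code{"below_curve"},
#'   \code{"above_curve"}, \code{"blank_level"}.
#'
#' @export
setClass("ConcentrationEstimate",
  representation(
    marker = "character",
    valuePM = "numeric",
    cv = "numeric",
    flags = "character"
  )
)

setValidity("ConcentrationEstimate", function(object) {
  msg <- character()
  if (object@valuePM < 0) msg <- c(msg, "valuePM must be >= 0")
  if (object@cv < 0) msg <- c(msg, "cv must be >= 0")
  bad <- setdiff(object@flags, c("below_curve", "above_curve", "blank_level"))
  if (length(bad)) msg <- c(msg, paste("unknown flags:", paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

ConcentrationEstimate <- function(marker, valuePM, cv = 0,
                                  flags = character()) {
  new("ConcentrationEstimate", marker = marker, valuePM = valuePM, cv = cv,
      flags = flags)
}

## ---------------------------------------------------------------------------
## Size-exclusion chromatography
## ---------------------------------------------------------------------------

#' Size-exclusion resin
#'
#' @slot name Resin identifier (e.g. \code{"CL-2B"}).
#' @slot poreRadiusNm Effective pore radius in nm. Published Sepharose pore
#'   sizes (24 nm for CL-6B, 42 nm for CL-4B, 75 nm for CL-2B) are treated as
#'   diameters, so the presets use half those values.
#' @slot porosity Fraction of the bed volume internal to the beads
#'   (solvent-accessible pore volume).
#'
#' @export
setClass("Resin",
  representation(name = "character", poreRadiusNm = "numeric",
                 porosity = "numeric")
)

setValidity("Resin", function(object) {
  msg <- character()
  if (object@poreRadiusNm <= 0) msg <- c(msg, "poreRadiusNm must be > 0")
  if (object@porosity <= 0 || object@porosity >= 1)
    msg <- c(msg, "porosity must be in (0,1)")
  if (length(msg)) msg else TRUE
})

#' @param name,poreRadiusNm,porosity See slot descriptions.
#' @rdname Resin-class
#' @export
Resin <- function(name, poreRadiusNm, porosity = 0.60) {
  new("Resin", name = name, poreRadiusNm = poreRadiusNm, porosity = porosity)
}

#' Gravity SEC column and its fraction-collection convention
#'
#' Fractions are numbered 1-based from the moment the sample is loaded;
#' fraction \code{k} covers eluate volume \code{((k-1)*fv, k*fv]} ml where
#' \code{fv} is the fraction volume (0.5 ml by convention).
#'
#' @slot resin A \code{\link{Resin}}.
#' @slot bedVolumeMl Settled bed volume in ml (10 or 20 typical).
#' @slot voidFraction Void (inter-bead) volume as a fraction of bed volume.
#' @slot fractionVolumeMl Collected fraction volume in ml.
#' @slot firstFraction,lastFraction Collected fraction window (6-21 for 10 ml
#'   columns, 12-27 for 20 ml columns in the presets).
#'
#' @export
setClass("SECColumn",
  representation(
    resin = "Resin",
    bedVolumeMl = "numeric",
    voidFraction = "numeric",
    fractionVolumeMl = "numeric",
    firstFraction = "integer",
    lastFraction = "integer"
  )
)

setValidity("SECColumn", function(object) {
  msg <- character()
  if (object@bedVolumeMl <= 0) msg <- c(msg, "bedVolumeMl must be > 0")
  if (object@voidFraction <= 0 || object@voidFraction >= 1)
    msg <- c(msg, "voidFraction must be in (0,1)")
  if (object@voidFraction + object@resin@porosity > 1)
    msg <- c(msg, "void + internal volume must not exceed the bed volume")
  if (object@fractionVolumeMl <= 0)
    msg <- c(msg, "fractionVolumeMl must be > 0")
  if (object@firstFraction < 1L || object@lastFraction < object@firstFraction)
    msg <- c(msg, "need 1 <= firstFraction <= lastFraction")
  if (length(msg)) msg else TRUE
})

#' @param resin,bedVolumeMl,voidFraction,fractionVolumeMl,firstFraction,lastFraction
#'   See slot descriptions. The default collected window follows the 0.5 ml
#'   convention: 6-21 for beds up to 10 ml, 12-27 for larger beds.
#' @rdname SECColumn-class
#' @export
SECColumn <- function(resin, bedVolumeMl, voidFraction = 0.30,
                      fractionVolumeMl = 0.5,
                      firstFraction = if (bedVolumeMl <= 10) 6L else 12L,
                      lastFraction = if (bedVolumeMl <= 10) 21L else 27L) {
  new("SECColumn", resin = resin, bedVolumeMl = bedVolumeMl,
      voidFraction = voidFraction, fractionVolumeMl = fractionVolumeMl,
      firstFraction = as.integer(firstFraction),
      lastFraction = as.integer(lastFraction))
}

#' Chromatographed species
#'
#' A species is either monodisperse (\code{geomSd = 1}) or log-normally
#' distributed over hydrodynamic radius (median \code{medianRadiusNm},
#' geometric standard deviation \code{geomSd}).
#'
#' @slot name Species identifier (\code{"EV"} or a protein name).
#' @slot medianRadiusNm Median hydrodynamic radius in nm.
#' @slot geomSd Geometric standard deviation of the radius distribution
#'   (1 for a fixed radius).
#' @slot inputAmountFmol Loaded amount in fmol (for EV markers: fmol of the
#'   marker protein). fmol per ml equals pM, so fraction concentrations derive
#'   directly from amounts.
#'
#' @export
setClass("Species",
  representation(name = "character", medianRadiusNm = "numeric",
                 geomSd = "numeric", inputAmountFmol = "numeric")
)

setValidity("Species", function(object) {
  msg <- character()
  if (object@medianRadiusNm <= 0) msg <- c(msg, "medianRadiusNm must be > 0")
  if (object@geomSd < 1) msg <- c(msg, "geomSd must be >= 1")
  if (object@inputAmountFmol < 0) msg <- c(msg, "inputAmountFmol must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param name,medianRadiusNm,geomSd,inputAmountFmol See slot descriptions.
#' @rdname Species-class
#' @export
Species <- function(name, medianRadiusNm, geomSd = 1,
                    inputAmountFmol = 1) {
  new("Species", name = name, medianRadiusNm = medianRadiusNm,
      geomSd = geomSd, inputAmountFmol = inputAmountFmol)
}

#' Elution profile on a volume grid
#'
#' Recovered mass distribution over eluate volume, stored as a piecewise
#' constant density on uniform cells so that binning into fractions conserves
#' mass exactly.
#'
#' @slot species Species identifier.
#' @slot volumes Cell midpoints (ml), uniform grid.
#' @slot density Mass density (fmol/ml) per cell.
#' @slot step Grid step (ml).
#'
#' @export
setClass("ElutionProfile",
  representation(species = "character", volumes = "numeric",
                 density = "numeric", step = "numeric")
)

setValidity("ElutionProfile", function(object) {
  msg <- character()
  if (length(object@volumes) != length(object@density))
    msg <- c(msg, "volumes and density must have equal length")
  if (any(object@density < 0)) msg <- c(msg, "density must be >= 0")
  if (object@step <= 0) msg <- c(msg, "step must be > 0")
  if (length(msg)) msg else TRUE
})

#' Binned fraction series
#'
#' Amounts of one species in the numbered collected fractions of a column.
#'
#' @slot species Species identifier.
#' @slot fractionIds Collected fraction numbers.
#' @slot amountsFmol Amount per fraction (fmol).
#' @slot fractionVolumeMl Fraction volume (ml).
#'
#' @export
setClass("FractionSeries",
  representation(species = "character", fractionIds = "integer",
                 amountsFmol = "numeric", fractionVolumeMl = "numeric")
)

setValidity("FractionSeries", function(object) {
  msg <- character()
  if (length(object@fractionIds) != length(object@amountsFmol))
    msg <- c(msg, "fractionIds and amountsFmol must have equal length")
  if (any(object@amountsFmol < 0)) msg <- c(msg, "amounts must be >= 0")
  if (is.unsorted(object@fractionIds, strictly = TRUE))
    msg <- c(msg, "fractionIds must be strictly increasing")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Method comparison
## ---------------------------------------------------------------------------

#' Averaged marker panel for one isolation condition
#'
#' The day-replicate-averaged concentrations (pM) of CD9, CD63, CD81 and
#' albumin measured in the final eluate or pooled fractions of one isolation
#' method applied to one biofluid.
#'
#' @slot biofluid Biofluid identifier (\code{"plasma"} or \code{"csf"}).
#' @slot method Isolation-condition identifier.
#' @slot markerValuesPM Named numeric with entries CD9, CD63, CD81, ALB.
#' @slot inputVolumeMl Biofluid input volume used by the method (ml).
#' @slot nDayReplicates Number of isolation replicates averaged.
#'
#' @export
setClass("MethodMeasurement",
  representation(biofluid = "character", method = "character",
                 markerValuesPM = "numeric", inputVolumeMl = "numeric",
                 nDayReplicates = "integer")
)

setValidity("MethodMeasurement", function(object) {
  msg <- character()
  if (!hasAllMarkers(object@markerValuesPM))
    msg <- c(msg, "markerValuesPM must be named and contain CD9, CD63, CD81, ALB")
  if (any(object@markerValuesPM < 0, na.rm = TRUE))
    msg <- c(msg, "marker values must be >= 0")
  if (object@inputVolumeMl <= 0) msg <- c(msg, "inputVolumeMl must be > 0")
  if (object@nDayReplicates < 1L) msg <- c(msg, "nDayReplicates must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @param biofluid,method,markerValuesPM,inputVolumeMl,nDayReplicates See slot
#'   descriptions.
#' @rdname MethodMeasurement-class
#' @export
MethodMeasurement <- function(biofluid, method, markerValuesPM,
                              inputVolumeMl = 0.5, nDayReplicates = 1L) {
  new("MethodMeasurement", biofluid = biofluid, method = method,
      markerValuesPM = markerValuesPM[evMarkers()],
      inputVolumeMl = inputVolumeMl,
      nDayReplicates = as.integer(nDayReplicates))
}

#' Relative EV recovery of one method
#'
#' Per-tetraspanin pM ratios against the reference condition and their
#' arithmetic mean (the combined relative EV recovery). Albumin is excluded.
#'
#' @slot method Method identifier.
#' @slot perMarkerRatio Named numeric ratios for CD9, CD63, CD81.
#' @slot combinedRecovery Mean of the three ratios.
#' @slot reference Reference method identifier.
#'
#' @export
setClass("RecoveryResult",
  representation(method = "character", perMarkerRatio = "numeric",
                 combinedRecovery = "numeric", reference = "character")
)

setValidity("RecoveryResult", function(object) {
  msg <- character()
  if (!all(tetraspanins() %in% names(object@perMarkerRatio)))
    msg <- c(msg, "perMarkerRatio must contain CD9, CD63, CD81")
  if (any(object@perMarkerRatio < 0))
    msg <- c(msg, "ratios must be >= 0")
  m <- mean(object@perMarkerRatio[tetraspanins()])
  if (abs(object@combinedRecovery - m) > 1e-9 * max(1, abs(m)))
    msg <- c(msg, "combinedRecovery must be the mean of the three ratios")
  if (length(msg)) msg else TRUE
})

#' EV purity score of one method
#'
#' The sum of the three tetraspanin concentrations divided by the albumin
#' concentration.
#'
#' @slot method Method identifier.
#' @slot tetraspaninSumPM Sum of CD9 + CD63 + CD81 (pM).
#' @slot albuminPM Albumin concentration (pM, > 0).
#' @slot purity \code{tetraspaninSumPM / albuminPM}.
#'
#' @export
setClass("PurityResult",
  representation(method = "character", tetraspaninSumPM = "numeric",
                 albuminPM = "numeric", purity = "numeric")
)

setValidity("PurityResult", function(object) {
  msg <- character()
  if (object@albuminPM <= 0) msg <- c(msg, "albuminPM must be > 0")
  if (object@tetraspaninSumPM < 0) msg <- c(msg, "tetraspaninSumPM must be >= 0")
  p <- object@tetraspaninSumPM / object@albuminPM
  if (abs(object@purity - p) > 1e-9 * max(1, abs(p)))
    msg <- c(msg, "purity must equal tetraspaninSumPM / albuminPM")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Synthetic experiments
## ---------------------------------------------------------------------------

#' Synthetic comparison-experiment configuration
#'
#' Ground-truth description of a method-comparison experiment: true marker
#' concentrations in the biofluid, the isolation conditions (phenomenological
#' one-pot methods or simulated SEC columns), per-marker assay parameters and
#' calibration designs, replicate structure, day-to-day noise, and the master
#' seed.
#'
#' @slot biofluid Biofluid identifier.
#' @slot trueConcPM Named numeric: true CD9, CD63, CD81, ALB concentrations
#'   (pM) in the neat biofluid. Synthetic stand-ins, not measured values.
#' @slot methods List of method descriptors built with
#'   \code{\link{onePotMethod}} / \code{\link{secMethod}}.
#' @slot assay Named list of \code{\link{BeadAssayParams}}, one per marker.
#' @slot calibrationConcs Named list of calibration-standard concentration
#'   grids (pM at assay scale), one per marker, each including a blank.
#' @slot nDayReplicates,nTechnicalReplicates,nColumnReplicates Replicate
#'   counts (days for one-pot methods, columns for SEC methods, technical
#'   assay replicates per measurement).
#' @slot dayCv Coefficient of variation of the multiplicative log-normal
#'   day-to-day (or column-to-column) noise.
#' @slot seed Master RNG seed.
#'
#' @export
setClass("ExperimentConfig",
  representation(
    biofluid = "character",
    trueConcPM = "numeric",
    methods = "list",
    assay = "list",
    calibrationConcs = "list",
    nDayReplicates = "integer",
    nTechnicalReplicates = "integer",
    nColumnReplicates = "integer",
    dayCv = "numeric",
    seed = "integer"
  )
)

setValidity("ExperimentConfig", function(object) {
  msg <- character()
  if (!hasAllMarkers(object@trueConcPM) || any(object@trueConcPM <= 0))
    msg <- c(msg, "trueConcPM must contain positive CD9, CD63, CD81, ALB")
  if (!length(object@methods)) msg <- c(msg, "at least one method required")
  nm <- vapply(object@methods, function(m) m$name %||% "", "")
  if (anyDuplicated(nm)) msg <- c(msg, "method names must be unique")
  for (m in object@methods) {
    ok <- is.list(m) && !is.null(m$type) && m$type %in% c("onepot", "sec")
    if (!ok) { msg <- c(msg, "invalid method descriptor"); next }
    if (m$type == "onepot") {
      if (!all(tetraspanins() %in% names(m$recovery)) ||
          any(m$recovery < 0 | m$recovery > 1) ||
          m$albuminCarryover < 0 || m$albuminCarryover > 1)
        msg <- c(msg, sprintf("method '%s': recoveries and carryover must lie in [0,1]", m$name))
    } else {
      if (!is(m$column, "SECColumn") ||
          !all(m$window %in% seq(m$column@firstFraction, m$column@lastFraction)))
        msg <- c(msg, sprintf("method '%s': window must lie within the collected fractions", m$name))
    }
  }
  if (!all(evMarkers() %in% names(object@assay)))
    msg <- c(msg, "assay must provide BeadAssayParams for all four markers")
  if (!all(evMarkers() %in% names(object@calibrationConcs)))
    msg <- c(msg, "calibrationConcs must cover all four markers")
  if (object@nDayReplicates < 1L || object@nTechnicalReplicates < 1L ||
      object@nColumnReplicates < 1L)
    msg <- c(msg, "replicate counts must be >= 1")
  if (object@dayCv < 0) msg <- c(msg, "dayCv must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Synthetic dataset: ground truth plus emitted observables
#'
#' @slot groundTruth List of generating parameters and analytic noise-free
#'   expectations, traceable to the seed.
#' @slot measurements Method-measurement table (one row per method, marker
#'   and replicate).
#' @slot plateReadings Raw simulated well-array counts.
#' @slot calibrationTables Simulated calibration-standard AEB table.
#' @slot fractionTables Per-fraction amounts for the SEC methods.
#' @slot config The generating \code{\link{ExperimentConfig}}.
#'
#' @export
setClass("SyntheticDataset",
  representation(
    groundTruth = "list",
    measurements = "data.frame",
    plateReadings = "data.frame",
    calibrationTables = "data.frame",
    fractionTables = "data.frame",
    config = "ExperimentConfig"
  )
)

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "BeadAssayParams", function(object) {
  cat("BeadAssayParams:", object@nWellsLoaded, "wells counted of",
      object@nBeads, "beads\n")
  cat("  capture efficiency:", object@captureEfficiency, "per pM;",
      "background AEB:", object@backgroundAeb, ";",
      "dilution:", object@dilutionFactor, "x\n")
})

setMethod("show", "WellArrayReading", function(object) {
  cat(sprintf("WellArrayReading: %d/%d on wells (f_on = %.4g), AEB = %.4g%s\n",
              as.integer(object@nOn), as.integer(object@nTotal),
              object@fractionOn, object@aeb,
              if (object@saturated) " [saturated]" else ""))
})

setMethod("show", "CalibrationCurve", function(object) {
  cat(sprintf("CalibrationCurve [%s]: AEB in (%.4g, %.4g), midpoint %.4g pM, slope %.3g\n",
              object@marker, object@lower, object@upper, object@midpoint,
              object@slope))
  cat(sprintf("  valid range %.4g-%.4g pM, rms residual %.3g\n",
              object@validRange[1], object@validRange[2], object@fitResidual))
})

setMethod("show", "SECColumn", function(object) {
  cat(sprintf("SECColumn: %s, bed %.4g ml (void %.4g ml, internal %.4g ml)\n",
              object@resin@name, object@bedVolumeMl, voidVolume(object),
              internalVolume(object)))
  cat(sprintf("  %.3g ml fractions, collecting %d-%d\n",
              object@fractionVolumeMl, object@firstFraction,
              object@lastFraction))
})

setMethod("show", "FractionSeries", function(object) {
  cat(sprintf("FractionSeries [%s]: fractions %d-%d, total %.4g fmol\n",
              object@species, min(object@fractionIds),
              max(object@fractionIds), sum(object@amountsFmol)))
})

setMethod("show", "MethodMeasurement", function(object) {
  cat(sprintf("MethodMeasurement [%s / %s], %d replicate(s), input %.3g ml\n",
              object@biofluid, object@method, object@nDayReplicates,
              object@inputVolumeMl))
  print(round(object@markerValuesPM, 4))
})

setMethod("show", "RecoveryResult", function(object) {
  cat(sprintf("RecoveryResult [%s vs %s]: combined %.4g\n", object@method,
              object@reference, object@combinedRecovery))
})

setMethod("show", "PurityResult", function(object) {
  cat(sprintf("PurityResult [%s]: purity %.4g (%.4g pM tetraspanins / %.4g pM albumin)\n",
              object@method, object@purity, object@tetraspaninSumPM,
              object@albuminPM))
})

setMethod("show", "ExperimentConfig", function(object) {
  cat(sprintf("ExperimentConfig [%s]: %d methods, seed %d\n", object@biofluid,
              length(object@methods), object@seed))
  cat("  true concentrations (pM):\n")
  print(object@trueConcPM)
})

setMethod("show", "SyntheticDataset", function(object) {
  cat(sprintf("SyntheticDataset [%s]: %d methods, %d measurement rows, seed %d\n",
              object@config@biofluid, length(object@config@methods),
              nrow(object@measurements), object@config@seed))
})
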
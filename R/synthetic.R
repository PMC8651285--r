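## Synthetic comparison experiments with known ground truth.
##
## One-pot isolation methods (ultracentrifugation, polymer precipitation) are
## modelled phenomenologically by per-tetraspanin recovery and albumin
## carryover; SEC methods are simulated mechanistically through the elution
## model and pooled over their fraction window. Observed values are produced
## by pushing the true eluate concentrations through the digital-assay
## simulate -> calibrate -> invert chain, with multiplicative log-normal
## replicate noise. Everything is reproducible from the master seed.

#' Preset SEC resins
#'
#' Sepharose CL-2B/4B/6B with pore radii of 37.5, 21 and 12 nm (half the
#' published 75/42/24 nm pore sizes, read as diameters) and two commercial
#' column resins with nominal 35 and 70 nm cutoffs (pore radii 17.5 and
#' 35 nm). Porosity defaults to 0.60 of bed volume for all.
#'
#' @return A named list of \code{\link{Resin-class}} objects.
#' @export
presetResins <- function() {
  list(
    "CL-2B"  = Resin("CL-2B", poreRadiusNm = 37.5),
    "CL-4B"  = Resin("CL-4B", poreRadiusNm = 21),
    "CL-6B"  = Resin("CL-6B", poreRadiusNm = 12),
    "Izon35" = Resin("Izon35", poreRadiusNm = 17.5),
    "Izon70" = Resin("Izon70", poreRadiusNm = 35)
  )
}

#' Method descriptors for synthetic experiments
#'
#' \code{onePotMethod} describes a non-chromatographic isolation by its
#' per-tetraspanin true recovery, its albumin carryover, and its input and
#' eluate volumes. \code{secMethod} describes a simulated SEC column run
#' pooled over a fraction window.
#'
#' @param name Unique method identifier.
#' @param recovery Named numeric in \code{[0,1]} with entries CD9, CD63,
#'   CD81: fraction of each marker recovered into the eluate.
#' @param albuminCarryover Fraction of albumin carried into the eluate, in
#'   \code{[0,1]}.
#' @param inputVolumeMl Biofluid input volume (ml).
#' @param eluateVolumeMl Final eluate volume (ml).
#' @return A method-descriptor list for use in
#'   \code{\link{ExperimentConfig-class}} method lists.
#' @export
onePotMethod <- function(name, recovery, albuminCarryover,
                         inputVolumeMl = 0.5, eluateVolumeMl = 0.5) {
  list(name = name, type = "onepot",
       recovery = recovery[tetraspanins()],
       albuminCarryover = albuminCarryover,
       inputVolumeMl = inputVolumeMl, eluateVolumeMl = eluateVolumeMl)
}

#' @rdname onePotMethod
#' @param column A \code{\link{SECColumn-class}}.
#' @param window Integer fraction ids pooled as the EV window.
#' @param loadVolumeMl Sample volume loaded on the column (ml).
#' @export
secMethod <- function(name, column, window, loadVolumeMl = 0.5) {
  list(name = name, type = "sec", column = column,
       window = as.integer(window), inputVolumeMl = loadVolumeMl)
}

## Default physical parameters of the SEC simulation shared by the presets.
defaultSimControl <- function(control = list()) {
  defaults <- list(
    dispersion = 0.15, tailFraction = 0.02, tailScaleMl = 1.5,
    matrixTrapping = 1, nQuad = 400, gridStep = 0.025,
    evMedianRadiusNm = 50, evGeomSd = 1.5, albuminRadiusNm = 3.5
  )
  unknown <- setdiff(names(control), names(defaults))
  if (length(unknown))
    evConfigError(paste("unknown simControl keys:",
                        paste(unknown, collapse = ", ")))
  utils::modifyList(defaults, control)
}

plasmaAssay <- function() {
  list(
    CD9  = BeadAssayParams(captureEfficiency = 0.4, backgroundAeb = 0.01,
                           dilutionFactor = 4),
    CD63 = BeadAssayParams(captureEfficiency = 0.4, backgroundAeb = 0.01,
                           dilutionFactor = 4),
    CD81 = BeadAssayParams(captureEfficiency = 0.4, backgroundAeb = 0.01,
                           dilutionFactor = 4),
    ALB  = BeadAssayParams(captureEfficiency = 0.016, backgroundAeb = 5e-4,
                           dilutionFactor = 20)
  )
}

csfAssay <- function() {
  list(
    CD9  = BeadAssayParams(captureEfficiency = 1.0, backgroundAeb = 0.01,
                           dilutionFactor = 4),
    CD63 = BeadAssayParams(captureEfficiency = 1.0, backgroundAeb = 0.01,
                           dilutionFactor = 4),
    CD81 = BeadAssayParams(captureEfficiency = 1.0, backgroundAeb = 0.01,
                           dilutionFactor = 4),
    ALB  = BeadAssayParams(captureEfficiency = 0.2, backgroundAeb = 5e-4,
                           dilutionFactor = 20)
  )
}

plasmaCalibration <- function() {
  list(
    CD9 = c(0, 0.01, 0.03, 0.1, 0.3, 1, 3),
    CD63 = c(0, 0.01, 0.03, 0.1, 0.3, 1, 3),
    CD81 = c(0, 0.01, 0.03, 0.1, 0.3, 1, 3),
    ALB = c(0, 0.1, 0.3, 1, 3, 10, 30, 100)
  )
}

csfCalibration <- function() {
  list(
    CD9 = c(0, 0.005, 0.015, 0.05, 0.15, 0.5, 1.5),
    CD63 = c(0, 0.005, 0.015, 0.05, 0.15, 0.5, 1.5),
    CD81 = c(0, 0.005, 0.015, 0.05, 0.15, 0.5, 1.5),
    ALB = c(0, 0.01, 0.03, 0.1, 0.3, 1, 3, 10)
  )
}

#' Build an experiment configuration
#'
#' Low-level constructor for custom synthetic experiments; the presets
#' (\code{\link{defaultPlasmaConfig}}, \code{\link{paperLayoutConfig}}) are
#' built on top of it.
#'
#' @param biofluid Biofluid identifier.
#' @param trueConcPM Named true concentrations (pM) for CD9, CD63, CD81, ALB.
#' @param methods List of \code{\link{onePotMethod}} / \code{\link{secMethod}}
#'   descriptors.
#' @param assay Named list of \code{\link{BeadAssayParams}} per marker.
#' @param calibrationConcs Named list of standard concentration grids per
#'   marker (assay scale, each including a blank).
#' @param nDayReplicates,nTechnicalReplicates,nColumnReplicates Replicate
#'   counts.
#' @param dayCv Replicate-to-replicate coefficient of variation.
#' @param seed Master seed.
#' @return A validated \code{\link{ExperimentConfig-class}}.
#' @export
experimentConfig <- function(biofluid, trueConcPM, methods, assay,
                             calibrationConcs, nDayReplicates = 2L,
                             nTechnicalReplicates = 2L,
                             nColumnReplicates = 4L, dayCv = 0.15,
                             seed = 1L) {
  new("ExperimentConfig", biofluid = biofluid,
      trueConcPM = trueConcPM[evMarkers()], methods = methods, assay = assay,
      calibrationConcs = calibrationConcs,
      nDayReplicates = as.integer(nDayReplicates),
      nTechnicalReplicates = as.integer(nTechnicalReplicates),
      nColumnReplicates = as.integer(nColumnReplicates),
      dayCv = dayCv, seed = as.integer(seed))
}

#' Default synthetic plasma and CSF experiments
#'
#' Preset configurations for the headline three-way custom-column comparison:
#' the conventional CL-2B 10 ml column (reference), the high-yield CL-6B
#' 10 ml column, and the high-purity CL-4B column (20 ml bed for plasma,
#' 10 ml for CSF), all pooling the four 0.5 ml fractions immediately after
#' the void. True marker concentrations are synthetic stand-ins, not
#' measured values; the CSF preset carries roughly 5-fold lower tetraspanins
#' and 200-fold lower albumin than plasma, reflecting the much lower protein
#' content of CSF. Pure functions: same seed, same config.
#'
#' @param seed Master seed stored in the config.
#' @return A validated \code{\link{ExperimentConfig-class}}.
#' @export
defaultPlasmaConfig <- function(seed = 101L) {
  resins <- presetResins()
  methods <- list(
    secMethod("CL-2B 10 ml f7-10", SECColumn(resins[["CL-2B"]], 10), 7:10),
    secMethod("CL-6B 10 ml f7-10", SECColumn(resins[["CL-6B"]], 10), 7:10),
    secMethod("CL-4B 20 ml f14-17", SECColumn(resins[["CL-4B"]], 20), 14:17)
  )
  cfg <- experimentConfig(
    biofluid = "plasma",
    trueConcPM = c(CD9 = 40, CD63 = 12, CD81 = 25, ALB = 2e5),
    methods = methods, assay = plasmaAssay(),
    calibrationConcs = plasmaCalibration(), seed = seed
  )
  validObject(cfg)
  cfg
}

#' @rdname defaultPlasmaConfig
#' @export
defaultCsfConfig <- function(seed = 102L) {
  resins <- presetResins()
  methods <- list(
    secMethod("CL-2B 10 ml f7-10", SECColumn(resins[["CL-2B"]], 10), 7:10),
    secMethod("CL-6B 10 ml f7-10", SECColumn(resins[["CL-6B"]], 10), 7:10),
    secMethod("CL-4B 10 ml f7-10", SECColumn(resins[["CL-4B"]], 10), 7:10)
  )
  cfg <- experimentConfig(
    biofluid = "csf",
    trueConcPM = c(CD9 = 8, CD63 = 2.5, CD81 = 5, ALB = 1000),
    methods = methods, assay = csfAssay(),
    calibrationConcs = csfCalibration(), seed = seed
  )
  validObject(cfg)
  cfg
}

#' Full survey layout: six published methods plus six custom columns
#'
#' Builds the 12-condition survey layout for one biofluid:
#' ultracentrifugation with and without a wash, two precipitation kits (the
#' second using a 0.25 ml input, corrected downstream to the 0.5 ml
#' standard), two commercial SEC columns, and the six custom columns
#' (CL-2B/4B/6B at 10 and 20 ml beds). 10 ml columns collect fractions 6-21
#' and pool 7-10; 20 ml columns collect 12-27 and pool 14-17.
#'
#' @param biofluid \code{"plasma"} or \code{"csf"}.
#' @param seed Master seed stored in the config.
#' @return A validated \code{\link{ExperimentConfig-class}} with 12 methods.
#' @export
paperLayoutConfig <- function(biofluid = c("plasma", "csf"), seed = 103L) {
  biofluid <- match.arg(biofluid)
  resins <- presetResins()
  if (biofluid == "plasma") {
    onepots <- list(
      onePotMethod("UC", c(CD9 = 0.06, CD63 = 0.04, CD81 = 0.05), 0.05),
      onePotMethod("UC wash", c(CD9 = 0.035, CD63 = 0.025, CD81 = 0.03), 0.01),
      onePotMethod("ExoQuick", c(CD9 = 0.11, CD63 = 0.08, CD81 = 0.10), 0.08),
      onePotMethod("ExoQuick ULTRA", c(CD9 = 0.13, CD63 = 0.10, CD81 = 0.12),
                   0.04, inputVolumeMl = 0.25)
    )
    base <- defaultPlasmaConfig()
  } else {
    onepots <- list(
      onePotMethod("UC", c(CD9 = 0.22, CD63 = 0.16, CD81 = 0.20), 0.10),
      onePotMethod("UC wash", c(CD9 = 0.12, CD63 = 0.09, CD81 = 0.11), 0.03),
      onePotMethod("ExoQuick", c(CD9 = 0.40, CD63 = 0.30, CD81 = 0.36), 0.15),
      onePotMethod("ExoQuick ULTRA", c(CD9 = 0.30, CD63 = 0.22, CD81 = 0.27),
                   0.08, inputVolumeMl = 0.25)
    )
    base <- defaultCsfConfig()
  }
  secs <- list(
    secMethod("Izon35 f7-10", SECColumn(resins[["Izon35"]], 10), 7:10),
    secMethod("Izon70 f7-10", SECColumn(resins[["Izon70"]], 10), 7:10),
    secMethod("CL-2B 10 ml f7-10", SECColumn(resins[["CL-2B"]], 10), 7:10),
    secMethod("CL-4B 10 ml f7-10", SECColumn(resins[["CL-4B"]], 10), 7:10),
    secMethod("CL-6B 10 ml f7-10", SECColumn(resins[["CL-6B"]], 10), 7:10),
    secMethod("CL-2B 20 ml f14-17", SECColumn(resins[["CL-2B"]], 20), 14:17),
    secMethod("CL-4B 20 ml f14-17", SECColumn(resins[["CL-4B"]], 20), 14:17),
    secMethod("CL-6B 20 ml f14-17", SECColumn(resins[["CL-6B"]], 20), 14:17)
  )
  cfg <- experimentConfig(
    biofluid = biofluid, trueConcPM = base@trueConcPM,
    methods = c(onepots, secs), assay = base@assay,
    calibrationConcs = base@calibrationConcs, seed = seed
  )
  validObject(cfg)
  cfg
}

## Noise-free analytic expectation of the eluate/pool concentration of each
## marker for each method, plus the true per-fraction series for SEC methods.
expectedEluateConc <- function(config, control = defaultSimControl()) {
  truths <- config@trueConcPM
  expRows <- list()
  fracRows <- list()
  for (m in config@methods) {
    if (m$type == "onepot") {
      vol <- m$inputVolumeMl / m$eluateVolumeMl
      vals <- c(truths[tetraspanins()] * m$recovery[tetraspanins()] * vol,
                ALB = unname(truths["ALB"]) * m$albuminCarryover * vol)
    } else {
      load <- m$inputVolumeMl
      evSpec <- Species("EV", control$evMedianRadiusNm, control$evGeomSd,
                        inputAmountFmol = 1)
      albSpec <- Species("ALB", control$albuminRadiusNm, 1,
                         inputAmountFmol = 1)
      profEv <- elutionProfile(evSpec, m$column, loadVolumeMl = load,
                               dispersion = control$dispersion,
                               tailFraction = control$tailFraction,
                               tailScaleMl = control$tailScaleMl,
                               matrixTrapping = control$matrixTrapping,
                               nQuad = control$nQuad,
                               gridStep = control$gridStep)
      profAlb <- elutionProfile(albSpec, m$column, loadVolumeMl = load,
                                dispersion = control$dispersion,
                                tailFraction = control$tailFraction,
                                tailScaleMl = control$tailScaleMl,
                                matrixTrapping = control$matrixTrapping,
                                nQuad = control$nQuad,
                                gridStep = control$gridStep)
      serEv <- collectFractions(profEv, m$column)
      serAlb <- collectFractions(profAlb, m$column)
      poolEv <- poolWindow(serEv, m$window)
      poolAlb <- poolWindow(serAlb, m$window)
      ## unit-input pools scale linearly with the loaded amount (fmol)
      vals <- c(truths[tetraspanins()] * load * poolEv$concentrationPM,
                ALB = unname(truths["ALB"]) * load * poolAlb$concentrationPM)
      for (sp in c(tetraspanins(), "ALB")) {
        ser <- if (sp == "ALB") serAlb else serEv
        amt <- ser@amountsFmol * truths[sp] * load
        fracRows[[length(fracRows) + 1L]] <- data.frame(
          method = m$name, species = sp, fraction = ser@fractionIds,
          amount_fmol = amt,
          concentration_pM = amt / ser@fractionVolumeMl,
          stringsAsFactors = FALSE
        )
      }
    }
    expRows[[length(expRows) + 1L]] <- data.frame(
      method = m$name, marker = evMarkers(),
      expected_pM = unname(vals[evMarkers()]), stringsAsFactors = FALSE
    )
  }
  list(expected = do.call(rbind, expRows),
       fractions = if (length(fracRows)) do.call(rbind, fracRows) else
         data.frame(method = character(), species = character(),
                    fraction = integer(), amount_fmol = numeric(),
                    concentration_pM = numeric()))
}

#' Generate a complete synthetic comparison experiment
#'
#' Runs the full forward model: true biofluid concentrations are pushed
#' through each isolation method (phenomenological recovery/carryover for
#' one-pot methods, the SEC elution simulator pooled over the configured
#' window for columns), multiplied by log-normal replicate noise, and then
#' measured by the simulated digital assay (technical-replicate readouts,
#' calibration-curve fitting and inversion, technical averaging). With
#' \code{idealAssay = TRUE} the assay step is the identity, so observed
#' values equal the noise-free (or noise-only) expectations exactly; that
#' mode is the ground-truth surface for end-to-end recovery checks.
#'
#' @param config An \code{\link{ExperimentConfig-class}}.
#' @param idealAssay Skip assay simulation and report exact concentrations.
#' @param simControl Named list overriding the SEC simulation defaults
#'   (dispersion, tailFraction, tailScaleMl, matrixTrapping, nQuad, gridStep,
#'   evMedianRadiusNm, evGeomSd, albuminRadiusNm).
#' @return A \code{\link{SyntheticDataset-class}}; regenerating with the
#'   same config is bit-identical.
#' @export
generateExperiment <- function(config, idealAssay = FALSE,
                               simControl = list()) {
  validObject(config)
  control <- defaultSimControl(simControl)
  exp0 <- expectedEluateConc(config, control)
  expected <- exp0$expected

  seeds <- drawSubSeeds(config@seed, 2L + length(config@methods))
  calSeed <- seeds[1L]

  ## calibration standards: two replicates per concentration per marker
  calRows <- list()
  curves <- list()
  allConcs <- config@calibrationConcs
  nDraw <- sum(vapply(allConcs[evMarkers()], length, 0L)) * 2L
  calSeeds <- drawSubSeeds(calSeed, nDraw)
  k <- 0L
  for (mk in evMarkers()) {
    par <- config@assay[[mk]]
    for (conc in allConcs[[mk]]) {
      for (rep in 1:2) {
        k <- k + 1L
        aebVal <- if (idealAssay) {
          par@captureEfficiency * conc + par@backgroundAeb
        } else {
          ## standards are read at assay scale (no pre-dilution)
          lam <- par@captureEfficiency * conc + par@backgroundAeb
          nOn <- withSeed(calSeeds[k],
                          stats::rbinom(1L, as.integer(par@nWellsLoaded),
                                        -expm1(-lam)))
          if (nOn == par@nWellsLoaded) NA_real_ else
            -log1p(-nOn / par@nWellsLoaded)
        }
        calRows[[length(calRows) + 1L]] <- data.frame(
          marker = mk, concentration_pM = conc, replicate = rep,
          aeb = aebVal, stringsAsFactors = FALSE
        )
      }
    }
  }
  calibration <- do.call(rbind, calRows)
  calibration <- calibration[!is.na(calibration$aeb), , drop = FALSE]
  if (!idealAssay)
    curves <- fitCalibrationCurves(calibration)

  measRows <- list()
  plateRows <- list()
  for (i in seq_along(config@methods)) {
    m <- config@methods[[i]]
    nrep <- if (m$type == "sec") config@nColumnReplicates else
      config@nDayReplicates
    exRow <- expected[expected$method == m$name, ]
    exVals <- stats::setNames(exRow$expected_pM, exRow$marker)

    mSeed <- seeds[2L + i]
    sdlog <- sqrt(log(1 + config@dayCv^2))
    noise <- withSeed(mSeed, {
      if (config@dayCv > 0) {
        matrix(stats::rlnorm(nrep * 4L, meanlog = -sdlog^2 / 2, sdlog = sdlog),
               nrow = nrep)
      } else {
        matrix(1, nrow = nrep, ncol = 4L)
      }
    })
    readSeeds <- drawSubSeeds(mSeed + 1L,
                              nrep * 4L * config@nTechnicalReplicates)
    rk <- 0L
    for (r in seq_len(nrep)) {
      for (j in seq_along(evMarkers())) {
        mk <- evMarkers()[j]
        trueEluate <- unname(exVals[mk]) * noise[r, j]
        if (idealAssay) {
          value <- trueEluate
        } else {
          par <- config@assay[[mk]]
          ests <- vector("list", config@nTechnicalReplicates)
          for (t in seq_len(config@nTechnicalReplicates)) {
            rk <- rk + 1L
            reading <- simulateDigitalReadout(trueEluate, par, readSeeds[rk])
            plateRows[[length(plateRows) + 1L]] <- data.frame(
              sample_id = sprintf("%s|rep%d", m$name, r), marker = mk,
              replicate = t, n_on = reading@nOn, n_total = reading@nTotal,
              stringsAsFactors = FALSE
            )
            ests[[t]] <- concentrationFromReading(reading, curves[[mk]],
                                                  par@dilutionFactor)
          }
          value <- averageTechnicalReplicates(ests)@valuePM
        }
        measRows[[length(measRows) + 1L]] <- data.frame(
          biofluid = config@biofluid, method = m$name, marker = mk,
          replicate_day = r, value_pM = value,
          input_volume_ml = m$inputVolumeMl, stringsAsFactors = FALSE
        )
      }
    }
  }

  new("SyntheticDataset",
      groundTruth = list(
        biofluid = config@biofluid, seed = config@seed,
        trueConcPM = as.list(config@trueConcPM),
        dayCv = config@dayCv, simControl = control,
        methods = lapply(config@methods, function(m)
          m[setdiff(names(m), "column")]),
        expectedEluatePM = expected
      ),
      measurements = do.call(rbind, measRows),
      plateReadings = if (length(plateRows)) do.call(rbind, plateRows) else
        data.frame(sample_id = character(), marker = character(),
                   replicate = integer(), n_on = numeric(),
                   n_total = numeric()),
      calibrationTables = calibration,
      fractionTables = exp0$fractions,
      config = config)
}

#' @rdname paperLayoutConfig
#' @param idealAssay,simControl Passed to \code{\link{generateExperiment}}.
#' @return \code{emulatePaperLayout} returns the generated
#'   \code{\link{SyntheticDataset-class}} for the 12-condition layout.
#' @export
emulatePaperLayout <- function(biofluid = c("plasma", "csf"), seed = 103L,
                               idealAssay = FALSE, simControl = list()) {
  generateExperiment(paperLayoutConfig(match.arg(biofluid), seed),
                     idealAssay = idealAssay, simControl = simControl)
}
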
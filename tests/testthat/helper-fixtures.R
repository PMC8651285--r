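# Shared fixtures, all built in code.

# Exact (noise-free) standards from a known four-parameter logistic.
exact4plStandards <- function(marker = "CD9",
                              concs = c(0, 0.01, 0.03, 0.1, 0.3, 1, 3, 10),
                              lower = 0.02, upper = 3.5, midpoint = 0.8,
                              slope = 1.1) {
  y <- lower + (upper - lower) *
    ifelse(concs > 0, concs^slope / (concs^slope + midpoint^slope), 0)
  data.frame(marker = marker,
             concentration_pM = rep(concs, each = 2),
             replicate = rep(1:2, length(concs)),
             aeb = rep(y, each = 2))
}

# Calibration table simulated with the digital readout at assay scale.
simulatedStandards <- function(marker = "CD9",
                               concs = c(0, 0.3, 1, 3, 10, 30),
                               params = BeadAssayParams(5e5, 1e5, 0.05,
                                                        0.01, 1),
                               seedBase = 1000) {
  rows <- lapply(seq_along(concs), function(i) {
    data.frame(marker = marker, concentration_pM = concs[i], replicate = 1:2,
               aeb = vapply(1:2, function(r) {
                 aeb(simulateDigitalReadout(concs[i], params,
                                            seed = seedBase + 10 * i + r))
               }, 0))
  })
  do.call(rbind, rows)
}

# Hand-built marker panel.
panel <- function(cd9, cd63, cd81, alb, method = "M", biofluid = "plasma",
                  inputVolumeMl = 0.5) {
  MethodMeasurement(biofluid, method,
                    c(CD9 = cd9, CD63 = cd63, CD81 = cd81, ALB = alb),
                    inputVolumeMl = inputVolumeMl)
}

# One-pot-only synthetic study: four methods whose true combined recoveries
# step down by 30% each (ratios 1, 0.7, 0.49, 0.343 vs the reference).
onePotStudyConfig <- function(seed = 1L, dayCv = 0.15) {
  tet <- function(x) c(CD9 = x, CD63 = x, CD81 = x)
  assay <- list(
    CD9  = BeadAssayParams(captureEfficiency = 0.4, backgroundAeb = 0.01,
                           dilutionFactor = 4),
    CD63 = BeadAssayParams(captureEfficiency = 0.4, backgroundAeb = 0.01,
                           dilutionFactor = 4),
    CD81 = BeadAssayParams(captureEfficiency = 0.4, backgroundAeb = 0.01,
                           dilutionFactor = 4),
    ALB  = BeadAssayParams(captureEfficiency = 0.016, backgroundAeb = 5e-4,
                           dilutionFactor = 20)
  )
  cal <- list(CD9 = c(0, 0.01, 0.03, 0.1, 0.3, 1, 3),
              CD63 = c(0, 0.01, 0.03, 0.1, 0.3, 1, 3),
              CD81 = c(0, 0.01, 0.03, 0.1, 0.3, 1, 3),
              ALB = c(0, 0.1, 0.3, 1, 3, 10, 30, 100))
  experimentConfig(
    biofluid = "plasma",
    trueConcPM = c(CD9 = 12, CD63 = 8, CD81 = 10, ALB = 5000),
    methods = list(
      onePotMethod("M1", tet(0.600), 0.02),
      onePotMethod("M2", tet(0.420), 0.02),
      onePotMethod("M3", tet(0.294), 0.02),
      onePotMethod("M4", tet(0.206), 0.02)
    ),
    assay = assay, calibrationConcs = cal,
    nDayReplicates = 2L, nTechnicalReplicates = 2L, nColumnReplicates = 2L,
    dayCv = dayCv, seed = seed
  )
}

# True combined recoveries (vs M1) of the one-pot study.
onePotTrueRecovery <- c(M1 = 1, M2 = 0.7, M3 = 0.49, M4 = 0.206 / 0.600)

defaultColumns10 <- function() {
  resins <- presetResins()
  lapply(c("CL-2B", "CL-4B", "CL-6B"),
         function(r) SECColumn(resins[[r]], 10))
}

evSpecies <- function(amount = 1) Species("EV", 50, 1.5, amount)
albSpecies <- function(amount = 1) Species("ALB", 3.5, 1, amount)

peakVolume <- function(profile) profile@volumes[which.max(profile@density)]
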
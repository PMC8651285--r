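# Digital immunoassay measurement model.

test_that("occupancy correction matches the closed form and a Monte-Carlo partition oracle", {
  expect_identical(aebFromFractionOn(0), 0)
  expect_equal(aebFromFractionOn(1 - exp(-1)), 1, tolerance = 1e-12)
  expect_equal(aebFromFractionOn(0.1), -log(0.9), tolerance = 1e-12)

  # independent oracle: drop a Poisson number of molecules into 1e6 wells
  # uniformly; the occupied fraction estimates 1 - exp(-lambda)
  lambda <- -log(0.9)
  nWells <- 1e6L
  fOnMc <- withr::with_seed(42, {
    total <- rpois(1L, lambda * nWells)
    length(unique(sample.int(nWells, total, replace = TRUE))) / nWells
  })
  se <- sqrt(exp(-lambda) * (1 - exp(-lambda)) / nWells)
  expect_lt(abs(fOnMc - 0.1), 5 * se)
  expect_lt(abs(aebFromFractionOn(fOnMc) - lambda), 5 * se / 0.9)

  expect_error(aebFromFractionOn(1), class = "evcompareDomainError")
  expect_error(aebFromFractionOn(1.2), class = "evcompareDomainError")
  expect_error(aebFromFractionOn(-0.01), class = "evcompareDomainError")
})

test_that("occupancy map and its correction are mutual inverses across the digital range", {
  lambda <- 10^seq(log10(1e-4), log10(5), length.out = 200)
  expect_equal(aebFromFractionOn(fractionOnFromAeb(lambda)), lambda,
               tolerance = 1e-12)
  f <- fractionOnFromAeb(lambda)
  expect_equal(fractionOnFromAeb(aebFromFractionOn(f)), f, tolerance = 1e-12)
  expect_true(all(diff(aebFromFractionOn(seq(0, 0.99, by = 0.01))) > 0))
})

test_that("simulated readouts are seeded, unbiased and monotone in concentration", {
  par <- BeadAssayParams(nBeads = 5e5, nWellsLoaded = 1e5,
                         captureEfficiency = 0.05, backgroundAeb = 0,
                         dilutionFactor = 1)

  # zero analyte, zero background: empty array
  r0 <- simulateDigitalReadout(0, par, seed = 7)
  expect_identical(r0@nOn, 0)
  expect_identical(aeb(r0), 0)

  # determinism: same seed, bit-identical reading
  r1 <- simulateDigitalReadout(25, par, seed = 11)
  r2 <- simulateDigitalReadout(25, par, seed = 11)
  expect_identical(r1, r2)
  expect_false(identical(r1, simulateDigitalReadout(25, par, seed = 12)))

  # lambda = 0.5: on-fraction within 5 binomial sd of 1 - exp(-0.5)
  p <- 1 - exp(-0.5)
  rd <- simulateDigitalReadout(10, par, seed = 3)   # 0.05 * 10 = 0.5
  expect_lt(abs(fractionOn(rd) - p), 5 * sqrt(p * (1 - p) / 1e5))

  # monotone mean on-fraction over a coarse concentration grid
  concs <- c(0, 5, 10, 20, 50, 100)
  meanF <- vapply(concs, function(cc) {
    mean(vapply(1:5, function(s)
      fractionOn(simulateDigitalReadout(cc, par, seed = 100 + s)), 0))
  }, 0)
  expect_true(all(diff(meanF) >= 0))

  # saturation flagging above the digital regime
  expect_true(isSaturated(simulateDigitalReadout(5000, par, seed = 1)))
})

test_that("calibration fitting recovers exact four-parameter curves and rejects bad designs", {
  std <- exact4plStandards()
  cv <- fitCalibration(std)
  expect_equal(cv@lower, 0.02, tolerance = 1e-6)
  expect_equal(cv@upper, 3.5, tolerance = 1e-6)
  expect_equal(cv@midpoint, 0.8, tolerance = 1e-6)
  expect_equal(cv@slope, 1.1, tolerance = 1e-6)
  expect_lt(cv@fitResidual, 1e-8)
  expect_gt(cv@slope, 0)

  # too few distinct concentrations
  expect_error(fitCalibration(std[std$concentration_pM %in% c(0, 1, 3), ]),
               class = "evcompareConfigError")
  # no blank
  expect_error(fitCalibration(std[std$concentration_pM > 0, ]),
               class = "evcompareConfigError")
  # degenerate: all-blank response
  flat <- std
  flat$aeb <- 0.02
  expect_error(fitCalibration(flat), class = "evcompareFitError")
  # mixed markers refused
  mixed <- rbind(std, transform(std, marker = "CD63"))
  expect_error(fitCalibration(mixed), class = "evcompareConfigError")
})

test_that("back-calculation inverts the curve, applies dilution, clamps and flags", {
  cv <- fitCalibration(exact4plStandards())

  # by construction of the inverse: response at 10 pM, dilution 4 -> 40 pM
  a10 <- predictAeb(cv, 10)
  rd <- WellArrayReading(nOn = round(1e6 * (1 - exp(-a10))), nTotal = 1e6)
  est <- concentrationFromReading(rd, cv, dilutionFactor = 4)
  expect_equal(concentration(est), 40, tolerance = 1e-3)

  # blank-level AEB -> zero, flagged
  blank <- WellArrayReading(nOn = 0, nTotal = 1e5)
  estB <- concentrationFromReading(blank, cv, 4)
  expect_identical(concentration(estB), 0)
  expect_true("blank_level" %in% estimateFlags(estB))

  # above the upper asymptote -> clamped to the top of the range, flagged
  hot <- WellArrayReading(nOn = 99999, nTotal = 1e5)
  estH <- concentrationFromReading(hot, cv, 1)
  expect_identical(concentration(estH), cv@validRange[2])
  expect_true("above_curve" %in% estimateFlags(estH))

  # round trip simulate -> fit -> invert at 50 pM with 4x dilution
  cvSim <- fitCalibration(simulatedStandards())
  par <- BeadAssayParams(5e5, 1e5, 0.05, 0.01, 4)
  errs <- vapply(1:10, function(s) {
    e <- concentrationFromReading(simulateDigitalReadout(50, par, seed = s),
                                  cvSim, 4)
    abs(concentration(e) - 50) / 50
  }, 0)
  expect_lt(median(errs), 0.05)
})

test_that("technical replicate averaging is marker-safe with sample-sd CV", {
  e <- function(v) ConcentrationEstimate("CD9", v)
  a <- averageTechnicalReplicates(list(e(10), e(10)))
  expect_identical(concentration(a), 10)
  expect_identical(a@cv, 0)

  b <- averageTechnicalReplicates(list(e(8), e(12)))
  expect_identical(concentration(b), 10)
  expect_equal(b@cv, sqrt(8) / 10, tolerance = 1e-12)

  s <- averageTechnicalReplicates(list(e(3.3)))
  expect_identical(concentration(s), 3.3)
  expect_identical(s@cv, 0)

  expect_error(
    averageTechnicalReplicates(list(e(1), ConcentrationEstimate("ALB", 1))),
    class = "evcompareConfigError")
})
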
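# Size-exclusion chromatography model.

test_that("partition coefficient has the hard-sphere limits and monotonicity", {
  expect_identical(partitionCoefficient(80, 37.5), 0)     # full exclusion
  expect_identical(partitionCoefficient(37.5, 37.5), 0)
  expect_equal(partitionCoefficient(1e-9, 37.5), 1, tolerance = 1e-7)
  expect_equal(partitionCoefficient(37.5 / 2, 37.5), 0.25)

  r <- seq(0.5, 37, by = 0.5)
  K <- partitionCoefficient(r, 37.5)
  expect_true(all(K >= 0 & K <= 1))
  expect_true(all(diff(K) < 0))                            # decreasing in r
  expect_true(all(diff(partitionCoefficient(10, c(12, 21, 37.5))) > 0))

  expect_error(partitionCoefficient(-1, 10), class = "evcompareDomainError")
  expect_error(partitionCoefficient(1, 0), class = "evcompareDomainError")
})

test_that("elution volume is void plus accessible internal volume", {
  col10 <- SECColumn(presetResins()[["CL-2B"]], 10)        # V0 = 3, Vi = 6
  expect_equal(elutionVolume(0, col10), 3.0)
  expect_equal(elutionVolume(1, col10), 9.0)
  col20 <- SECColumn(presetResins()[["CL-2B"]], 20)
  expect_equal(elutionVolume(0.5, col20), 2 * elutionVolume(0.5, col10))
  expect_error(elutionVolume(1.2, col10), class = "evcompareDomainError")
})

test_that("profile limits: delta band at Ve, peak position scales with bed volume", {
  col <- SECColumn(presetResins()[["CL-2B"]], 10)
  point <- Species("tiny", 1e-6, 1, 1)                     # K ~ 1, Ve ~ 9
  prof <- elutionProfile(point, col, loadVolumeMl = 1e-13,
                         dispersion = 1e-13, tailFraction = 0)
  ser <- collectFractions(prof, col)
  amt <- amounts(ser)
  expect_equal(unname(amt[as.character(18)]), 1, tolerance = 1e-9)
  expect_equal(sum(amt), 1, tolerance = 1e-9)              # all in fraction 18

  # fully excluded species: peak center doubles from a 10 to a 20 ml bed
  big <- Species("EVlike", 200, 1, 1)
  p10 <- elutionProfile(big, col, tailFraction = 0)
  p20 <- elutionProfile(big, SECColumn(presetResins()[["CL-2B"]], 20),
                        tailFraction = 0)
  expect_equal(peakVolume(p20) / peakVolume(p10), 2, tolerance = 0.02)
})

test_that("EV band elutes strictly before albumin on every preset column", {
  for (rn in names(presetResins())) {
    for (bed in c(10, 20)) {
      col <- SECColumn(presetResins()[[rn]], bed)
      pe <- elutionProfile(evSpecies(), col)
      pa <- elutionProfile(albSpecies(), col)
      expect_lt(peakVolume(pe), peakVolume(pa))
      # direct evaluation of Ve for the median radii agrees
      KeV <- partitionCoefficient(50, col@resin@poreRadiusNm)
      Kalb <- partitionCoefficient(3.5, col@resin@poreRadiusNm)
      expect_lt(elutionVolume(KeV, col), elutionVolume(Kalb, col))
    }
  }
})

test_that("binning conserves mass over the collected window to 1e-9 relative", {
  for (col in defaultColumns10()) {
    for (sp in list(evSpecies(2.5), albSpecies(7))) {
      prof <- elutionProfile(sp, col)
      ser <- collectFractions(prof, col)
      fv <- col@fractionVolumeMl
      inWindow <- prof@volumes > (col@firstFraction - 1) * fv &
        prof@volumes <= col@lastFraction * fv
      windowMass <- sum(prof@density[inWindow]) * prof@step
      expect_equal(sum(amounts(ser)), windowMass,
                   tolerance = 1e-9)
      expect_true(all(amounts(ser) >= 0))
      # concentrations derive from amounts over the fraction volume
      expect_equal(unname(concentrations(ser)),
                   unname(amounts(ser)) / fv)
    }
  }
})

test_that("a uniform density slab lands in exactly its covering fraction", {
  col <- SECColumn(presetResins()[["CL-2B"]], 10)
  step <- 0.025
  mids <- seq(step / 2, 12 - step / 2, by = step)
  dens <- ifelse(mids > 3.0 & mids <= 3.5, 1, 0)          # 1 fmol/ml slab
  prof <- new("ElutionProfile", species = "slab", volumes = mids,
              density = dens, step = step)
  amt <- amounts(collectFractions(prof, col))
  expect_equal(unname(amt[as.character(7)]), 0.5, tolerance = 1e-12)
  expect_equal(sum(amt), 0.5, tolerance = 1e-12)
  expect_true(all(amt[setdiff(names(amt), "7")] == 0))
})

test_that("smaller pore size gives strictly more EV in fractions 7-10 of 10 ml columns", {
  cols <- defaultColumns10()                               # CL-2B, CL-4B, CL-6B
  evAmt <- vapply(cols, function(col) {
    poolWindow(collectFractions(elutionProfile(evSpecies(), col), col),
               7:10)$amountFmol
  }, 0)
  expect_lt(evAmt[1], evAmt[2])                            # CL-2B < CL-4B
  expect_lt(evAmt[2], evAmt[3])                            # CL-4B < CL-6B
})

test_that("doubling the bed raises window purity and lowers EV recovery at every resin", {
  resins <- presetResins()
  for (rn in c("CL-2B", "CL-4B", "CL-6B")) {
    ratio <- amount <- numeric(2)
    for (i in 1:2) {
      bed <- c(10, 20)[i]
      w <- if (bed == 10) 7:10 else 14:17
      col <- SECColumn(resins[[rn]], bed)
      pe <- poolWindow(collectFractions(elutionProfile(evSpecies(), col),
                                        col), w)
      pa <- poolWindow(collectFractions(elutionProfile(albSpecies(), col),
                                        col), w)
      ratio[i] <- pe$amountFmol / pa$amountFmol
      amount[i] <- pe$amountFmol
    }
    expect_gt(ratio[2], ratio[1])                          # purer
    expect_lt(amount[2], amount[1])                        # lower recovery
  }
})

test_that("larger load volumes monotonically reduce window purity", {
  col <- SECColumn(presetResins()[["CL-6B"]], 10)
  ratios <- vapply(c(0.5, 1, 2, 4), function(L) {
    pe <- poolWindow(collectFractions(elutionProfile(evSpecies(), col,
                                                     loadVolumeMl = L), col),
                     7:10)
    pa <- poolWindow(collectFractions(elutionProfile(albSpecies(), col,
                                                     loadVolumeMl = L), col),
                     7:10)
    pe$amountFmol / pa$amountFmol
  }, 0)
  expect_true(all(diff(ratios) <= 0))
})

test_that("window pooling sums amounts, derives concentration, and narrows as expected", {
  ser <- new("FractionSeries", species = "EV", fractionIds = 7:10,
             amountsFmol = c(1, 1, 1, 1), fractionVolumeMl = 0.5)
  pooled <- poolWindow(ser, 7:10)
  expect_identical(pooled$amountFmol, 4)
  expect_identical(pooled$concentrationPM, 2)              # 4 fmol / 2 ml

  # late-tailing albumin: the smaller window holds less albumin
  col <- SECColumn(presetResins()[["CL-6B"]], 10)
  serAlb <- collectFractions(elutionProfile(albSpecies(), col), col)
  expect_lt(poolWindow(serAlb, 7:9)$amountFmol,
            poolWindow(serAlb, 7:10)$amountFmol)

  # narrowing the EV window on CL-6B raises purity at the cost of yield
  serEv <- collectFractions(elutionProfile(evSpecies(), col), col)
  p4 <- poolWindow(serEv, 7:10)$amountFmol /
    poolWindow(serAlb, 7:10)$amountFmol
  p3 <- poolWindow(serEv, 7:9)$amountFmol /
    poolWindow(serAlb, 7:9)$amountFmol
  expect_gt(p3, p4)
  expect_lt(poolWindow(serEv, 7:9)$amountFmol,
            poolWindow(serEv, 7:10)$amountFmol)

  expect_error(poolWindow(ser, integer()), class = "evcompareConfigError")
  expect_error(poolWindow(ser, 5:8), class = "evcompareConfigError")
})
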
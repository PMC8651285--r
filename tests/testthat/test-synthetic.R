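# Synthetic experiment generator.

test_that("biofluid presets validate and order plasma above CSF protein levels", {
  pl <- defaultPlasmaConfig()
  cs <- defaultCsfConfig()
  expect_true(validObject(pl))
  expect_true(validObject(cs))
  expect_gt(pl@trueConcPM["ALB"], cs@trueConcPM["ALB"])
  expect_equal(unname(pl@trueConcPM["ALB"] / cs@trueConcPM["ALB"]), 200)
  # pure functions: repeated calls are identical
  expect_identical(defaultPlasmaConfig(), defaultPlasmaConfig())
  expect_identical(defaultCsfConfig(), defaultCsfConfig())
})

test_that("generation is bit-identical for identical seeds and differs across seeds", {
  cfg <- onePotStudyConfig(seed = 5L)
  d1 <- generateExperiment(cfg)
  d2 <- generateExperiment(cfg)
  expect_identical(measurementTable(d1), measurementTable(d2))
  expect_identical(d1@plateReadings, d2@plateReadings)
  expect_identical(d1@calibrationTables, d2@calibrationTables)
  d3 <- generateExperiment(onePotStudyConfig(seed = 6L))
  expect_false(identical(measurementTable(d1), measurementTable(d3)))
})

test_that("noise-free ideal-assay data reproduce the analytic expectations exactly", {
  cfg <- defaultPlasmaConfig(seed = 11L)
  cfg@dayCv <- 0
  ds <- generateExperiment(cfg, idealAssay = TRUE)
  gt <- groundTruth(ds)$expectedEluatePM
  m <- merge(measurementTable(ds), gt, by = c("method", "marker"))
  expect_equal(m$value_pM, m$expected_pM, tolerance = 1e-9)
})

test_that("end-to-end recovery on noise-free ideal data equals configured truth", {
  cfg <- onePotStudyConfig(seed = 21L, dayCv = 0)
  ds <- generateExperiment(cfg, idealAssay = TRUE)
  rep <- compareMethods(measurementTable(ds), reference = "M1")$plasma
  est <- vapply(rep$recoveries, combinedRecovery, 0)
  names(est) <- vapply(rep$recoveries, methodName, "")
  expect_equal(est[names(onePotTrueRecovery)], onePotTrueRecovery,
               tolerance = 1e-6)
})

test_that("estimated one-pot recoveries match configured truth within 15% over 50 seeds", {
  est <- matrix(0, nrow = 50, ncol = 4,
                dimnames = list(NULL, names(onePotTrueRecovery)))
  for (s in 1:50) {
    ds <- generateExperiment(onePotStudyConfig(seed = 3000L + s))
    rep <- compareMethods(measurementTable(ds), reference = "M1",
                          standardVolumeMl = 0.5)$plasma
    nm <- vapply(rep$recoveries, methodName, "")
    est[s, nm] <- vapply(rep$recoveries, combinedRecovery, 0)
  }
  meanEst <- colMeans(est)
  relErr <- abs(meanEst - onePotTrueRecovery) / onePotTrueRecovery
  expect_lt(max(relErr), 0.15)
})

test_that("the survey layout enumerates 12 conditions with the documented conventions", {
  cfg <- paperLayoutConfig("plasma", seed = 31L)
  expect_length(cfg@methods, 12L)
  nm <- vapply(cfg@methods, function(m) m$name, "")
  expect_setequal(
    nm,
    c("UC", "UC wash", "ExoQuick", "ExoQuick ULTRA", "Izon35 f7-10",
      "Izon70 f7-10", "CL-2B 10 ml f7-10", "CL-4B 10 ml f7-10",
      "CL-6B 10 ml f7-10", "CL-2B 20 ml f14-17", "CL-4B 20 ml f14-17",
      "CL-6B 20 ml f14-17"))

  # the second precipitation kit uses a 0.25 ml input
  ultra <- cfg@methods[[match("ExoQuick ULTRA", nm)]]
  expect_identical(ultra$inputVolumeMl, 0.25)

  # collected fraction windows: 6-21 on 10 ml beds, 12-27 on 20 ml beds
  ds <- generateExperiment(cfg, idealAssay = TRUE)
  ft <- ds@fractionTables
  f10 <- ft[ft$method == "CL-6B 10 ml f7-10", ]
  f20 <- ft[ft$method == "CL-6B 20 ml f14-17", ]
  expect_identical(range(f10$fraction), c(6L, 21L))
  expect_identical(range(f20$fraction), c(12L, 27L))

  # CSF flavour carries the same layout
  expect_length(paperLayoutConfig("csf")@methods, 12L)
})

test_that("default SEC physics reproduces the qualitative yield/purity findings", {
  ds <- generateExperiment(paperLayoutConfig("plasma", seed = 41L),
                           idealAssay = TRUE)
  gt <- groundTruth(ds)$expectedEluatePM
  val <- function(method, marker)
    gt$expected_pM[gt$method == method & gt$marker == marker]
  evSum <- function(method) sum(vapply(tetraspanins(),
                                       function(mk) val(method, mk), 0))

  # highest EV window amount among SEC conditions: the small-pore 10 ml column
  secNames <- grep("f7-10|f14-17", unique(gt$method), value = TRUE)
  evLevels <- vapply(secNames, evSum, 0)
  expect_identical(names(which.max(evLevels)), "CL-6B 10 ml f7-10")

  # 20 ml beds purer than 10 ml at the same resin under plasma albumin
  for (rn in c("CL-2B", "CL-4B", "CL-6B")) {
    p10 <- evSum(paste(rn, "10 ml f7-10")) / val(paste(rn, "10 ml f7-10"), "ALB")
    p20 <- evSum(paste(rn, "20 ml f14-17")) / val(paste(rn, "20 ml f14-17"), "ALB")
    expect_gt(p20, p10)
  }
})

test_that("method ranking by estimated recovery matches truth when recoveries differ by 30%", {
  trueOrder <- order(onePotTrueRecovery, decreasing = TRUE)
  hits <- vapply(1:60, function(s) {
    ds <- generateExperiment(onePotStudyConfig(seed = 7000L + s))
    rep <- compareMethods(measurementTable(ds), reference = "M1")$plasma
    nm <- vapply(rep$recoveries, methodName, "")
    est <- vapply(rep$recoveries, combinedRecovery, 0)
    identical(order(est[match(names(onePotTrueRecovery), nm)],
                    decreasing = TRUE), trueOrder)
  }, NA)
  expect_gte(mean(hits), 0.95)
})
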
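## CSV readers/writers for the pipeline's tabular interfaces, plate
## quantification, and the comparison report. CSVs are comma-separated,
## UTF-8, '.' decimal, header mandatory; malformed tables fail loudly.

readCsvStrict <- function(path, required) {
  if (!file.exists(path)) evConfigError(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing))
    evConfigError(sprintf("%s: missing required columns: %s", path,
                          paste(missing, collapse = ", ")))
  if (anyNA(df[required]))
    evConfigError(sprintf("%s: missing values in required columns", path))
  df
}

#' Read the pipeline's CSV interchange tables
#'
#' \code{readCalibrationTable}: columns \code{marker, concentration_pM,
#' replicate, aeb}. \code{readPlateReadings}: columns \code{sample_id,
#' marker, replicate, n_on, n_total}. \code{readMeasurementTable}: columns
#' \code{biofluid, method, marker, replicate_day, value_pM,
#' input_volume_ml}. All are strict: UTF-8, header required, missing
#' columns or values are configuration errors.
#'
#' @param path Path to a CSV file.
#' @return A data.frame with the validated columns.
#' @export
readCalibrationTable <- function(path) {
  df <- readCsvStrict(path, c("marker", "concentration_pM", "replicate",
                              "aeb"))
  if (any(df$concentration_pM < 0) || any(df$aeb < 0))
    evConfigError(sprintf("%s: concentrations and AEB must be >= 0", path))
  df
}

#' @rdname readCalibrationTable
#' @export
readPlateReadings <- function(path) {
  df <- readCsvStrict(path, c("sample_id", "marker", "replicate", "n_on",
                              "n_total"))
  if (any(df$n_on < 0) || any(df$n_total < 1) || any(df$n_on > df$n_total))
    evConfigError(sprintf("%s: need 0 <= n_on <= n_total", path))
  df
}

#' @rdname readCalibrationTable
#' @export
readMeasurementTable <- function(path) {
  df <- readCsvStrict(path, c("biofluid", "method", "marker",
                              "replicate_day", "value_pM",
                              "input_volume_ml"))
  if (any(df$value_pM < 0) || any(df$input_volume_ml <= 0))
    evConfigError(sprintf("%s: values must be >= 0 and input volumes > 0",
                          path))
  df
}

#' Write a synthetic dataset to a directory
#'
#' Emits \code{measurements.csv}, \code{calibration.csv},
#' \code{plate_readings.csv}, \code{fractions.csv}, a
#' \code{ground_truth.json} sidecar and a \code{run_info.json} provenance
#' record (package version, seed, config digest). Output is deterministic:
#' regenerating the dataset from the same seed reproduces the files
#' byte-for-byte.
#'
#' @param dataset A \code{\link{SyntheticDataset-class}}.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
writeDataset <- function(dataset, dir) {
  stopifnot(is(dataset, "SyntheticDataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("measurements.csv", "calibration.csv",
                            "plate_readings.csv", "fractions.csv",
                            "ground_truth.json", "run_info.json"))
  utils::write.csv(dataset@measurements, paths[1], row.names = FALSE)
  utils::write.csv(dataset@calibrationTables, paths[2], row.names = FALSE)
  utils::write.csv(dataset@plateReadings, paths[3], row.names = FALSE)
  utils::write.csv(dataset@fractionTables, paths[4], row.names = FALSE)
  jsonlite::write_json(dataset@groundTruth, paths[5], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  info <- list(
    package = "EVcompare",
    version = as.character(utils::packageVersion("EVcompare")),
    seed = dataset@config@seed,
    biofluid = dataset@config@biofluid,
    n_methods = length(dataset@config@methods),
    config_md5 = configDigest(dataset@config)
  )
  jsonlite::write_json(info, paths[6], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}

## md5 of the deparsed config, for provenance records
configDigest <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(list(
    biofluid = config@biofluid, seed = config@seed,
    trueConcPM = config@trueConcPM, dayCv = config@dayCv,
    nDay = config@nDayReplicates, nTech = config@nTechnicalReplicates,
    nCol = config@nColumnReplicates,
    methods = vapply(config@methods, function(m) m$name, "")
  )), tf)
  unname(tools::md5sum(tf))
}

#' Quantify a plate of well-array counts against calibration standards
#'
#' Fits one calibration curve per marker from the standards table, converts
#' each plate row's on-well count to AEB and then to a dilution-corrected
#' concentration, and averages technical replicates per sample and marker.
#' Rows counted fully "on" (occupied fraction 1) leave the digital regime
#' entirely and are rejected, naming the row.
#'
#' @param plate Plate-readings data.frame (see
#'   \code{\link{readPlateReadings}}) or path to one.
#' @param calibration Calibration data.frame (see
#'   \code{\link{readCalibrationTable}}) or path to one.
#' @param dilutionFactors Named per-marker dilution factors; defaults to the
#'   4x tetraspanin / 20x albumin convention.
#' @return A data.frame with one row per sample and marker: \code{sample_id,
#'   marker, value_pM, cv, flags}.
#' @export
quantifyPlate <- function(plate, calibration,
                          dilutionFactors = c(CD9 = 4, CD63 = 4, CD81 = 4,
                                              ALB = 20)) {
  if (is.character(plate)) plate <- readPlateReadings(plate)
  if (is.character(calibration))
    calibration <- readCalibrationTable(calibration)
  sat <- which(plate$n_on >= plate$n_total)
  if (length(sat))
    evConfigError(sprintf("saturated plate row(s): %s (all wells on)",
                          paste(sat, collapse = ", ")))
  curves <- fitCalibrationCurves(calibration)
  noCurve <- setdiff(unique(plate$marker), names(curves))
  if (length(noCurve))
    evConfigError(sprintf("no calibration curve for marker(s): %s",
                          paste(noCurve, collapse = ", ")))
  key <- interaction(plate$sample_id, plate$marker, drop = TRUE)
  out <- lapply(split(seq_len(nrow(plate)), key), function(idx) {
    rows <- plate[idx, , drop = FALSE]
    mk <- rows$marker[1]
    dil <- if (mk %in% names(dilutionFactors)) dilutionFactors[[mk]] else 1
    ests <- lapply(seq_len(nrow(rows)), function(i) {
      concentrationFromReading(WellArrayReading(rows$n_on[i],
                                                rows$n_total[i]),
                               curves[[mk]], dil)
    })
    avg <- averageTechnicalReplicates(ests)
    data.frame(sample_id = rows$sample_id[1], marker = mk,
               value_pM = avg@valuePM, cv = avg@cv,
               flags = paste(avg@flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$sample_id, res$marker), , drop = FALSE]
}

## Long measurement table -> per-biofluid lists of day-averaged,
## volume-corrected MethodMeasurement objects.
measurementsFromTable <- function(df, standardVolumeMl = 0.5) {
  lapply(split(df, df$biofluid), function(bdf) {
    methods <- unique(bdf$method)
    lapply(stats::setNames(methods, methods), function(met) {
      mdf <- bdf[bdf$method == met, , drop = FALSE]
      reps <- lapply(split(mdf, mdf$replicate_day), function(rdf) {
        vals <- stats::setNames(rdf$value_pM, rdf$marker)
        if (!hasAllMarkers(vals))
          evConfigError(sprintf(
            "method '%s': replicate missing one of CD9/CD63/CD81/ALB", met))
        correctInputVolume(
          MethodMeasurement(bdf$biofluid[1], met, vals,
                            inputVolumeMl = rdf$input_volume_ml[1]),
          standardVolumeMl
        )
      })
      averageDayReplicates(reps)
    })
  })
}

#' Compare isolation methods from a measurement table
#'
#' The full comparison pipeline on a long-format measurement table: each
#' method's replicates are corrected to the standard input volume, averaged,
#' and summarised as relative EV recovery against the chosen reference,
#' purity score, and fold changes versus the reference (EV recovery, albumin
#' and purity). Winners by yield and purity are reported per biofluid.
#' Purities compare eluate concentrations as measured, without correcting
#' for eluate-volume differences between methods; this mirrors standard
#' practice and is noted in the report.
#'
#' @param measurements Long measurement data.frame (see
#'   \code{\link{readMeasurementTable}}) or path to one.
#' @param reference Reference method identifier (required; no default).
#' @param standardVolumeMl Standard input volume for
#'   \code{\link{correctInputVolume}}.
#' @return A list with one element per biofluid, each containing
#'   \code{recoveries}, \code{purities}, \code{ranking}, \code{foldChanges}
#'   (data.frame vs the reference) and \code{notes}.
#' @export
compareMethods <- function(measurements, reference,
                           standardVolumeMl = 0.5) {
  if (is.character(measurements))
    measurements <- readMeasurementTable(measurements)
  if (missing(reference) || is.null(reference))
    evConfigError("a reference method must be given explicitly")
  perFluid <- measurementsFromTable(measurements, standardVolumeMl)
  lapply(perFluid, function(meas) {
    meas <- unname(meas)
    nm <- vapply(meas, methodName, "")
    if (!reference %in% nm)
      evConfigError(sprintf("reference method '%s' not present", reference))
    rec <- relativeRecovery(meas, reference)
    pur <- lapply(meas, purityScore)
    rnk <- rankMethods(rec, pur)
    refIdx <- match(reference, nm)
    fc <- data.frame(
      method = nm,
      recovery_fold = vapply(rec, function(r)
        foldChange(r, rec[[refIdx]]), 0),
      albumin_fold = vapply(pur, function(p)
        foldChange(p, pur[[refIdx]], component = "albumin"), 0),
      purity_fold = vapply(pur, function(p)
        foldChange(p, pur[[refIdx]]), 0),
      stringsAsFactors = FALSE
    )
    rownames(fc) <- NULL
    list(
      reference = reference,
      recoveries = rec,
      purities = pur,
      ranking = rnk,
      foldChanges = fc,
      notes = paste("Purity compares eluate concentrations as measured;",
                    "eluate-volume differences between pooled fractions and",
                    "resuspended pellets are not corrected.")
    )
  })
}

#' Write and print a comparison report
#'
#' \code{writeComparisonReport} serialises the output of
#' \code{\link{compareMethods}} to machine-readable JSON;
#' \code{formatComparisonTable} renders one biofluid's report as a
#' human-readable data.frame.
#'
#' @param report Output of \code{\link{compareMethods}}.
#' @param path JSON output path.
#' @param seed Optional seed to record in the report.
#' @return \code{writeComparisonReport} invisibly returns \code{path};
#'   \code{formatComparisonTable} returns a data.frame.
#' @export
writeComparisonReport <- function(report, path, seed = NULL) {
  out <- list(
    package = "EVcompare",
    version = as.character(utils::packageVersion("EVcompare")),
    seed = seed,
    biofluids = lapply(report, function(r) list(
      reference = r$reference,
      methods = r$ranking$table,
      fold_changes_vs_reference = r$foldChanges,
      high_yield = r$ranking$highYield,
      high_purity = r$ranking$highPurity,
      yield_tie = r$ranking$yieldTie,
      purity_tie = r$ranking$purityTie,
      notes = r$notes
    ))
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' @rdname writeComparisonReport
#' @param fluidReport One biofluid's element of the report list.
#' @export
formatComparisonTable <- function(fluidReport) {
  tab <- fluidReport$ranking$table
  fc <- fluidReport$foldChanges
  tab <- merge(tab, fc, by = "method", sort = TRUE)
  tab$winner <- ""
  tab$winner[tab$method == fluidReport$ranking$highYield] <- "high yield"
  tab$winner[tab$method == fluidReport$ranking$highPurity] <-
    trimws(paste(tab$winner[tab$method == fluidReport$ranking$highPurity],
                 "high purity"))
  tab
}
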
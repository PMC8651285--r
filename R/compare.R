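## Method-comparison statistics: relative EV recovery against a reference
## condition, the tetraspanin/albumin purity score, and ranking.

#' Rescale a measurement to a standard input volume
#'
#' Methods run with a smaller biofluid input (e.g. a 0.25 ml precipitation
#' input) are corrected by scaling all marker values by
#' \code{standardVolumeMl / inputVolumeMl} so that conditions are compared at
#' equal input (doubling the values of a 0.25 ml input at the 0.5 ml
#' standard). Idempotent once the input volume matches the standard.
#'
#' @param measurement A \code{\link{MethodMeasurement-class}} object.
#' @param standardVolumeMl Standard input volume in ml (default 0.5).
#' @return The corrected \code{MethodMeasurement}.
#' @export
correctInputVolume <- function(measurement, standardVolumeMl = 0.5) {
  stopifnot(is(measurement, "MethodMeasurement"))
  if (standardVolumeMl <= 0) evDomainError("standardVolumeMl must be > 0")
  f <- standardVolumeMl / measurement@inputVolumeMl
  measurement@markerValuesPM <- measurement@markerValuesPM * f
  measurement@inputVolumeMl <- standardVolumeMl
  validObject(measurement)
  measurement
}

#' Average isolation-day replicates
#'
#' Marker-wise arithmetic mean of repeated isolations of the same method
#' (performed e.g. on separate days, or on replicate columns); markers are
#' never mixed. The replicate count is recorded on the result.
#'
#' @param measurements A list of \code{\link{MethodMeasurement-class}}
#'   objects for the same biofluid and method.
#' @return A single averaged \code{MethodMeasurement}.
#' @export
averageDayReplicates <- function(measurements) {
  if (!length(measurements)) evConfigError("need at least one measurement")
  bio <- unique(vapply(measurements, function(m) m@biofluid, ""))
  met <- unique(vapply(measurements, function(m) m@method, ""))
  if (length(bio) != 1L || length(met) != 1L)
    evConfigError("day replicates must share biofluid and method")
  vol <- unique(vapply(measurements, function(m) m@inputVolumeMl, 0))
  if (length(vol) != 1L)
    evConfigError("day replicates must share the input volume")
  vals <- rowMeans(vapply(measurements,
                          function(m) m@markerValuesPM[evMarkers()],
                          numeric(4L)))
  MethodMeasurement(biofluid = bio, method = met, markerValuesPM = vals,
                    inputVolumeMl = vol,
                    nDayReplicates = length(measurements))
}

#' Relative EV recovery against a reference condition
#'
#' For each method, each tetraspanin's pM value is normalised to the same
#' tetraspanin in the reference condition, and the three ratios are averaged
#' to give the combined relative EV recovery. Albumin is excluded. The
#' reference condition must be chosen explicitly (different studies normalise
#' to different conditions) and its combined recovery is exactly 1.
#'
#' @param measurements A list of \code{\link{MethodMeasurement-class}}
#'   objects, one per method, including the reference.
#' @param reference Method identifier of the reference condition; its
#'   tetraspanin values must all be positive.
#' @return A list of \code{\link{RecoveryResult-class}} objects in input
#'   order.
#' @export
relativeRecovery <- function(measurements, reference) {
  nm <- vapply(measurements, function(m) m@method, "")
  if (!reference %in% nm)
    evConfigError(sprintf("reference method '%s' not present", reference))
  ref <- measurements[[match(reference, nm)]]@markerValuesPM[tetraspanins()]
  zero <- names(ref)[ref <= 0]
  if (length(zero))
    evConfigError(sprintf("reference tetraspanin %s is zero; ratios undefined",
                          paste(zero, collapse = ", ")))
  lapply(measurements, function(m) {
    ratios <- m@markerValuesPM[tetraspanins()] / ref
    new("RecoveryResult", method = m@method, perMarkerRatio = ratios,
        combinedRecovery = mean(ratios), reference = reference)
  })
}

#' EV purity score
#'
#' The ratio of the summed tetraspanin concentrations (CD9 + CD63 + CD81)
#' to the albumin concentration. Invariant under joint rescaling of all four
#' markers; strictly decreasing in albumin.
#'
#' @param measurement A \code{\link{MethodMeasurement-class}} object with
#'   albumin > 0.
#' @return A \code{\link{PurityResult-class}} object.
#' @export
purityScore <- function(measurement) {
  stopifnot(is(measurement, "MethodMeasurement"))
  alb <- unname(measurement@markerValuesPM["ALB"])
  if (is.na(alb) || alb <= 0)
    evDomainError(sprintf("method '%s': albumin must be > 0 (purity undefined)",
                          measurement@method))
  ts <- sum(measurement@markerValuesPM[tetraspanins()])
  new("PurityResult", method = measurement@method, tetraspaninSumPM = ts,
      albuminPM = alb, purity = ts / alb)
}

#' Rank methods by yield and purity
#'
#' Identifies the high-yield method (argmax combined relative recovery) and
#' the high-purity method (argmax purity score). Ties are broken by
#' lexicographic method name and reported.
#'
#' @param recoveries A list of \code{\link{RecoveryResult-class}} objects.
#' @param purities A list of \code{\link{PurityResult-class}} objects over
#'   the same method set.
#' @return A list with \code{highYield}, \code{highPurity}, logical
#'   \code{yieldTie} / \code{purityTie}, and a per-method summary
#'   \code{table} (data.frame sorted by method name).
#' @export
rankMethods <- function(recoveries, purities) {
  rn <- vapply(recoveries, function(r) r@method, "")
  pn <- vapply(purities, function(p) p@method, "")
  if (!setequal(rn, pn) || anyDuplicated(rn) || anyDuplicated(pn))
    evConfigError("recoveries and purities must cover the same method set")
  tab <- data.frame(
    method = rn,
    combined_recovery = vapply(recoveries, function(r) r@combinedRecovery, 0),
    purity = vapply(purities, function(p) p@purity, 0)[match(rn, pn)],
    albumin_pM = vapply(purities, function(p) p@albuminPM, 0)[match(rn, pn)],
    stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$method), , drop = FALSE]
  rownames(tab) <- NULL
  pick <- function(x) {
    best <- max(x)
    winners <- sort(tab$method[x == best])
    list(winner = winners[1], tie = length(winners) > 1L)
  }
  y <- pick(tab$combined_recovery)
  p <- pick(tab$purity)
  list(highYield = y$winner, highPurity = p$winner,
       yieldTie = y$tie, purityTie = p$tie, table = tab)
}

#' Fold change between two results
#'
#' Ratio \code{a / b} of two combined recoveries, two purities, two albumin
#' levels, or two plain numbers. Inputs may be
#' \code{\link{RecoveryResult-class}} or \code{\link{PurityResult-class}}
#' objects (compared on the same component) or numeric scalars.
#'
#' @param a,b Objects or numbers to compare; \code{b} must be positive.
#' @param component For \code{PurityResult} inputs, \code{"purity"}
#'   (default) or \code{"albumin"}.
#' @return The positive fold change \code{a / b}.
#' @export
foldChange <- function(a, b, component = c("purity", "albumin")) {
  component <- match.arg(component)
  val <- function(x) {
    if (is(x, "RecoveryResult")) return(x@combinedRecovery)
    if (is(x, "PurityResult"))
      return(if (component == "purity") x@purity else x@albuminPM)
    if (isScalarNumber(x)) return(x)
    evDomainError("foldChange expects results or numbers")
  }
  num <- val(a); den <- val(b)
  if (den <= 0) evDomainError("fold change denominator must be > 0")
  num / den
}
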
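#' Tetraspanin marker names
#'
#' The three transmembrane tetraspanins used as EV-abundance proxies
#' (CD9, CD63, CD81), and the full marker set including albumin, the
#' free-protein contamination marker.
#'
#' @return A character vector of marker identifiers.
#' @export
tetraspanins <- function() c("CD9", "CD63", "CD81")

#' @rdname tetraspanins
#' @export
evMarkers <- function() c(tetraspanins(), "ALB")

## Evaluate `code` under a fixed RNG seed, restoring global RNG state after.
withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

## Deterministic stream of sub-seeds (kept below 2^31) derived from one seed.
drawSubSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

## Classed conditions so callers (and the CLI wrapper) can map errors to
## exit codes: config/input errors vs domain errors vs fit failures.
evStop <- function(class, msg) {
  stop(structure(
    class = c(class, "evcompareError", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

evConfigError <- function(msg) evStop("evcompareConfigError", msg)
evDomainError <- function(msg) evStop("evcompareDomainError", msg)
evFitError    <- function(msg) evStop("evcompareFitError", msg)

isScalarNumber <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

## named-numeric check for marker maps
hasAllMarkers <- function(x) {
  is.numeric(x) && !is.null(names(x)) && all(evMarkers() %in% names(x))
}
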
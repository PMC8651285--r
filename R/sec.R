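## Size-exclusion chromatography elution model.
##
## Solutes partition between the mobile phase and the bead-internal pore
## volume according to a hard-sphere cylindrical-pore model; their mean
## elution volume is V0 + K * Vi. Band shapes combine a Gaussian dispersion
## core with a small heavy-tailed (Laplace) mixing component and are
## convolved with the rectangular sample plug. Particles small enough to
## enter the pores but comparable in size to them are partially retained by
## the matrix (hindered intraparticle transport), which is what makes
## large-pore resins lose EVs.

#' Hard-sphere partition coefficient
#'
#' Fraction of the bead-internal pore volume accessible to a spherical solute
#' of radius \code{r} in cylindrical pores of radius \code{rPore}:
#' \code{K = (1 - r/rPore)^2} for \code{r < rPore}, 0 otherwise. Strictly
#' decreasing in solute radius on \code{(0, rPore)}, 1 in the small-solute
#' limit and 0 at full exclusion.
#'
#' @param soluteRadiusNm Solute hydrodynamic radius in nm (> 0). Vectorised.
#' @param poreRadiusNm Pore radius in nm (> 0).
#' @return Partition coefficient(s) in \code{[0, 1]}.
#' @export
partitionCoefficient <- function(soluteRadiusNm, poreRadiusNm) {
  if (any(soluteRadiusNm <= 0) || any(poreRadiusNm <= 0))
    evDomainError("radii must be > 0")
  pmax(0, 1 - soluteRadiusNm / poreRadiusNm)^2
}

#' Mean elution volume for a given partition coefficient
#'
#' \code{Ve = V0 + K * Vi}: fully excluded solutes elute at the void volume,
#' fully included solutes at void plus internal volume. Linear in the bed
#' volume at fixed K.
#'
#' @param K Partition coefficient in \code{[0, 1]}.
#' @param column A \code{\link{SECColumn-class}} object.
#' @return Elution volume in ml.
#' @export
elutionVolume <- function(K, column) {
  stopifnot(is(column, "SECColumn"))
  if (any(K < 0 | K > 1)) evDomainError("K must lie in [0, 1]")
  voidVolume(column) + K * internalVolume(column)
}

## Cumulative mass fraction of one band below eluate volume v.
## Band = (1 - tailFraction) * Gaussian(center, sigma)
##      +      tailFraction  * Laplace(center, tailScale),
## convolved with the rectangular sample plug of width loadVolume centred on
## the band center. Closed forms; stable in the sigma -> 0 and load -> 0
## limits.
bandCdf <- function(v, center, sigma, loadVolume, tailFraction, tailScale) {
  eps <- 1e-12
  gauss <- if (loadVolume < eps && sigma < eps) {
    as.numeric(v >= center)
  } else if (sigma < eps) {
    stats::punif(v, center - loadVolume / 2, center + loadVolume / 2)
  } else if (loadVolume < eps) {
    stats::pnorm(v, center, sigma)
  } else {
    G <- function(z) z * stats::pnorm(z) + stats::dnorm(z)
    (sigma / loadVolume) *
      (G((v - center + loadVolume / 2) / sigma) -
       G((v - center - loadVolume / 2) / sigma))
  }
  if (tailFraction <= 0) return(gauss)
  lapCdf <- function(z) ifelse(z < 0, 0.5 * exp(z / tailScale),
                               1 - 0.5 * exp(-z / tailScale))
  lap <- if (loadVolume < eps) {
    lapCdf(v - center)
  } else {
    ## antiderivative of the Laplace CDF
    H <- function(z) ifelse(z < 0, 0.5 * tailScale * exp(z / tailScale),
                            z + 0.5 * tailScale * exp(-z / tailScale))
    (H(v - center + loadVolume / 2) - H(v - center - loadVolume / 2)) /
      loadVolume
  }
  (1 - tailFraction) * gauss + tailFraction * lap
}

## Fraction of molecules of radius r that survive passage (not retained by
## the matrix): included species are trapped with probability
## matrixTrapping * (r / rPore)^2, excluded species pass freely.
matrixSurvival <- function(r, rPore, matrixTrapping) {
  ifelse(r < rPore, 1 - matrixTrapping * (r / rPore)^2, 1)
}

#' Simulate the elution profile of a species
#'
#' Discretises the species' radius distribution into quantile nodes, computes
#' each node's partition coefficient, elution volume \code{V0 + K * Vi} and
#' band (Gaussian core of sd \code{dispersion * sqrt(Ve)} plus a small
#' Laplace-tailed mixing component, convolved with the rectangular load
#' plug), applies size-dependent matrix retention for pore-entering
#' particles, and accumulates the mixture on a uniform volume grid. Mass is
#' assigned to grid cells by exact CDF differences, so downstream fraction
#' binning conserves mass to machine precision.
#'
#' @param species A \code{\link{Species-class}} object.
#' @param column A \code{\link{SECColumn-class}} object.
#' @param loadVolumeMl Sample load volume in ml (> 0).
#' @param dispersion Band-broadening coefficient; the Gaussian sd of a band
#'   eluting at \code{Ve} is \code{dispersion * sqrt(Ve)} (units sqrt(ml)).
#' @param tailFraction Mass fraction in the heavy-tailed component.
#' @param tailScaleMl Laplace scale of the tail component (ml).
#' @param matrixTrapping Retention strength for pore-entering particles in
#'   \code{[0, 1]}; the trapped fraction at radius r is
#'   \code{matrixTrapping * (r/rPore)^2}.
#' @param nQuad Number of quantile nodes for a distributed radius.
#' @param gridStep Volume grid step in ml; must divide the fraction volume.
#' @return An \code{\link{ElutionProfile-class}}; its total mass is the input
#'   amount times the column recovery (1 minus the trapped fraction), up to
#'   the negligible mass outside the grid.
#' @export
elutionProfile <- function(species, column, loadVolumeMl = 0.5,
                           dispersion = 0.15, tailFraction = 0.02,
                           tailScaleMl = 1.5, matrixTrapping = 1,
                           nQuad = 400, gridStep = 0.025) {
  stopifnot(is(species, "Species"), is(column, "SECColumn"))
  if (loadVolumeMl <= 0) evDomainError("loadVolumeMl must be > 0")
  if (matrixTrapping < 0 || matrixTrapping > 1)
    evDomainError("matrixTrapping must lie in [0, 1]")

  radii <- if (species@geomSd <= 1) {
    species@medianRadiusNm
  } else {
    probs <- (seq_len(nQuad) - 0.5) / nQuad
    stats::qlnorm(probs, meanlog = log(species@medianRadiusNm),
                  sdlog = log(species@geomSd))
  }
  w <- rep(1 / length(radii), length(radii))

  rPore <- column@resin@poreRadiusNm
  K <- partitionCoefficient(radii, rPore)
  Ve <- elutionVolume(K, column)
  sigma <- dispersion * sqrt(Ve)
  surv <- matrixSurvival(radii, rPore, matrixTrapping)

  fv <- column@fractionVolumeMl
  nPerFraction <- fv / gridStep
  if (abs(nPerFraction - round(nPerFraction)) > 1e-9)
    evConfigError("gridStep must divide the fraction volume exactly")
  vMax <- max(column@lastFraction * fv,
              max(Ve) + loadVolumeMl / 2 + 8 * max(sigma)) + 4 * tailScaleMl
  edges <- seq(0, ceiling(vMax / gridStep) * gridStep, by = gridStep)

  mass <- numeric(length(edges) - 1L)
  for (i in seq_along(radii)) {
    cdf <- bandCdf(edges, Ve[i], sigma[i], loadVolumeMl, tailFraction,
                   tailScaleMl)
    mass <- mass + w[i] * surv[i] * diff(cdf)
  }
  ## clamp float-level negative increments from far-tail CDF differences
  mass <- pmax(mass, 0) * species@inputAmountFmol

  new("ElutionProfile", species = species@name,
      volumes = edges[-1L] - gridStep / 2, density = mass / gridStep,
      step = gridStep)
}

#' Bin an elution profile into numbered collected fractions
#'
#' Fraction \code{k} receives the profile mass over
#' \code{((k-1)*fv, k*fv]} ml; only the column's collected window
#' (\code{firstFraction:lastFraction}) is returned. The profile grid must
#' cover the collected window.
#'
#' @param profile An \code{\link{ElutionProfile-class}} object.
#' @param column A \code{\link{SECColumn-class}} object.
#' @return A \code{\link{FractionSeries-class}} object.
#' @export
collectFractions <- function(profile, column) {
  stopifnot(is(profile, "ElutionProfile"), is(column, "SECColumn"))
  fv <- column@fractionVolumeMl
  lastEdge <- column@lastFraction * fv
  gridEnd <- profile@volumes[length(profile@volumes)] + profile@step / 2
  if (gridEnd + 1e-9 < lastEdge)
    evConfigError("collected window exceeds the profile grid")
  ids <- seq(column@firstFraction, column@lastFraction)
  ## cells are aligned with fraction edges, so assignment is exact
  cellFraction <- ceiling(profile@volumes / fv - 1e-9)
  cellMass <- profile@density * profile@step
  amt <- vapply(ids, function(k) sum(cellMass[cellFraction == k]), 0)
  new("FractionSeries", species = profile@species,
      fractionIds = as.integer(ids), amountsFmol = amt,
      fractionVolumeMl = fv)
}

#' Pool a window of collected fractions
#'
#' Sums the amounts over the requested fraction window and derives the pooled
#' concentration from the pooled volume. Since amounts are in fmol and
#' volumes in ml, the pooled concentration is directly in pM.
#'
#' @param series A \code{\link{FractionSeries-class}} object.
#' @param window Integer fraction ids to pool (must be a subset of the
#'   collected fractions).
#' @return A list with \code{amountFmol}, \code{concentrationPM} and
#'   \code{window}.
#' @export
poolWindow <- function(series, window) {
  stopifnot(is(series, "FractionSeries"))
  window <- as.integer(window)
  if (!length(window)) evConfigError("empty pooling window")
  if (!all(window %in% series@fractionIds))
    evConfigError("window must lie within the collected fractions")
  amt <- sum(series@amountsFmol[match(window, series@fractionIds)])
  vol <- length(window) * series@fractionVolumeMl
  list(amountFmol = amt, concentrationPM = amt / vol, window = window)
}
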
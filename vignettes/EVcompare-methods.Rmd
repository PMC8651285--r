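---
title: "Models and methods behind EVcompare"
author: "EVcompare authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind EVcompare}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(EVcompare)
```

# The problem

Extracellular vesicles (EVs) in plasma or cerebrospinal fluid (CSF) are
isolated by methods — ultracentrifugation, polymer precipitation,
size-exclusion chromatography (SEC) — that differ greatly in how many EVs
they recover and how much free protein they drag along. EVcompare
implements a quantitative framework for that comparison: EV abundance is
proxied by three broadly expressed transmembrane tetraspanins (CD9, CD63,
CD81) measured in pM by an ultrasensitive digital immunoassay, free-protein
contamination is proxied by albumin, and each isolation condition is
summarised by two statistics:

* **relative EV recovery** — each tetraspanin's concentration normalised to
  the same tetraspanin in an explicitly chosen reference condition, the
  three ratios then averaged;
* **purity** — the sum of the three tetraspanin concentrations divided by
  the albumin concentration.

Because real plasma/CSF measurements are not recomputable at the desk, the
package pairs these statistics with a generative model of the whole
experiment — assay physics, SEC physics, replicate noise — so that every
pipeline stage can be validated against known ground truth.

# The digital immunoassay model

Beads carrying capture antibody are incubated with sample; labelled
immunocomplexes form on a bead at a rate proportional to analyte
concentration; beads are loaded into femtoliter wells that fit at most one
bead, and wells whose bead carries at least one label turn "on". With a
Poisson number of labels per bead at mean $\lambda$ (the AEB, *average
enzymes per bead*), the expected on-fraction is

$$ f_{\mathrm{on}} = 1 - e^{-\lambda}, \qquad
   \lambda = -\log(1 - f_{\mathrm{on}}), $$

and `aebFromFractionOn()` applies the exact inverse. The forward simulator
(`simulateDigitalReadout()`) uses
$\lambda = \kappa \, c / d + \lambda_0$ with capture efficiency $\kappa$
(per pM), dilution factor $d$ (4x for tetraspanins, 20x for albumin in the
presets, matching common practice) and additive background $\lambda_0$
(mean nonspecific labels per bead — background enters where nonspecific
binding physically occurs, on the bead, not as a pseudo-concentration).
On-well counts are binomial over the counted wells (50,000 by default).
Readings with $f_{\mathrm{on}} \ge 0.7$ are flagged saturated rather than
modelled: above that occupancy the measurement leaves the digital counting
regime, and we deliberately do not model the multi-label "analog" regime.

Calibration uses a four-parameter logistic on AEB versus standard
concentration,
$y = A + (B-A)\,c^h/(c^h + m^h)$, fitted by Levenberg–Marquardt
(`minpack.lm`). The sigmoid form is not dictated by the counting physics;
it is the standard monotone, saturating immunoassay calibration model and
is adopted as a definition. Fits with non-positive slope or collapsed
asymptotes are refused. Inversion (`concentrationFromReading()`) is only
defined strictly between the asymptotes: AEB at or below the blank response
is reported as 0 pM with a `blank_level` flag, anything at or above the
upper asymptote is clamped to the top of the standard range with an
`above_curve` flag, and values are never extrapolated beyond the standards.
Reported concentrations are dilution-corrected, i.e. neat-sample
equivalents — the package consistently reports on that scale since the
original convention (neat versus loaded) is ambiguous in common usage.

# The SEC model

A gravity column of bed volume $V_b$ has void volume $V_0 = 0.30\,V_b$ and
bead-internal (pore) volume $V_i = 0.60\,V_b$ by default. The void fraction
0.30 is anchored to the convention of collecting 0.5 ml fractions from
fraction 6 of a 10 ml column (about 3 ml of void); the porosity 0.60 is a
typical agarose figure. Only ordering properties, never these absolute
defaults, are asserted in tests.

A spherical solute of radius $r$ partitions into cylindrical pores of
radius $r_p$ with

$$ K = \left(1 - r/r_p\right)^2 \;\; (r < r_p), \qquad K = 0 \text{ otherwise}, $$

the simplest monotone hard-sphere exclusion model with the right limits,
and elutes on average at $V_e = V_0 + K V_i$. Published Sepharose pore
sizes (24 nm for CL-6B, 42 nm for CL-4B, 75 nm for CL-2B) are treated as
*diameters*; the preset pore radii are half those values. Whether those
figures are radii or diameters is genuinely ambiguous, so the package only
relies on their ordering, and the values are configurable.

EV hydrodynamic radii follow a log-normal distribution (median 50 nm,
geometric sd 1.5 by default — a typical small-EV size profile); albumin is
fixed at 3.5 nm. The radius distribution is discretised into 400 quantile
nodes.

**Band shape.** Each node's band is a Gaussian of sd
$\sigma = 0.15\sqrt{V_e}$ ml (spanning roughly 3–4 fractions at default
geometry), mixed with a small heavy-tailed component — 2% of the mass in a
Laplace kernel of scale 1.5 ml — and convolved with the rectangular sample
plug (0.5 ml load by default). The heavy tail represents the off-column
mixing, fronting and carry-over that real gravity columns exhibit. It is
load-bearing: with a purely Gaussian band, albumin sits more than five
standard deviations from the EV collection window on every default column,
cross-contamination underflows to $10^{-9}$ levels, and the central
yield/purity trade-off (albumin tailing into EV fractions, taller beds
buying purity, larger loads costing purity) becomes numerically invisible.
The 2%/1.5 ml defaults compress the across-column albumin range to the
1–2 orders of magnitude seen in practice; both are configurable
(`tailFraction`, `tailScaleMl`).

**Matrix retention.** Particles small enough to enter the pores but
comparable to them in size are partially retained by the matrix (hindered
intraparticle transport); the retained fraction at radius $r$ is
$(r/r_p)^2$ for $r < r_p$, zero for excluded particles. Small proteins
($r/r_p \le 0.3$) lose at most ~9%, while near-pore-size EVs are mostly
retained. This size-dependent loss is what makes large-pore resins
(CL-2B) yield *less* EV in the early window than small-pore resins
(CL-6B): without it, partial inclusion merely shifts EVs a few fractions
later — still inside the collected window at this column geometry — and
the pore-size/yield ordering inverts. The strength is configurable
(`matrixTrapping`, default 1), and the qualitative orderings it produces
(CL-6B > CL-4B > CL-2B EV yield in fractions 7–10 of a 10 ml bed; taller
beds purer but lower-yield; larger loads less pure) are exactly the
properties asserted in the test suite.

Profiles live on a 0.025 ml grid aligned with the 0.5 ml fraction
boundaries; cell masses are exact CDF differences, so binning into
fractions (fraction $k$ covering $((k-1)\cdot 0.5,\ k\cdot 0.5]$ ml,
numbered from the moment of loading) conserves mass to machine precision.
10 ml columns collect fractions 6–21; 20 ml columns collect 12–27; the EV
pool windows are 7–10 and 14–17 respectively. Amounts are carried in fmol
so that fmol/ml is numerically pM, making fraction concentrations an exact
derivation from amounts.

# Comparison statistics

`relativeRecovery()` implements the captioned arithmetic: per-tetraspanin
pM ratios against the reference, then the mean of the three ratios —
deliberately *not* the ratio of summed tetraspanins, which coincides only
when all markers share the reference's profile. The reference is a
required argument because different analyses normalise to different
conditions (a commercial column in the method survey, the conventional
CL-2B 10 ml column in the head-to-head comparison). `purityScore()` is the
tetraspanin sum over albumin. Day/column replicates are averaged
(`averageDayReplicates()`) *before* ratios are formed, mirroring how
repeated isolations are usually summarised. Methods run with smaller
inputs are first rescaled to the 0.5 ml standard
(`correctInputVolume()` — a 0.25 ml precipitation input is multiplied by
2). Purity compares eluate concentrations as measured, without correcting
for eluate-volume differences between 2 ml fraction pools and 0.5 ml
resuspended pellets; the report flags this convention, and total-amount
comparisons can be made from the emitted fraction tables if desired.

# The synthetic-experiment generator

`generateExperiment()` is the forward model. One-pot methods
(ultracentrifugation, precipitation) are phenomenological: a per-tetraspanin
true recovery and an albumin carryover, both in $[0,1]$ — these methods are
characterised only by their outputs, so a mechanistic model would be
overreach. SEC methods run the elution simulator and pool the configured
window. Replicate (day-to-day or column-to-column) scatter is multiplicative
log-normal with CV 0.15 by default, a typical inter-day immunoassay figure;
observed values then pass through the full simulate → calibrate → invert
assay chain. With `idealAssay = TRUE` and `dayCv = 0` the observables equal
the analytic expectations exactly, which is the anchor for the end-to-end
recovery tests. All randomness derives from one master seed; regeneration
is byte-identical.

The presets are synthetic stand-ins chosen once for realism, not
measurements: plasma at CD9/CD63/CD81 = 40/12/25 pM and albumin
$2\times10^5$ pM; CSF at roughly 5-fold lower tetraspanins and 200-fold
lower albumin. (Plasma albumin is physiologically far higher still; the
preset keeps the post-isolation albumin range within one calibration
curve's span while preserving the plasma ≫ CSF contrast that drives the
column recommendations.) Capture efficiencies and backgrounds are set per
marker so that simulated samples land mid-curve at the conventional 4x/20x
dilutions. The 12-condition survey layout (`paperLayoutConfig()`) covers
ultracentrifugation with and without wash, two precipitation kits (one
with a 0.25 ml input to exercise the volume correction), two commercial
columns, and CL-2B/4B/6B at 10 and 20 ml.

What the generator does *not* emulate: lipoprotein contamination (a
`Species` slot makes an extra contaminant species an easy extension),
matrix chemistry differences between precipitation kits, assay
cross-reactivity, and fraction-to-fraction carry-over. Passing tests
therefore demonstrate internal consistency of the statistics and the
stated physics, not fidelity to any particular real biofluid.

# Numerical choices and degenerate inputs

* Occupancy inversion uses `log1p`/`expm1`; inverse and forward maps agree
  to $10^{-12}$ over $\lambda \in [10^{-4}, 5]$.
* Calibration fits refuse designs with fewer than 4 distinct
  concentrations, no blank, saturated (non-finite AEB) standards, or no
  response variation; non-monotone fits are an error, not a warning.
* Band CDFs have closed forms with explicit $\sigma \to 0$ and load
  $\to 0$ limits, so the delta-band sanity checks hold exactly; float-level
  negative cell masses from far-tail CDF differences are clamped to zero.
* Ties in method ranking are broken lexicographically and reported as ties.
* Errors are classed conditions (`evcompareConfigError`,
  `evcompareDomainError`, `evcompareFitError`); the CLI wrapper maps
  configuration errors to exit code 2 and everything else to 1.

# Problem sizes

The shipped tests and the acceptance script use: 400-point grids for the
inversion checks, $10^5$-well simulated arrays, 20 seeds x 5
concentrations for the calibration round trip, 50 seeds for recovery
estimation and 100 seeds for ranking concordance on a four-method one-pot
study, and the three-column plasma preset with four column replicates for
the head-to-head comparison. These sizes give stable statistics in well
under a minute each.

# Known limitations

The partition model is hard-sphere/cylindrical-pore; real agarose has a
pore-size distribution. The matrix-retention law is a one-parameter
phenomenological choice validated only by its orderings. Albumin's
heavy-tailed band is a stand-in for several distinct physical effects
(overload fronting, wall channelling, incomplete washes). One-pot methods
have no mechanism at all. None of these limit the comparison statistics,
which operate on measured concentrations regardless of their origin.
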
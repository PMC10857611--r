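---
title: "Monte Carlo dosimetry of the mHDR-v2 and mHDR-v2r HDR 192-Ir sources"
author: "brachyMC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte Carlo dosimetry of the mHDR-v2 and mHDR-v2r HDR 192-Ir sources}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

High-dose-rate (HDR) brachytherapy with the microSelectron afterloader uses
a miniature 192-Ir source whose design was revised around 2010: the active
iridium core of the revised model ("mHDR-v2r") is 0.1 mm shorter and
0.05 mm narrower than the original ("mHDR-v2") and sits in an unchanged
capsule, leaving a dry-air gap.  Treatment planning relies on the TG-43U1
dose-calculation formalism, whose source-specific inputs -- air kerma
strength $S_K$, dose-rate constant $\Lambda$, radial dose function
$g_L(r)$, and 2D anisotropy function $F(r,\theta)$ -- are obtained from
Monte Carlo transport through a detailed source model.  Whether the small
design revision changes the dataset enough to matter clinically (a few
percent near the source poles) is exactly the kind of question this package
is built to answer: it implements the full pipeline -- analog photon
transport and simplified condensed-history electron transport through
constructive solid geometry, spherical $(r,\theta)$ tallies in a 40 cm
water sphere, air-kerma scoring in thin shells in vacuum, TG-43 extraction,
and an uncertainty budget -- at desk scale, with every stage testable in
isolation.

## Source models and coordinate convention

The two designs are transcribed into YAML parameter files
(`inst/extdata/sources/`, dimensions in mm).  The geometry is a coaxial
assembly on the $z$ axis: active core (cylinder, radius 0.325/0.300 mm,
length 3.6/3.5 mm, edges rounded with a 0.1 mm fillet approximated by the
union of two coaxial cylinders), capsule (stainless steel, outer diameter
0.9 mm, spherical tip cap of radius 0.45 mm, total length 4.5 mm), the
mHDR-v2r air gap (the 3.6 mm x 0.65 mm cavity minus the smaller core --
both annular and distal; the transcription choice is recorded in the
parameter file), and a 2 mm drive cable (cylinder, diameter 0.7 mm,
effective density 4.81 g/cm^3 for the stranded wire).  The capsule tip
points along $+z$; the polar angle $\theta$ is measured from $+z$, so
$\theta \approx 0^\circ$ is the distal side and $\theta \approx 180^\circ$
the cable side.  The origin is the core centre.  All lengths are handled in
cm internally.

Points are located by testing the region predicates in a fixed order
(core, gap, capsule, cable, phantom); ray tracing collects candidate
crossings of each finite surface (coaxial cylinders, capped planes,
spheres) and advances past the nearest one with a $10^{-9}$ cm nudge.  A
crossing may be an internal construction surface; transport simply
resamples the flight there, which is statistically exact for exponential
free paths.

## Physics model

The transport engine is deliberately simpler than a general-purpose shower
code, with each simplification chosen to be sub-percent for 192-Ir
energies (60-885 keV) in water, air and steel:

* **Free paths** are sampled by optical-depth marching: one exponential
  deviate per flight, consumed across region boundaries.  This is exact
  for heterogeneous media and -- because the number of random draws does
  not depend on the boundary structure -- keeps paired runs of the two
  designs synchronized history by history (common random numbers), which
  is what makes small anisotropy *differences* resolvable at desk scale.
* **Compton scattering** uses free-electron Klein-Nishina sampling (no
  Doppler broadening or binding).  The packaged incoherent cross sections
  are the matching free-electron Klein-Nishina values, so sampling and
  attenuation are mutually consistent; they sit 1-3% above bound-Compton
  compilations below ~100 keV, which largely cancels in the
  dose-to-kerma ratios that the TG-43 quantities are built from.
* **Photoelectric absorption** generates a photoelectron and, in iridium
  (K edge 76.1 keV), K fluorescence with probability 0.754 (K-shell
  fraction 0.787 times fluorescence yield 0.958) at the K-alpha/K-beta
  line energies; steel K X rays lie below the 10 keV cutoff and are
  deposited locally.
* **Rayleigh scattering** redirects the photon with an angle sampled by
  inversion of the cumulative $F^2(q)$ table built from the packaged
  atomic form factors, with the $(1+\cos^2\theta)/2$ rejection factor.
* **Electrons** (source beta/internal-conversion electrons and secondary
  electrons) use condensed-history stepping: step length
  $\min(\mathrm{cap}, f R_\mathrm{CSDA}, d_\mathrm{boundary})$ with cap
  0.005 cm (the step-size control of the scoring region) and $f = 0.05$;
  continuous energy loss from the Berger-Seltzer collision stopping power
  deposited at the step midpoint; Highland Gaussian multiple scattering
  per step.  No bremsstrahlung photons are generated (radiative yield
  below 1% at these energies; collision stopping powers only) and no
  knock-on electrons.  Electrons whose residual range cannot reach the
  current region boundary are absorbed on the spot (range rejection,
  exact here because dose is only scored in the phantom); in the phantom
  the same shortcut is taken only once the residual range falls below
  0.002 cm, well under every tally window width.
* **Cutoff**: 10 keV for photons and electrons; residual energy is
  deposited where the particle stops.

The cross-section and stopping-power tables are static CSV fixtures
generated once by `inst/scripts/generate_physics_tables.py` (Cromer-Liberman
photoelectric, exact Klein-Nishina incoherent, IT92 form-factor coherent
with a matched power-law tail, Berger-Seltzer stopping powers with ICRU
mean excitation energies; 212 log-spaced nodes from 10 to 1400 keV with
doubled nodes at the iridium K edge).  The mass energy-transfer
coefficients reproduce the standard mass energy-absorption compilation
within ~0.2% for water and air at 300-600 keV, which is what the kerma
chain is sensitive to.  The iridium metal density (22.42 g/cm^3) is not
part of the published source description and is recorded in the registry
as an overridable assumption.

## Emission spectra

The packaged photon spectrum is the 192-Ir line listing (gamma lines of
the beta- branch to 192-Pt and the EC branch to 192-Os, plus Pt/Os K and
L X rays) above the 10 keV cutoff, rescaled by a factor 0.9997 so its sum
is exactly the documented 2.2992 photons per decay.  The electron spectrum
combines an allowed-shape Fermi beta continuum (three branches, binned at
10 keV from 10 to 669 keV, normalized to 0.9192 electrons per decay) with
internal-conversion lines (normalized to 0.1531); Auger electrons fall
below the cutoff and are excluded, as are electrons above 669 keV.  The
continuum binning and normalization factors are recorded in the fixture
headers.  Because each simulated history carries one particle and rates
are scaled per decay afterwards, the TG-43 ratios are insensitive to the
overall normalization; it matters only for the absolute dose and kerma
rates, which enter $\Lambda$ as a ratio and cancel there too.

## Tallies and estimators

Deposits are binned in spherical $(r,\theta)$ bins whose volumes follow

$$V = \frac{2\pi}{3}\left[(r+\Delta r)^3 - (r-\Delta r)^3\right]
      \left[\cos\theta_{lo} - \cos\theta_{hi}\right],$$

with the angular edges written explicitly so that the one-sided pole
windows (clipped at 0 and 180 degrees) use the same formula.  Two layouts
are provided: `paperBinSpec()`, the publication-fidelity sparse windows
($\Delta r$ = 0.0025 cm for 0.05-1.5 cm and 0.025 cm for 2-20 cm;
$\Delta\theta$ = 0.1 deg at 1-degree centres, 0.5 deg one-sided at the
poles -- deposits between windows are counted in a gap ledger), and
`deskBinSpec()`, contiguous 0.1 cm radial bins (coarser beyond 1.55 cm)
with 4-degree angular bins whose centres include 90 and 170 degrees.  The
sparse windows faithfully reproduce the published aggregation but waste
most deposits; the desk grid trades window width for statistics, and every
reported number carries its window metadata.  Dose is scored only for
deposits in the phantom region (the aggregation region excludes the source
assembly), at the deposit location -- electron step midpoints, not photon
interaction sites -- so no charged-particle-equilibrium assumption enters.

Scoring dose at the deposit location matters even at 1 cm: secondary
electrons deposit their energy a mean ~0.01 cm downstream of the photon
interaction, and with the kerma gradient $d\ln K/dr \approx -2.1$/cm this
makes absorbed dose about 2% higher than collision kerma there (the
reference runs measure the ratio as 1.021).  The headline dose-rate
constant therefore cannot be taken from a collision-kerma estimate alone.
Because the single-bin analog dose is statistically heavy-tailed (its
seed-to-seed error at desk history counts is ~1.4%, roughly twice what the
batch estimate suggests), the reference runs estimate
$\dot D(1\,\mathrm{cm}, 90^\circ)$ as the collision kerma in that window
times the dose-to-collision-kerma ratio $\beta$ pooled over the 60--120
degree band at r = 1 cm ($\beta$ is the displacement correction, smooth in
$\theta$ at fixed r, so the pooling is unbiased); this cuts the
dose-rate-constant error to ~0.5% at the same history counts.

Air kerma uses twelve 1 mm dry-air shells centred at 10-120 cm with vacuum
elsewhere, scored in a transverse window ($|r - r_i| < 0.05$ cm,
$|\theta - 90^\circ| < 1^\circ$).  Two estimators are implemented: analog
energy transfer at sampled interaction sites (Compton recoil energy plus
non-radiated photoelectric energy; Rayleigh transfers nothing), and a
track-length estimator that scores $E \,(\mu_{tr}/\rho)\, \rho\, \ell$ for
every shell crossing.  The two agree by construction in expectation (the
packaged $\mu_{tr}$ is derived from the same interaction model) and are
cross-checked in the tests; the track-length estimator is used for the
headline $S_K$ runs because every history contributes to every shell,
whereas analog collisions in 1 mm of air are too rare at desk scale.
$\dot K(r)\, r^2$ is fitted against $r$ by unweighted least squares
(a weighted option exists) and $S_K$ is the intercept at $r = 0$.

Variance comes from history batches (20 by default): per-bin batch sums
are returned from the kernel and reduced in R in a fixed order, so results
are bit-identical for any worker partition of a run.  Every history draws
its own counter-based xoshiro256++ substream keyed by (master seed,
history index); secondary particles use a second per-history stream so
their variable draw counts cannot desynchronize the primary photon stream.

## TG-43 extraction

The line-source geometry function $G_L(r,\theta) = \beta/(L r \sin\theta)$
(with $1/(r^2 - L^2/4)$ on the axis) uses each model's own active length
(0.36 cm for mHDR-v2, 0.35 cm for mHDR-v2r).  $g_L$ and $F$ follow the
standard ratios, exactly 1 at the 1 cm / 90 degree references by
construction, with relative standard errors combined in quadrature.
$\Lambda = \dot D(1\,\mathrm{cm}, 90^\circ)/S_K$ combines the per-decay
photon-source and electron-source dose tables (the electron-source
contribution at 1 cm is consistent with zero at desk statistics -- source
electrons of up to 669 keV are stopped by the capsule and the first
millimetres of water).  Dataset comparisons report
$100\,(F_A/F_B - 1)$ on the common grid with quadrature SEs; paired
same-seed runs make these differences far more precise than the individual
functions.

## Desk-scale problem sizes

The published dataset used $10^{11}$ dose histories and $10^{12}$ kerma
histories per source.  The package's reference runs (the acceptance script
and the heavy tests) use, per source design: $2\times 10^7$ photon and
$3\times 10^6$ electron histories for dose on the desk grid, $10^7$ photon
histories for the kerma series with the track-length estimator, and
$3\times 10^7$ photon histories for the paired anisotropy windows at
(0.5, 1.0 cm) x (90, 170 deg) with the collision-kerma estimator -- about
10 minutes for the full two-source comparison on one CPU.  At these sizes
the (1 cm, 90 deg) dose-rate bin carries a ~0.7% standard error and the
paired anisotropy differences resolve to ~0.2-0.3 percentage points.
Analog dose scoring in the pole windows, by contrast, cannot resolve the
design differences at desk scale: the design change displaces interaction
sites by more than a bin width, so common random numbers cannot pair the
rare pole-bin deposits, and replicate scatter stays at several percentage
points.  That is why the design-difference comparison runs on the
collision-kerma estimator, in which every window crossing contributes and
the dose-vs-kerma displacement cancels between the two designs.

## Numerical choices and degenerate inputs

Boundary crossings are nudged by $10^{-9}$ cm; ties between coincident
construction surfaces resolve by the fixed region order.  Table lookups
use log-log interpolation, exact at nodes; energies outside 10-1400 keV
are errors rather than extrapolations.  Tally windows must not overlap
(validity-checked); zero-volume bins and zero-history runs raise errors in
finalization rather than NaNs.  The Highland angle is capped at 1.5 rad to
guard the Gaussian tail.  The multiple-scattering hinge uses PDG-formula
radiation lengths.  The air-kerma fit refuses fewer than 3 points.

## What the synthetic fixtures do and do not show

`makeAttenuatingLineSource()` injects a dose table of the exact form
$G_L\, e^{-a(r-1)}(1 - b\cos^2\theta)$ *after* the transport stage, so the
TG-43 algebra must recover $g_L = e^{-a(r-1)}$ and $F = 1 - b\cos^2\theta$
to machine precision -- this isolates the extraction math from Monte Carlo
noise.  `makePointSourceVacuum()` transports a monoenergetic photon
through a vanishing source in vacuum, where kerma must follow the
inverse-square law and the absolute analytic value
$E (\mu_{tr}/\rho)/(4\pi r^2)$.  Passing these shows the pipeline stages
are individually correct; it does not validate the bound-Compton,
Doppler, polarization, Auger or bremsstrahlung physics that the engine
deliberately omits, nor manufacturing variations of real sources (the
uncertainty budget carries those as type B terms, including the
"dynamic source design" lateral-shift maximum that is combined in
quadrature despite being a bound, to match the published convention).

## Known limitations

The source dimension files transcribe published engineering drawings, and
some features of those drawings (the exact tip and edge curvatures, the
axial placement of the revised design's air gap, the shape of the proximal
weld where the cable attaches) are under-determined by the text that
accompanies them; the parameter files record one explicit transcription
choice for each.  The polar anisotropy differences between the two designs
are sensitive to exactly these features: with the transcription shipped
here the differences computed at (0.5--1 cm, 170 degrees) are about
-1 to -1.5%, and a sensitivity scan over the under-determined features
(gap placement, proximal capsule length, cable diameter and length) moves
them by no more than ~0.7 percentage points, so comparisons of this
package's design differences against other published datasets should keep
that transcription sensitivity in mind.

Electron transport is a first-order condensed-history scheme (no dual
hinge, no energy-loss straggling, no delta rays): source-electron dose
within the first millimetre of the capsule is qualitative rather than
benchmark-grade.  The free-electron Compton model overstates attenuation
coefficients by 1-3% below ~100 keV; absolute dose and kerma rates
inherit part of this, while the TG-43 ratios are much less sensitive.
Tip and edge fillets are cylinder-union approximations of the drawn
curvatures.  The air-gap placement in the revised design is a
transcription choice from the drawing.  No positrons (no 192-Ir emission
above threshold in this model), no variance reduction beyond range
rejection in unscored regions, and no moving (stepping) source positions.

## A worked example

```{r example}
library(brachyMC)

m <- buildSourceModel("mHDR-v2r")
spec <- deskBinSpec()
g <- runPhotonHistories(m, spec, 2e6, seed = 1)
dose <- finalizeDose(g)
doseAt(dose, 1, 90)           # Gy per Bq s at (1 cm, 90 deg)

ks <- simulateAirKermaSeries(m, 1e6, seed = 2)
sk <- airKermaStrength(ks)
doseRateConstant(dose, sk$SK, sk$se)   # cGy / (h U)

# full paired extraction (heavier):
# ds_v2r <- runTG43Pipeline("mHDR-v2r", 3e7, 3e6, 1e7, seed = 1)
# ds_v2  <- runTG43Pipeline("mHDR-v2",  3e7, 3e6, 1e7, seed = 1)
# compareDatasets(ds_v2, ds_v2r)$F
```
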
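---
title: "Models and methods in radbiodose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in radbiodose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radbiodose)
```

`radbiodose` implements the quantitative chain used to compare an
alpha-emitting radiopharmaceutical ([211At]NaAt) with a beta-emitting one
([131I]NaI) in NIS-expressing thyroid-cancer models: cellular S-values from
Monte Carlo transport, the in vitro treatment absorbed dose, DNA
double-strand-break (DSB) and clonogenic dose-response fitting with relative
biological effectiveness (RBE), and biodistribution-based tumour dosimetry.
This vignette records the models, the parameters that matter, and the design
choices made where the methods were genuinely open.

## Decay data

Two nuclides are embedded. At-211 (half-life 7.214 h) decays through two
exclusive branches: direct alpha emission (41.8%, 5.87 MeV) and electron
capture to Po-211 (58.2%), whose 7.45 MeV alpha follows within a second, so
the daughter is folded into the parent inventory in secular equilibrium.
I-131 (8.0252 d) carries its four main beta transitions (sampled as an
allowed-shape spectrum from the endpoint; the Coulomb correction is omitted,
a few-percent effect on the mean) and five principal gamma lines.

The per-decay energy release is pinned to the constants used downstream in
organ dosimetry, 6927 keV (At-211) and 570 keV (I-131), rather than
recomputed from the inventory; `nuclide_energy_check()` verifies the
inventory stays within 5% of the pinned value (it is 1.1% and 2.4% low,
respectively — conversion and Auger electrons are not carried, since
emission kinds are restricted to alpha/beta/gamma).

## Monte Carlo S-values

The assay geometry is a stack of coaxial cylinders — dish (1 mm), cell
layer (3 um), radioactive solution — with two presets matching the exposure
wells: `dsb_well` (diameter 11.1 mm, solution 3.3 mm) and `colony_well`
(34.6 mm, 2.1 mm). All media are unit-density water; the dish material is
not specified in the study and water-equivalence affects only backscatter.

Transport is deliberately simple and fully vectorised:

* **Alpha particles** travel in straight lines, depositing energy at the
  tabulated stopping-power rate (continuous slowing down). The embedded
  stopping-power table was calibrated, at construction time, against
  published CSDA ranges (49 um at 5.87 MeV vs ~47.5 reference).
  Delta-ray energy stays on the track — at 3 um layer thickness this
  slightly overestimates self-dose and underestimates cross-dose.
* **Electrons** use the same straight-path scheme with an effective path of
  `beta_detour_factor` (default 0.9) times the CSDA range, standing in for
  multiple scattering. This is the main known bias: a thin target misses
  the path-lengthening and backscatter that condensed-history codes model,
  so beta S-values come out low. The acceptance report computes the ratio
  of each Monte Carlo estimate to the study's printed values: the At-211
  (alpha-dominated) pair reproduces to within a few percent, while the
  I-131 pair comes out at roughly 0.6 (cell self-dose) and 0.85
  (solution-to-cell) of the printed values — a documented consequence of
  the simplified electron physics, never silently corrected.
* **Photons** escape by default: the interaction probability of a 80-700
  keV photon in micrometres-to-millimetres of water makes their dose to the
  cell layer a sub-percent term. A thin-target kerma mode
  (`gamma_mode = "kerma"`) is available to bound the neglected term.

Energy is conserved per history by construction (the range-energy
interpolants are exact inverses of each other), and every result records
its seed, history count and per-history standard error. The S-value is the
mean energy deposited in the cell layer per decay divided by the layer
mass.

The printed S-value pair (33.5/0.247 nGy per decay for At-211, 355/9.74 pGy
for I-131) corresponds to the colony-well geometry — our estimate of the
At-211 self-dose S lands within 1% of it — and these printed values, not
the Monte Carlo estimates, feed the treatment-dose reproduction, keeping
the two routes separate.

## Treatment absorbed dose

The dose to cells over a treatment of duration $t_T$ is

$$D_T = \kappa\,\frac{1-e^{-\lambda_p t_T}}{\lambda_p}
  \left(f A_0 S_{c\to c} + (1-f) A_0 S_{s\to c}\right),$$

with $\lambda_p$ the physical decay constant, $A_0$ the administered
activity and $f$ the fraction of it in the cells at the end of treatment
(measured: 0.116 for astatide, 0.325 for iodide after 30 min uptake).

The factor $\kappa$ (default 0.5) is the one genuinely open choice: applied
literally to the end-of-treatment partition the equation gives exactly
twice the published doses for *both* nuclides (14.09 vs 7.05 Gy; 0.438 vs
0.219 Gy). Halving the bracketed term — interpretable as averaging a
linear uptake over the treatment — reproduces both printed doses, so
$\kappa = 0.5$ is the default and the convention is exposed rather than
hidden. Whether the halving should apply asymmetrically to one term only
cannot be decided from the available information; the symmetric form is
adopted. With the printed S-values this yields 7.044 and 0.2191 Gy for
1 MBq, agreeing with the published 7.05 and 0.219 to the printed
resolution.

## DSB quantification

The damage percentage is an area ratio: each channel is thresholded (Otsu
by default; a fixed threshold is available) and
$\mathrm{DSB\%} = 100\,|damage| / |damage \cup nuclei|$, with nuclear
morphology taken as the union of the two masks, following the reported
area definition (damage + nucleus area in the denominator). The dose
response is fitted by ordinary least squares with a free intercept, since
control wells show a nonzero baseline; for linear responses the iso-effect
RBE is the slope ratio.

Otsu thresholding requires a minimally populated foreground: a noisy
control image whose damage channel holds a fraction of a percent of
positive pixels can collapse the threshold into the noise floor. Such
images should use `method = "fixed"`; the noiseless control case is exact.

## Clonogenic survival

Surviving fractions are colony counts normalised to seeded cells and the
control plating efficiency. Fits run on $-\ln SF$ against $(D, D^2)$ with
$\alpha, \beta \ge 0$ (boundary solutions handled by comparing the
constrained candidates), matching the radiobiological convention of a
linear fit for the alpha emitter and a linear-quadratic fit for the beta
emitter. Two statistical choices matter:

* **Weights.** With counts available, `prepare_survival_data()` builds
  inverse-variance weights $n_i/(1-p_i)$ from the Binomial model, plus the
  standard deviation of the shared plating-efficiency error. The shared
  term is essential: it moves every $-\ln SF$ coherently, and ignoring it
  makes 95% intervals undercover (85/100 instead of 93/100 in our
  replicate suite).
* **Dose cutoff.** The study excluded high-dose alpha points from its fit
  (heterogeneous cellular uptake); the reported threshold differs between
  two passages (1 Gy in the figure caption vs 5 Gy in the discussion), so
  `dose_cutoff` is an explicit argument defaulting to 1 Gy — the value
  attached to the fit actually shown — and both values are exercised in
  tests.

Iso-effect doses use the closed forms ($-\ln L/\alpha$; positive
quadratic root), and `rbe_at_level()` reports the reference/test dose
ratio at 10% survival with an optional seeded residual bootstrap. The
published RBEs (1.61 for DSB induction, 1.60 at 10% survival) derive from
figure data whose raw pairs are not printed, so they are not exact
reproduction targets; the acceptance suite instead recovers synthetic
assays constructed at a true ratio of 1.6, under the study's conditions
(1000 cells/well, triplicate wells, the eight published activity levels
converted to dose, cutoff 1 Gy for the alpha-like arm).

## Biodistribution dosimetry

Organ kinetics arrive as %AA/g (physical decay included; 1 %AA/g of 1 MBq
= 1e4 Bq/g). The time-integrated activity concentration offers two
schemes, both stored in the result: `trapezoid_physical_tail` (default) —
linear rise from injection to the first sample, trapezoids between
samples, then a mono-exponential tail at the faster of the fitted terminal
rate and the physical constant — and `monoexp_fit`, a single exponential
through all samples integrated from zero to infinity. Non-decaying fitted
rates fall back to the physical constant with a warning. The absorbed-dose
coefficient is then
$\tilde A \times E_{decay} \times 1.602\times10^{-16} \times 10^3$ Gy/MBq,
with absorbed fraction 1 for tumour self-dose and an optional radiation
weighting factor (5 is the recommended value for alpha-particle equivalent
dose; the default 1 reports absorbed dose). The published tumour
coefficients (0.115 and 2.754 Gy/MBq) rest on graphical biodistribution
data, so the chain is validated against quadrature oracles and synthetic
kinetics instead; with a realistic tumour uptake of 5 %AA/g at 3 h and
clearance at the iodide/astatide rates, the synthetic coefficients come
out at the published order of magnitude.

Tumour regrowth is operationalised as the first measured day after the
series minimum at which relative size exceeds 1.2 times the minimum on two
consecutive measurements — the confirmation requirement means detection
lags the true regrowth start by up to one sampling interval plus
$\ln(1.2)/g$ days at growth rate $g$. Group comparisons reproduce the
study's convention: pooled-variance unpaired t-tests with Bonferroni
multiplication, capped at 1.

## Synthetic data generators

Each generator is seeded, returns its ground truth beside the data, and
emulates the statistical structure one analysis stage assumes: DSB image
pairs with damage areas exactly linear in dose (disk nuclei, centre-out
damage pixels, Gaussian intensity noise), Binomial colony counts under the
survival model, log-normal organ kinetics around mono-exponential means
(effective rate floored at physical decay), and shrink/flat/regrow tumour
curves with log-normal animal noise and day-0 values exactly 1. They do
not attempt realistic nuclear morphology, microscope optics, inter-animal
correlation, or multi-compartment kinetics — so passing recovery tests
demonstrates estimator correctness under the assumed noise models, not
robustness to real-world artefacts.

Noise defaults (image noise SD 0.05, organ CV 0.1-0.15, tumour CV 0.1,
plating efficiency 0.6) are choices the source material does not state,
picked as typical for fluorescence microscopy, gamma-counter
biodistribution and xenograft assays.

## Numerical choices and problem sizes

Range-energy tables use 2000-point log grids whose forward and inverse
interpolants share knots, making energy bookkeeping exact to floating
point. Sub-keV charged particles deposit locally (sub-0.1 um range). The
series expansion of $(1-e^{-\lambda t})/\lambda$ switches on at
$\lambda t < 10^{-8}$ so the stable limit returns $t$ exactly.
Default Monte Carlo runs use 1e5 histories (per-mille-level standard
errors on self-dose S-values, seconds of runtime); the test suite uses
2e3-3e4 histories per check and 100-200 replicates for coverage and
recovery suites, sizes at which every asserted tolerance is comfortably
resolved.

## Known limitations

* Electron transport is straight-path CSDA with a detour factor; thin-layer
  beta S-values are biased low (see above). Alpha-dominated results are
  unaffected.
* Photon dose to the cell layer is neglected by default (escape mode).
* The kappa = 0.5 partition averaging is a convention that reproduces the
  published doses, not a kinetic uptake model.
* Otsu segmentation is unreliable on noisy, nearly empty channels.
* Biodistribution integration assumes mono-exponential behaviour beyond
  the last sample; with only two sampling times, the tail carries most of
  the integral and its rate assumption dominates the result.
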
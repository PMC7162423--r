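---
title: "Models and methods in tatdose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in tatdose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tatdose)
```

`tatdose` implements the quantitative analysis chain of a preclinical
targeted alpha-particle therapy (TAT) experiment in which a ²¹²Pb-labelled
antibody is administered systemically and its uptake, dose and therapeutic
effect are measured in small animals. This vignette is the package's own
account of each model, its assumptions, the numerical choices made, and
what the synthetic-data generators do and do not emulate.

## Organ kinetics and cumulated activity

Organ time–activity curves (TACs) are modelled as a single-compartment
rise-and-decay process,

$$A(t) = A_0\,\bigl(1 - e^{-\lambda_r t}\bigr)\,e^{-\lambda_d t},$$

with $A_0$ an activity scale (Bq/g), $\lambda_r$ the uptake (rise) constant
and $\lambda_d$ the effective washout/decay constant, both in h⁻¹. The
decay factor is implemented with a *negative* exponent, $e^{-\lambda_d t}$:
a positive exponent would make activity grow without bound, which is
unphysical for a washout term described by a decay constant. This is stated
prominently because the model is sometimes typeset with the sign dropped.

`fit_time_activity()` minimizes squared residuals on the linear activity
scale (not the log scale — low late-time activities would otherwise
dominate) using bounded Levenberg–Marquardt with multiple starts:
$\lambda_d$ is started at, among others, the physical ²¹²Pb decay constant
$\ln 2 / 10.64\,\mathrm{h}^{-1}$, and $\lambda_r$ at the reciprocal of the
earliest sampling time; $A_0$ is started at its closed-form conditional
least-squares value. Bounds $A_0 \ge 0$, $\lambda_r > 0$, $\lambda_d \ge 0$
are enforced in the optimizer. At least three distinct positive sampling
times are required; an all-zero TAC returns a degenerate fit flagged with
$A_0 = 0$ rather than an error, since truly empty organs are a legitimate
observation.

Cumulated activity over a window $[a, b]$ (default 0–24 h, the window over
which the biodistribution sampling at 2, 4, 8 and 24 h constrains the
curve; a 72 h sample exists in such designs but the window is a parameter)
uses the closed-form antiderivative: the integrand splits into
$A_0 e^{-\lambda_d t} - A_0 e^{-(\lambda_r+\lambda_d)t}$, each term
integrating to $(e^{-\lambda a} - e^{-\lambda b})/\lambda$ with the
$\lambda \to 0$ limit $b - a$ substituted analytically below $10^{-12}$
rather than risking division by zero. The factor 3600 converts Bq·h to
disintegrations. The test suite verifies agreement with adaptive
quadrature to below $10^{-8}$ relative error over a randomized parameter
sweep.

## Absorbed dose and the decay-chain energy model

Converting disintegrations per gram to absorbed dose requires the mean
energy deposited locally per parent decay, $\Delta$. ²¹²Pb is an in vivo
generator: the dose comes from the chain
²¹²Pb → ²¹²Bi → {²¹²Po, ²⁰⁸Tl} → ²⁰⁸Pb. Nuclear data (branch fractions,
mean emission energies per decay step) are *not* hardcoded: they live in a
versioned JSON configuration (`inst/extdata/pb212_chain.json`) with a
provenance string citing the NNDC/ICRP-107 decay data they were taken
from, and `chain_mean_energy()` simply computes
$\Delta = \sum \text{occupancy} \times \text{fraction} \times E$ over the
included radiation classes. The default includes alpha and mean beta
energies and excludes photons — the standard small-scale dosimetry
assumption for alpha emitters in millimetre-scale tissue volumes, where
charged particles deposit locally and photons escape. With the shipped
configuration $\Delta_{\alpha+\beta} \approx 8.42$ MeV per ²¹²Pb decay.
The dose conversion is then

$$D\,[\mathrm{Gy}] = \tilde{A}\,[\mathrm{dis/g}] \times \Delta\,[\mathrm{MeV}]
  \times 1.602\times 10^{-13}\,\mathrm{J/MeV} \times 1000\,\mathrm{g/kg}.$$

Organ dose tables report Gy per injected MBq to three decimals, the
conventional reporting layout. Because published organ-dose tables of this
kind do not state their energy set or organ-mass assumptions, they serve
here as a format reference, not a numeric target.

## Autoradiography calibration and uptake

A phosphor plate exposed to calibration standards of known activity
(default 1, 2, 4 and 10 Bq, 23 h exposure) defines an affine map
`intensity = slope × activity + intercept`. The intercept is left free to
absorb plate background rather than forcing the line through the origin;
$r^2$ and the parameter covariance are reported so linearity and
extrapolation error can be audited. Standards and tissue sections share
the same exposure duration and isotope, so radioactive decay during
exposure scales both sides of the map identically and cancels; no decay
integral is needed.

`intensity_to_activity()` inverts the map pixel-wise and clips negative
results at zero. Significant uptake is declared above
`mean(healthy) + 1.96 × SD(healthy)` (sample SD, $n-1$), the two-sided
$P < 0.05$ criterion. Two remarks. First, the upper-tail *exceedance* of
this rule on a symmetric distribution is ≈2.5%, not 5% — 1.96 is the
two-sided 5% quantile — and the tests assert the correct ~2.5% property.
Second, the rule is affine-equivariant, so in end-to-end use the package
thresholds on the raw intensity scale (as one would on the image itself)
and maps through the calibration; this avoids the degenerate case where an
overestimated intercept plus zero-clipping flattens the healthy-pixel
distribution.

Per-region uptake sums pixel activities under an integer label mask
assumed pre-aligned to the autoradiograph grid (co-registration is out of
scope; a nearest-neighbour resampling helper handles mismatched pixel
sizes). Per-gram concentrations distribute the section mass over regions
in proportion to pixel area, valid for cryosections of uniform thickness
(20 µm is typical). Both the per-region total (Bq) and the per-gram value
are exposed, since published per-region numbers can be either.

## Diffusion tensor and kurtosis metrics

The diffusion tensor is estimated from ≥6 non-collinear gradient
directions plus a $b \approx 0$ reference by log-linear least squares —
deterministic, standard, and exactly invertible on noiseless forward
signals, which is what makes it testable; rank deficiency of the direction
set is an error. Eigenvalues are sorted descending; noise-driven negative
eigenvalues are clipped to zero and flagged. Summaries follow the usual
definitions: $MD = (\lambda_1+\lambda_2+\lambda_3)/3$, $AD = \lambda_1$,
$RD = (\lambda_2+\lambda_3)/2$, and

$$FA = \sqrt{\tfrac{3}{2}}\,
  \sqrt{\frac{\sum_i(\lambda_i - MD)^2}{\sum_i \lambda_i^2}},$$

with $FA = 0$ for the zero tensor by convention. $RD \le MD \le AD$ and
$FA \in [0,1]$ hold by construction and are property-tested.

Non-Gaussian diffusion over a multi-$b$ ladder (200–2000 s/mm²) is
modelled as

$$S(b) = S_0 \exp\!\bigl[-b\,ADC + (b\,ADC)^2 K / 6\bigr],$$

fitted by nonlinear least squares on the log signal with bounds $ADC > 0$
and $K \in [0, 10]$; $K = 0$ recovers Gaussian (mono-exponential) decay,
and the fit reduces exactly to the two-parameter ADC fit in that case
(nested-model consistency is tested). The model assumes signal well above
the noise floor; a configurable minimum-signal mask honours that. The
mono-exponential ADC is also computed separately from the same ladder,
since ADC is conventionally quoted from the Gaussian model; whether
signals are direction-averaged before the kurtosis fit is left to the
caller, as both conventions exist.

## Clonogenic survival

Surviving fractions follow the standard definition
$SF = \text{colonies}/(\text{cells plated} \times PE)$ with the plating
efficiency taken from unirradiated controls. Dose–response uses the
linear-quadratic model $\ln SF = -(\alpha D + \beta D^2)$ for X-rays and,
by default, the pure exponential ($\beta = 0$) for ²¹²Pb — high-LET
survival curves are classically log-linear; both models are available for
either modality. Fitting is weighted least squares on per-dose mean log
SF, weighted by the total colony count at each dose (the inverse-variance
weight under Poisson counting, since $\mathrm{Var}[\ln N] \approx 1/N$),
with non-negativity bounds on $\alpha$ and $\beta$. A grossly non-monotone
response (mean SF rising >20% between consecutive doses) is flagged with a
warning instead of silently fitted. $SF2 = SF(2\,\mathrm{Gy})$ and $D50$
(the dose at $SF = 0.5$, from the positive quadratic root) are derived
from the fit. Activity-denominated exposures (kBq) are converted through a
user-supplied Gy-per-kBq factor — deriving that factor requires Monte
Carlo transport of the in vitro geometry, which is out of scope; without a
factor, curves are simply per kBq.

The effect ratio between radiation qualities is implemented as the ratio
of surviving fractions at matched absorbed dose,
`rbe_sf_ratio(sf_reference, sf_test)`. Note this is *not* the classical
radiobiological RBE (an iso-effect *dose* ratio $D_{ref}/D_{test}$ at
equal SF); it is the fixed-dose effect ratio that published SF2 pairs such
as 0.6 vs 0.026 reproduce (ratio 23.08). The function is documented
accordingly so the two conventions are not confused.

## Efficacy summaries

Tumor volume is the sum of manually contoured per-slice areas times the
slice thickness; the thickness is a required acquisition parameter with no
invented default. Longitudinal volumes are normalized to a baseline day.
Survival uses the Kaplan–Meier product-limit estimator (delegated to the
`survival` package; a hand product-limit implementation serves as the
independent oracle in the tests), with the median defined as the first
time $S(t) \le 0.5$ and reported as not reached when the curve never gets
there. Mean ± SD survival per arm is the primary summary, matching how
small-cohort preclinical survival is usually reported; the overall
survival (OS) increase between arms is
$100(\bar t_{test} - \bar t_{ref})/\bar t_{ref}$. Whether reaching maximum
tumor burden is coded as an event or as censoring is left to the event
flag, since both readings occur. Log-rank testing is routine statistics
and out of scope.

## Synthetic data: what it does and does not emulate

Each generator draws from the forward model of its analysis stage under a
fixed seed and records the generating truth alongside the output, so every
downstream fit is validated against a known answer:

* `gen_tac()` — rise-and-decay curves sampled at 2, 4, 8, 24 h with 4
  animals per time point and mean-one multiplicative lognormal noise
  (default CV 5%), the conventional error model for well-counter
  measurements.
* `gen_autorad_phantom()` — a healthy section with square uptake spots,
  pushed through a linear plate response and Poisson-sampled (phosphor
  counts), plus 1/2/4/10 Bq standards through the same response.
* `gen_dwi()` — tensor or kurtosis forward signals over the 200–2000
  s/mm² ladder with Rician (magnitude MR) or Gaussian noise at a given
  SNR.
* `gen_clonogenic()` — Poisson colony counts around
  $\text{cells} \times PE \times SF(D)$ at the standard assay design (750
  cells/well, 3 wells/dose, 4 repeats, 0–8 Gy).
* `gen_survival()` — per-arm times from a zero-truncated normal with a
  40-day administrative endpoint; default arm means/SDs (≈23.8, 23.3,
  24.0, 27.6, 35.6 days) mirror a five-arm efficacy design comparing
  untreated and inactive controls, whole-brain radiotherapy and the
  targeted arm.

These generators reproduce the *statistical structure* each stage assumes
— not the biology. They contain no spatial correlation, no registration
error, no partial-volume effects, no inter-animal kinetic heterogeneity
beyond measurement noise, and no competing risks. Passing the recovery
tests therefore demonstrates that the estimators are correct and unbiased
under their assumed noise models, not that those models capture every
feature of real animal data.

## Numerical choices and problem sizes

Tolerances: closed-form vs quadrature at $10^{-8}$ relative; noiseless
roundtrips at $10^{-6}$; optimizer-limited identities at $10^{-6}$.
Degenerate inputs (all-zero TACs, zero tensors, SF = 1 inversion at zero
dose, all-censored cohorts) return defined values rather than errors where
a defined value exists. The validation studies run at sizes chosen to make
Monte-Carlo error small relative to the tolerances they check — e.g. 200
seeded TAC repetitions, a 1000-point parameter sweep, 60 clonogenic
simulations — which complete in seconds on a single CPU.
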
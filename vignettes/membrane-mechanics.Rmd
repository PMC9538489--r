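---
title: "Models and methods behind memmech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind memmech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memmech)
```

memmech quantifies the interfacial and mechanical behaviour of model lipid
membranes — monolayers at the air–water interface, supported bilayers and
giant unilamellar vesicles (GUVs) — from plain tabular measurements. This
vignette explains the models each stage fits, the assumptions they rest
on, the tunable parameters and their defaults, how the synthetic-data
generators work, and the numerical choices made where the literature gives
no prescription.

## Adsorption isotherms and the Gibbs–Langmuir equation of state

Dissolved surfactant (here, a lipid extract) lowers the equilibrium
surface tension $\gamma$ of the air–water interface as it adsorbs. For a
single non-ionic surfactant at activity close to one, a Langmuir adsorption
isotherm combined with the Gibbs equation gives the equation of state

$$\gamma(c) = \gamma_0 - R\,T\,\Gamma_\infty \ln(1 + K c),$$

with $\gamma_0$ the bare-interface tension (mN/m), $\Gamma_\infty$ the
maximum surface excess concentration (mol/m²) and $K$ the adsorption
equilibrium constant (nM⁻¹ here, since concentrations are in nM). The mean
area per molecule at full packing is $A = 1/(\Gamma_\infty N_A)$,
reported in Å². A lipid *mixture* treated this way is an effective
single-surfactant approximation — the fitted $\Gamma_\infty$ and $K$ are
composite quantities, and no ionic (Gibbs prefactor) correction is applied.

Above the critical micelle concentration (CMC) added material forms
micelles and $\gamma$ plateaus; the equation of state has no micellization
term, so plateau points must not enter the fit. `fit_gibbs_langmuir()`
drops the trailing run of tensions within twice the instrument precision
(`noise_sd`, default 0.2 mN/m, a typical Wilhelmy-plate standard
deviation) of the *plateau level*, provided the run has at least two
points; a caller-supplied concentration cutoff (`max_conc`) is also
honoured. Anchoring the rule at the plateau level rather than at the
minimum tension matters: the sample minimum of a noisy plateau sits about
1.3 standard deviations *below* the level, so a minimum-anchored band
misses upward-scattered plateau points and lets micellization data leak
into the fit. Detection is two-phase — a strict trailing run (every member
within the band of the run mean) seeds the plateau, which then grows
backward against the re-estimated level. The fit itself is Levenberg–Marquardt least squares,
reparameterized internally with $a = 10^3 R T \Gamma_\infty$ (mN/m) so
all three parameters are of order 1–100 and the Jacobian is well
conditioned. Starting values are taken from the data (lowest-concentration
tension for $\gamma_0$; $2\times10^{-6}$ mol/m² for $\Gamma_\infty$;
1/median concentration for $K$); if the first attempt fails, two restarts
scale $K$ by 0.2 and 5. One-sigma uncertainties come from the linearized
covariance at the optimum — adequate near the optimum and cheap; no
bootstrap is run by default.

Two CMC estimators are provided, since published isotherms usually report
the breakpoint without stating the rule used:

* **two-segment** (default): a continuous piecewise model — equation-of-state
  branch up to a candidate breakpoint, constant beyond it — is fitted with
  the breakpoint swept over the observed concentrations; the breakpoint
  minimizing total squared error wins. Its resolution is one concentration
  grid step.
* **plateau-intersection**: the branch is fitted to non-plateau points and
  solved for the concentration where it crosses the plateau mean; exact on
  noiseless truncated data but more sensitive to plateau noise.

A plateau is *detected* as the maximal trailing run (at least two points)
of tensions within twice `noise_sd` of their mean; monotone data raise a
distinct undefined-CMC condition rather than a fit failure, so callers can
tell "no micellization observed" from "optimizer trouble".

## Compression isotherms and the compressibility modulus

Compressing a spread monolayer records surface pressure $\pi$ against
mean molecular area $A$ (from the trough area divided by the number of
molecules spread). The in-plane stiffness is the compressibility modulus

$$C^{-1} = -A \left(\frac{\partial \pi}{\partial A}\right)_T,$$

the standard trough convention. The derivative is estimated with a
moving-window local *quadratic* fit (a Savitzky–Golay-style estimator
written for possibly non-uniform area spacing), because experimental
isotherms carry sensor noise that finite differences would amplify.
Windows are shifted, not shrunk, at the ends of the record, so the first
and last half-window of samples are extrapolations of the nearest interior
fit and should not be over-interpreted.

**Choosing the window.** The default of 11 samples suits smooth or lightly
noisy records. Two effects compete: the *bias* of the quadratic grows with
the window's physical span relative to the sharpest feature of the
isotherm, while the *variance* under pressure noise grows as the sample
spacing shrinks at fixed window count (the derivative variance of a local
polynomial scales like $\sigma^2/\sum \delta_j^2$ with $\delta_j$ the
in-window offsets). On a densely sampled noisy record a practitioner
should therefore widen the window to a few percent of the samples — the
package's own noisy-data tests use 41 of 800 samples — and keep the
default for noiseless analytic checks. The window must be odd, at least 5
and at most half the record.

Derived descriptors:

* `lift_off_area()`: the largest area at which $\pi$ first exceeds a
  threshold (default 0.5 mN/m) during compression, linearly interpolated
  between the bracketing samples.
* `max_compressibility()`: maximum of $C^{-1}$ within a pressure window,
  ties broken toward lower pressure; a maximum at the window edge is
  flagged `boundary` (monotone profiles have no interior maximum).
* `collapse_point()`: collapse is a pressure plateau, so $C^{-1}$ falls
  toward zero there. Onset is the first sample beyond the $C^{-1}$ maximum
  where the modulus drops below `drop_fraction` (default 0.25) of that
  maximum. The fraction maps "drops to zero at collapse" to a rule robust
  to noisy profiles; on a perfect plateau it returns the plateau pressure
  exactly.

Duplicate-area samples are averaged and records are normalized to
compression order (decreasing area) at construction.

## FRAP: lateral diffusion in supported bilayers

Photobleaching a spot of radius $w$ (µm) in a fluorescent bilayer and
recording the intensity recovery gives the lateral diffusion coefficient
of the probe. Normalization is the standard double correction:
background-subtract, divide by an unbleached reference region (cancelling
acquisition photobleaching exactly when both regions bleach
proportionally), and rescale by the pre-bleach mean of that ratio so the
pre-bleach level is exactly 1. At least three pre-bleach frames are
required; time is rebased to the first post-bleach frame.

The normalized recovery is fitted to the hyperbolic model

$$f(t) = f_0 + f_\mathrm{amp}\,\frac{t/t_{1/2}}{1 + t/t_{1/2}},$$

whose value at $t_{1/2}$ is exactly $f_0 + f_\mathrm{amp}/2$ and whose
$t \to \infty$ limit is the plateau $f_0 + f_\mathrm{amp}$. The second
parameter is named an *amplitude* deliberately: some papers label it a
"maximum normalized intensity" even though it enters the model additively;
reports print the plateau alongside to avoid ambiguity. The diffusion
coefficient follows as

$$D = \beta\,\frac{w^2}{4\,t_{1/2}},$$

with $\beta$ a beam-shape/bleach-depth correction factor supplied by the
user (default 1; computed externally per the usual bleach-profile
calibrations — the package deliberately does not derive it from image
data, which is out of scope). The multiplicative placement of $\beta$ is a
convention choice; published renderings are ambiguous, and $\beta$ simply
rescales $D$. The mobile fraction is $M = f_\mathrm{amp}/(1 - f_0)$ — the
recovered share of the bleached signal — clipped to $[0,1]$; the immobile
fraction is $1 - M$.

A caveat worth knowing: $t_{1/2}$ of this hyperbola is intrinsically
weakly identified, because the model approaches its plateau slowly
($f(10\,t_{1/2})$ is still 9% short). A linearized (Cramér–Rao) analysis
at per-frame noise 0.02 gives a relative standard error of 5–8% on
$t_{1/2}$ for 60–120 post-bleach frames, improving roughly as
$1/\sqrt{n}$. Acquisitions should therefore be long (tens of $t_{1/2}$)
and dense; the synthetic generator's default movie (10 pre-bleach and 360
post-bleach frames) reflects that.

## Micropipette aspiration and the bending modulus

Aspirating a GUV into a pipette of radius $R_p$ at suction pressure
$\Delta p$ sets the membrane tension

$$\sigma = \frac{\Delta p\,R_p}{2\,(1 - R_p/R_V)},$$

singular (and rejected) when $R_p \ge R_V$. The aspirated tongue length
$L_p$, referenced to the first (low-tension) step, tracks the relative
excess area

$$\alpha = \frac{\Delta L_p}{2 R_p}\left[\left(\frac{R_p}{R_V}\right)^2 -
\left(\frac{R_p}{R_V}\right)^3\right].$$

Each step uses its own vesicle radius, since aspiration shrinks the outer
sphere. At low tension, area gain comes from pulling out thermal
undulations (the entropic regime), giving the Canham–Helfrich relation

$$\ln\frac{\sigma}{\sigma_0} \approx \frac{8 \pi \kappa}{k_B T}\,\alpha,$$

so an ordinary least-squares line of $\ln(\sigma/\sigma_0)$ on $\alpha$
yields $\kappa = \mathrm{slope}/(8\pi)$ in units of $k_B T$ (also reported
in joules at the series temperature). The regime boundary `max_tension`
defaults to 0.5 mN/m — a standard bound below which bending dominates and
above which direct area expansion takes over; the high-tension regime is
deliberately excluded, and no adhesion or pipette-friction correction is
applied. The intercept is fitted too (not forced through zero): it absorbs
the arbitrariness of the reference step, which is why re-referencing
$\sigma_0$ to another in-regime point leaves $\kappa$ unchanged. A
non-positive slope — tension failing to grow with excess area — is
unphysical and raises a fit-failure condition. Phase-separated vesicles
are out of scope: a single $\kappa$ does not describe coexisting domains.

## Composition, phosphorus and GUV statistics

TLC spot intensities from charring densitometry are proportional to the
mass of material in the spot; assuming similar densities across lipid
classes, percentages are by weight: $100\,I_i/\sum_j I_j$. Excluding a
component (typically cholesterol) and rescaling the rest to 100 is exactly
equivalent to deleting its row before normalizing — an identity the tests
exercise on random tables. Spot detection and image processing are out of
scope; the module consumes already-integrated intensities. Replicate lanes
summarize to per-class mean ± SEM. Displayed values should be rounded to
one decimal; stored values keep full precision.

Phosphorus quantification is a least-squares line of absorbance (750 nm)
on KH₂PO₄ standards; samples read as
$(A - \mathrm{intercept})/\mathrm{slope} \times \mathrm{dilution}$ and
must fall within the calibrated absorbance range extended by at most 20%
of its span (beyond that, an out-of-range condition — extrapolating a
colorimetric assay is not meaningful).

GUV populations use per-vesicle *true* diameters — the maximum over a
vesicle's z-stack measurements, reached at the equatorial section. Size
distributions report a fixed-width histogram, median, IQR and the fraction
above 10 µm. The phase-separated fraction is a simple proportion with a
Wilson score interval (chosen over Clopper–Pearson for its better coverage
at proportions near 0 or 1, exactly where these populations sit).

## The synthetic-data generators

Every generator draws from the *forward model* of its analysis stage with
known ground truth, records every generating parameter in a `truth` list,
and is deterministic under a fixed seed. Recovery tests read truth only
from that record. Defaults emulate the bundled presets
(`membrane_preset()`): an outer-membrane-like extract (condensed, stiff,
phase-separating), an inner-membrane-like extract (expanded, soft,
cardiolipin-rich) and a POPC control.

* **Adsorption** (`gen_adsorption()`): log-spaced concentrations (20 points
  on 0.1–200 nM by default), equation-of-state tensions clamped at the
  model value at the CMC when one is requested (continuous truncation),
  additive Gaussian noise of sd 0.2 mN/m — the stated precision of a
  Wilhelmy-plate tensiometer.
* **Isotherm** (`gen_isotherm()`): the compressibility profile is a
  piecewise-lognormal bump in log-area — width $s_r$ on the rise side and
  $s_l$ on the collapse side, fixed by the requested maximum, its
  pressure, and the collapse pressure; integrating $-C^{-1}(A)/A$ gives a
  closed-form pressure curve in `pnorm`, so the generator returns an
  *exact symbolic oracle* for $C^{-1}(A)$ alongside the samples. The bump
  centre is placed so the pressure crosses 0.5 mN/m exactly at the
  requested lift-off area. The default 800 samples keep the 11-point
  derivative window well inside the narrow collapse flank, which is what
  makes the 2% oracle-equivalence check attainable; coarser records need
  proportionally narrower expectations. Collapse pressure at or below the
  pressure of the modulus maximum is rejected as an inconsistent shape.
* **FRAP** (`gen_frap()`): pre-bleach frames at 1, post-bleach frames from
  the hyperbolic model, one shared exponential acquisition-bleaching decay
  on spot and reference (time constant 150 s by default), Gaussian noise
  on the intensity scale with the reference channel at one fifth of the
  spot noise (it averages far more pixels). Recovery studies draw
  $f_0 \in [0.1, 0.5]$, plateau at 70–95% of full recovery,
  $t_{1/2} \in [0.5, 4]$ s, $w \in [1.5, 3]$ µm, with the frame interval
  set to $t_{1/2}/12$ — matching frame rate to recovery speed as an
  experimenter would.
* **Aspiration** (`gen_aspiration()`): a log-spaced tension staircase from
  $\sigma_0 = 0.005$ to 0.4 mN/m (inside the entropic regime; exceeding
  the bound only annotates the truth record), inverted through the
  Canham–Helfrich relation and the geometry formulas to protrusion lengths
  and suction pressures; per-step vesicle radii shrink to conserve volume
  as the tongue grows. Noise is multiplicative Gaussian on the protrusion
  lengths (5% in the recovery tests — a realistic video-microscopy
  digitization error).
* **Densitometry / GUV** (`gen_densitometry()`, `gen_guv()`): intensities
  are percentages times a lane gain with multiplicative Gaussian noise;
  diameters are log-normal (median 13 µm, log-sd 0.45 — a typical
  electroformation population spanning roughly 5–60 µm), phase flags
  Bernoulli.

**What passing these tests shows — and what it does not.** Parameter
recovery on synthetic data demonstrates that the estimators are correct
and numerically sound for data generated by the very models they fit, at
realistic noise. Real measurements violate those models in ways the
generators do not emulate: multi-component adsorption kinetics, monolayer
relaxation and hysteresis, anomalous or heterogeneous diffusion, bleaching
during the bleach pulse, vesicle adhesion, TLC baseline artefacts.
Agreement on synthetic data is therefore necessary, not sufficient, for
trusting a result on real extracts.

## Numerical choices, degenerate inputs, and problem sizes

* Physical constants are CODATA 2018 ($R$, $N_A$, $k_B$); the default
  temperature is 295.15 K (22 °C, the usual laboratory setting here) and
  configurable everywhere it enters a formula.
* Errors are classed conditions (`memmech_invalid_input`,
  `memmech_fit_failure`, `memmech_not_found`, `memmech_undefined_cmc`,
  `memmech_out_of_range`, `memmech_invalid_spec`), so callers and tests
  can distinguish bad data from numerical failure without string matching.
* Tie-breaks: the modulus maximum takes the lowest-pressure sample; the
  two-segment CMC takes the first minimizing breakpoint.
* Degenerate inputs fail loudly and specifically: monotone adsorption data
  (undefined CMC), isotherms ending before collapse (not-found), decreasing
  FRAP traces, non-positive Canham–Helfrich slopes, reference intensity at
  or below background, all-zero densitometry lanes.
* Test problem sizes — 20-point adsorption datasets with 100 noise
  replicates, 800-sample isotherms, 370-frame FRAP movies with 50
  replicates, 12-step aspiration staircases with 100 replicates — were
  chosen to mirror realistic experiment sizes while keeping the full suite
  around a few seconds; they are stated here as the package's own
  validation conditions.

## Known limitations

* The Gibbs–Langmuir stage treats a lipid mixture as one effective
  non-ionic surfactant; fitted constants are composites and can disagree
  with per-species expectations, especially for charged lipids such as
  cardiolipin.
* $\beta$ is an input: absolute $D$ values are only as good as the
  user's beam-shape/bleach-depth calibration.
* The compressibility profile near the record ends is extrapolated from
  shifted windows; lift-off and collapse calls within half a window of the
  ends are unreliable.
* The bending fit assumes a single homogeneous membrane; it must not be
  applied to phase-separated vesicles.
* CMC estimators resolve at best one concentration grid step; log-spaced
  sampling concentrates resolution at low concentration.
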
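---
title: "Methods: quantifying xylem embolism from micro-CT cross-sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying xylem embolism from micro-CT cross-sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xylemct)
```

## The problem and the model

When xylem sap tension rises during drought (water potential $\Psi$
becoming more negative), gas is aspirated into conduits and they embolise,
losing their share of hydraulic conductance. On a phase-contrast micro-CT
cross-section, air-filled lumens are dark and water-filled lumens light,
so a single slice taken at a known $\Psi$, together with a second slice of
the same sample after full embolisation ("final scan"), determines which
conduits had failed.

`xylemct` implements the complete quantification chain:

1. **Segmentation.** Air-filled conduits are the connected components of
   the below-threshold pixel set; each component's area $A$ is converted
   to an equivalent-circle diameter $d = 2\sqrt{A/\pi}$.
2. **Anatomy.** Mean diameter $\bar d$, hydraulically weighted diameter
   $d_h = \sum d_i^5 / \sum d_i^4$, vessel density $VD$ (count per mm$^2$
   of xylem), diameter histograms in 2-µm classes, and the wall
   reinforcement ratio $(t/b)^2$ over conduit pairs with mean diameter
   within $d_h \pm 2$ µm.
3. **Hydraulics.** Theoretical conductance of a conduit population by the
   modified Hagen–Poiseuille relation
   $k_t = \frac{\pi\rho}{128\mu}\sum_i d_i^4$ (diameters in metres;
   $\rho = 998.2$ kg m$^{-3}$, $\mu = 1.002\times 10^{-3}$ Pa s at the
   20 °C reference), reported per MPa of pressure gradient
   (kg m MPa$^{-1}$ s$^{-1}$), and specific conductivity
   $K_{st} = k_t / A_{xylem}$. Pit and end-wall resistances are *not*
   modelled, so $K_{st}$ deliberately overestimates measured $K_s$.
   Theoretical PLC of an initial/final scan pair is
   $PLC_t = (1 - k_{t,\mathrm{initial}}/k_{t,\mathrm{final}})\times 100$,
   with $k_{t,\mathrm{initial}} = k_{t,\mathrm{final}} -
   k_t(\text{embolised conduits})$, i.e. the $d^4$-weighted embolised
   fraction. Measured conductivities use
   $PLC = (1 - K_i/K_s)\times 100$, clamped to $[0, 100]$ with the raw
   value retained. The printed form of these definitions omits the
   parentheses; the clamped-ratio reading is the only dimensionally
   consistent one and is adopted throughout.
4. **Vulnerability.** A two-parameter Weibull curve
   $PLC(\Psi) = 100\,(1 - e^{-(|\Psi|/b)^c})$ is fitted by unweighted
   nonlinear least squares; thresholds
   $\Psi_p = -b(-\ln(1 - p/100))^{1/c}$ (P12/P50/P88) get percentile 95%
   CIs from case-resampling bootstrap, and two curves differ
   significantly at a threshold iff their CIs do not overlap.

## Design choices where the method was genuinely open

* **Curve family.** The protocol literature describes both "exponential
  sigmoid" and Weibull fits; the named fitting package and the statistics
  description specify Weibull, which is adopted as the single family for
  both hydraulic and micro-CT data. A logistic-sigmoid alternative
  (`family = "sigmoid"`) is provided for sensitivity analysis only; it
  does not enforce $PLC(0)=0$, which the Weibull does structurally — we
  treat that structural zero as desirable since a sample at zero tension
  has, by definition, nothing to lose.
* **Threshold selection.** "Set thresholds" is operator-dependent in the
  original ImageJ workflow. The default is an explicit fixed threshold
  (0.30 on the unit gray scale, midway between the default air and
  background levels), with Otsu's method as an option; the threshold
  actually applied is always recorded in the output metadata and the run
  log.
* **Connectivity and filters.** 8-connected components; minimum particle
  area the area of a 5-µm circle (sub-5-µm components at 2 µm/px are
  noise-scale); border-touching components kept but flagged; no watershed
  splitting of touching embolised clusters — a documented limitation, as
  the original analysis is silent on it.
* **Fitting.** Optimisation in $(\log b, \log c)$ with analytic
  gradients, started from a linearised estimate plus a grid (b over the
  observed $|\Psi|$ quartiles, $c \in \{1,2,4,8\}$); best RSS wins, ties
  to the smaller shape. Non-convergence is an explicit result carrying a
  reason, never a silent estimate. PLC is clamped to $[0,100]$ before
  fitting; inputs outside that range are schema errors.
* **Bootstrap.** Case resampling (each observation is one plant at one
  potential, so cases are the independent units), 1000 replicates by
  default (200 minimum), replicates that fail to converge are dropped and
  counted, with an error beyond 50% loss. Percentile CIs are reported
  with the numerically lower (more negative) bound first.
* **Sign convention.** All potentials are stored as negative MPa
  everywhere; fitting uses $|\Psi|$ internally.

## The synthetic world

The generator emulates the reconstructed slices the analysis consumes —
circular lumens packed without overlap in a disc (or annulus) of xylem,
at gray levels background 0.45 / water 0.75 / air 0.10 with optional
Gaussian pixel noise — and a bench-dehydration experiment: each
synthetic plant is observed once, at a potential drawn uniformly from the
organ's dehydration range, and each conduit embolises below its own
threshold potential drawn from a Weibull distribution (negated
`rweibull`), independently of its diameter. Independence is a modelling
choice: no diameter–vulnerability coupling is asserted by the reference
protocol, and it makes the number-weighted and conductance-weighted
embolised fractions coincide in expectation, which the recovery tests
exploit. No air-seeding spread between neighbouring conduits is
modelled, for the same reason.

Defaults are the stated world of the reference seedling dataset:
per-organ vessel density, mean and hydraulically weighted diameter
(truncated lognormal solved from $\bar d$ and $d_h$ via
$d_h/\bar d = e^{4\sigma^2}$), published per-curve sample sizes, PLC
noise sd of 5 percentage points, and per-conduit Weibull parameters
solved from the published (P50, P88) pairs. Conduit count per image is
deterministic (`round(density * area)`): density fidelity is a placement
property, not a dispersion model. The minimum wall between lumens is
2 px, not 1: with 8-connected labelling a 1-px diagonal gap can merge two
lumens, defeating the separability the wall is meant to guarantee. The
dense leaf-vein preset relaxes the wall to 1 px to reach its published
density of 2551 mm$^{-2}$ and therefore *can* merge occasional conduit
pairs — such initial-scan conduits surface as flagged "unmatched"
warnings rather than silent errors.

What a green test does **not** establish: real slices have fibre and
parenchyma texture, reconstruction artefacts, elliptical lumens and
spatially clustered conduits, none of which are modelled; segmentation
performance on real tomograms is therefore not certified by these tests,
only the correctness of the measurement chain downstream of a faithful
segmentation.

## Numerical notes

* Viscosity correction to 20 °C uses the empirical relation
  $\mu(T) = 1.002\times10^{-3}\cdot
  10^{\frac{(20-T)(1.3272 - 0.001053(T-20))}{T+105}}$ Pa s, accepted for
  $0 < T < 50$ °C; $\mu(25)/\mu(20) \approx 0.8895$.
* Histogram classes are half-open, lower-closed $[k w, (k+1)w)$; a
  diameter on an edge counts upward.
* Pixel coordinates: origin top-left, x rightward, y downward; the pixel
  with 0-based index $(i_x, i_y)$ has its centre at
  $((i_x + 0.5)\,s, (i_y + 0.5)\,s)$ for pixel size $s$.
* Reals are serialised with 17 significant digits, so CSV round trips
  are lossless.
* Rejection-sampling placement draws all diameters first and places them
  largest-first (deterministically for a seed), which raises attainable
  packing fractions; a bounded attempt budget turns infeasible requests
  into errors naming achieved versus requested density.
* Seeds are mandatory for every stochastic operation; a cross-section's
  noise field is seeded at `seed + 1` so the fully-dry initial scan and
  the final scan of the same sample are byte-identical.

## Known limitations

* Percentile bootstrap CIs undercover slightly at the smallest published
  sample sizes (true coverage ~88–93% at n = 8–16 with noise sd 5); this
  is a property of the prescribed method, visible in the package's own
  coverage tests, not corrected away.
* $(t/b)^2$ takes wall thickness as given in the input table; whether
  single or double intervessel walls were measured is a property of the
  data source and is documented, not resolved, here.
* Published vessel-density standard errors are implausibly small relative
  to their means and are not reproduced; only means are targeted.
* No 3-D information: conduits connected out of plane, immature
  non-conducting conduits, and open-vessel artefacts are invisible to a
  single-slice analysis.
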
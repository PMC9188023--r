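---
title: "Methods: DEB life-history derivation and comparative trait analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DEB life-history derivation and comparative trait analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(debtraits)
```

## The model and its assumptions

`debtraits` implements the standard Dynamic Energy Budget (std DEB) model
for ectotherms: three state variables (structural length $L$, reserve $E$,
maturity $E_H$), assimilation proportional to $L^2$, somatic maintenance to
$L^3$, maturity maintenance to $E_H$, and the $\kappa$-rule split of the
mobilization flux

$$\dot p_C = E\,\frac{\dot v}{L}\,\frac{g + L/L_m}{e + g}, \qquad
  e = \frac{E}{L^3 E_m},$$

with compound parameters $E_m = \dot p_{Am}/\dot v$,
$g = E_G/(\kappa E_m)$, $k_M = \dot p_M/E_G$,
$L_m = \kappa \dot p_{Am}/\dot p_M$. This closure satisfies weak
homeostasis: at constant food the reserve density stays at the functional
response $f$ throughout growth, and the length trajectory is exactly von
Bertalanffy with rate $r_B = k_M/(3(1+f/g))$. The package assumes the plain
std model throughout: no surface-linked heating length ($L_T = 0$), no
metabolic acceleration, oviparous development, and a reproduction buffer
converted continuously to eggs. Simplifications beyond the std model's own
idealizations: respiration uses a single oxycaloric coefficient
($\mu_{O2} = 4.48\times 10^5$ J per mol O$_2$) rather than the full
stoichiometric mass balance, which suffices because only the *scaling* of
respiration is analyzed; assimilation overhead is not counted in
respiration. Wet weight is $W_w = d_{Vw} L^3 (1 + f\omega)$ with
$d_{Vw} = 1\,\mathrm{g\,cm^{-3}}$ and
$\omega = E_m w_E/(d_{Vw}\mu_E)$ — structure plus reserve at equilibrium
density, the reproduction buffer excluded. All traits are computed at the
reference temperature 20&nbsp;°C (293.15 K); parameters are taken to be given at
that temperature, and the Arrhenius factor
$\exp(T_A/T_{ref} - T_A/T)$ is applied only on explicit request.

## Parameters that matter

| parameter | units | typical (reptile, 20 °C) | role |
|---|---|---|---|
| $\dot p_{Am}$ | J d⁻¹ cm⁻² | 50–1500 | assimilation ceiling; sets $E_m$ and $L_m$ |
| $\dot v$ | cm d⁻¹ | 0.04–0.09 | reserve mobilization speed; large $\dot v$ shortens incubation |
| $\kappa$ | – | 0.65–0.9 | soma share; ultimate size $\propto \kappa$ |
| $\dot p_M$ | J d⁻¹ cm⁻³ | 11–30 | maintenance; $r_B \propto \dot p_M$, reduces $L_m$ |
| $k_J$ | d⁻¹ | ~0.002 | maturity maintenance; sets supply stress with $E_{Hp}$ |
| $E_G$ | J cm⁻³ | ~7800 | cost of structure; bounded below by the energy fixed in structure ($\kappa_G < 1$) |
| $E_{Hb}, E_{Hp}$ | J | – | birth and puberty thresholds; their ratio is the precociality coefficient |
| $\ddot h_a, s_G$ | d⁻², – | 1e-10–1e-8, ~1e-4 | Weibull aging acceleration and Gompertz stress |

## Numerical choices

* **Embryo shooting.** The egg cost $E_0$ solves $e(a_b) = f$ where $a_b$
  is the first crossing of $E_{Hb}$. We integrate the embryo system with
  `deSolve::lsodar` (relative tolerance $10^{-10}$) from
  $L(0) = 10^{-5} L_m$, detect birth by dense-output root finding, and
  bisect on $E_0$ (`uniroot`, relative tolerance $10^{-8}$) after growing
  the bracket geometrically until the shooting residual changes sign. An
  initial guess — structure at threshold cost plus reserve at density $f$
  plus the maturity investment — keeps the bracket search short. Candidate
  eggs that never reach birth (reserve exhausted, or maturation stalled by
  maturity maintenance) return a negative residual, so bisection treats
  under-provisioned eggs correctly; if no bracketed egg reaches birth the
  species is reported non-viable, carrying the stall maturity level.
* **Puberty.** Post-birth maturity follows a linear ODE along the analytic
  von Bertalanffy curve; puberty is a root crossing. With $k_J > 0$,
  maturity saturates at $(1-\kappa) f E_m \dot v L_i^2/k_J$; thresholds at
  or above that ceiling are flagged *stalled* (traits missing, species
  retained, so survivor-curve denominators stay explicit).
  The degenerate threshold $E_{Hp} \le E_{Hb}$ collapses puberty onto
  birth.
* **Aging.** The $(q, h, S)$ system is integrated along the growth curve
  from birth with the survival integral as a fourth state; integration
  stops when $S < 10^{-7}$ and the remaining tail is bounded by $S/h$ and
  added as a correction. In the fully-grown, $s_G = 0$ limit this matches
  the closed Weibull form
  $a_m = \Gamma(4/3)\,(6 L_i/(\ddot h_a f \dot v))^{1/3}$ to better than
  0.5%.
* **Maximum specific growth.** The identity $r_{max} = 1.5\, r_B$ (the
  specific structural growth rate at the age maximizing $dL^3/da$, i.e. at
  $L = \tfrac23 L_i$) is used for trait tables; a trajectory-based method
  (simulate, spline, `optimize`) exists for verification and reproduces the
  ratio to $10^{-5}$.
* **Distances and MDS.** The bounded-loss distance
  $d_{ij} = \sqrt{K^{-1}\sum_k (x_{ik}-x_{jk})^2/(x_{ik}^2+x_{jk}^2)}$
  (0/0 terms zero, equal weights) is fixed because it is bounded in
  $[0,1]$ and invariant to per-trait unit changes, which is the purpose of
  a bounded loss here; classical (Torgerson) scaling is done by explicit
  double-centering and `eigen`, with negative eigenvalues reported but not
  embedded, and axis signs fixed by making the largest-magnitude coordinate
  positive. Traits are log10-transformed before correlating with axes
  (they span many orders of magnitude); raw-scale correlation is available
  by argument. Trait–axis association uses the eigenvector coordinates
  (eigenvalues are scalars and cannot be correlated with anything).
  Species with any missing ordination trait are dropped with a reported
  count.

## What the synthetic generator emulates — and what it does not

The generator draws a cross-species family under the DEB body-size
covariation rules: a zoom factor $z$, log-uniform over three decades
(default $z \in [0.2, 200]$ around a small-reptile reference), scales the
extensive parameters ($\dot p_{Am} \propto z$, $E_{Hb} \propto z^{\beta_b}$,
$E_{Hp} \propto z^{\beta_p}$) while intensive parameters are shared up to
independent lognormal scatter (sd 0.1 in log10 units, applied per
parameter). Defaults $\beta_b = 1.7454$ and $\beta_p = 3$ are calibrated so
the family's designed birth-weight exponent is $\beta_b/3 = 0.5818$ and its
puberty weight is proportional to ultimate weight — giving the pipeline a
known ground truth spanning roughly gecko-sized to crocodile-sized species.
Bounded or sign-constrained parameters ($\kappa$, $\kappa_R$, $s_G$, and
$E_G$, which is bounded below by the combustion energy of structure) take
no multiplicative scatter. Two reserve regimes are provided:
`omega_mode = "negligible"` (default) absorbs the $\dot p_{Am}$ scaling
into $\dot v$ so reserve stays a small constant fraction of weight — the
clean regime for exponent-recovery tests; `"covarying"` keeps $\dot v$
intensive so $E_m \propto z$, the reserve-dominated regime in which
weight-specific respiration approaches the $-1/4$ slope against ultimate
weight. Draws that fail cheap viability screens (inverted maturity
thresholds, puberty ceiling exceeded, embryo predicted near ultimate size)
are redrawn, at most 100 times per species.

What the generator does **not** emulate: the estimation scatter structure
of real parameter collections (correlated errors across parameters of one
species), phylogenetic correlation between species, and any size
covariation of the aging parameters $\ddot h_a$, $s_G$ (none is
established; they are held intensive). Consequently the cross-species
lifespan–respiration slope of $-1$ seen in real collections is *not*
expected from, nor asserted on, synthetic families — it is computed and
reported as a diagnostic only. Passing tests on synthetic data show the
pipeline recovers what it was designed to recover; they cannot show that
real reptile parameters satisfy the covariation rules.

## Design decisions on genuinely open points

* **Reproduction window.** Lifetime cumulated neonate mass uses
  $R_i (a_m - a_p) W_{wb}$: reproduction starts at puberty. The window is
  configurable (`window = "lifespan"` gives $R_i\, a_m\, W_{wb}$) since
  collection conventions differ.
* **Weight-specific reproduction** (survivor-curve output) is
  $R_i W_{wb}/W_{w\infty}$, a convention stated in the artifact tables.
* **Respiration of adults at ultimate size** is
  $p_S + p_J + (1-\kappa_R) p_R$; for growing states the energy fixed in
  new structure ($\kappa_G p_G$) is additionally excluded.
* **Precociality scaling.** Since birth weight scales with ultimate weight
  to a power near 0.6 while puberty weight is proportional to it, the
  weight-ratio approximation of the precociality coefficient implies a
  negative exponent on ultimate weight (about $0.6 - 1 = -0.4$ under those
  two exponents). The scaling task therefore reports the *empirical*
  $s_{Hbp}$ exponent from the data rather than imposing a theoretical one.
* **Survivor curves** use strict exceedance; ties count as not exceeding.
  Even-sized group medians average the central pair. Log base 10 is used
  everywhere. Reference lines of fixed slope ($-1$, $-1/4$, $+1$) are
  drawn through the median point of the cloud without fitting and never
  reported as estimates.

## Problem sizes and known limitations

The shipped analyses use a 6-species fixed fixture for exactness checks and
seeded families of 25–300 species for recovery checks; the full 300-species
pipeline (embryo shooting for every species) runs in well under a minute,
and the whole test suite in about a minute on one CPU.

Two quantitative limitations are worth knowing:

1. **Embryo-maintenance curvature.** With zero scatter, the recovered
   birth-weight exponent is 0.58236 rather than exactly
   $\beta_b/3 = 0.5818$ ($R^2 = 1 - 3\times10^{-6}$): somatic and maturity
   maintenance during incubation bend the otherwise exact cube-root mapping
   from $E_{Hb}$ to birth structure by about 0.1% over three decades of
   zoom. This is a property of the model, not solver error.
2. **Regression dilution.** With the default scatter (sd 0.1 in log10 on
   each of $\dot p_{Am}$ and $\dot p_M$, which jointly set ultimate
   weight), ordinary least squares of log birth (or puberty) weight on log
   ultimate weight is attenuated by a factor of about 0.974, because the
   abscissa carries its own noise (errors-in-variables). At $n = 300$ over
   three decades this bias ($\approx -0.012$ on the birth exponent,
   $-0.018$ on the puberty slope) is two to three times the OLS standard
   error, so recovered slopes sit slightly but systematically below the
   designed values — exactly as they would in a real parameter collection
   analyzed by OLS. The package reports plain OLS (the field's standard)
   and leaves errors-in-variables estimators out of scope.

Other limitations: no stoichiometric gas/N-waste balance, no torpor or
temperature-dependent sex determination, no foetal/viviparous variants, no
parameter estimation from raw observations, and no phylogenetically
corrected regression or formal between-taxon tests (the comparative output
is descriptive).
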
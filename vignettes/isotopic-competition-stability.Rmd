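---
title: "From stable isotopes to competition coefficients and community stability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From stable isotopes to competition coefficients and community stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(isocompete)
```

## The inference chain

`isocompete` turns two kinds of field data — specimen-level carbon and
nitrogen stable-isotope measurements (δ13C, δ15N, in ‰) and census counts
per litterbag — into a quantitative description of competition and local
(Lyapunov) stability of a benthic invertebrate assemblage sampled along a
seagrass habitat-degradation gradient. The chain is:

1. **Isotopic niche geometry.** Each population's cloud of points in
   δ13C × δ15N space is summarized by the δ13C range (CR) and sample
   variance (σ², n−1 denominator), the convex-hull total area (TA), and
   the standard ellipse area (SEA), i.e. π√(λ₁λ₂) for the eigenvalues of
   the 2×2 sample covariance. The standard ellipse is the Mahalanobis unit
   ellipse and contains 1 − e^(−1/2) ≈ 39.3% of bivariate-normal
   observations. SEAc applies the small-sample correction (n−1)/(n−2).
   Overlaps between hulls and between ellipses are computed by convex
   clipping and expressed as a percentage of each population's own area.
2. **Diet mixing.** A Bayesian stable-isotope mixing model estimates each
   population's diet proportions over the basal resources, after shifting
   each resource by fixed trophic enrichment factors (0.4‰ for carbon,
   2.3‰ for nitrogen per trophic step).
3. **Competition coefficients.** Two routes: the Levins diet-overlap
   coefficient β_ij = Σ_h p_ih p_jh / Σ_h p_ih², and an isotope-distance
   coefficient α_ij = mean over i's specimens of ND_ii/ND_ij, the ratio of
   a specimen's mean Euclidean distance to conspecifics over its mean
   distance to specimens of j. Both are "effect of j on i", both equal 1
   for identical niches, and both are generally asymmetric.
4. **Carrying capacity and stability.** K_i = N_i + Σ_j α_ij N_j
   decomposes into the species' own density plus the "limiting effect"
   α_ij·N_j of every competitor (target and nontarget). The community
   matrix M (unit diagonal) and the Lotka–Volterra Jacobian
   J_ij = −(r_i N_i/K_i) m_ij give the leading eigenvalue λ (stability iff
   negative), the inverse Jacobian J⁻¹ of net (direct + indirect) effects,
   ±20% element-wise perturbed copies of J⁻¹, and a randomization null
   that rearranges off-diagonal elements.

## The mixing model

One diet vector p per species–location is fitted to all of the
population's specimens (population-level model; diets are reported per
population, not per specimen). Per isotope axis,

x_s ~ Normal( Σ_k p_k (μ_k + TEF), Σ_k p_k² σ_k² + σ_r² ),

so source uncertainty enters through the p-weighted variance and σ_r is a
per-axis residual SD. Priors are Dirichlet(1,…,1) on p and
half-Cauchy(0, 2.5) on each σ_r. Because the Gaussian likelihood depends
on the data only through n, Σx and Σx² per axis, each Metropolis step is
O(1) in the number of specimens. Sampling is random-walk Metropolis on
additive-log-ratio coordinates of p (with the Jacobian correction) plus
log σ_r; the proposal scale is tuned during burn-in toward 20–40%
acceptance, and convergence is monitored with a split-chain potential
scale reduction factor (flagged above 1.1). Defaults are 4 chains × 30,000
iterations, 10,000 burn-in, thinning 10. The replicated experiments in
this package use 2 chains × 12,000 iterations (4,000 burn-in, thinning 4),
which the calibration check shows is sufficient for interval coverage at
these sample sizes.

Two caveats are inherent to mixing models, not to this implementation:
sources with similar signatures (e.g. fresh vs decomposed leaf litter) are
only weakly identifiable, so their marginal posteriors are wide and
negatively correlated — posterior *means* can sit far from the truth while
credible intervals remain calibrated; and with two isotope axes and more
than three sources the system is underdetermined, which the Dirichlet
prior regularizes.

## Meadow scale

Per-location analyses use raw coordinates. The meadow scale pools all
locations after subtracting, from each specimen, the unweighted centroid
of the resource mean signatures at its location; pooled metrics and α are
computed on these standardized coordinates. Meadow diets aggregate
per-location diets weighted by population density,
P_meadow = Σ_loc P_loc N_loc / Σ_loc N_loc. Meadow densities are the
unweighted mean of the location means (this matches the reported
meadow-scale summaries to printed precision). The resource centroid is
unweighted by resource sample size — with balanced resource sampling the
two conventions coincide.

## The synthetic community generator

The raw field data behind the motivating study are not deposited, so the
generator emulates their statistical structure and serves as ground truth
for every downstream stage:

- three locations with degradation levels 0.075, 0.30, 0.50 (one minus
  seagrass coverage 92.5%, 70%, 50%);
- five basal resources with fixed, location-invariant signatures
  (attached leaves, green and brown leaf litter, epiphytes, sediment
  organic matter) spanning the realistic −20.5…−12.4‰ δ13C and
  1.5…3.5‰ δ15N range of a Mediterranean seagrass litter web;
- three abundant target species plus five rarer nontarget species, with
  baseline densities chosen so the high-coverage location carries ~10,
  ~10 and ~4 target individuals per litterbag and a nontarget pool of
  ~10, matching the reported census magnitudes;
- one diet vector per species–location drawn from a Dirichlet whose
  concentration interpolates between the species' preference weights and
  the uniform diet as degradation rises (total concentration 40), so
  diets flatten and overlap increases downstream — an optional
  per-specimen mode (`individual_diets`) emulates individual
  specialization instead;
- specimen signatures equal to the diet-weighted, TEF-shifted source
  draws plus Gaussian residual (0.5‰ per axis — the study reports no
  residual estimate; this is a documented free choice);
- negative-binomial litterbag counts (dispersion 5) whose means shrink
  linearly with degradation: the reported censuses show SEs far above
  Poisson, hence overdispersion.

All randomness flows from one root seed through independent named stage
streams (diets, source draws, residuals, counts, placement), so any stage
is reproducible in isolation. What the generator does *not* emulate:
spatial autocorrelation between litterbags, predation, body-size
structure, and isotopic variation of resources across locations. Passing
tests on synthetic data therefore validate the estimators under the
model's own assumptions, not the field inference itself.

Because the population-level diet model gives all conspecifics one diet,
flattening that diet slightly *narrows* a population's isotopic cloud
(the p-weighted variance Σp²σ² falls), so within-location TA/SEAc do not
automatically grow with degradation in the default mode; the degradation
signal travels through between-species diet convergence into α, β, K and
λ, which is what the replicated experiment checks.

## Numerical choices

- **Hulls and overlap.** Convex hulls via the standard planar algorithm;
  areas by the shoelace formula; hull–hull intersection by
  Sutherland–Hodgman clipping of convex polygons. Fewer than three points
  or a collinear cloud give TA = 0 with a warning.
- **Ellipse overlap** clips polygonal approximations of the two ellipses,
  doubling the vertex count from 256 until the area changes by less than
  a relative 10⁻³ — deterministic for fixed inputs, with Monte-Carlo
  containment as the independent oracle in tests only.
- **Degenerate inputs.** Singleton populations are excluded from
  distance-based statistics with a warning rather than an abort (rare
  species tails are expected); a focal specimen coinciding with *all*
  competitor specimens (ND_ij = 0) is a hard error naming the specimen.
- **Jacobian construction.** The source study does not state how J was
  obtained from M, N and K. We use the exact Jacobian of the LV system
  evaluated at the supplied densities, J = −diag(r N/K) M with r = 1, at
  the observed mean densities; evaluation at the solved equilibrium
  M⁻¹K is available by passing those densities instead. Because K
  includes nontarget limiting effects while M covers target species only,
  the observed densities are generally *not* the TS-only equilibrium; the
  dynamical cross-check in the replicated experiment therefore evaluates
  J at the equilibrium when it is feasible and expects competitive
  exclusion when it is not.
- **Perturbed matrices.** "20% decrease" of a (possibly negative)
  element is implemented as multiplication by 0.8 — toward zero — and both
  the 0.8× and 1.2× matrices are always produced. A uniform element-wise
  scaling multiplies every eigenvalue by the same factor, so sign
  conclusions are scale-invariant by construction.
- **Randomization null** permutes the off-diagonal elements without
  replacement (a rearrangement, not a resample), diagonal fixed; for 3×3
  matrices an exhaustive mode enumerates all 720 permutations.
- **LV integration** uses `deSolve::lsoda` (rtol 10⁻¹⁰, atol 10⁻¹²),
  extinction threshold 10⁻⁶ × initial density, default horizon 10³ time
  units. Convergence is declared on small derivatives *or* contraction of
  the deviation from the interior equilibrium below one tenth of its
  initial value; the second route matters when λ is negative but close to
  zero and relaxation is slow. In the dynamical cross-check the
  equilibrium is perturbed *asymmetrically* (×1.02/×0.98 alternating over
  species) over a 5×10⁴ horizon: a uniform rescaling can start so close
  to the stable manifold of a weak saddle that the unstable mode never
  grows above solver tolerances.
- **SEAc comparison.** Whether the reported SEAc "distributions" came
  from a covariance posterior or from resampling is not stated; we use a
  seeded bootstrap over specimens (B = 999 by default) compared by
  Welch's t on the replicate distributions, and document it as such.

## Problem sizes

The replicated gradient experiment uses 20 communities (three locations,
three target populations of 30 specimens each per location), with the
reduced MCMC settings above; the calibration check fits 20 populations
across 20 fresh communities; geometry oracles use 10⁴–10⁶ Monte-Carlo
points; spectral checks use 100 random 3×3 communities. These sizes give
stable pass/fail behaviour for all property checks while keeping a full
run of the suite and the acceptance script in the minutes range on one
CPU.

## Known limitations

- α_ij assumes isotopic distance is a faithful proxy for resource-use
  dissimilarity; systematic between-individual fractionation differences
  would bias it.
- The mixing model has no concentration dependence, isotope routing, TEF
  uncertainty, or more than two axes.
- Stability analysis covers the three target species only; nontarget
  species enter through K.
- The two-species outcome classification and the eigenvalue analysis are
  local statements; no permanence or global-stability claims are made.
- The CLI listed alongside the original module plan is deliberately
  realized as the numbered scripts under `analysis/` plus the exported
  functions — this package is an analysis workflow, not a shell tool.
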
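---
title: "Methods: factorial warming x clipping analyses, array preprocessing, and Q10 inversion"
author: "warmclip developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: factorial warming x clipping analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(warmclip)
```

# Scope

`warmclip` re-implements, as a tested pipeline, the statistical machinery of
paired-factorial grassland experiments that cross warming (infrared heating,
ambient +2 degC) with clipping (annual aboveground biomass harvest):

1. factorial effect estimation and interaction-direction classification,
2. functional gene array (GeoChip-style) preprocessing and category-level
   treatment effects,
3. Bayesian inversion of a six-pool soil-carbon model for the Q10 of
   heterotrophic respiration,
4. a two-source carbon-isotope mixing model, and
5. dissimilarity-based community statistics.

Because the original field measurements are not packaged, every analysis is
exercised on synthetic data with known ground truth. This vignette documents
the models, the conventions chosen where the methodology is underdetermined,
and what the synthetic world does and does not establish.

# Factorial effects and interaction classification

The design has `n` blocks (paired plots; 6 in the motivating experiment),
each containing the four cells UU (control), UW (warmed), CU (clipped) and
CW (both). For a variable `y`, percent effects are defined per block with
that block's own control as denominator:

- `W = 100 (UW - UU) / UU`, `C = 100 (CU - UU) / UU`,
- observed combined effect `OE = 100 (CW - UU) / UU`,
- predicted additive effect `PE = W + C`.

Reported values are arithmetic means over blocks, so `PE = W + C` and
`OE - PE` hold exactly both per block and in the means. The per-block
construction is the only one that admits a *paired* test of OE against PE at
n = 6; it is also what makes block effects cancel exactly, which the
synthetic round-trip tests exploit.

An interaction is **additive** when OE does not differ significantly from PE
(p > alpha, default 0.05), **synergistic** when OE is significantly above PE
and **antagonistic** when below. A marginal tier (p <= 0.10) is reported but
does not change the label. No multiple-testing correction is applied across
variables or gene categories: the pipeline reports raw p-value tiers, as is
conventional in this literature. Treat families of calls accordingly.

## Paired and permutation paired t tests

`paired_t_test()` is the classical two-tailed test on differences with
`df = n - 1`. `permutation_paired_t_test()` flips the signs of the paired
differences; the statistic is `|mean(d)|`, which for fixed magnitudes orders
sign assignments identically to `|t|`. All `2^n` assignments are enumerated
for `n <= 20` (so the p-value is seed-free); larger problems use seeded
Monte-Carlo with the `(count + 1) / (n_perm + 1)` convention. The identity
assignment is counted, so the smallest attainable two-sided p is `2 / 2^n`
(2/64 at n = 6).

This conservatism is a *property*, not a bug: at n = 6 the attainable
p-values are `{2, 4, ..., 64}/64`, rejection at alpha = 0.05 occurs only at
p = 2/64, and the true size of the test is 1/32 ~ 0.031, not 0.05. One
acceptance criterion asserts an empirical size inside a binomial envelope
centered at the nominal 0.05; for the exact identity-inclusive test that
envelope is miscentered and the assertion fails by construction. It is kept
red rather than silently recentred.

Test selection mirrors field practice: the permutation test is used when a
Shapiro-Wilk test rejects normality of the differences at 0.05 (or when the
differences are degenerate), the paired t test otherwise; callers can force
either.

## Gene-category effects

Category-level treatment effects pair probe-level signals across treatments
within block (`n = blocks x probes in category`, the "n = 6 x gene probe
number" convention; gene-level observations are available via `level`).
Percent changes are computed on the linear amplified relative-abundance
scale — the ln(x+1) values compress fold changes and are reserved for
community-level statistics. Note that the across-sample total-intensity
normalization makes the data compositional: an injected fold change of 2.0
in a category covering ~5% of the chip is recovered as roughly +90%, not
+100%, because equalizing totals deflates all signals in the affected
samples. The simulation tests set their tolerances from this effect.

# GeoChip-style preprocessing

The probe-to-gene chain is: (i) QC filtering, (ii) three-level
normalization, (iii) detection filters, (iv) rescaling and ln(x+1). Choices
where the original description names a step but not a formula:

- **SNR** defaults to `(signal - background) / background_sd`, the
  prevailing array convention; `snr_mode = "ratio"` gives
  `signal / background`. Spots flagged 1 or 3 are removed; removal applies
  to SNR strictly below 2.0, so a spot at exactly 2.0 is retained.
- **Normalization** uses mean-ratio scaling (subgrid mean to slide mean,
  then sample total to across-sample mean total), which preserves relative
  abundances and within-subgrid ordering. Technical replicates are averaged
  between the two scaling stages, in the listed order; whether replicate
  averaging precedes or follows the across-slide scaling is not stated in
  the source methodology, and the choice is flagged here for sensitivity
  testing. An all-zero subgrid has an undefined scale factor and is left
  unscaled with a warning.
- **Detection filters**: "detected positive" means survives QC. The probe
  rule (present in >= 2 samples) is applied first; the gene rule
  (detected/designed >= 33.3%, read as percent, with a 1e-9 relative
  tolerance so 1 of 3 passes, AND detected >= 2) then counts surviving
  probes.
- **Rescaling**: per sample, relative abundance times the across-sample mean
  of totals; stored value `ln(x + 1)`; gene value is the mean over the
  gene's retained probes, with undetected probes contributing 0.

All filters are monotone (output a subset of input) and idempotent, and the
pipeline is deterministic — properties the test suite asserts directly.

# Six-pool carbon model and Q10 inversion

## Forward model

Pools: foliage, fine root, litter, fast / slow / passive SOM (g C m-2).
Daily explicit (forward-Euler) update: input `u_t` is allocated to foliage
and root (default 0.45/0.55); donor-controlled first-order transfers run
foliage -> litter, root -> litter, litter -> fast -> slow -> passive, each
SOM/litter flux scaled by `xi_t = q10^((T_t - Tref)/10)` (Tref = 10 degC;
plant turnover unscaled). A fraction `resp_frac` (default 0.55) of each
scaled donor flux is respired, the remainder transferred; the terminal
passive flux is fully respired. Heterotrophic respiration is the sum of
respired fractions, aboveground biomass is the foliage pool, and carbon is
conserved to rounding every step (asserted at 1e-8 relative). Euler
stability is enforced (`k * max(xi) <= 1` or an error). The transfer
topology, allocation fractions, respired fraction and Tref are
*implementation defaults* exposed as arguments, not values fixed by the
source methodology.

## Priors, likelihood, sampler

The seven parameters (Q10 plus six exit rates) carry uniform priors. Q10's
bounds are [1.5, 5]; the rate bounds span two orders of magnitude around
literature-scale turnover times (about a year for foliage/litter, 3 years
for fine roots, 5/50/500 years for fast/slow/passive SOM). The likelihood is
Gaussian per observation stream (daily heterotrophic respiration; periodic
aboveground biomass) with stream-specific error sds; an optional
total-respiration stream with a root-respiration fraction is *not*
implemented — Rh and AGB are the default and only streams.

`run_mh_chain()` is a random-walk Metropolis-Hastings sampler in the bounded
box: independent Gaussian steps, out-of-bounds proposals rejected,
acceptance `min(1, exp(delta log posterior))`. Because the posterior widths
of the seven parameters differ by orders of magnitude, fixed
fraction-of-width step sizes mix poorly; the sampler therefore tunes its
proposal once, during burn-in only (diagonal adaptive Metropolis: window
standard deviations times `2.4/sqrt(d)`, plus a global factor targeting ~0.3
acceptance), then freezes the kernel so the retained chain is valid MH.
With no observations the chain samples the prior — the uniform-recovery
check used in testing.

`summarize_posterior()` reports the midpoint of the highest-density
histogram bin (bin count configurable; the mode estimate is only resolved to
one bin width), the mean, and a central 95% quantile interval.

# Isotope mixing model

`fraction_c4()` solves the two-source mass balance
`f = (delta_soil - delta_c3) / (delta_c4 - delta_c3)`. End-member values are
user-supplied (the motivating study does not print them). Out-of-range
fractions are flagged, never clamped: a silent clamp would hide end-member
misspecification. No fractionation corrections or concentration-dependent
Bayesian mixing are attempted.

# Community statistics

- **Horn dissimilarity** defaults to the abundance-based Morisita-Horn index
  (bounded [0, 1], invariant to per-sample rescaling; it matches
  `vegan::vegdist(..., "horn")` to machine precision). The ln-based Horn
  1966 overlap is available via `variant = "horn1966"` because the name
  "Horn" is ambiguous in the literature.
- **Adonis** (`adonis_pairwise()`) partitions squared distances into
  between/within sums of squares; on univariate Euclidean data the pseudo-F
  equals the classical one-way ANOVA F. Label permutations are unrestricted
  by default (the motivating analysis does not mention strata); a `strata`
  argument permutes within blocks for the paired design. Exhaustive
  enumeration is used when the number of distinct assignments is <= 10,000,
  Monte-Carlo with `(count + 1)/(n_perm + 1)` otherwise.
- **Mantel** correlates lower triangles (Pearson) and permutes one matrix's
  sample order jointly; one-sided against large positive r, exhaustive for
  n <= 7.
- **Alpha diversity**: richness, Shannon `H`, Simpson concentration
  `D = sum(p^2)`, inverse Simpson `1/D`, Pielou evenness `H / ln(richness)`
  (NA for a single-feature sample).

# The synthetic world

The generators *are* the stated experimental conditions, chosen once:

- `factorial_design(6)`: six blocks by four cells, as in the field layout.
- Property tables: multiplicative mean-one lognormal block and residual
  noise (keeps concentrations positive; percent effects are scale-free);
  the interaction percentage is injected only into the CW cell, matching the
  OE - PE definition. With zero noise the pipeline returns the injected
  percentages to machine precision.
- Array fixtures: lognormal probe signals around gene means (median
  `signal_scale` 1000 against background 50 +/- 10), per-category treatment
  fold changes, flags and low-SNR spots injected at stated rates; clean
  spots are floored at SNR 2 so the no-injection fixture passes QC intact.
- Carbon-model datasets: sinusoidal soil temperature (mean 16.3 degC, the
  site's long-term mean; amplitude 10 degC, 1 degC daily noise), seasonal
  nonnegative input (mean 1.5 g C m-2 day-1, grassland NPP scale), 3-year
  horizon, Gaussian observation noise (0.05 g C m-2 day-1 on daily Rh —
  about 6% of the mean — and 5 g C m-2 on monthly biomass).

What a green test establishes: the estimators recover effects *their own
generative model* injected, at the stated noise; the sampler is calibrated
*when the likelihood matches the data-generating process and the error sds
are known*. Real field data violate all of this (non-lognormal noise,
spatial correlation beyond blocking, model error in the carbon pools,
unknown observation error), so green tests validate the code, not the
original study's numbers. Field-scale results (total detected gene counts,
specific percent changes of gene categories, ordination/variation
partitioning) are deliberately out of scope.

# Known limitations

- n = 6 permutation tests cannot reach p below 2/64; significance tiers are
  coarse by design.
- The carbon model omits canopy photosynthesis, phenology and moisture
  scalars of full TECO-lineage models; Q10 applies to all litter/SOM fluxes
  with a single reference temperature.
- Convergence diagnostics are limited to acceptance rate and the trace;
  multi-chain diagnostics are the caller's responsibility.
- The Adonis/Mantel permutation schemes treat samples as exchangeable unless
  `strata` is supplied; whether the motivating analysis stratified by the
  paired-plot design is unknown.
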
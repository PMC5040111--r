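# warmclip

Analysis pipeline for **paired-factorial grassland experiments crossing
warming and clipping**, aimed at ecologists and biogeochemists who need the
full computational chain of such studies as reusable, tested code: from raw
functional-gene-array probe tables and plot-level soil/plant measurements to
interaction calls, community statistics, and a Bayesian estimate of the
temperature sensitivity (Q10) of heterotrophic soil respiration.

## What it computes

**Factorial effects.** For each block (paired plot) with treatment cells UU
(control), UW (warmed), CU (clipped), CW (both), percent effects use the
block's own control as denominator:

    W  = 100 (UW - UU) / UU          warming alone
    C  = 100 (CU - UU) / UU          clipping alone
    OE = 100 (CW - UU) / UU          observed combined effect
    PE = W + C                       predicted additive effect

OE is tested against PE per block by a two-tailed paired *t* test, or by an
exact sign-flip permutation paired *t* test (all 2^n assignments for
n <= 20) when the differences fail a Shapiro-Wilk normality check. The
interaction is *additive* (p > 0.05), *synergistic* (OE significantly above
PE) or *antagonistic* (below), with a marginal tier at p <= 0.10.

**Array preprocessing.** GeoChip-style probe tables pass through QC (flags
1/3 removed; SNR = (signal - background)/background_sd < 2 removed),
three-level normalization (subgrid -> slide, technical-replicate averaging,
sample total -> mean total), detection filters (gene kept iff detected
probes >= 33.3% of designed AND >= 2; probe kept iff seen in >= 2 samples),
then relative-abundance rescaling and ln(x + 1).

**Q10 inversion.** A six-pool carbon model (foliage, fine root, litter,
fast/slow/passive SOM; donor-controlled first-order transfers,
litter/SOM fluxes scaled by `q10^((T - 10)/10)`) is inverted by random-walk
Metropolis-Hastings under uniform priors — Q10 bounded to [1.5, 5] — against
daily heterotrophic respiration and periodic aboveground biomass, reporting
the posterior mode, mean and 95% credible interval.

**Community statistics.** Morisita-Horn dissimilarity, pairwise
permutational MANOVA (Adonis pseudo-F), Mantel tests, and alpha diversity
(richness, Shannon, Simpson, inverse Simpson, evenness).

**Isotope mixing.** Two-source delta-13C mass balance for the fraction of
soil carbon derived from C4 plants.

A synthetic-data module generates all inputs with known ground truth, so the
entire pipeline is testable without field data.

## Worked example

```r
library(warmclip)

design <- factorial_design(6)   # 6 blocks x {UU, UW, CU, CW}
tab <- generate_factorial_properties(design, list(
  soil_temperature = effect_spec(14.1, warming_pct = 8.1, clipping_pct = 0.8,
                                 interaction_pct = 5.5, block_sd = 0.15,
                                 noise_sd = 0.02, seed = 101),
  soil_ammonium = effect_spec(5.6, warming_pct = -6.6, clipping_pct = -19.8,
                              block_sd = 0.2, noise_sd = 0.25, seed = 102)))
effects_table(tab, seed = 1)
#>           variable      W      C   OE     PE OE_minus_PE p_value test_used
#> 1 soil_temperature  6.309   1.57 13.6   7.88        5.75 0.00554  paired_t
#> 2    soil_ammonium -0.229 -11.48 -4.0 -11.71        7.71 0.76576  paired_t
#>          tier interaction
#> 1 significant synergistic
#> 2        none    additive
```

The temperature variable was generated with a +5.5% interaction injected
into the combined cell on top of ~2% measurement noise: the estimated
`OE - PE` is +5.75% and the paired test calls it synergistic (p = 0.006).
Ammonium, generated additive with 25% noise, is correctly labeled additive.

```r
ds <- generate_teco_dataset(teco_dataset_spec(
  true_params = teco_parameters(q10 = 2.5), seed = 7))
chain <- run_mh_chain(ds$drivers, ds$obs, config = mh_config(seed = 8),
                      initial = ds$initial)
chain
#> teco_mcmc: 20000 steps (burn-in 5000), acceptance 0.21
s <- summarize_posterior(chain, "q10")
#> Q10 mode 2.50, mean 2.50, 95% CI [2.48, 2.52]
```

Three years of synthetic daily respiration and monthly biomass generated at
Q10 = 2.5 are inverted back to a posterior mode of 2.50 with a tight
credible interval — the parameter-recovery behavior the acceptance tests
assert across replicate datasets at Q10 in {2.0, 2.5, 3.5}.

A command-line interface covers the same pipeline
(`exec/warmclip simulate|preprocess|effects|invert-q10|stats|mixing`, TOML
configs; see `?warmclip_cli`).

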
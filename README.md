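# dissipath

Steady-state dissipation and performance analysis of enzyme catalytic
cycles in R.

Enzymes convert substrate to product by cycling through a small number of
conformations — free enzyme E, enzyme–substrate complex ES, optionally an
intermediate EZ, and enzyme–product complex EP. When substrate and product
concentrations are clamped (the chemiostatic condition), the cycle runs as
a genuine non-equilibrium steady state, and if *all* microscopic rate
constants are known, both the familiar kinetic performance parameters and
the thermodynamic cost of catalysis can be computed exactly. `dissipath`
is for enzymologists and systems biologists who want to put those two
descriptions side by side: how do k<sub>cat</sub> and
k<sub>cat</sub>/K<sub>m</sub> relate to the free energy an enzyme
dissipates per second?

## The model

For a reversible N-state cycle (N = 2, 3, 4) with forward first-order
constants k<sub>1</sub>, k<sub>3</sub>, … and reverse constants
k<sub>2</sub>, k<sub>4</sub>, … (binding steps folded with [S] and [P]),
the package computes in closed form:

- net cycle flux **J** = (∏ k<sub>odd</sub> − ∏ k<sub>even</sub>)/D, with
  D the sum of the cycle's King–Altman directed-tree terms, and one-way
  fluxes J⁺, J⁻ with J = J⁺ − J⁻;
- thermodynamic force **X/RT** = ln K, K = ∏ k<sub>odd</sub>/∏ k<sub>even</sub>;
- dissipation function **φ/RT = J·X/RT** (s⁻¹), equal to the entropy
  production times T, reduced by RT;
- **k<sub>cat</sub>**, **K<sub>m</sub>**, **k<sub>cat</sub>/K<sub>m</sub>**
  for the forward direction;
- stationary state probabilities (master equation) and their Shannon
  entropy.

On top of that sit a packaged 58-reaction compilation of observed values
with its summary statistics, two stochastic noise protocols (forward
variations at fixed step equilibrium constants; trade-off variations at
fixed total force, with a maximum-dissipation search and Eff/Tur
classification), log-log power-law scaling regression with bootstrap
sensitivity analysis, and seeded synthetic-data generators. The methods
vignette (`vignettes/dissipation-scaling.Rmd`) documents the model,
conventions and numerical choices.

## Worked example

A toy three-state isomerase, k = (100, 1, 10, 1, 10, 1) s⁻¹ at
[S] = 1 mM:

```r
library(dissipath)

sc <- reaction_scheme(c(100, 1, 10, 1, 10, 1), substrate_conc = 1e-3,
                      product_conc = 1e-4, label = "toy isomerase")
performance_params(sc)
#> $kcat        4.761905          # s^-1, = k3*k5/(k3+k4+k5)
#> $km          5.285714e-05      # M
#> $efficiency  90090.09          # M^-1 s^-1

steady_state(sc)
#> <steady_state_solution>
#>   J = 4.49798 s^-1 (J+ = 4.49843, J- = 0.000449843)
#>   X/RT = 9.21034, phi/RT = 41.4279 s^-1, K = 10000
#>   p = 0.04993 0.49528 0.45479  (entropy 0.856 nats)
```

The cycle turns over 4.5 times per second per enzyme against a
9.2 RT free-energy drop, dissipating 41.4 RT·s⁻¹. Searching the
fixed-force trade-off family for the maximum-entropy-production state:

```r
res <- find_max_dissipation(sc, method = "grid")
#> g_opt 0.3162, phi_max 53.9 vs phi_obs 41.4
#> efficiency fold 0.318, kcat fold 1.56  ->  "Tur"
```

The optimum raises dissipation by 30% and turnover by 56% while *lowering*
efficiency — this scheme is a Tur-type reaction: maximum dissipation can
improve its turnover number but not its specificity.

The packaged compilation reproduces the published scaling law:

```r
tab <- load_reaction_table(1)
loglog_power_fit(tab$efficiency, tab$dissipation_rt)
#> <power_law_fit> n = 58: log10(y) = -1.831 + 0.726 log10(x), R^2 = 0.927
#>   exponent 95% CI (0.672, 0.781), slope p < 0.001
```

i.e. dissipation grows as roughly the 0.73 power of catalytic efficiency
across six orders of magnitude, with the "perfect" diffusion-limited
enzymes (carbonic anhydrase II, ketosteroid isomerase, inorganic
pyrophosphatase) at the high-dissipation end and generalist/bifunctional
enzymes concentrated in the low-dissipation tail
(`generalist_partition_counts(tab, 30)` → 1 generalist in the top 30,
7 in the bottom 28). `reproduce_paper_stats()` recomputes the full set of
published summary statistics — both regressions, the bootstrap, the
Mann–Whitney comparison, partition counts and k<sub>cat</sub>/J ratios —
each paired with its reference value.

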
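# tumoreqtl

Cell-type-aware *cis*-eQTL mapping from bulk tumor expression data.

## The problem

Expression quantitative trait loci (eQTLs) in cancer have almost always been
mapped from bulk tumor biopsies. A biopsy is not a pure sample of cancer
cells: it is a mixture of cancer cells and tumor-associated normal cells
(immune cells, stroma, normal epithelium), and tumor purity — the
cancer-cell fraction — varies widely across patients. A regression of bulk
expression on genotype therefore recovers associations from *both*
compartments, and an eQTL that acts only in the normal cells can easily be
misattributed to the cancer itself.

`tumoreqtl` implements a purity-aware mapping strategy for analysts working
with tumor expression cohorts (e.g., TCGA-style data with genotypes,
RNA expression and consensus purity estimates), plus a complete simulation
framework for benchmarking it.

## The models

For each SNP-gene pair, with expression $y$, genotype dosage
$x \in \{0,1,2\}$, genotype principal components $\boldsymbol{a}$ and
expression-heterogeneity factors $\boldsymbol{b}$:

**Conventional model**

$$y = \beta_0 + \beta_1 x + \boldsymbol{\beta_2}\cdot\boldsymbol{a} +
\boldsymbol{\beta_3}\cdot\boldsymbol{b} + \epsilon$$

**Interaction model** — adds the normal-cell fraction
$p = 1 - \text{purity}$ and its product with genotype:

$$y = \beta_0 + \beta_1 x + \boldsymbol{\beta_2}\cdot\boldsymbol{a} +
\boldsymbol{\beta_3}\cdot\boldsymbol{b} + \beta_4 p + \beta_5 (p \times x) +
\epsilon$$

Because $p = 0$ corresponds to a sample of pure cancer cells, $\beta_1$ in
the interaction model is the eQTL effect **extrapolated to 100% cancer
cells**; $\beta_5$ measures how the effect differs between cell types.
Significance is a two-sided *t* test on $\beta_1$; false-discovery rates use
Benjamini-Hochberg. A *Z* statistic,
$Z = (\beta_A - \beta_B)/\sqrt{SE_A^2 + SE_B^2}$, compares effect sizes
between two cohorts.

The simulator builds cohorts with known ground truth: per-gene baselines
from Normal(1, 1), effect sizes on a ±0.5 grid (step 0.01), six eQTL
architecture groups of 100 genes (cancer-specific, normal-specific, shared,
independent, none, shared-with-noise) plus optional extra normal-only
genes, purity-weighted linear mixing of the two compartments, and
quantile-preserving measurement noise on purity.

## Worked example

```r
library(tumoreqtl)

co <- simulate_cohort(sim_config(), seed = 7)
co
#> <eqtl_cohort>
#>   1000 samples x 600 genes (one cis variant per gene)
#>   groups: 1=100 2=100 3=100 4=100 5=100 6=100
#>   purity: mean 0.717 sd 0.140
#>   seed: 7

res_conv <- eqtl_scan(co, model = "conventional")
measured <- add_purity_noise(co$purity, noise_sd = 0.1, seed = 8)
res_int  <- eqtl_scan(co, model = "interaction", purity = measured)

classify_performance(res_conv, co$truth)
#> <eqtl_performance: conventional model, q < 0.05>
#>   sensitivity 82.8%  specificity 73.5%  true FDR 13.8%
#>   TP 331  FP 53 (51 normal-driven)  TN 147  FN 69

classify_performance(res_int, co$truth)
#> <eqtl_performance: interaction model, q < 0.05>
#>   sensitivity 62.5%  specificity 97.5%  true FDR 2.0%
#>   TP 250  FP 5 (4 normal-driven)  TN 195  FN 150
```

Both scans impose a nominal BH FDR of 5%, but against the simulated truth
the conventional model's *realized* FDR is 13.8% — almost all of its false
discoveries are eQTLs simulated only in the normal compartment — while the
interaction model keeps the realized FDR at 2.0%, at the cost of power
(extrapolating to a pure-cancer state costs precision). Per-pair records
(`beta1`, `se1`, `t`, `p`, `q`, plus `beta4`/`beta5` for the interaction
model) come back as a tibble, so results chain directly into dplyr; `tidy()`
and `glance()` methods summarize performance objects, and `autoplot()` draws
purity-binned effect plots (`binned_effects()`) and noise-sweep curves
(`noise_sweep()`).

A thin command-line front end (`inst/cli/tumoreqtl.R`) exposes `simulate`,
`map`, `evaluate`, `sweep`, `zdiff` and `pipeline` subcommands over the same
functions; `run_pipeline()` executes a YAML-configured workflow and writes a
manifest alongside its TSV outputs.

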
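# seqnoise

Technical noise in small RNA sequencing is not Poisson across the board.
When the same RNA sample is prepared and sequenced repeatedly, per-gene
counts across the replicate libraries show two distinct regimes:

- **low-read genes** (mean reads roughly below 10): variance ≈ mean, the
  Poisson signature of rare-event counting;
- **high-read genes**: variance ∝ mean², the signature of a **gamma**
  distribution with roughly constant coefficient of variation.

The quadratic regime follows mechanistically from PCR amplification: each
template molecule doubles with probability *p* (the amplification
efficiency) per cycle, a Galton–Watson branching process whose per-molecule
limit is approximately exponential; summing the *m* starting molecules of a
gene gives an approximately gamma-distributed amplified count.

`seqnoise` is an R toolkit for scientists analysing technical-replicate
count data (cell lines, pooled samples, benchmark libraries). It provides:

- **Diagnostics** — per-gene moments across replicates, the OLS fit of
  `log10(variance + 1)` on `log10(mean + 1)` (slope ≈ 1 ⇒ Poisson,
  slope ≈ 2 ⇒ gamma), and per-gene Kolmogorov–Smirnov goodness-of-fit
  tests against plug-in Poisson(λ̂) and Gamma(k̂, θ̂) fits.
- **Differential expression for two groups of replicates**, with the
  variance model made explicit. Identity-link GLM Wald tests in closed
  form under the Poisson family (z = Δ/√(μ̂₀/n₀ + μ̂₁/n₁), normal
  reference) and the gamma family
  (t = Δ/√(φ̂(μ̂₀²/n₀ + μ̂₁²/n₁)), t reference with N−2 df, Pearson
  dispersion φ̂), plus the simple alternative: a **cube-root
  transformation followed by a two-sample t-test**, which normalizes
  gamma-distributed counts (Wilson–Hilferty) and tracks the gamma GLM
  closely.
- **A PCR simulator** — the branching process itself, its exact
  mean/variance, a multinomial read-sampling stage, and a report
  quantifying how close the amplified counts are to a fitted gamma.
- **A synthetic-data generator** — Poisson-gamma hierarchical counts
  (variance = μ + μ²/k) that reproduce both regimes in one mechanism, with
  configurable replicates, DE fraction and fold changes, plus a
  ground-truth table.
- **An evaluation harness** — Monte-Carlo type-I error, power, p-value
  agreement between methods, and a discordance screen for genes one method
  calls significant and another does not.

## Worked example

```r
library(seqnoise)

# technical sextuplicates for two samples, gamma noise (shape 10),
# 20% of genes differentially expressed at fold change 4
sim <- generate_matrix(synthetic_config(n_genes = 2000,
                                        mean_grid = c(100, 10000),
                                        gamma_shape = 10,
                                        de_fraction = 0.2, fold_changes = 4,
                                        seed = 1))

fit_mean_variance_line(gene_moments(sim$counts, "A"), mean_threshold = 100)
#> log-log mean-variance fit (1973 genes with mean > 100)
#>   log10(var + 1) = -1.0801 + 1.9973 * log10(mean + 1)

tab <- run_de_table(sim$counts, methods = c("poisson_glm", "gamma_glm",
                                            "crt_ttest"))
method_agreement(tab)
#>    method_a    method_b correlation n_genes
#> 1 crt_ttest   gamma_glm   0.9791858    2000
#> 2 crt_ttest poisson_glm   0.8448407    2000
#> 3 gamma_glm poisson_glm   0.8664025    2000

head(discordance_report(tab), 2)
#>   method_strict method_lenient    gene_id p_strict_method p_lenient_method
#> 1   poisson_glm      crt_ttest gene_00004    6.627933e-14        0.6205306
#> 2   poisson_glm      crt_ttest gene_00013    1.061231e-05        0.8238525
#>    mean_g0  mean_g1
#> 1 5962.833 5633.333
#> 2 2858.000 2723.667
```

The fitted slope 2.00 is the quadratic (gamma) law. The agreement table
shows the cube-root t-test ordering genes almost identically to the gamma
GLM (Spearman 0.98) while the Poisson GLM diverges; the discordance rows
are genes the Poisson test calls overwhelmingly significant (p < 1e-4)
although the regime-appropriate tests see nothing (p > 0.5) — false
positives produced by assuming variance = mean when variance ∝ mean².

A command-line interface with `diagnose`, `de`, `simulate-pcr`,
`simulate-data` and `evaluate` subcommands is in `inst/cli/seqnoise`; all
randomness flows through `--seed` and repeated runs are byte-identical.

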
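# archwalk

Tools for asking how demographic and selective history shape the genetic
architecture of a quantitative trait — written for the contrast between a
large, long-established population sitting at its fitness optimum
(stabilizing selection, many small-effect variants) and small, recently
founded island populations adapting to a shifted optimum through a
Fisher–Orr adaptive walk (few large-effect substitutions arriving first,
smaller ones later). The motivating system is flowering time in highly
selfing plant accessions grown in a replicated common garden.

## What the package computes

Given a biallelic VCF of inbred lines and a replicate-level phenotype table,
`archwalk` runs the full chain:

* per-line **median phenotypes** and broad-sense heritability
  H² = σ²_line / (σ²_line + σ²_res) from the block design (REML);
* **mixed-model association** with a centered kinship matrix
  K = (1/m) Σⱼ (xⱼ − x̄ⱼ1)(xⱼ − x̄ⱼ1)ᵀ: the variance ratio
  λ = σ²_g/σ²_e is profiled through one eigendecomposition of K, each
  marker is tested by a 1-df likelihood-ratio test with λ re-optimized per
  marker, and PVE = λ̂·k̄/(λ̂·k̄ + 1) with k̄ = tr(K)/n;
* **Lindley local scores** sᵢ = −log₁₀ pᵢ − ξ, Lᵢ = max(0, Lᵢ₋₁ + sᵢ),
  with per-chromosome significance thresholds from uniform-null resampling;
  each excursion above threshold is a candidate locus;
* **LD reduction**: greedy clumping (p < 0.01, 1 Mbp, r² > 0.8),
  sliding-window pruning (50/10/0.3), and one representative SNP per locus
  thinned at r² > 0.5;
* **architecture statistics**: maximum-likelihood comparison (AIC, k = 1
  each) of an exponential (λ̂ = 1/x̄) versus a uniform-(0, θ̂] (θ̂ = max)
  model for the absolute effect sizes — exponential is the adaptive-walk
  signature, uniform the stabilizing-selection one — plus Mann–Whitney
  between-population tests, Pearson correlations of derived allele
  frequency with effect size and of allele age with frequency, Watterson's
  θ_W = S/(aₙL), N_e = θ_W/(4μ), and a neutral allele-age expectation
  t̄(p) = −4N_e·p·ln(p)/(1 − p).

A forward Wright–Fisher simulator (partial selfing, infinite sites,
Gaussian stabilizing selection, optimum shift with a founder-event
bottleneck, per-mutation ground truth) generates both study regimes so the
whole pipeline is testable without any external data.

## A worked example

```r
library(archwalk)
res <- run_two_regimes(seed = 1)
print(res$report)
```

```
Genetic-architecture report: 2 population(s)
  island: 7 loci, 1 zones, 1 clumps, H2 = 0.946, PVE = 0.988; effect sizes favor exponential (AIC 29.36 vs 38.90)
  continent: 3 loci, 4 zones, 13 clumps, H2 = 0.951, PVE = 0.977; effect sizes favor uniform (AIC 5.29 vs 1.43)
  MW |beta| island-continent: U = 15.0, p = 0.3833
```

The island's locus effects (days) are 13.96, 1.17, 0.93, 0.82, 0.68, 0.57,
0.05 — one dominant substitution followed by a tail of small ones, which the
AIC comparison reads as exponential; the continent's detected loci have
similar moderate effects and more clumps, and read as uniform. Heritability
and PVE are the replicate-based and relatedness-based fractions of
phenotypic variance explained.

The same comparison on a hand-held effect set:

```r
fit_effect_distributions(c(0.1, 0.2, 0.4, 3.0))
#> Effect-size distribution fit (n = 4 loci)
#>   exponential: rate = 1.081  logLik = -3.6882  AIC = 9.38
#>   uniform(0, theta]: theta = 3  logLik = -4.3944  AIC = 10.79
#>   chosen: exponential
```

File-based use mirrors the in-memory chain:

```r
out <- run_sim("island_run", config = island_config(1))   # VCF + TSVs
gw  <- run_gwas(out$paths$vcf, out$paths$phenotypes, "gwas_out")
run_architecture("gwas_out/assoc.tsv", out$paths$vcf, "arch_out",
                 population = "island")
```

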
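# transfinemap

Transancestral meta-analysis and Bayesian fine-mapping of case-control
GWAS loci, for statistical geneticists who want to localize causal
variants by combining studies across ancestry groups.

A GWAS association signal usually spans many variants that are nearly
interchangeable within one population because of linkage disequilibrium
(LD). When the causal variant is shared across ancestry groups, LD around
it differs between groups, and combining studies across ancestries both
increases sample size and lets the differing correlation structures cancel
out everything except the variants that track the causal allele in every
population. `transfinemap` implements this analysis end-to-end:

- **Per-study association**: additive logistic regression of case-control
  status on dosage with covariates, variant QC (MAF ≥ 1%, info ≥ 0.4), and
  exact conditioning on index-variant genotypes.
- **Fixed-effects meta-analysis**: inverse-variance weighting, Cochran's
  *Q*, genome-wide significance at *p* < 5×10⁻⁸.
- **Bayesian transancestral meta-analysis**: studies are clustered by a
  centre-based Bayesian partition model over their pairwise mean allele
  frequency distances; within a cluster the latent allelic effect is
  *b* ~ N(0, τ²) (τ = 0.2 by default), and the marginal likelihood is
  averaged over all enumerated partitions. Reported are the log₁₀ Bayes
  factor of association (genome-wide significant at ≥ 6) and a log₁₀ Bayes
  factor of between-study heterogeneity (single-cluster vs unconstrained).
- **Distinct signals**: stepwise conditional delineation under the joint
  threshold (log₁₀BF ≥ 6 **and** *p* < 5×10⁻⁸), then leave-one-out
  refinement of each index variant.
- **99% credible sets**: per-variant posterior masses
  π*_j_* = Λ*_j_* / Σ*_k_* Λ*_k_* from the (conditional) Bayes factors,
  ranked and accumulated to the credible level; interval spans are
  inclusive (max − min + 1 bp).
- **Annotation overlap**: credible-set variants against BED regulatory
  tracks, with summed posterior mass per element.
- **A multi-ancestry simulator** (Balding–Nichols frequency drift +
  haplotype-mosaic LD divergence, case-control rejection sampling,
  imputation-quality degradation) so the whole pipeline is testable and
  calibratable without consortium genotypes.

## Worked example

Simulate a locus with two planted causal variants (allelic OR 1.4) shared
by three diverged ancestry groups, then run the full pipeline:

```r
library(transfinemap)

cfg <- pipeline_config(
  seed = 11,
  n_variants = 30, region_length = 60000, n_ancestral_haplotypes = 300,
  ancestries = data.frame(
    label       = c("EAsia", "EurSAsia", "Afr"),
    F           = c(0.05, 0.10, 0.15),      # Balding-Nichols drift
    switch_rate = c(2e-4, 8e-4, 2e-3),      # mosaic switch rate per bp
    n_haplotypes = c(250, 250, 250),
    n_case      = c(1500, 1500, 1500),
    n_control   = c(1500, 1500, 1500)),
  n_causal = 2, causal_or = 1.4)

bundle <- run_pipeline(cfg)
bundle
#> Transancestral fine-mapping report
#>   distinct signals: 2
#>   [1] snp0021  OR 1.452 (1.353-1.559)  P 4.84e-25  log10BF 21.35  BF_het -0.36
#>   [2] snp0001  OR 1.443 (1.343-1.550)  P 8.69e-24  log10BF 20.11  BF_het -0.39
#>   seed 11, config 9031443e9c7985828ce0cf7544bf0325
```

Both planted signals are recovered at genome-wide significance, the fitted
odds ratios cover the simulated value 1.4, and the negative heterogeneity
Bayes factors correctly report that allelic effects are homogeneous across
the three ancestry groups. The credible-set comparison shows the
resolution gain from combining ancestries — where a single clade needs up
to 28 variants, the transancestral analysis pins each signal to one:

```r
print(bundle$credset_comparison, row.names = FALSE)
#>  INDEX_SNP    ANALYSIS SNPS DISTANCE_BP    INTERVAL
#>    snp0021     clade_1    1           1 39124-39124
#>    snp0021     clade_2    1           1 39124-39124
#>    snp0021     clade_3   28       55713   904-56616
#>    snp0021 all_studies    1           1 39124-39124
#>    snp0001     clade_1    6       53425    34-53458
#>    snp0001     clade_2    1           1       34-34
#>    snp0001     clade_3    1           1       34-34
#>    snp0001 all_studies    1           1       34-34

bundle$element_masses$snp0001
#>   ELEMENT    STATE N_SNPS TOTAL_PI
#> 1   el001 enhancer      1        1
```

The second signal's entire credible set (total π = 1.00) falls inside a
simulated islet enhancer element — the kind of annotation convergence the
analysis is designed to surface.

A thin command-line wrapper is installed with the package
(`system.file("cli", "transfinemap.R", package = "transfinemap")`) with
`run-all` and `simulate` subcommands over a YAML configuration.

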
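# boostgwas

Insulin resistance drives type 2 diabetes, fatty liver and cardiovascular
disease, but the gold-standard measurement (glycemic-clamp glucose
disposal) cannot be performed at biobank scale. The ratio of serum
triglycerides to HDL cholesterol (TG/HDL) is a cheap surrogate that is
strongly correlated with clamp measurements — and a GWAS of TG/HDL is
therefore a route to insulin-resistance genes, *if* one can separate
loci that genuinely act on the ratio from loci that merely move TG or
HDL.

`boostgwas` implements that analytic path as a tested, reusable R
pipeline:

* **Boost score.** At each genomic risk locus,
  `BS = -log10 p(TG/HDL) - max(-log10 p(TG), -log10 p(HDL))`, computed
  entirely in `-log10` space so extreme associations (p down to
  10^-1952) never underflow. Positive scores flag candidate
  insulin-resistance loci; the top quartile by rank is carried forward.
* **Sex dimorphism.** `t = (beta_f - beta_m) / sqrt(se_f^2 + se_m^2)`
  from sex-stratified scans, Bonferroni-tested over the discovered loci.
* **Fine-mapping.** A sum-of-single-effects Bayesian model on z-scores
  and LD over 1 Mb windows, yielding per-SNP posterior inclusion
  probabilities and purity-filtered 95% credible sets.
* **Gene nomination.** Causal SNPs (PIP > 0.1) are matched to
  annotations with precedence exonic > promoter > fine-mapped eQTL >
  regulatory, falling back to the nearest gene; direction-of-effect is
  called from coding deleteriousness or eQTL/GWAS concordance.
* **Gene-level corroboration.** Nested rare-variant burden masks with a
  maximum-dosage collapse, predicted-expression (TWAS-style)
  association, approximate-Bayes-factor colocalization, proxy-SNP
  replication classification, and mediation analysis.
* **Synthetic cohorts.** `simulate_cohort()` generates LD-block
  genotypes (Gaussian copula with calibrated dosage correlation),
  correlated log-lipid phenotypes with planted locus classes
  (ratio-specific, component-specific, shared-lipid, sex-dimorphic,
  null), rare deleterious variants, expression weights and a mediator —
  plus the ground truth needed to test recovery, so the whole analysis
  runs with no data download.

## Worked example

```r
library(boostgwas)

# a single boost score from -log10 p exponents (ratio, TG, HDL)
boost_score(412, 0, 1952, log10p = TRUE)
#> [1] -1540        # HDL-driven locus: strongly negative, a lipid locus

# full pipeline on the default synthetic cohort (20,000 individuals,
# 20 planted loci; ~45 s on one core)
b <- run_pipeline(pipeline_config(sim = sim_config(n_individuals = 20000, seed = 1)))
print(b)
#> pipeline_bundle
#>  - simulate: 20000 individuals, 480 SNPs, 20 planted loci (seed 1)
#>  - gwas: lambda_gc(TGHDL_all) = 202.4213 (recorded, correction not applied: signal-dense panel)
#>  ...
#>  - clump: 13 genomic risk loci at p < 5e-08
#>  - boost: 3/13 loci in the top quartile (implied threshold 57.26); 7 with score > 0
#>  - sexdim: 3/13 loci sex-dimorphic at p < 0.05/13
#>  - finemap: 3/3 selected loci converged
#>  - nominate: 3 loci with a causal variant and a nominated gene
#>  - evidence: burden tests on 8 gene-mask pairs; twas t = 18.13; mediated proportion = 0.51

b$report[, c("gene", "boost_score", "annotation", "direction", "true_class", "gene_correct")]
#>      gene boost_score annotation   direction     true_class gene_correct
#> 1 GENE03A    77.86956     Exonic LOF_harmful ratio_specific         TRUE
#> 2 GENE01A    69.91533     Exonic LOF_harmful ratio_specific         TRUE
#> 3 GENE04A    57.26417     Exonic LOF_harmful ratio_specific         TRUE
```

Every top-quartile locus here is a planted ratio-specific locus and each
nominated gene is the planted target: the boost ranking does what it is
for. The funnel (`b$funnel`) records locus counts through each stage;
the burden table shows the planted 0.2-SD rare-variant effect gaining
significance as the mask stringency relaxes (p = 0.19 for the 2-variant
pLOF mask with 35 carriers, p = 0.005 for all 12 rare variants with 313
carriers); `b$mediation` estimates the planted 50% mediated fraction as
0.51 (CI 0.46–0.55).

The inflation factors logged above are expected to be enormous on the
synthetic panel — most simulated SNPs tag a planted locus, so the median
test statistic is not a null-median estimate. Genomic-control
*correction* is therefore opt-in (`apply_gc = TRUE`); `genomic_control()`
itself is fully implemented and calibrated on mostly-null input.

A thin command-line wrapper is installed at
`inst/scripts/run_pipeline.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/run_pipeline.R", package="boostgwas"))')" \
    --seed 1 --n 20000 --outdir pipeline_out
```

## Package layout

| Path | Contents |
|---|---|
| `R/synthdata.R` | synthetic cohort generator and ground truth |
| `R/gwas_core.R` | phenotype transforms, OLS scan, QC, genomic control |
| `R/loci.R` | FUMA-style clumping, positional overlap, proxy replication |
| `R/locus_stats.R` | boost score, top-quartile selection, sex dimorphism |
| `R/finemap.R` | sum-of-single-effects fine-mapping, credible sets |
| `R/nominate.R` | SNP-to-gene nomination, direction of effect, colocalization |
| `R/gene_evidence.R` | burden masks/tests, predicted expression, mediation |
| `R/pipeline.R` | end-to-end orchestration and reporting |
| `vignettes/boostgwas-methods.Rmd` | the methods vignette (model, defaults, limitations) |
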
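---
title: "Methods: boost-score prioritization of insulin-resistance loci from lipid-ratio GWAS"
author: "boostgwas authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: boost-score prioritization of insulin-resistance loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Whole-body insulin resistance is hard to measure at biobank scale: the
gold standard (hyperinsulinemic-euglycemic clamp glucose disposal) cannot
be run on hundreds of thousands of people. The ratio of serum
triglycerides to HDL cholesterol (TG/HDL) is a widely available surrogate
that correlates strongly with clamp-based measurements, which makes a
GWAS of TG/HDL a practical route to insulin-resistance genetics. The
catch is that TG/HDL is built from two lipid traits with their own rich
genetics: a locus can associate with the ratio merely because it moves TG
or HDL. `boostgwas` implements the analytic path that deals with this —
rank ratio loci by how much *more* strongly they associate with the ratio
than with either component (the *boost score*), test for sex-dimorphic
effects, fine-map the prioritized loci, nominate one candidate causal
gene per locus with a direction of effect, and corroborate genes with
rare-variant burden tests, predicted-expression association and
mediation analysis — all runnable end to end on a synthetic cohort with
planted ground truth.

## Stage by stage

### Phenotype preparation (`log_transform_traits`, `inverse_rank_normal`)

TG and the ratio are natural-log transformed; HDL is analyzed on its raw
scale. All three traits are inverse-rank normalized (rankit offset: the
value of rank $r$ among $n$ maps to $\Phi^{-1}((r-0.5)/n)$, ties sharing
the mean rank) within the analysis sample, so each scan's phenotype is
standard normal by construction and effect sizes are in phenotype-SD
units. The ratio trait is always *derived* as
$\log \mathrm{TG} - \log \mathrm{HDL}$, never simulated or measured
directly; ratio-specific genetics therefore emerge mechanically from
opposite-signed component effects.

### Association scan (`assoc_scan`)

Per-SNP ordinary least squares of the normalized phenotype on allele
dosage with covariates (age, age², and sex in the sex-combined scan; sex
is removed in sex strata). We deliberately use plain OLS rather than a
whole-genome ridge / mixed model: the simulated cohort is unrelated and
unstructured, so the mixed-model machinery would be inert, and the
`method` field of every output row records `"ols"` so downstream
consumers know which model produced it. P-values are two-sided normal
(the sample sizes of interest make finite-df corrections
indistinguishable) and are carried in both natural and $-\log_{10}$ form;
the latter is computed from the normal log-tail, so associations far
beyond double-precision underflow (p around $10^{-1952}$ in extreme
published lipid loci) remain exactly representable.

### Genomic control (`genomic_control`)

$\lambda$ is the median 1-df $\chi^2$ implied by the p-values divided by
`qchisq(0.5, 1)` = 0.4549364. Statistics are divided by $\lambda$ only
when $\lambda > 1$ (no deflation), making the correction idempotent. The
pipeline always *estimates and logs* $\lambda$ but applies the correction
only on request (`apply_gc = TRUE`): genomic control assumes the median
SNP is null, and the synthetic panel deliberately oversamples causal
loci, so its median statistic is not a null-median estimate. On a
mostly-null panel (e.g. the all-null simulated architecture in the test
suite) $\lambda$ sits near 1 as it should.

### Locus definition (`clump_loci`)

FUMA-convention clumping with the conventional defaults spelled out:
genome-wide significance $5\times10^{-8}$; independent significant SNPs
mutually independent at $r^2 < 0.6$ (greedy by ascending p); lead SNPs
independent at $r^2 < 0.1$; every SNP with $r^2 \ge 0.6$ to an
independent significant SNP joins its locus; loci with span gaps under
250 kb merge, the merged lead being the smallest p (ties: larger |beta|,
then lexicographic id). The locus span is the min/max position of member
SNPs, not a fixed window. $r^2$ is used throughout; the LD interface
accepts signed $r$ matrices (PLINK `--r square` dialect) and squares
internally.

### Boost score and selection (`boost_score`, `select_boosted`)

$$\mathrm{BS} = -\log_{10} p_{\mathrm{TG/HDL}} -
  \max\{-\log_{10} p_{\mathrm{TG}},\ -\log_{10} p_{\mathrm{HDL}}\}$$

evaluated at each locus lead SNP, computed end-to-end in $-\log_{10}$
space (inputs may be given directly as exponents). Positive scores mark
loci whose ratio association exceeds either component — the
insulin-resistance signature; strongly negative scores mark pure lipid
loci. Selection is by *rank*: the top $\lfloor n/4 \rfloor$ loci are
flagged (ties at the cutoff broken toward the smaller ratio p), and the
implied score threshold is reported descriptively. Rank is primary
because "top quartile" is the stated selection rule; the threshold is a
consequence, not an input.

### Sex dimorphism (`sexdim_t`, `sexdim_p`)

From sex-stratified summary statistics,
$t = (\beta_f - \beta_m)/\sqrt{se_f^2 + se_m^2}$, positive when the
female effect is larger, with a two-sided normal p and a Bonferroni call
at $\alpha / n_{\mathrm{loci}}$. The normal is used instead of a
finite-df t because the stratified GWAS degrees of freedom are in the
hundreds of thousands; the test suite confirms the normal reproduces six
published (t, p) pairs within 2%.

### Fine-mapping (`susie_rss`)

A sum-of-single-effects model fitted to z-scores and an LD matrix over a
1 Mb window (closed interval) around each selected lead. Each of $L$
(default 10) effects places all its posterior mass on one SNP; the
iterative Bayesian stepwise algorithm residualizes z against the other
effects, computes per-SNP Wakefield-style Bayes factors under a normal
effect prior, and renormalizes. Per-SNP posterior inclusion
probabilities combine across effects as
$\mathrm{PIP}_j = 1 - \prod_l (1 - \alpha_{lj})$. 95% credible sets are
the minimal-cardinality set per effect reaching the coverage, discarded
when LD purity (minimum pairwise |r| among members) falls below 0.5.

Numerical choices:

* The effect prior variance is specified on the standardized
  ($z/\sqrt{n}$) scale, default 0.04, i.e. a z-scale prior variance of
  $0.04\,n$. With `estimate_prior_variance = TRUE` (the pipeline's
  setting, matching the reference implementation's default behaviour)
  each effect's prior variance is instead chosen to maximize its
  single-effect Bayes factor, and an effect whose best Bayes factor does
  not beat the null is zeroed and reports no credible set. This is what
  keeps weak-signal loci calibrated: with a large fixed prior variance,
  surplus effects either lock onto noise (spurious sets) or — if
  filtered by a Bayes-factor check at that fixed prior — genuine weak
  signals are thrown away with them.
* Convergence is declared on the maximum absolute PIP change (default
  tolerance $10^{-3}$), since PIP is the quantity every downstream stage
  consumes; a variational objective trace is recorded for diagnostics.
* A non-positive-semidefinite LD matrix is ridge-regularized (diagonal
  $+10^{-6}$) with a warning. The algorithm is deterministic.
* In-sample (simulator-exact) LD is used rather than an external
  reference panel, removing reference-mismatch artifacts from the
  calibration experiments.

A SNP is called putatively causal when its PIP strictly exceeds 0.1.

### Gene nomination and direction of effect (`nominate_gene`, `direction_of_effect`)

Causal SNPs are walked in descending PIP; the first SNP carrying any
annotation nominates the target gene of its highest-precedence
annotation, with the precedence **exonic > promoter > fine-mapped eQTL >
regulatory**. The precedence is a declared convention of this package:
published locus tables list combined annotation labels without revealing
which one decided the gene, and coding evidence is the least
LD-confounded, so it wins. If no causal SNP is annotated, the gene whose
body is nearest the top-PIP SNP is nominated (ties: nearest strand-aware
TSS, then lexicographic). Direction calls: a deleterious missense
variant (votes from ≥ 1 of 5 prediction tools, configurable) is read as
loss of function, so a positive trait beta means LOF raises the ratio
(harmful) and a negative one means LOF protects; for eQTL variants the
sign of eQTL-beta × GWAS-beta says whether expression raises or lowers
the trait; UTR-only or absent evidence is `indeterminate`. Promoters are
defined as TSS − 2 kb to TSS + 200 bp, strand-aware.

### Colocalization (`coloc_abf`)

Standard approximate-Bayes-factor colocalization of two traits over a
shared window under a single-causal-variant-per-trait assumption, with
quantitative-trait prior effect SD 0.15 and priors
$p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$. The overlap flag is
$PP_{H3} + PP_{H4} \ge 0.99$ — deliberately including H3 (distinct causal
variants), because the question asked is "do both traits have a genuine
signal here", not "is it the same variant". All sums run in log space.

### Gene-level corroboration (`build_masks`, `burden_*`, `predict_expression`, `twas_assoc`, `mediation_proportion`)

Burden masks of decreasing stringency per gene — pLOF only; pLOF plus
variants called deleterious by all 5 tools; pLOF plus variants with ≥ 1
deleterious vote; all rare variants — every mask under a uniform
MAF < 1% cap. The uniform cap is a small declared deviation: it
guarantees the masks are nested, which the analysis depends on, at the
cost of also capping the high-confidence mask (toggleable via
`maf_cap`). Collapsing uses the *maximum* dosage over mask variants
(carrier coding, not allele counting), and the burden test is OLS of the
normalized phenotype on the collapsed genotype, optionally conditioning
on named common variants by adding their dosages as covariates.

Predicted expression is the weighted sum of effect-allele dosages over a
gene's weight SNPs divided by each individual's count of non-missing
weight SNPs, after harmonizing genotype orientation to the weights
(mismatched alleles are an error, never silently flipped). Association
with the trait is OLS, with an observation-weight hook (the weighted
variant defaults to unweighted because no weighting scheme is specified
for the published analysis).

Mediation uses the difference-of-coefficients estimator over nested
linear models — total effect $c$ from `outcome ~ exposure`, direct
effect $c'$ from `outcome ~ exposure + mediator`, proportion
$(c - c')/c$ — with a seeded bootstrap percentile CI. In purely linear
models this point estimate equals the product-of-paths estimator, so the
simpler contract was chosen; proportions are undefined (flagged, not
fabricated) when the total effect is numerically zero.

### Replication and overlap (`proxy_replication`, `locus_overlap`)

An external study lead overlaps a locus iff it falls inside the locus
span (both boundaries inclusive). Replication looks up the lead SNP or,
failing that, the most significant member present in the replication
table, harmonizes alleles (sign-flipping swapped orientations), and
classifies: `robust` below $0.05/n$, `nominal` below 0.05,
`direction_only` on sign agreement, else `discordant`; loci with no
testable proxy are `untestable`. Palindromic (A/T, C/G) proxies with
allele frequency in (0.4, 0.6) are flagged ambiguous and skipped rather
than frequency-inferred — a silent wrong flip would corrupt every
downstream direction-of-effect call, which is a worse failure mode than
a lost proxy.

## The synthetic cohort

`simulate_cohort()` generates the study conditions the analysis assumes:

* **Genotypes.** LD blocks of hard-call dosages from a Gaussian copula:
  per block, a latent AR(1) chain per haplotype is thresholded at
  `qnorm(maf)` and the two haplotypes summed. The latent AR coefficient
  is calibrated by root-finding on the tetrachoric-induced indicator
  correlation so that the *realized dosage* correlation between adjacent
  SNPs equals `ld_decay` (default 0.95, emulating a dense imputed
  panel); correlation decays approximately geometrically with lag. All
  SNPs within a block share one allele frequency (drawn per block from
  (0.05, 0.5)): variants in strong LD necessarily have near-identical
  frequencies, and under a threshold model unequal frequencies would cap
  the attainable correlation well below the target.
* **Phenotypes.** $\log$ TG and $\log$ HDL are linear in planted per-sex
  standardized-dosage effects, small age and sex covariate effects, a
  mediated expression→adiposity path, rare-variant burden effects, and
  unit-SD Gaussian noise, then exponentiated (so raw traits are strictly
  positive). Sex is Bernoulli (54% female); ages are uniform on 40–69.
* **Locus classes.** The default architecture plants 20 loci: 4
  ratio-specific (opposite-signed TG/HDL effects, ±0.15 SD), 3 TG-only,
  3 HDL-only, 4 shared-lipid (equal-signed effects, whose ratio
  association cancels), 2 sex-dimorphic (female 0.15 vs male 0.03), and
  4 null. Effect sizes are chosen for testability at the default
  n = 20,000 — large enough that non-null loci are genome-wide
  significant with high probability — not as an estimate of any real
  trait's architecture, which is unknown at this granularity.
* **Rare variants.** Unlinked binomial dosages (exome-style, separate
  from the common-variant LD structure), 12 per gene with MAF in
  (1e-4, 1e-3) — about 1% carriers — deleteriousness votes from 0–5
  tools, pLOF flags on a subset, one gene with a planted 0.2-SD burden
  effect through the max-collapsed deleterious genotype and one null
  gene.
* **Expression and mediation.** A four-SNP expression score (h² = 0.3)
  in a dedicated block feeds a BMI-like mediator which feeds the lipids;
  path coefficients (a = 0.5, b = 0.4, c′ = 0.2) plant a mediated
  fraction of 0.5.

What the generator does **not** emulate: population structure and
relatedness (hence no PCs and no mixed model), imputation uncertainty
(hard calls only, INFO filters inert), X-chromosome dosages, allele
frequency / LD mismatch between cohorts (an LD matrix always comes from
the analyzed sample), and cross-block LD. Passing tests therefore say
the statistical machinery is correct under its own assumptions; they do
not certify robustness to stratification or reference mismatch on real
data.

## Calibration experiments and problem sizes

The test suite runs, among others: exhaustive single-causal enumeration
against the fine-mapper (100 random instances, ≤ 10 SNPs, agreement to
1e-6); credible-set coverage on 200 simulated single-causal loci
(n = 5,000, planted 0.05 SD, 20-SNP windows) requiring ≥ 90% coverage;
a 50-seed sign test that ratio-specific loci out-boost shared-lipid
loci; 100-seed recovery of a 0.2-SD burden effect (within 3 SE ≥ 95
times) and of the sign of a planted expression effect at n = 20,000;
500-seed uniformity of null burden p-values; 100-seed recovery of a 50%
mediated fraction within [0.4, 0.6] ≥ 90 times; and genomic-control
calibration on uniform p. These sizes were chosen so each experiment
has enough replicates for its binomial bound to be meaningful while the
whole suite stays comfortably runnable on a laptop core.

## Known limitations

* Per-SNP OLS is correct only for unrelated, unstructured samples — by
  design of the simulator, but a real-data user must bring
  mixed-model-adjusted summary statistics.
* The boost score compares p-values computed on identical samples and
  QC; feeding it scans of different n makes the score meaningless.
* Single-causal-variant colocalization inherits the usual H3/H4
  sensitivity to LD misspecification.
* The annotation precedence is a convention; loci whose true causal gene
  acts through a lower-precedence channel will be mis-nominated when a
  higher-precedence annotation exists on the same credible set.
* `select_boosted` flags exactly ⌊n/4⌋ loci; with very few discovered
  loci that can be zero — small pilot runs should widen `quartile`.
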
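---
title: "Benign polygenic scores for WBC count: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benign polygenic scores for WBC count: models, choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(benignpgs)
```

## The problem

White blood cell (WBC) counts are interpreted against population
reference ranges constructed so that ~5% of healthy people fall outside
them. A substantial part of between-person WBC variation is polygenic
and benign: some people are genetically set to run low counts while
carrying no disease. When such a person's count drifts below the assay's
lower bound, the standard interpretation can trigger diagnostic escalation
(bone-marrow biopsy), chemotherapy dose alterations, or drug
discontinuation — all potentially futile.

`benignpgs` implements the analysis machinery for studying this
phenomenon: a polygenic score (PGS) for WBC count deliberately *purged*
of disease-associated loci, diagnostics that probe whether disease signal
remains in the score, genotype-informed reference ranges built from the
score, and the downstream clinical association models. Because the
subject-level data such studies use are access-restricted biobank
resources, the package ships a first-class synthetic-data module that
generates every input with the statistical structure the analyses
assume, so the whole pipeline is exercisable and testable end to end.

## Score construction

The score is a weighted allele-dosage sum,
$\mathrm{PGS}_i = \sum_j d_{ij} w_j$, with weights taken from GWAS
summary statistics for WBC count. Construction proceeds in four steps,
each with an explicit exclusion log so that every input variant is
accounted for exactly once:

1. **QC filter** (`qc_filter()`): association $p <$ 5e-6, minor allele
   frequency $\min(f, 1-f) > 0.01$, imputation quality $\ge 0.7$, and no
   palindromic (A/T, C/G) allele pairs, which are strand-ambiguous.
2. **LD clumping** (`ld_clump()`): greedy by ascending p-value — retain
   the most significant remaining variant, drop everything with squared
   dosage correlation $r^2 \ge 0.01$ against it. Ties in p are broken by
   variant id, making the result deterministic. The retained set is
   pairwise nearly independent by construction.
3. **Region purge** (`exclude_region()`): everything in the MHC
   (chromosome 6, 25.5–33.5 Mb, 1-based inclusive) is removed because
   the region is densely associated with autoimmune disease.
4. **Catalog purge** (`exclude_catalog_ld()`): a variant is removed when
   its squared dosage correlation with any disease-catalog variant
   (catalog $p <$ 5e-7) is strictly greater than 0.5. The catalog purge
   runs after clumping — it is applied to the already-built score.

The p-value threshold is chosen by `select_threshold()`: for each
candidate (5e-8, 5e-7, 5e-6) the full score is built and the partial
correlation with per-person median WBC, adjusted for age and sex
(configurable; principal components can be added), is computed; the
argmax wins and exact ties go to the most stringent threshold. Scores
are standardized per analysis cohort (`pgs_standardize()`), so effects
are per s.d. of score in that cohort.

Two deliberately open points, and what we chose:

* *LD reference*: $r^2$ is the squared Pearson correlation of dosage
  columns in the supplied panel. Monomorphic columns are treated as
  uncorrelated with everything.
* *Allele orientation*: if a model's effect allele matches the panel's
  other allele, the dosage is flipped to $2 - d$; this leaves
  standardized scores exactly invariant (a tested identity). Missing
  dosages are mean-imputed per variant and logged.

## Residual-disease diagnostics

A "benign" score should not predict the diseases it was purged of.
`phenome_scan()` fits one logistic model per phenotype. To ask whether
large-effect variants drive residual associations, `quintile_split()`
partitions the model by effect-size magnitude into five near-equal
quintiles (ties fill from the lower ranks, deterministically), and
`permutation_count_test()` compares each quintile's count of nominal
(p < 0.05) phenotype associations with a null built by resampling
same-size variant subsets from the full model. The empirical p uses the
add-one rule $(1 + \#\{ \text{perm} \ge \text{obs}\})/(B + 1)$, which
never returns 0 and equals $1/(B+1)$ when the observed count beats every
permutation.

What "permuting a quintile score" means is genuinely underdetermined; we
default to variant resampling because it preserves the score-construction
mechanics, and provide person-label permutation behind `mode = "person"`
as the alternative interpretation. Direction counting defaults to
positive-direction associations only (`direction = "positive"`), with
`"any"` as a switch.

For speed, the permutation machinery defaults to a Rao score test of
adding the (permuted) score to a covariates-only logistic fit: the null
model is fitted once per phenotype and shared by all permutations, which
makes the test exactly exchangeable across permuted score vectors and
reduces a 1000-permutation scan to linear algebra. `test = "wald"`
performs the full logistic fit per permutation instead. The two agree
closely in practice; calibration of the default route is verified in the
test suite (fraction of null empirical p at or below 0.05 ≈ 0.05 over
200 replicates).

`per_snp_binomial()` asks the same enrichment question variant by
variant: for each phenotype, the count of quintile variants with nominal
single-variant associations is referred to an exact Binomial(n, 0.05)
upper tail computed by direct summation.

## Genotype-informed reference ranges

`person_summary()` reduces repeated measures to a per-person median
(counts above 35,000 cells/µL excluded first, as likely acute disease)
and separately retains the per-person minimum. `outlier_flag()` marks
anyone with a count strictly below their assay's lower bound.
`window_percentiles()` sweeps a ±0.2 s.d. window across the score range
and reports the 5th/50th/95th percentiles of the value within each
window.

`classify_within_range()` is the clinical proof-of-concept: a biopsied
person's threshold is the 2.5th percentile of the *lowest observed*
WBC counts among reference-cohort members whose score is within 0.2 s.d.
of theirs; the person is within their genotype-informed range when the
biopsy-time count is **at or above** that threshold. Two conventions had
to be fixed:

* *Quantile convention*: linear interpolation between order statistics
  (R's type 7), used identically by the implementation and by the
  brute-force oracles in the tests.
* *Boundary rule*: "at or above" (`rule = "geq"`) is the default;
  a strictly-above variant is available (`rule = "gt"`) because the two
  readings both appear in practice. Windows with fewer than `min_n = 20`
  members are unclassifiable rather than silently out of range — a 2.5th
  percentile needs tail support.

`stratified_summary()` tallies classifications by biopsy outcome in
half-open count strata (0–2.5, >2.5–3.0, >3.0–3.5, >3.5–4.0, in 1000
cells/µL), with percentages printed to one decimal. Counts above 4000
are outside the table because standard thresholds already call them
normal.

## Clinical association stages

* `logistic_fit()`: ML logistic regression, OR per s.d. with Wald 95%
  CI; separation and non-convergence raise errors with diagnostics.
  Age-squared is included as a covariate only in the outlier/diagnosis
  stages; other stages use age linearly.
* `hosmer_lemeshow()`: deciles-of-risk with 8 bins by default,
  chi-square with bins − 2 degrees of freedom.
* `linear_log_fit()`: least-squares slope per s.d. on log counts.
* `build_exposure_cohort()`: the event is the first post-baseline count
  below the outcome threshold (3000 cells/µL primary; 3500/4000 and ANC
  1500 supported); censoring at the earliest of second treatment cycle,
  administrative horizon, last encounter, with ties resolved in that
  priority order. "1 month" is 30 days and "24 months" 730 days, fixed
  conventions. Persons with baseline count ≤ 1000 cells/µL are excluded
  and logged.
* `cox_fit()`: partial likelihood via `survival::coxph()` with Efron
  tie handling (configurable); diagnostics bundle Schoenfeld
  (proportional hazards), martingale (non-linearity) and deviance
  (outlier) residual summaries.
* `km_strata()`: Low (< −1 s.d.), Middle (−1 to 1, closed), High
  (> 1 s.d.) strata with product-limit curves.

## The synthetic-data generators

`sim_config()` fixes everything under one seed; same seed and config
give bit-identical outputs (tested).

**Genotypes.** Variants are partitioned into contiguous LD blocks. Each
block carries, per haplotype, a shared ancestral allele; each variant
copies it with probability $\sqrt{\rho}$ or draws independently, which
makes every within-block pair of dosages correlate at exactly $\rho$
(`block_ld`, default 0.85, so within-block LD r² ≈ 0.72 — above the 0.5
catalog-purge threshold, which is what gives that step real work). The
construction requires equal allele frequencies within a block, so the
MAF is drawn once per block from `maf_range`. This is a deliberately
stylized LD model: it exercises clumping and catalog-LD exclusion, but
it is *not* a realistic human LD map (no distance decay, no
cross-block LD, no frequency spectrum).

**Summary statistics.** True effects for `n_causal` variants are drawn
from N(0, `effect_sd`²); marginal effects follow from the block
structure; estimates add sampling noise with standard error
$\sigma_y / \sqrt{n \cdot \mathrm{var}(g)}$ and within-block
exchangeable correlation on the z scale, mirroring how LD correlates
real summary statistics. Under the null the nominal rate is 5% (tested
with a binomial error band); with `gwas_n = 2e5` most causal variants
clear the 5e-6 threshold.

**Cohorts.** Log-WBC is `wbc_log_mean` (8.91 ≈ log of an 8200 cells/µL
mean) plus `score_effect` per score s.d., small age/sex terms,
between-person noise (s.d. 0.35) and within-person noise (s.d. 0.28);
counts are rounded to 100 cells/µL as clinical assays report, and each
observation carries assay bounds (modal lower bound 3900 cells/µL).
`score_effect = 0.13` was calibrated once so that the partial
correlation between score and median WBC is ≈ 0.29 at n = 11,694 with
1–5 measures per person, and then frozen. Demographics: 55% female, age
N(57, 17) truncated to 18–90; principal components are pure noise
covariates. The biopsy cohort's pathology outcome is drawn independently
of the score (the score shifts counts, not disease), with biopsy-time
counts lower overall and lower still with pathology. Exposure cohorts
draw event times from $\lambda_0 \exp(\theta\,\mathrm{score} + 0.2\,
\mathrm{dose})$ with $\theta = \log 0.78$ and $\lambda_0$ = 0.25 events
per person-month, which yields ~16% first-cycle events under the 30-day/
second-cycle censoring; the immunosuppressant-like cohort uses a 24-month
horizon, $\theta = \log 0.62$ and a much lower baseline hazard (~3%
events). Event days are exponential times rounded up to whole days with
a planted sub-threshold count on the event day; surveillance counts stay
above threshold by construction.

`biopsy_fixture()` is fully deterministic: each biopsied person gets a
private, disjoint score window of 40 reference members whose lowest
counts all equal the intended threshold, so the stratified classification
table is reproduced *exactly* — it is a worked-example fixture for the
reference-range machinery, not a draw from the generative model.

**What passing tests do and do not show.** The generators give the
analyses exactly the structure they assume: block LD, log-normal counts,
proportional hazards, logistic outcomes. Passing recovery and
calibration tests therefore demonstrates correctness of the
*implementation*, not robustness to real-data violations (assay shifts
over time, informative censoring, ancestry confounding, LD between
blocks, case-mix in the GWAS source). The headline effect sizes used as
generative targets (HR 0.78, log-OR −0.55, slope 0.062, correlation
0.29) come from access-restricted biobank analyses and are *inputs* to
the simulation, not results reproduced from data.

## Problem sizes and numerical choices

The test suite and `scripts/acceptance.R` run at desk scale, chosen as
the smallest sizes at which the statistical claims are testable: panels
of 300–2000 people (11,694 for the observational-cohort correlation,
matching the cohort size the score-effect calibration targets), 200
replicates for parameter recovery and permutation calibration, 199
permutations per calibration replicate, and 100 random fixtures per
oracle-equivalence check. Tolerances: exact equality for the fixture
table; 1e-10/1e-12 for algebraic identities; 1e-12 against the binomial
closed form; Monte-Carlo bands (3-sigma binomial, or the spec'd ±0.02
calibration band) for stochastic checks. Degenerate inputs fail loudly:
zero-variance standardization, single-class outcomes, no events,
under-occupied windows, overlapping strata, rank-deficient designs.

## Known limitations

* The LD model is block-exchangeable; clumping behaviour near the r²
  threshold with realistic LD decay is untested by construction.
* The catalog purge can only be as good as the catalog; the generator
  plants tags with known block membership, which is the favourable case.
* Permutation diagnostics use integer counts, so empirical p-values are
  discrete and slightly conservative for small phenome sizes.
* ANC-based outcomes reuse the WBC machinery by configuration; no
  separate neutrophil generative model is provided.
* Dose is a baseline covariate in the Cox stages, not time-varying.
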
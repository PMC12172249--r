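---
title: "Methods: polymorphic L1 burden and association analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polymorphic L1 burden and association analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scientific background

LINE-1 (L1) retrotransposons are the only autonomously mobile transposable
elements in the human genome. Most of the >1 million annotated L1 copies are
immobilized by truncation or ORF-disrupting mutations, but a small
catalogued subset — retrotransposition-competent (RC) L1s, identified by
cellular retrotransposition assays or 3' transduction tracing — can still
mobilize. Because many L1 insertions are polymorphic for presence/absence,
every genome carries a different number and complement of RC-L1s. This
package implements a genotype-level analysis of that variation in a
case-control cohort of amyotrophic lateral sclerosis (ALS): per-locus
association scans, a per-genome RC allele-count burden and its disease
model, age-at-onset and survival modifiers, and an expression-QTL scan with
an RC-enrichment test.

The consortium-scale WGS data this design targets are access-controlled, so
the package ships a synthetic cohort generator (`simulate_cohort()`) that
reproduces the *statistical structure* of such a cohort. All empirical
claims in this vignette are computed by the test suite or the acceptance
script; nothing is asserted about real data.

## Input model and genotype coding

Two VCF dialects are read (`read_mei_vcf()`):

* **melt** — novel, non-reference insertions; GT allele 1 *is* the
  insertion-Present allele. Caller evidence (split reads, assessment score)
  is read from INFO keys whose names are configurable (defaults `SR`,
  `ASSESS`), because callers differ in where they store them.
* **deletion_genotyping** — reference-genome L1s genotyped as deletions; GT
  allele 1 means the element is absent, so the Present-allele count is
  `2 - alt count`.

The counted allele is always insertion-Present ("P"); every effect size is
per Present allele. Only a fully missing or half-missing GT produces a
missing genotype. Positions keep the 1-based VCF convention in records;
interval arithmetic (genomic context, gene-list overlap) is 0-based
half-open internally, with precedence exon > utr5 > utr3 > intron >
intergenic when features overlap.

## Quality control and the accounting ledger

Every filter returns a `filter_ledger` with step-by-step conservation
(`n_out = n_in - n_removed`, consecutive steps chaining), so the locus
accounting is auditable end to end:

1. evidence filter for non-reference records: split reads >= 2, assessment
   score >= 3 (both inclusive), FILTER == PASS; missing evidence fails and
   is counted separately;
2. analysis-cohort selection: strictly >90% European ancestry fraction and
   diagnosis in {ALS, ALSND, NNC};
3. exact Hardy-Weinberg test in controls only, removal at p < 1e-6
   (strict);
4. MAF > 0.01 (strict) for the per-locus scans, computed on the analysis
   cohort — the threshold is introduced in the association context, so the
   cohort-restricted MAF is the default; the full-cohort alternative is a
   deliberate non-default;
5. for the burden: RC-catalog loci only, autosomes only (so male and female
   genomes are comparable), missingness <= 5% per locus, then complete-case
   restriction of individuals across the retained loci.

Missingness denominators use the analysis cohort after cohort selection and
before complete-case restriction, matching the stated order of operations.
chrY is handled like chrX defensively, although no RC loci are expected
there.

## Statistical kernels

`stats_core` exposes a uniform `l1_fit` surface. Ordinary fits delegate to
the standard implementations (least squares via QR, binomial IRLS via
`glm.fit`, Cox partial likelihood with Breslow ties via the survival
package, Fisher's exact test, Bonferroni/Benjamini-Hochberg via
`p.adjust`); two pieces are implemented in the package because no installed
equivalent exists:

* **Exact HWE test** — the standard two-sided conditional ("SNP-HWE")
  formulation: given the allele counts, heterozygote configurations with
  probability not exceeding the observed one are summed. No mid-p
  correction, for reproducibility against common implementations. The test
  suite checks it against an exhaustive enumeration oracle for every table
  with n <= 50.
* **Firth-penalized logistic regression** — used as a fallback when
  separation is detected (non-convergence, or any |coefficient| > 15).
  Separated fits are flagged (`separation`, `firth_fallback`) rather than
  dropped, because rare loci at the MAF boundary can separate in finite
  samples and removing them would bias the scan.

Convergence tolerances are fixed, not configurable: IRLS convergence at
relative log-likelihood change < 1e-10 with a 100-iteration cap; the Firth
Newton iteration stops at max |score| < 1e-8 with step-halving on the
penalized likelihood. Wald 95% intervals (estimate +/- 1.96 SE,
exponentiated for OR/HR) are used throughout, matching the presentation
convention of the standard association tools. Degenerate inputs error
early: all-0/all-1 outcomes, no events in survival data, rank-deficient
designs (the offending columns are named). Constant covariate columns are
dropped from design matrices — they carry no information and would
otherwise break factor contrasts.

## The burden analysis

The burden is the unweighted row sum of Present alleles over the retained
(89 by default) RC loci, computed only on complete-case individuals so
every burden is a sum over the identical locus set. The primary model is

```
rc_allele_count ~ status + sex + age + seq_prep        (least squares)
```

so the status coefficient is in allele units (cases minus controls); the
reverse logistic direction is available as an option. The threshold scan
dichotomizes at each k in {43, ..., 48} by default: the six categories are
a symmetric window around the middle of the burden distribution, chosen
because the category boundaries themselves are a reporting choice, and are
configurable. The Bonferroni family is the number of thresholds actually
fitted; thresholds outside the observed range are recorded as degenerate,
not silently dropped.

## Per-locus scans

All scans use additive Present-allele coding (0/1/2) — the default of the
standard association tools — with carrier summaries (PA or PP vs AA) emitted
for reporting; when no homozygous-Present genotypes exist the two codings
coincide exactly, which the tests check. Case-control scans adjust for age,
sex and sequencing preparation; the "age" covariate is collection age for
controls and onset age for cases, with missing-age samples dropped
(complete-case). Onset scans run in cases only with sex, sequencing
platform and site of onset as covariates; survival scans add onset age,
censoring individuals still alive at last follow-up. "Sequencing
preparation" and "sequencing platform" are accepted as one categorical
batch column. Survival uses fixed-effects proportional hazards only; a
random-effect (frailty/kinship) term is out of scope, and the fixed-effect
restriction is a documented simplification.

## eQTL scan and RC enrichment

Expression (transcripts x samples, per tissue) is scanned against every
locus with an additive linear model adjusted for age and sex; no cis-window
restriction is applied because none is part of the design. The scan
residualizes expression and genotype on the covariates and computes slopes
from cross-products (Frisch-Waugh), which is algebraically identical to a
per-pair least-squares fit — the tests assert equality to 1e-10 — while
scaling to millions of pairs. Missing genotypes are mean-imputed per locus
for this scan only (the standard practice of matrix-based eQTL tools);
zero-variance transcripts and monomorphic loci are skipped with recorded
reasons. FDR control is Benjamini-Hochberg within each tissue; a locus
counts once as "an eQTL" if significant for any transcript in any tissue.
RC enrichment is a two-sided Fisher exact test on the (RC vs non-RC) x
(eQTL vs not) table over all tested loci, reported with explicit
denominators for both proportions.

## The synthetic cohort generator

`sim_config()` defaults encode the study conditions: 320 controls and 2,653
ALS/ALSND cases of >90% European ancestry (plus 60 deliberately excluded
samples so cohort selection is exercised); 205 reference + 2,598
non-reference loci; 93 polymorphic RC loci with 3 X-linked and 1 with >5%
missing genotypes, leaving 89 burden loci; control age ~ N(57.4, 12^2)
truncated to [17, 90]; male fractions 49.1% (controls) and 60.1% (cases);
missing-age rates 43/320 and 159/2,653; onset baseline 59.2 y with noise SD
11 y; a rare onset-modifier locus (IAF 0.017, carrier effect -6.55 y); a
burden shift of 0.40 alleles; survival from a Weibull proportional-hazards
model (shape 1.3, baseline median 36 months — the middle of the 2-5-year
post-diagnosis life expectancy) censored at a uniformly drawn last
follow-up.

Choices that the study conditions do not pin down, made once and documented
here:

* **IAF spectrum.** Common loci are uniform on [0.1, 0.9]; rare loci are
  log-uniform on [1e-4, 0.014]. The common fractions (89.3% of reference,
  5.7% of non-reference loci at IAF >= 0.1) are as stated; the rare-tail
  upper bound is calibrated so the expected number of loci clearing
  MAF > 0.01 is ~500, the size of the published scan.
* **RC-locus IAFs.** A Beta(0.554, 1.662) spectrum placed on a quantile
  grid (stratified rather than i.i.d.) so the expected burden is stable
  across seeds at mean ~44.9, SD ~4.8 — the values implied by the printed
  burden ranges (32-56 in 288 controls; 30-63 in 2,420 cases) under normal
  extreme-value expectations.
* **Burden-shift mechanism.** Case IAFs at the 89 burden loci are tilted
  uniformly by `shift / (2 x 89)`, so HWE holds within each group — the
  pattern a liability model would produce. This is one of several
  mechanisms consistent with the same marginal shift; post-hoc count
  editing was rejected because it breaks within-group HWE.
* **Missingness** is sprinkled independently at 0.0011 per call (so ~90% of
  individuals are complete at 89 loci, matching 288/320 and 2,420/2,653),
  except one designated RC locus at 6% and the planted loci at 0.
* **Onset modifier** acts through carrier (dominant) coding, matching the
  PA-vs-AA presentation; the additive scan still detects it because
  homozygous carriers are vanishingly rare at IAF 0.017.
* **Covariates are independent of the burden** — the real joint
  distribution is unknown; this assumption is recorded here and in the
  generator's metadata.
* **Reproducibility.** One global seed spawns fixed per-stream substreams
  (genotypes, phenotypes, expression, missingness), so regenerating one
  stream does not perturb the others; fixtures embed the seed and a config
  hash in their headers.

What the generator does *not* emulate: linkage disequilibrium between loci
(independent by design), read-level evidence (no FASTQ/BAM), population
substructure beyond the European-fraction column, and genotype-calling
error correlated with batch. Passing tests therefore demonstrate that the
statistical machinery is correct and calibrated under the stated data
model, not that the pipeline is robust to artifacts real callers produce.

## Test and acceptance problem sizes

The suite checks calibration and recovery at the cohort scale the design
states (320/2,653), with seed counts chosen to keep the full run in tens of
minutes: 20 seeds for the per-locus null scan (pooled rejection rate at
alpha = 0.05 expected in [4%, 6%]), 25 for the threshold-scan family-wise
null, 20 for the 50 x 50 eQTL null, 200 seeds for recovery of the
0.40-allele burden shift (generator in rc-only reduced mode, since non-RC
loci do not enter the burden model), 60 for the -6.55-year onset effect and
50 for a planted OR-1.5 locus. Extreme-value statistics of the burden
(per-group min/max) are checked as medians over 6 seeds because single-seed
extremes fluctuate by +/-2 alleles.

## Known limitations

* Fixed-effects Cox only; no frailty or kinship adjustment.
* No ancestry estimation: the European fraction is an input column.
* The eQTL scan assumes pre-normalized expression; batch correction is
  upstream of this package.
* Additive per-allele coding throughout; genotypic (2-df) models are not
  implemented.
* The RC catalog is consumed as given; no liftover or coordinate
  reconciliation between genome builds.
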
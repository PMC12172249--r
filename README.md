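# l1burden

Genotype-level analysis of polymorphic LINE-1 (L1) retrotransposon
insertions in case-control cohorts, built around the question of whether
the *retrotransposition-competent* (RC) subset of L1s — the copies that can
still mobilize — contributes to amyotrophic lateral sclerosis (ALS) risk
and progression.

The package is aimed at statistical geneticists working with
mobile-element-insertion (MEI) genotypes from whole-genome sequencing. It
takes VCF genotype calls (MELT-style non-reference insertions and
deletion-genotyped reference insertions), a curated RC-L1 catalog and a
phenotype table, and provides:

* **QC with a full accounting ledger** — caller-evidence filters
  (split reads ≥ 2, assessment score ≥ 3, PASS), exact Hardy–Weinberg
  filtering in controls (p < 10⁻⁶), strict MAF > 0.01, cohort selection,
  and the RC-burden locus accounting (autosomes only, ≤ 5% missingness,
  complete-case individuals), each step recorded as
  `n_in → n_out (criterion)`.
* **The RC allele-count burden** — per genome,
  `b_i = Σ_j g_ij` over the retained RC loci with `g ∈ {0,1,2}`
  Present-allele counts, modeled as
  `b ~ status + sex + age + seq_prep` (least squares, effect in alleles)
  plus a threshold scan: logistic regression of status on `I(b ≥ k)` for
  `k ∈ {43..48}`, Bonferroni over the thresholds fitted.
* **Per-locus scans** — additive logistic case-control ORs, linear
  age-at-onset effects (cases only) and Cox proportional-hazards survival
  (Breslow ties, censoring at last follow-up), each with covariates and
  Bonferroni correction, mirroring the standard MEI association workflow.
* **eQTL scan with RC enrichment** — additive linear model of expression on
  genotype with age and sex covariates across every (locus, transcript)
  pair in two tissues, Benjamini–Hochberg FDR within tissue, and a Fisher
  exact test of whether RC loci are over-represented among eQTL loci.
* **A synthetic cohort generator** — a fully seeded simulator of the whole
  data structure (320 controls / 2,653 cases, 2,803 loci with a bimodal
  insertion-allele-frequency spectrum, 93 RC loci reducing to 89 burden
  loci, planted burden/onset/eQTL effects, censored survival), so the
  entire pipeline is testable without access-controlled data.

The statistical kernels sit behind one interface (`fit_linear`,
`fit_logistic` with a Firth fallback under separation, `fit_coxph`,
`hwe_exact_test`, `fisher_exact_2x2`, `bonferroni`, `bh_fdr`); the exact
HWE test and the Firth penalty are implemented in the package, everything
standard delegates to base R and the survival package.

## Worked example

```r
library(l1burden)

sim <- simulate_cohort(sim_config(), seed = 1)
fixture <- file.path(tempdir(), "fixture")
write_fixture(sim, fixture)

out <- file.path(tempdir(), "run")
run_pipeline(fixture, out)
```

The pipeline logs every ledger and family size as it runs; on this seed:

```
locus registry: 2803 loci (205 reference + 2598 non-reference)
annotate_rc: 93 of 2803 loci are in the RC catalog
cohort selection (samples):
  analysis_cohort          3033 ->   2973 (-60)  european_fraction > 0.9 (strict) and diagnosis in {ALS, ALSND, NNC}
burden locus filter:
  rc_restrict              2803 ->     93 (-2710)  RC-catalog loci only
  autosomal                  93 ->     90 (-3)  chrX/chrY RC loci removed
  missingness                90 ->     89 (-1)  missing-genotype fraction > 0.05 removed
complete-case samples:
  complete_individuals     2973 ->   2695 (-278)  samples with any missing genotype across 89 burden loci dropped
case-control scan: 549 loci fitted (Bonferroni m = 549), 0 skipped
```

meaning: of 2,803 polymorphic loci, 93 are RC-catalog members, and after
removing the 3 X-linked loci and 1 locus with > 5% missing genotypes, 89
autosomal RC loci define the burden; 2,695 individuals have complete
genotypes at all 89 and enter the burden models; 549 loci cleared
MAF > 0.01 and entered the per-locus scans. The burden model for this seed
estimates the planted 0.40-allele case-control shift:

```r
read.delim(file.path(out, "burden_models.tsv"))[1, c("effect", "se", "p_unadj")]
#      effect        se    p_unadj
#   0.7227339 0.3328781 0.02991854
```

a single-cohort estimate of the generator's true shift of 0.40 alleles —
the per-seed sampling SE is ~0.33 alleles, so individual seeds scatter
around the truth and the recovery tests average 200 seeds. The
threshold-scan output (`threshold_scan.tsv`) carries the OR, CI, per-group
counts and percentages at each `k` (at `k = 46` on this seed: 47.3% of
controls vs 55.4% of cases at or above, OR 1.36, unadjusted p 0.024),
ready for a forest plot.

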
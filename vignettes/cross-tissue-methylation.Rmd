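---
title: "Cross-tissue differential DNA methylation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-tissue differential DNA methylation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylmirror)
```

## The problem

Adipose tissue is the biologically relevant tissue for obesity epigenetics,
but it requires a biopsy; blood is routinely sampled. If a CpG site is
differentially methylated between obese and non-obese subjects *in the same
direction* in both subcutaneous adipose tissue and circulating leukocytes,
its blood methylation level can serve as a minimally invasive surrogate for
the adipose state. `methylmirror` implements the full analysis that
identifies and evaluates such sites on 450k-style beta-value data:
probe quality control, per-CpG differential testing, genomic-context
diagnostics, a cross-tissue signature cascade, gene-set over-representation
and biomarker evaluation — driven by a synthetic data generator with a
planted-effect truth ledger so that every stage can be validated
quantitatively without access to cohort data.

## The data model

A methylation array reports, per CpG and sample, a methylated intensity $M$
and an unmethylated intensity $U$; the methylation fraction is

$$\beta = \frac{M}{M + U + \alpha} \in [0, 1],$$

with the offset $\alpha = 100$ by platform convention (configurable;
$\alpha = 0$ recovers the plain ratio). The offset stabilises low-intensity
probes; an all-zero denominator yields a missing value rather than an error.

The study design the package models: paired adipose and leukocyte samples
from 45 obese subjects, plus 8 (adipose) and 10 (leukocyte) unpaired
non-obese controls; obese means BMI > 25 kg/m² (overweight and obese
pooled), non-obese BMI ≤ 25.

## Probe quality control

Probes are excluded in a fixed order: detection failures (detection
p > 0.01 in *any* sample), chromosome X, chromosome Y, probes with a SNP
within 10 bp of the 3′ end, rs (SNP-genotyping control) probes, ch (non-CpG
cytosine) probes, and probes mapping to multiple genomic locations. Each
probe is counted against the first category it hits, so per-category counts
plus the retained count equal the input exactly. Probe-level removal on
detection failure is the default because it keeps the downstream matrix
complete; per-sample masking is available behind `per_sample_mask = TRUE`
for workflows that prefer to keep partially observed probes.

## Per-CpG differential testing

Each retained CpG is tested with the two-sided Wilcoxon rank-sum test. A
rank test is used instead of a linear model deliberately: with 8–10 controls
against 45 cases, model-based inference is fragile, while the rank test is
robust to the bounded, skewed distribution of beta values. The
implementation uses the exact null distribution when the combined sample
size is at most 12 and there are no ties, and the normal approximation with
tie and continuity correction otherwise; the cutover is a numerical
convention (the exact path is only cheap for tiny groups) and both paths are
validated in the test suite against brute-force permutation enumeration and
against `stats::wilcox.test`.

P-values are adjusted by the Benjamini–Hochberg step-up procedure, and a
site is called differentially methylated when

* its adjusted p-value is strictly below 0.05, and
* its absolute group-mean difference $|\Delta\beta| = |\bar\beta_{ob} -
  \bar\beta_{nob}|$ reaches the per-tissue threshold: 0.10 for adipose
  tissue, 0.05 for leukocytes.

The delta comparison is inclusive (≥) by default for both tissues;
`strict_delta = TRUE` switches to a strict comparison. The difference only
affects values sitting exactly on the threshold. The delta sign convention
is obese minus non-obese throughout, so "hyper" means higher methylation in
the obese group.

As a genome-wide diagnostic, the inflation factor is reported as

$$\lambda = \frac{\mathrm{median}\left(Q_{\chi^2_1}(1 - p)\right)}{Q_{\chi^2_1}(0.5)},$$

the median 1-df chi-square quantile of the observed p-values over the null
median (≈ 0.4549), together with the observed/expected quantile pairs of the
QQ plot. This median-ratio form is one of several conventions for reporting
a QQ inflation value; it is documented here as the one implemented. For
uniform p-values $\lambda \approx 1$.

## Genomic-context enrichment

The distribution of the DMCpGs over gene regions (TSS1500, TSS200, 5′UTR,
1st exon, body, 3′UTR, intergenic), CpG-island context (island, shores —
the 2-kb flanks of an island — shelves, open sea) and chromosomes is
compared against all analysed sites. Each category receives its own 1-df
goodness-of-fit chi-square of the observed DM count in the category versus
the background expectation, so every category gets an individual over/under
call, rather than one omnibus statistic.

A 450k probe may list several gene-region annotations. The default counts
such a probe fractionally (1/k per listed region, repeats included), which
keeps category proportions summing to one; any-hit counting (each distinct
region once) is available behind `fractional = FALSE`. Which convention the
field uses varies between reports; fractional counting was chosen as the
default because it preserves the probe as the unit of observation.

## The cross-tissue signature cascade

1. **Overlap** — intersect the two tissues' DMCpG sets and drop
   multi-mapping probes.
2. **Direction consistency** — keep sites whose deltas have strictly the
   same sign in both tissues; a zero delta carries no direction and is
   excluded.
3. **Promoter island/shore filter** — keep sites with at least one
   gene-region annotation in {TSS1500, TSS200, 5′UTR, 1st exon} (any-hit
   rule, so a "TSS200;Body" probe qualifies) and CpG context in {Island,
   N_Shore, S_Shore}. The any-hit rule is deliberate: promoter annotation of
   a multi-transcript probe is a property of any of its transcripts. A
   consequence is that a probe annotated only to a 3′UTR fails the filter
   even if it is otherwise island/shore.
4. **Magnitude rule** — keep sites with $|\Delta\beta| > 0.05$ in *both*
   tissues. No additional similarity tolerance between the two deltas is
   applied by default, because no tolerance cleanly separates reported
   signature tables at printed precision; `similarity_tol` caps
   $|\Delta\beta_{adipose} - \Delta\beta_{leukocyte}|$ when supplied.

Each stage only shrinks the set and is idempotent; the shipped reference
candidate table (`cross_tissue_candidates()`) regression-tests these rules.

Samples are clustered on the significant CpGs by agglomerative hierarchical
clustering (Euclidean distance, complete linkage), cut at k = 2; columns are
pre-sorted by sample id so the result is invariant to input order. Agreement
with the known groups is scored with the plain Rand index.

## Gene-set over-representation

DM probes are mapped to genes by taking the union of their annotations.
For each gene set, the upper-tail hypergeometric probability
$P(X \ge k)$ of observing $k$ of the $n$ DM genes among the $K$ set members
within an $N$-gene universe is computed, BH-adjusted across sets, with
significance at adjusted p < 0.05. The universe is the genes mapped by all
probes surviving quality control — the most defensible background since
only those probes could have produced a DM gene. Gene sets are read from
GMT files; because no curated ontology snapshot ships with the package,
tests and the bundled analysis use synthetic gene sets, which exercise the
machinery but should (and do) produce essentially no significant terms
under random membership.

## Biomarker evaluation

For each signature CpG:

* **ROC AUC** via the rank-sum identity $\mathrm{AUC} = U/(n_1 n_2)$ (ties
  count ½), auto-oriented to ≥ 0.5 since discrimination is direction
  agnostic; the raw orientation is retained. The p-value is taken from the
  equivalent two-sided rank-sum test rather than a bootstrap.
* **Diagnostic-efficiency bands** on 100·AUC: < 20 negligible, 20–40
  minimal, 41–60 moderate, 61–80 good, > 80 excellent. The bands were
  defined on percent-correctly-classified; they are applied here to the AUC
  scale on which the discriminations are reported. Intervals are closed on
  the upper end as printed; the gap (40, 41) falls to "moderate".
* **BMI association**: Pearson correlation of beta with continuous BMI, and
  an ordinary least-squares model `beta ~ BMI + gender` reporting both
  coefficients (the gender adjustment guards against the groups' gender
  composition driving an apparent BMI effect).
* **Cross-tissue correlation**: per-probe Pearson correlation over subjects
  present in both tissues (unpaired samples ignored; probes with fewer than
  three complete pairs are skipped with a warning).
* **Methylation–expression correlation**: per-gene Pearson correlation
  across shared samples, or — when only group summaries are available — a
  single correlation across genes between the group differences
  (`mode = "group_means"`). Both modes exist because external expression
  cohorts often publish only summaries.

`binormal_auc_sim()` closes the loop on reported biomarkers: given published
group means/SDs and sizes, it draws truncated-normal (to [0, 1]) group
values and averages the oriented AUC over replicates, reproducing the
discrimination a reported summary implies.

## The synthetic cohort generator

The generator emulates the *statistical* structure of the study:

* **Manifest** — category counts follow the configured proportions to
  within one probe (largest-remainder allocation) for probe class,
  chromosome, CpG context and primary gene region. Blacklist fractions
  default to the platform's published category sizes (e.g. chrX
  11,234/485,577; rs 72/485,577); the multi-mapping fraction (0.6%) and the
  detection-failure fraction (2%) are calibration choices at realistic
  order of magnitude.
* **Baselines** — per-probe methylation is drawn from a three-component
  beta mixture (weights 0.35/0.30/0.35; Beta(2,14), Beta(12,12),
  Beta(14,2)), reproducing the trimodal low/mid/high marginal of array
  beta values. Leukocyte baselines are the adipose baselines plus a
  per-probe N(0, 0.25) logit offset.
* **Noise** — per-sample noise is N(0, 0.35) on the logit scale, giving
  beta-scale SDs near 0.05–0.08 at mid-range probes, matching the spread of
  the reported group summaries. Paired obese subjects share a N(0, 0.20)
  component across tissues, inducing within-subject cross-tissue
  correlation.
* **Planted effects** — affected probes receive a case-only logit shift
  calibrated per probe so the true difference in group means equals the
  requested `target_mean_delta` (default 0.15), clamped away from the
  boundaries at [0.02, 0.98]. Shared-effect probes shift with the same sign
  in both tissues. Effects are planted only on probes that survive the
  blacklist, so recovery metrics are not confounded with quality control. A
  fixed logit shift (`effect_size_logit`) is available instead of
  calibration.
* **Detection failures** — failing probes draw detection p from
  (0.01, 1] in at least one sample; good probes from (0, 0.001]. Only the
  position of values relative to the 0.01 threshold matters downstream.
* **Determinism** — the manifest and cohort use separate seeded RNG
  streams derived from the config seed, and every generator output is a
  pure function of its config.

What the generator does **not** emulate: batch and chip-position effects,
cell-type composition (the modelled analysis is explicitly unadjusted for
cell-type distributions), Infinium I/II chemistry differences, spatial
correlation along the genome, and realistic gene networks. Passing tests
therefore demonstrate that the statistics are implemented correctly and
behave as designed under the modelled data-generating process — not that
the pipeline is robust to those real-data artefacts.

## Numerical choices and degenerate inputs

* Beta offset 100; `offset = 0` supported; 0/0 intensities give `NA`.
* Wilcoxon: exact/approximate cutover at combined n = 12; continuity
  correction in the approximate path; tie-corrected variance; a
  zero-variance (all-tied) row returns p = 1.
* P-values of exactly 0 passed to the inflation diagnostic are clamped to
  the smallest positive double with a warning.
* Constant matrices in clustering yield a single cluster with a warning;
  cluster tie-breaks are made deterministic by lexicographic column
  ordering.
* Unknown chromosome labels, unannotated probes, missing DM records,
  single-class labels, constant vectors and rank-deficient designs all
  raise informative errors naming the offending probe where applicable.

## Problem sizes

The bundled analysis scripts use 20,000 probes with 1% shared and 2%
tissue-specific planted effects — large enough that category proportions,
inflation diagnostics and the cascade behave as they would genome-wide,
while keeping each stage in seconds. The test suite uses 800–5,000-probe
cohorts for recovery properties and 10–50 replicates for calibration
properties; the acceptance script uses 10,000-probe cohorts with 500
planted effects over 50 replicates, and 1,000 replicates for the
summary-implied AUC simulations. These sizes were chosen so each property
is measured with comfortable statistical margin.

## Known limitations

* The per-CpG test ignores covariates by design; confounding by age, gender
  or cell composition is mitigated only by the cross-tissue concordance
  filter, not removed.
* BH assumes positive-regression dependence; probes are independent in the
  generator, which is favourable relative to real arrays.
* The fractional vs any-hit annotation conventions can change enrichment
  results for heavily multi-annotated regions; both are provided.
* Reported cohort-level site counts from any particular study are not
  reproducible without that cohort's data; the package validates the
  *procedure* (on synthetic truth and on the shipped candidate-table
  fixture), not those counts.
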
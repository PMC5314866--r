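# methylmirror

Cross-tissue differential DNA methylation analysis for obesity biomarker
discovery, with a synthetic 450k-style data generator and planted ground
truth.

## The problem

Adipose tissue drives obesity pathophysiology, but sampling it requires a
biopsy. If a CpG site is differentially methylated between obese and
non-obese subjects in the *same direction* in both subcutaneous adipose
tissue and circulating leukocytes, its blood methylation level can act as a
minimally invasive surrogate marker of the adipose epigenetic state.
`methylmirror` implements the complete analysis that finds and evaluates
such sites, for epigenomics researchers working with Illumina
450k-style beta-value data (and for methodologists who want every stage of
that analysis to be testable against known truth).

## What it computes

Per CpG, the methylation fraction is `beta = M / (M + U + 100)` in [0, 1].
The pipeline then runs:

1. **Probe QC** — ordered exclusion cascade: detection p > 0.01, chrX,
   chrY, SNP-within-10bp, rs control probes, ch non-CpG probes,
   multi-mapping probes; first-match-wins accounting.
2. **Differential testing** — per-CpG two-sided Wilcoxon rank-sum (obese
   vs non-obese), Benjamini–Hochberg FDR; a DMCpG needs q < 0.05 and
   |Δβ| ≥ 0.10 (adipose) / 0.05 (leukocytes); genomic inflation
   λ = median(χ²₁ quantiles of p) / 0.4549 as a QQ diagnostic.
3. **Context enrichment** — per-category 1-df chi-square of the DMCpG
   distribution vs all analysed sites across gene region, CpG-island
   context and chromosome.
4. **Cross-tissue cascade** — overlap of the tissue DMCpG sets (minus
   multi-mapping probes) → same-direction filter → promoter
   (TSS1500/TSS200/5′UTR/1st exon) island/shore filter → strict |Δβ| > 0.05
   in both tissues.
5. **Gene-set over-representation** — upper-tail hypergeometric per GMT
   term with BH adjustment.
6. **Biomarker evaluation** — ROC AUC via the rank-sum identity
   U/(n₁n₂) with diagnostic-efficiency bands (> 80% excellent), BMI
   correlation, gender-adjusted OLS association, cross-tissue and
   methylation–expression correlation.

A synthetic cohort generator emulates the study design (45 paired obese
subjects; 8/10 non-obese controls; trimodal beta baselines; logit-scale
planted effects, shared-direction or tissue-specific; detection failures;
blacklist probes) and emits a truth ledger, so sensitivity, empirical FDR
and direction accuracy of every stage are measurable exactly. See the
vignette (`vignettes/cross-tissue-methylation.Rmd`) for models, parameter
defaults and design rationale.

## Worked example

```r
library(methylmirror)
cfg <- pipeline_config(seed = 42,
                       sim = list(n_probes = 5000,
                                  fraction_shared_effects = 0.02,
                                  fraction_tissue_specific_effects = 0.01))
res <- run_pipeline(cfg)
unlist(res$counts)
#>          input_probes      retained_adipose    retained_leukocyte
#>                  5000                  4705                  4705
#>        dmcpgs_adipose      dmcpgs_leukocyte                common
#>                   109                   118                    82
#>        same_direction promoter_island_shore             signature
#>                    82                    20                    20
unlist(res$recovery$adipose)
#>        sensitivity      empirical_fdr direction_accuracy
#>              0.872              0.000              1.000
res$biomarkers[1:3, c("probe_id", "auc_adipose", "band_adipose",
                      "auc_leukocyte", "cross_tissue_r")]
#>     probe_id auc_adipose band_adipose auc_leukocyte cross_tissue_r
#> 1 cg65706957       0.992    excellent         0.991         0.0197
#> 2 cg19511121       0.992    excellent         1.000         0.5597
#> 3 cg11332852       0.922    excellent         0.936         0.4389
```

Reading: of 5,000 simulated probes, 4,705 survive QC; 109 adipose and 118
leukocyte DMCpGs are called, 82 overlap and all 82 share direction; 20 sit
in promoter islands/shores and clear the strict magnitude rule. Against the
planted truth, the adipose DM stage recovered 87% of true effects with no
false discoveries and perfect direction calls. Each signature CpG separates
obese from non-obese samples with excellent efficiency (AUC > 0.9) in both
tissues; `res$signature` carries the per-tissue deltas and annotations, and
`write_report(res, dir)` serialises everything to JSON + TSV.

The same workflow is laid out as narrated stages under `analysis/`
(`01_simulate.R` … `07_biomarker_evaluation.R`), each writing its tables to
`results/` (large intermediates go to `scratch/`); run them in order from
the repository root.

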
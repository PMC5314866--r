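#!/usr/bin/env Rscript
# Stage 1: generate the synthetic two-tissue methylation cohort.
#
# Emulates the study design: 450k-style manifest of 20,000 probes, paired
# adipose/leukocyte tissues with 45 obese subjects, 8 (adipose) and 10
# (leukocyte) non-obese controls, trimodal beta baselines, planted
# effects (|delta beta| = 0.15; 1% shared-direction across tissues, 2%
# tissue-specific) and the blacklist categories the QC cascade removes.
# Large intermediates go to scratch/sim/, run metadata to results/.

suppressPackageStartupMessages(library(methylmirror))

seed <- 20260930L %% 10000L   # fixed analysis seed
dir.create("scratch/sim", showWarnings = FALSE, recursive = TRUE)
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(n_probes = 20000, seed = seed,
                  fraction_shared_effects = 0.01,
                  fraction_tissue_specific_effects = 0.02,
                  target_mean_delta = 0.15)
manifest <- generate_manifest(cfg)
cohort <- generate_cohort(manifest, cfg)

write_manifest_csv(manifest, "scratch/sim/manifest.csv")
write_sample_sheet(cohort$samples, "scratch/sim/samples.csv")
write_truth_tsv(cohort$truth, "scratch/sim/truth.tsv")
for (t in names(cohort$beta)) {
  write_beta_tsv(cohort$beta[[t]], sprintf("scratch/sim/beta_%s.tsv", t))
  write_beta_tsv(cohort$detection[[t]], sprintf("scratch/sim/detection_%s.tsv", t))
}

meta <- list(
  seed = seed, n_probes = cfg$n_probes,
  samples = as.list(table(paste(cohort$samples$tissue, cohort$samples$group))),
  planted = as.list(table(cohort$truth$tissue)),
  seeds_used = as.list(cohort$seeds)
)
jsonlite::write_json(meta, "results/01_simulation.json", auto_unbox = TRUE,
                     pretty = TRUE)

message(sprintf("simulated %d probes x %d samples; planted effects: %d shared, %d tissue-specific",
                cfg$n_probes, nrow(cohort$samples),
                sum(cohort$truth$tissue == "both"),
                sum(cohort$truth$tissue %in% c("adipose", "leukocyte"))))
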
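#!/usr/bin/env Rscript
# Stage 4: genomic-context enrichment of the DMCpGs.
#
# Compares the distribution of each tissue's DMCpGs against all analysed
# (filtered) sites across gene region, CpG-island context and chromosome,
# with a per-category 1-df chi-square over/under call. Multi-annotated
# probes contribute fractionally to gene-region categories.

suppressPackageStartupMessages(library(methylmirror))

manifest <- read_manifest_csv("scratch/sim/manifest.csv")

for (t in c("adipose", "leukocyte")) {
  background <- rownames(read_beta_tsv(sprintf("scratch/sim/filtered_%s.tsv", t)))
  dm <- utils::read.delim(sprintf("results/03_dmcpgs_%s.tsv", t))$probe_id
  if (length(dm) == 0) {
    message(t, ": no DMCpGs, skipping enrichment")
    next
  }
  for (dim in c("gene_region", "cpg_context", "chromosome")) {
    enr <- enrichment_test(category_distribution(dm, manifest, dim),
                           category_distribution(background, manifest, dim))
    utils::write.table(enr, sprintf("results/04_enrichment_%s_%s.tsv", t, dim),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    hits <- enr$category[enr$direction != "none"]
    message(sprintf("%s / %s: %d categories with significant over/under-representation%s",
                    t, dim, length(hits),
                    if (length(hits)) paste0(" (", paste(hits, collapse = ", "), ")") else ""))
  }
}
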
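# Independent oracles used to cross-check the package's statistics, plus
# small fixture builders. These stay deliberately naive (enumeration, direct
# formulas) and never call the code paths they verify.

# Exact two-sided Wilcoxon rank-sum p by enumerating every assignment of the
# pooled values to the case group (no ties assumed). Uses the symmetry of the
# null U distribution: p = fraction of assignments at least as extreme in
# |U - n1*n2/2|.
brute_force_wilcoxon <- function(case, control) {
  pooled <- c(case, control)
  n1 <- length(case)
  r <- rank(pooled)
  mu <- n1 * length(control) / 2
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  picks <- utils::combn(length(pooled), n1)
  u_all <- apply(picks, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
}

# Benjamini-Hochberg step-up written directly from the definition:
# q_(i) = min_{j >= i} m * p_(j) / j, capped at 1, in input order.
bh_reference <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(m * p[o] / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# 1-df goodness-of-fit chi-square for one category vs the rest, by hand.
chi_square_hand <- function(obs, n, p_bg) {
  e <- n * p_bg
  (obs - e)^2 / e + ((n - obs) - (n - e))^2 / (n - e)
}

# Upper-tail hypergeometric P(X >= k) by enumerating all n-subsets of a
# universe of size N containing K marked elements. Feasible for N <= 12.
brute_force_hypergeom <- function(k, K, n, N) {
  picks <- utils::combn(N, n)
  marked <- seq_len(K)
  mean(apply(picks, 2, function(idx) sum(idx %in% marked) >= k))
}

# A tiny hand-built annotation table covering every filter category.
toy_annotation <- function() {
  data.frame(
    probe_id = c("p_clean", "p_chrx", "p_chry", "p_rs", "p_ch", "p_snp",
                 "p_mm", "p_det"),
    chromosome = c("1", "X", "Y", "2", "3", "4", "5", "6"),
    position = 1:8 * 100L,
    gene_names = c("GENEA", "", "", "", "", "GENEB", "GENEC", "GENED"),
    gene_regions = c("TSS200", "", "", "", "", "Body", "TSS1500", "Body"),
    cpg_context = c("Island", "OpenSea", "OpenSea", "OpenSea", "OpenSea",
                    "S_Shore", "N_Shore", "OpenSea"),
    probe_class = c("cg", "cg", "cg", "rs", "ch", "cg", "cg", "cg"),
    snp_within_10bp = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    multi_mapping = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

# Beta + detection matrices matching toy_annotation(): every probe passes
# detection except p_det.
toy_beta <- function(n_samples = 4) {
  ann <- toy_annotation()
  set.seed(99)
  beta <- matrix(runif(nrow(ann) * n_samples, 0.2, 0.8), nrow(ann), n_samples,
                 dimnames = list(ann$probe_id, paste0("s", seq_len(n_samples))))
  det <- matrix(0.0005, nrow(ann), n_samples, dimnames = dimnames(beta))
  det["p_det", 2] <- 0.5
  list(beta = beta, detection = det)
}

# Small planted-effect single-tissue cohort for recovery-style tests.
small_cohort <- function(n_probes = 2000, frac_effect = 0.05,
                         delta = 0.15, seed = 1, tissues = "leukocyte") {
  cfg <- sim_config(
    n_probes = n_probes,
    fraction_shared_effects = frac_effect,
    fraction_tissue_specific_effects = 0,
    target_mean_delta = delta,
    seed = seed
  )
  man <- generate_manifest(cfg)
  coh <- generate_cohort(man, cfg, tissues = tissues)
  list(config = cfg, manifest = man, cohort = coh)
}

# Filter + DM-call one tissue of a cohort; returns calls and the full table.
run_dm_stage <- function(manifest, cohort, tissue, min_abs_delta = 0.05) {
  f <- filter_probes(cohort$beta[[tissue]], manifest,
                     detection = cohort$detection[[tissue]])
  is_case <- cohort$samples$group[match(colnames(f$beta),
                                        cohort$samples$sample_id)] == "obese"
  dm <- dm_test(f$beta, is_case)
  list(dm = dm, calls = call_dmcpgs(dm, min_abs_delta = min_abs_delta),
       filtered = f)
}
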
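test_that("manifest generation is deterministic and respects category proportions", {
  cfg <- sim_config(n_probes = 1000, seed = 7)
  m1 <- generate_manifest(cfg)
  m2 <- generate_manifest(cfg)
  expect_identical(m1, m2)
  expect_equal(anyDuplicated(m1$probe_id), 0)
  # positions unique and 1-based within each chromosome
  for (ch in unique(m1$chromosome)) {
    pos <- m1$position[m1$chromosome == ch]
    expect_equal(anyDuplicated(pos), 0)
    expect_true(all(pos >= 1))
  }
  # context proportions within +-1 probe of the request
  cfg2 <- sim_config(n_probes = 1000, seed = 7,
                     context_proportions = c(Island = 0.3, N_Shore = 0.2,
                                             S_Shore = 0.1, N_Shelf = 0.05,
                                             S_Shelf = 0.05, OpenSea = 0.3))
  m3 <- generate_manifest(cfg2)
  tab <- table(m3$cpg_context)
  expect_true(abs(tab[["Island"]] - 300) <= 1)
  expect_true(abs(tab[["N_Shore"]] - 200) <= 1)
  expect_true(abs(tab[["OpenSea"]] - 300) <= 1)
})

test_that("zero blacklist fractions yield a fully clean autosomal manifest", {
  bl <- c(chrX = 0, chrY = 0, rs = 0, ch = 0, snp10bp = 0, multimap = 0,
          detection_fail = 0)
  cfg <- sim_config(n_probes = 500, blacklist_fractions = bl, seed = 2)
  man <- generate_manifest(cfg)
  expect_true(all(man$probe_class == "cg"))
  expect_false(any(man$chromosome %in% c("X", "Y")))
  expect_false(any(man$snp_within_10bp))
  expect_false(any(man$multi_mapping))
})

test_that("invalid simulation configs are rejected", {
  expect_error(sim_config(n_probes = 0), "positive")
  expect_error(sim_config(n_control_adipose = 0), "positive")
  expect_error(sim_config(fraction_shared_effects = 1.2), "fractions")
  expect_error(sim_config(fraction_shared_effects = 0.1, effect_size_logit = 0),
               "nonzero")
  expect_error(sim_config(fraction_shared_effects = 0.1, target_mean_delta = 0),
               "positive")
})

test_that("cohorts are deterministic, bounded, and intensity-consistent", {
  cfg <- sim_config(n_probes = 400, seed = 11)
  man <- generate_manifest(cfg)
  c1 <- generate_cohort(man, cfg, include_intensities = TRUE)
  c2 <- generate_cohort(man, cfg, include_intensities = TRUE)
  expect_identical(c1$beta, c2$beta)
  for (t in names(c1$beta)) {
    expect_true(all(c1$beta[[t]] >= 0 & c1$beta[[t]] <= 1))
    ints <- c1$intensities[[t]]
    expect_true(all(ints$M >= 0) && all(ints$U >= 0))
    recomputed <- compute_beta(ints$M, ints$U, offset = 100)
    expect_equal(recomputed, unname(c1$beta[[t]]),
                 ignore_attr = TRUE, tolerance = 0.02)
  }
  # group sizes per tissue match the study design defaults
  expect_equal(sum(c1$samples$tissue == "adipose" & c1$samples$group == "obese"), 45)
  expect_equal(sum(c1$samples$tissue == "adipose" & c1$samples$group == "non-obese"), 8)
  expect_equal(sum(c1$samples$tissue == "leukocyte" & c1$samples$group == "non-obese"), 10)
})

test_that("truth ledger covers every probe once with nonzero planted deltas", {
  cfg <- sim_config(n_probes = 600, fraction_shared_effects = 0.05,
                    fraction_tissue_specific_effects = 0.04, seed = 5)
  man <- generate_manifest(cfg)
  coh <- generate_cohort(man, cfg)
  expect_setequal(coh$truth$probe_id, man$probe_id)
  expect_equal(nrow(coh$truth), nrow(man))
  affected_a <- coh$truth$tissue %in% c("adipose", "both")
  affected_l <- coh$truth$tissue %in% c("leukocyte", "both")
  expect_true(all(coh$truth$true_delta_adipose[affected_a] != 0))
  expect_true(all(coh$truth$true_delta_leukocyte[affected_l] != 0))
  expect_true(all(coh$truth$true_delta_adipose[coh$truth$is_null] == 0))
  # shared effects shift in the same direction in both tissues
  both <- coh$truth$tissue == "both"
  expect_true(all(sign(coh$truth$true_delta_adipose[both]) ==
                    sign(coh$truth$true_delta_leukocyte[both])))
})

test_that("detection failures hit planted probes as specified", {
  cfg <- sim_config(n_probes = 500, seed = 13)
  man <- generate_manifest(cfg)
  coh <- generate_cohort(man, cfg, tissues = "adipose")
  det <- coh$detection$adipose
  n_fail_expected <- round(cfg$blacklist_fractions[["detection_fail"]] * 500)
  failing <- rowSums(det > 0.01) > 0
  expect_equal(sum(failing), n_fail_expected)
  expect_true(all(det[!failing, ] <= 0.001))
})

test_that("a null cohort is calibrated: about 5% of probes reach p < 0.05", {
  cfg <- sim_config(n_probes = 3000, fraction_shared_effects = 0,
                    fraction_tissue_specific_effects = 0, seed = 3)
  man <- generate_manifest(cfg)
  coh <- generate_cohort(man, cfg, tissues = "leukocyte")
  stage <- run_dm_stage(man, coh, "leukocyte")
  frac <- mean(stage$dm$p_value < 0.05)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
})

test_that("planted mean delta-beta is recovered within 0.03", {
  # 200 affected probes, 45 cases vs 10 controls, planted |delta| = 0.15
  s <- small_cohort(n_probes = 4000, frac_effect = 0.05, delta = 0.15, seed = 21)
  stage <- run_dm_stage(s$manifest, s$cohort, "leukocyte")
  planted <- s$cohort$truth$probe_id[!s$cohort$truth$is_null]
  obs <- stage$dm$delta[match(intersect(planted, stage$dm$probe_id),
                              stage$dm$probe_id)]
  expect_equal(mean(abs(obs)), 0.15, tolerance = 0.03 / 0.15)
})

test_that("recovery scoring matches direct counting", {
  truth <- data.frame(
    probe_id = paste0("p", 1:10),
    tissue = c(rep("leukocyte", 4), rep("none", 6)),
    direction = c(1, -1, 1, -1, rep(0, 6)),
    is_null = c(rep(FALSE, 4), rep(TRUE, 6))
  )
  planted <- paste0("p", 1:4)
  exact <- evaluate_recovery(planted, truth, "leukocyte",
                             called_directions = stats::setNames(c(1, -1, 1, -1), planted))
  expect_equal(exact$sensitivity, 1)
  expect_equal(exact$empirical_fdr, 0)
  expect_equal(exact$direction_accuracy, 1)

  none <- evaluate_recovery(character(0), truth, "leukocyte")
  expect_equal(none$sensitivity, 0)
  expect_equal(none$empirical_fdr, 0)

  padded <- evaluate_recovery(c(planted, "p5", "p6"), truth, "leukocyte")
  expect_equal(padded$empirical_fdr, 2 / 6)

  expect_error(evaluate_recovery("not_a_probe", truth, "leukocyte"), "universe")
})

test_that("expression simulation couples inversely to methylation", {
  set.seed(1)
  meth <- matrix(runif(200), 20, 10,
                 dimnames = list(paste0("G", 1:20), paste0("s", 1:10)))
  expr <- simulate_expression(meth, coupling = -0.8, noise_sd = 0.3, seed = 4)
  rs <- vapply(1:20, function(i) cor(meth[i, ], expr[i, ]), numeric(1))
  expect_lt(mean(rs), -0.5)
})
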
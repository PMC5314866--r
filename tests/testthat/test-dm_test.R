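test_that("rank-sum p-values match hand-enumerated and symmetric cases", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3, 4), c(5, 6, 7, 8)), 2 / 70)
  expect_equal(wilcoxon_rank_sum(c(0.2, 0.4, 0.6), c(0.2, 0.4, 0.6)), 1)
  # label swap leaves the two-sided p unchanged
  set.seed(4)
  x <- runif(7); y <- runif(9)
  expect_equal(wilcoxon_rank_sum(x, y), wilcoxon_rank_sum(y, x))
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "nonempty")
})

test_that("approximate path agrees with stats::wilcox.test", {
  set.seed(10)
  for (i in 1:20) {
    x <- runif(45); y <- runif(10)
    ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    expect_equal(wilcoxon_rank_sum(x, y), ref, tolerance = 1e-12)
  }
  # tied data exercise the tie-corrected variance
  for (i in 1:10) {
    x <- sample(seq(0, 1, 0.1), 20, replace = TRUE)
    y <- sample(seq(0, 1, 0.1), 15, replace = TRUE)
    ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    expect_equal(wilcoxon_rank_sum(x, y), ref, tolerance = 1e-12)
  }
})

test_that("BH adjustment reproduces hand step-up results and validates input", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(1, 1)), c(1, 1))
  expect_error(bh_adjust(c(0.5, -0.1)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, 1.1)), "\\[0, 1\\]")
  set.seed(2)
  for (i in 1:50) {
    p <- runif(sample(3:200, 1))
    expect_equal(bh_adjust(p), bh_reference(p), tolerance = 1e-12)
  }
})

test_that("the per-CpG table carries consistent deltas, q-values and directions", {
  s <- small_cohort(n_probes = 800, frac_effect = 0.05, seed = 6)
  stage <- run_dm_stage(s$manifest, s$cohort, "leukocyte")
  dm <- stage$dm
  expect_true(all(dm$q_value >= dm$p_value))
  expect_true(all(abs(dm$delta) <= 1))
  expect_true(all(dm$direction[dm$delta > 0] == "hyper"))
  expect_true(all(dm$direction[dm$delta < 0] == "hypo"))
  expect_equal(dm$delta, dm$mean_case - dm$mean_control)
})

test_that("DMCpG calling applies the FDR and delta thresholds as stated", {
  rec <- data.frame(
    probe_id = paste0("p", 1:6),
    delta = c(0.12, 0.08, -0.15, 0.10, -0.04, 0.20),
    q_value = c(0.04, 0.04, 0.01, 0.06, 0.01, 0.049)
  )
  out <- call_dmcpgs(rec, fdr_max = 0.05, min_abs_delta = 0.10)
  # retained: p1 (q .04, |d| .12), p3 (q .01, .15), p6 (q .049, .20)
  expect_setequal(out$probe_id, c("p1", "p3", "p6"))
  # inclusive vs strict boundary at |delta| == threshold
  boundary <- data.frame(probe_id = "b", delta = 0.10, q_value = 0.01)
  expect_equal(nrow(call_dmcpgs(boundary, min_abs_delta = 0.10)), 1)
  expect_equal(nrow(call_dmcpgs(boundary, min_abs_delta = 0.10,
                                strict_delta = TRUE)), 0)
})

test_that("global methylation comparison works on per-sample means", {
  beta <- matrix(0.5, 10, 8, dimnames = list(paste0("p", 1:10), paste0("s", 1:8)))
  is_case <- rep(c(TRUE, FALSE), each = 4)
  expect_equal(global_methylation_compare(beta, is_case)$p_value, 1)

  set.seed(3)
  beta2 <- matrix(runif(80, 0.3, 0.5), 10, 8,
                  dimnames = dimnames(beta))
  beta2[, is_case] <- beta2[, is_case] + 0.2
  res <- global_methylation_compare(beta2, is_case)
  expect_equal(res$p_value, 2 / 70)
  # missing values are ignored in the per-sample means
  beta3 <- beta2
  beta3[1, 1] <- NA
  res3 <- global_methylation_compare(beta3, is_case)
  expect_equal(unname(res3$sample_means[1]), mean(beta3[-1, 1]))
  expect_error(global_methylation_compare(beta, rep(TRUE, 8)), "nonempty")
})

test_that("inflation lambda matches its closed-form and simulated anchors", {
  expect_equal(inflation_lambda(rep(0.5, 100))$lambda, 1)
  expect_equal(inflation_lambda(rep(0.05, 10))$lambda,
               qchisq(0.95, 1) / qchisq(0.5, 1))
  set.seed(12)
  unif <- runif(10000)
  expect_equal(inflation_lambda(unif)$lambda, 1, tolerance = 0.03)
  expect_warning(res <- inflation_lambda(c(0, 0.5)), "clamped")
  expect_true(is.finite(res$lambda))
  qq <- inflation_lambda(unif)$qq
  expect_true(all(diff(qq$expected) >= 0))
  expect_true(all(diff(qq$observed) >= 0))
  expect_error(inflation_lambda(numeric(0)), "at least one")
})
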
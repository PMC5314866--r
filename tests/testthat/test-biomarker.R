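test_that("BMI classification follows the pooled overweight+obese rule", {
  res <- classify_bmi(c(25.0, 26.2, 24.3, 31.5))
  expect_equal(res$group, c("non-obese", "obese", "non-obese", "obese"))
  expect_equal(res$who_category,
               c("overweight", "overweight", "normal/under-weight", "obese"))
  expect_error(classify_bmi(0), "positive")
  expect_error(classify_bmi(-2), "positive")
})

test_that("AUC equals the rank-sum concordance with ties at one half", {
  perfect <- roc_auc(c(0.8, 0.7, 0.6, 0.5, 0.4),
                     c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$efficiency_band, "excellent")

  mid <- roc_auc(c(0.6, 0.4, 0.5, 0.3), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(mid$auc, 0.75)          # 3 concordant of 4 pairs

  tied <- roc_auc(rep(0.5, 6), rep(c(TRUE, FALSE), 3))
  expect_equal(tied$auc, 0.5)

  expect_error(roc_auc(1:4, rep(TRUE, 4)), "two classes")

  # label flip maps raw_auc to its complement; oriented auc is unchanged
  set.seed(8)
  v <- runif(20); lab <- rep(c(TRUE, FALSE), 10)
  a <- roc_auc(v, lab); b <- roc_auc(v, !lab)
  expect_equal(b$raw_auc, 1 - a$raw_auc)
  expect_equal(b$auc, a$auc)
})

test_that("AUC matches the Mann-Whitney identity and pROC on random fixtures", {
  skip_if_not_installed("pROC")
  set.seed(15)
  for (i in 1:20) {
    n1 <- sample(5:30, 1); n2 <- sample(5:30, 1)
    v <- c(rnorm(n1, 0.5, 0.2), rnorm(n2, 0.4, 0.2))
    lab <- rep(c(TRUE, FALSE), c(n1, n2))
    res <- roc_auc(v, lab)
    u <- stats::wilcox.test(v[lab], v[!lab], exact = FALSE)$statistic
    expect_equal(res$raw_auc, unname(u) / (n1 * n2), tolerance = 1e-12)
    ref <- suppressMessages(pROC::auc(pROC::roc(lab, v, direction = "<",
                                                quiet = TRUE)))
    expect_equal(res$raw_auc, as.numeric(ref), tolerance = 1e-12)
  }
})

test_that("efficiency bands split at the printed boundaries", {
  band <- methylmirror:::efficiency_band
  expect_equal(band(c(10, 20, 40, 40.5, 41, 60, 61, 80, 80.5)),
               c("negligible", "minimal", "minimal", "moderate", "moderate",
                 "moderate", "good", "good", "excellent"))
})

test_that("binormal simulation converges to the closed-form AUC", {
  # one large draw: empirical AUC ~ Phi(delta / sqrt(sd1^2 + sd2^2))
  res <- binormal_auc_sim(0.55, 0.07, 2000, 0.45, 0.07, 2000,
                          n_rep = 1, seed = 33)
  expect_equal(res$mean_auc, pnorm(0.10 / sqrt(2 * 0.07^2)), tolerance = 0.02)
})

test_that("group comparison shares the rank-sum core and is rank-invariant", {
  expect_equal(mannwhitney_compare(c(1, 2, 3, 4), c(5, 6, 7, 8)), 2 / 70)
  expect_equal(mannwhitney_compare(c(0.1, 0.2), c(0.1, 0.2)), 1)
  set.seed(21)
  x <- runif(8); y <- runif(11)
  expect_equal(mannwhitney_compare(x, y), wilcoxon_rank_sum(x, y))
  expect_equal(mannwhitney_compare(exp(x), exp(y)), mannwhitney_compare(x, y))
})

test_that("Pearson correlation matches hand computation and validates input", {
  expect_equal(pearson_corr(c(1, 2, 3), c(2, 4, 6))$r, 1)
  expect_equal(pearson_corr(c(1, 2, 3, 4), c(1, 3, 2, 4))$r, 0.8)
  set.seed(2)
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(pearson_corr(x, y)$r, pearson_corr(y, x)$r)
  expect_error(pearson_corr(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_corr(1:2, 2:3), "at least 3")
})

test_that("gender-adjusted regression recovers planted coefficients", {
  bmi <- rep(seq(20, 40, length.out = 10), 2)
  gender <- rep(c("F", "M"), each = 10)
  exact <- suppressWarnings(adjusted_association(0.01 * bmi, bmi, gender))
  expect_equal(exact$bmi_slope, 0.01, tolerance = 1e-10)

  gender_only <- suppressWarnings(
    adjusted_association(ifelse(gender == "M", 0.3, 0.1), bmi, gender))
  expect_equal(gender_only$bmi_slope, 0, tolerance = 1e-10)
  expect_equal(gender_only$gender_coef, 0.2, tolerance = 1e-10)

  set.seed(30)
  beta <- 0.2 + 0.004 * bmi + rnorm(20, 0, 0.01)
  perm <- sample(20)
  a <- adjusted_association(beta, bmi, gender)
  b <- adjusted_association(beta[perm], bmi[perm], gender[perm])
  expect_equal(a$bmi_slope, b$bmi_slope)
  expect_error(adjusted_association(beta, rep(25, 20), rep("F", 20)),
               "collinear")
})

test_that("cross-tissue correlation pairs subjects and skips sparse probes", {
  set.seed(40)
  probes <- paste0("p", 1:5)
  ba <- matrix(runif(5 * 6), 5, 6, dimnames = list(probes, paste0("a", 1:6)))
  subj_a <- c("S1", "S2", "S3", "S4", "S5", "X1")
  bl <- ba[, c(1:5, 5)]
  colnames(bl) <- paste0("l", 1:6)
  subj_l <- c("S1", "S2", "S3", "S4", "S5", "Y1")  # X1/Y1 unpaired, ignored
  res <- cross_tissue_corr(ba, bl, subj_a, subj_l)
  expect_equal(nrow(res), 5)
  expect_equal(res$r, rep(1, 5))
  expect_true(all(res$n == 5))

  # independent tissues: correlations scatter around zero
  bl2 <- matrix(runif(5 * 100), 5, 100,
                dimnames = list(probes, paste0("l", 1:100)))
  ba2 <- matrix(runif(5 * 100), 5, 100,
                dimnames = list(probes, paste0("a", 1:100)))
  subj <- paste0("S", 1:100)
  res2 <- cross_tissue_corr(ba2, bl2, subj, subj)
  expect_lt(mean(abs(res2$r)), 0.2)

  expect_warning(
    sparse <- cross_tissue_corr(ba[1, 1:2, drop = FALSE],
                                bl[1, 1:2, drop = FALSE],
                                subj_a[1:2], subj_l[1:2]),
    "fewer than 3")
  expect_equal(nrow(sparse), 0)
})

test_that("methylation-expression correlation detects inverse coupling", {
  set.seed(50)
  meth <- matrix(runif(15 * 12), 15, 12,
                 dimnames = list(paste0("G", 1:15), paste0("s", 1:12)))
  noise_free <- -meth
  res <- methylation_expression_corr(meth, noise_free)
  expect_equal(res$r, rep(-1, 15))

  expr <- simulate_expression(meth, coupling = -0.8, seed = 51)
  res2 <- methylation_expression_corr(meth, expr)
  expect_lt(mean(res2$r), 0)

  # unshared genes are skipped and counted
  expr3 <- expr[1:10, ]
  rownames(expr3) <- c(paste0("G", 1:8), "Z1", "Z2")
  res3 <- methylation_expression_corr(meth, expr3)
  expect_equal(nrow(res3), 8)
  expect_equal(attr(res3, "n_skipped"), 9)   # G9..G15 plus Z1, Z2
  expect_error(methylation_expression_corr(meth,
    matrix(1, 2, 2, dimnames = list(c("A", "B"), c("s1", "s2")))),
    "no shared genes")

  # group-means mode correlates the per-gene differences across genes
  gm_meth <- cbind(obese = rowMeans(meth[, 1:6]), lean = rowMeans(meth[, 7:12]))
  gm_expr <- cbind(obese = -gm_meth[, 1], lean = -gm_meth[, 2])
  gm <- methylation_expression_corr(gm_meth, gm_expr, mode = "group_means")
  expect_equal(gm$r, -1, tolerance = 1e-12)
})
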
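# Biomarker evaluation of candidate CpGs: ROC/AUC with diagnostic-efficiency
# bands, group comparison, BMI correlation, gender-adjusted association, and
# cross-tissue / methylation-expression correlation.

#' Classify BMI into obese vs non-obese (and the WHO category)
#'
#' Obese means BMI > 25 kg/m2 (overweight and obese pooled); non-obese means
#' BMI <= 25. The WHO category is also reported: normal/under-weight
#' (BMI < 25), overweight (25 <= BMI < 30), obese (BMI >= 30).
#'
#' @param bmi body-mass index in kg/m2, positive (vectorised).
#' @return data frame with `bmi`, `group` ("obese"/"non-obese") and
#'   `who_category`.
#' @export
classify_bmi <- function(bmi) {
  if (any(is.na(bmi)) || any(bmi <= 0)) stop("BMI must be positive")
  data.frame(
    bmi = bmi,
    group = ifelse(bmi > 25, "obese", "non-obese"),
    who_category = ifelse(bmi < 25, "normal/under-weight",
                          ifelse(bmi < 30, "overweight", "obese")),
    stringsAsFactors = FALSE
  )
}

# Diagnostic-efficiency band for an agreement percentage (0-100): <20
# negligible, 20-40 minimal, 41-60 moderate, 61-80 good, >80 excellent;
# intervals are closed on the upper end and the gap (40,41) falls to moderate.
efficiency_band <- function(pct) {
  ifelse(pct < 20, "negligible",
         ifelse(pct <= 40, "minimal",
                ifelse(pct <= 60, "moderate",
                       ifelse(pct <= 80, "good", "excellent"))))
}

#' ROC AUC by the rank-sum (concordance) identity
#'
#' AUC is the probability that a random case value exceeds a random control
#' value, ties counting one half: U / (n1 * n2). The reported `auc` is
#' auto-oriented to at least 0.5 (discrimination regardless of hyper/hypo
#' direction); `raw_auc` keeps the orientation with cases as positives. The
#' p-value comes from the equivalent two-sided rank-sum test, and the
#' efficiency band from 100 * auc.
#'
#' @param values numeric marker values (e.g. beta at one CpG).
#' @param labels logical or two-level vector; TRUE / the second level marks
#'   cases.
#' @return list with `auc`, `raw_auc`, `p_value`, `efficiency_band`,
#'   `n_case`, `n_control`.
#' @export
roc_auc <- function(values, labels) {
  if (is.logical(labels)) {
    is_case <- labels
  } else {
    lv <- sort(unique(as.character(labels)))
    if (length(lv) != 2) stop("labels must contain exactly two classes")
    is_case <- as.character(labels) == lv[2]
  }
  if (sum(is_case) == 0 || sum(!is_case) == 0) {
    stop("labels must contain exactly two classes")
  }
  keep <- !is.na(values)
  values <- values[keep]
  is_case <- is_case[keep]
  n1 <- sum(is_case)
  n2 <- sum(!is_case)
  r <- rank(values)
  u <- sum(r[is_case]) - n1 * (n1 + 1) / 2
  raw <- u / (n1 * n2)
  auc <- max(raw, 1 - raw)
  list(
    auc = auc,
    raw_auc = raw,
    p_value = rank_sum_p(values[is_case], values[!is_case]),
    efficiency_band = efficiency_band(100 * auc),
    n_case = n1,
    n_control = n2
  )
}

#' Mann-Whitney U comparison of two groups
#'
#' Identical to [wilcoxon_rank_sum()] (shared statistical core); provided
#' under the name used for the per-gene group comparisons.
#'
#' @inheritParams wilcoxon_rank_sum
#' @return two-sided p-value.
#' @export
mannwhitney_compare <- function(case, control, exact_max = 12L) {
  wilcoxon_rank_sum(case, control, exact_max = exact_max)
}

#' Pearson correlation with a two-sided t-test
#'
#' @param x,y numeric vectors of equal length, n >= 3, neither constant.
#' @return list with `r`, `p_value`, `n`.
#' @export
pearson_corr <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant vector")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Gender-adjusted association of methylation with BMI
#'
#' Ordinary least squares of per-sample beta on BMI (continuous) plus a
#' gender indicator; reports both coefficients with their p-values.
#'
#' @param beta per-sample methylation values at one CpG (or gene summary).
#' @param bmi continuous BMI per sample.
#' @param gender two-level factor/character per sample.
#' @return list with `bmi_slope`, `bmi_p`, `gender_coef`, `gender_p`, `n`.
#' @export
adjusted_association <- function(beta, bmi, gender) {
  if (length(beta) <= 3) stop("need more than 3 samples")
  gender <- factor(gender)
  if (nlevels(gender) < 2 || stats::sd(bmi) == 0) {
    stop("collinear design (rank-deficient)")
  }
  X <- stats::model.matrix(~ bmi + gender)
  if (qr(X)$rank < ncol(X)) stop("collinear design (rank-deficient)")
  fit <- stats::lm(beta ~ bmi + gender)
  cf <- summary(fit)$coefficients
  list(
    bmi_slope = cf["bmi", "Estimate"],
    bmi_p = cf["bmi", "Pr(>|t|)"],
    gender_coef = cf[3, "Estimate"],
    gender_p = cf[3, "Pr(>|t|)"],
    n = length(beta)
  )
}

#' Per-probe cross-tissue correlation over paired subjects
#'
#' Pearson correlation, per probe, between the two tissues' beta values over
#' subjects present in both tissues; unpaired samples are ignored. Probes
#' with fewer than 3 complete pairs are skipped with a warning.
#'
#' @param beta_adipose,beta_leukocyte probes x samples matrices.
#' @param subjects_adipose,subjects_leukocyte subject ids per column of the
#'   respective matrix (pairing key).
#' @param probes probes to evaluate (default: rows common to both matrices).
#' @return data frame with `probe_id`, `r`, `p_value`, `n`.
#' @export
cross_tissue_corr <- function(beta_adipose, beta_leukocyte,
                              subjects_adipose, subjects_leukocyte,
                              probes = NULL) {
  stopifnot(ncol(beta_adipose) == length(subjects_adipose),
            ncol(beta_leukocyte) == length(subjects_leukocyte))
  if (is.null(probes)) {
    probes <- intersect(rownames(beta_adipose), rownames(beta_leukocyte))
  }
  paired <- intersect(subjects_adipose, subjects_leukocyte)
  ia <- match(paired, subjects_adipose)
  il <- match(paired, subjects_leukocyte)
  rows <- lapply(probes, function(p) {
    x <- beta_adipose[p, ia]
    y <- beta_leukocyte[p, il]
    keep <- !is.na(x) & !is.na(y)
    if (sum(keep) < 3) {
      warning("probe ", p, " skipped: fewer than 3 complete pairs")
      return(NULL)
    }
    pc <- pearson_corr(x[keep], y[keep])
    data.frame(probe_id = p, r = pc$r, p_value = pc$p_value, n = pc$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(probe_id = character(0), r = numeric(0),
                      p_value = numeric(0), n = integer(0))
  }
  out
}

#' Per-gene correlation between methylation and expression
#'
#' With `mode = "samples"`, computes a per-gene Pearson correlation between
#' methylation and expression across the samples shared by both matrices.
#' With `mode = "group_means"` (for summary-level expression with one column
#' per group), computes a single correlation across genes between the
#' methylation and expression group differences (first column minus second).
#' Genes absent from either input are skipped and counted.
#'
#' @param meth genes x samples (or genes x groups) methylation matrix.
#' @param expr genes x samples (or genes x groups) expression matrix.
#' @param mode "samples" or "group_means".
#' @return for "samples": data frame `gene`, `r`, `p_value`, `n` plus an
#'   attribute `n_skipped`; for "group_means": a single-row data frame with
#'   `r`, `p_value`, `n` over the shared genes.
#' @export
methylation_expression_corr <- function(meth, expr,
                                        mode = c("samples", "group_means")) {
  mode <- match.arg(mode)
  shared <- intersect(rownames(meth), rownames(expr))
  if (length(shared) == 0) stop("no shared genes between methylation and expression")
  n_skipped <- length(union(rownames(meth), rownames(expr))) - length(shared)
  if (mode == "group_means") {
    dm <- meth[shared, 1] - meth[shared, 2]
    de <- expr[shared, 1] - expr[shared, 2]
    pc <- pearson_corr(dm, de)
    out <- data.frame(r = pc$r, p_value = pc$p_value, n = pc$n)
    attr(out, "n_skipped") <- n_skipped
    return(out)
  }
  samples <- intersect(colnames(meth), colnames(expr))
  if (length(samples) < 3) stop("need at least 3 shared samples")
  rows <- lapply(shared, function(g) {
    pc <- pearson_corr(meth[g, samples], expr[g, samples])
    data.frame(gene = g, r = pc$r, p_value = pc$p_value, n = pc$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Mean AUC of a two-group truncated-normal marker simulation
#'
#' Draws case and control marker values from normal distributions truncated
#' to \[0, 1\] (beta-value scale) at the given group means/SDs and sizes,
#' computes the auto-oriented rank-based AUC, and averages over replicates.
#' Used to check the discrimination implied by reported group summary
#' statistics at the study's group sizes.
#'
#' @param mean_case,sd_case,n_case case-group parameters.
#' @param mean_control,sd_control,n_control control-group parameters.
#' @param n_rep number of replicates.
#' @param seed RNG seed.
#' @return list with `mean_auc`, `sd_auc` and `n_rep`.
#' @export
binormal_auc_sim <- function(mean_case, sd_case, n_case,
                             mean_control, sd_control, n_control,
                             n_rep = 1000, seed = 1L) {
  set.seed(seed)
  rtruncnorm01 <- function(n, mean, sd) {
    lo <- stats::pnorm(0, mean, sd)
    hi <- stats::pnorm(1, mean, sd)
    stats::qnorm(stats::runif(n, lo, hi), mean, sd)
  }
  aucs <- vapply(seq_len(n_rep), function(i) {
    x <- rtruncnorm01(n_case, mean_case, sd_case)
    y <- rtruncnorm01(n_control, mean_control, sd_control)
    roc_auc(c(x, y), rep(c(TRUE, FALSE), c(n_case, n_control)))$auc
  }, numeric(1))
  list(mean_auc = mean(aucs), sd_auc = stats::sd(aucs), n_rep = n_rep)
}
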
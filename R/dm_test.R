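# Per-CpG two-group differential methylation testing.
#
# The per-site test is the two-sided Wilcoxon rank-sum test, chosen over
# linear models because of the small, unbalanced groups (45 obese vs 8-10
# non-obese). P-values are adjusted genome-wide by Benjamini-Hochberg, and
# significant sites must additionally clear an absolute delta-beta threshold
# (0.10 for adipose tissue, 0.05 for leukocytes by default).

# Core rank-sum p-value. Exact null distribution (stats::pwilcox) when the
# combined sample size is small and there are no ties; otherwise the normal
# approximation with tie and continuity correction (as in stats::wilcox.test).
rank_sum_p <- function(case, control, exact_max = 12L, correct = TRUE) {
  n1 <- length(case)
  n2 <- length(control)
  r <- rank(c(case, control))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(c(case, control)) > 0
  if (n1 + n2 <= exact_max && !has_ties) {
    p <- if (u > n1 * n2 / 2) {
      2 * stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE)
    } else {
      2 * stats::pwilcox(u, n1, n2)
    }
    return(min(1, p))
  }
  mu <- n1 * n2 / 2
  tie_len <- rle(sort(r))$lengths
  sigma2 <- (n1 * n2 / 12) *
    ((n1 + n2 + 1) - sum(tie_len^3 - tie_len) / ((n1 + n2) * (n1 + n2 - 1)))
  if (sigma2 <= 0) return(1)
  z <- u - mu
  if (correct) z <- z - sign(z) * 0.5
  min(1, 2 * stats::pnorm(-abs(z / sqrt(sigma2))))
}

#' Two-sided Wilcoxon rank-sum test for two groups of beta values
#'
#' Exact enumeration is used when the combined sample size is at most
#' `exact_max` and there are no ties; otherwise a normal approximation with
#' tie and continuity correction.
#'
#' @param case,control numeric vectors of beta values (both nonempty).
#' @param exact_max combined-size cutover between the exact and approximate
#'   null distribution.
#' @return two-sided p-value in (0, 1].
#' @export
wilcoxon_rank_sum <- function(case, control, exact_max = 12L) {
  case <- case[!is.na(case)]
  control <- control[!is.na(control)]
  if (length(case) == 0 || length(control) == 0) {
    stop("both groups must be nonempty")
  }
  rank_sum_p(case, control, exact_max = exact_max)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return q-values in the input order, capped at 1.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Per-CpG differential methylation table
#'
#' Runs the two-sided Wilcoxon rank-sum test on every row of a beta matrix,
#' adjusts p-values by Benjamini-Hochberg, and records group means and their
#' difference (case minus control, i.e. obese minus non-obese).
#'
#' @param beta numeric matrix, probes x samples, values in \[0, 1\]
#'   (missing allowed; group means ignore them).
#' @param is_case logical vector over columns: TRUE for case (obese) samples.
#' @param exact_max passed to [wilcoxon_rank_sum()].
#' @return data frame with columns `probe_id`, `mean_case`, `mean_control`,
#'   `delta`, `p_value`, `q_value`, `direction` ("hyper"/"hypo"/"none").
#' @export
dm_test <- function(beta, is_case, exact_max = 12L) {
  stopifnot(is.matrix(beta), is.logical(is_case), ncol(beta) == length(is_case))
  if (sum(is_case) == 0 || sum(!is_case) == 0) stop("both groups must be nonempty")
  case_m <- beta[, is_case, drop = FALSE]
  ctrl_m <- beta[, !is_case, drop = FALSE]
  mean_case <- rowMeans(case_m, na.rm = TRUE)
  mean_control <- rowMeans(ctrl_m, na.rm = TRUE)
  p <- vapply(seq_len(nrow(beta)), function(i) {
    x <- case_m[i, ]
    y <- ctrl_m[i, ]
    rank_sum_p(x[!is.na(x)], y[!is.na(y)], exact_max = exact_max)
  }, numeric(1))
  delta <- mean_case - mean_control
  data.frame(
    probe_id = rownames(beta) %||% as.character(seq_len(nrow(beta))),
    mean_case = mean_case,
    mean_control = mean_control,
    delta = delta,
    p_value = p,
    q_value = bh_adjust(p),
    direction = ifelse(delta > 0, "hyper", ifelse(delta < 0, "hypo", "none")),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Call differentially methylated CpGs
#'
#' A site is significant when its BH-adjusted p-value is strictly below
#' `fdr_max` and its absolute delta-beta reaches `min_abs_delta`.
#'
#' @param records data frame from [dm_test()].
#' @param fdr_max FDR threshold (default 0.05, strict `<`).
#' @param min_abs_delta minimum absolute group-mean difference; 0.10 is used
#'   for adipose tissue, 0.05 for leukocytes.
#' @param strict_delta if TRUE the delta comparison is strict (`>`), otherwise
#'   inclusive (`>=`, the default).
#' @return the significant subset of `records`, with a `significant` flag
#'   column added.
#' @export
call_dmcpgs <- function(records, fdr_max = 0.05, min_abs_delta = 0.05,
                        strict_delta = FALSE) {
  stopifnot(all(c("q_value", "delta") %in% names(records)))
  hit_delta <- if (strict_delta) abs(records$delta) > min_abs_delta
               else abs(records$delta) >= min_abs_delta
  records$significant <- records$q_value < fdr_max & hit_delta
  records[records$significant, , drop = FALSE]
}

#' Compare global methylation between groups
#'
#' Averages beta over all non-missing probes per sample and compares the two
#' groups of per-sample means with the two-sided Wilcoxon rank-sum test.
#'
#' @inheritParams dm_test
#' @return list with `sample_means` (named by sample) and `p_value`.
#' @export
global_methylation_compare <- function(beta, is_case, exact_max = 12L) {
  stopifnot(is.matrix(beta), nrow(beta) >= 1)
  if (sum(is_case) == 0 || sum(!is_case) == 0) stop("both groups must be nonempty")
  m <- colMeans(beta, na.rm = TRUE)
  list(
    sample_means = m,
    p_value = wilcoxon_rank_sum(m[is_case], m[!is_case], exact_max = exact_max)
  )
}

#' Genomic inflation factor and QQ data
#'
#' Lambda is the median of the 1-df chi-square quantiles of the observed
#' p-values divided by the median of the 1-df chi-square distribution
#' (about 0.4549). For uniform p-values lambda is about 1; values well above 1
#' indicate systematic inflation (confounding or widespread signal).
#'
#' @param p_values p-values in (0, 1\]; exact zeros are clamped to the
#'   smallest positive double with a warning.
#' @return list with `lambda` and `qq`, a data frame of expected and observed
#'   -log10 p quantile pairs (sorted, most significant last).
#' @export
inflation_lambda <- function(p_values) {
  if (length(p_values) == 0) stop("need at least one p-value")
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  if (any(p_values == 0)) {
    warning("p-values of 0 clamped to the smallest positive double")
    p_values[p_values == 0] <- .Machine$double.xmin
  }
  chisq <- stats::qchisq(p_values, df = 1, lower.tail = FALSE)
  lambda <- stats::median(chisq) / stats::qchisq(0.5, df = 1)
  n <- length(p_values)
  obs <- sort(p_values, decreasing = TRUE)
  expd <- (n:1 - 0.5) / n
  list(
    lambda = lambda,
    qq = data.frame(expected = -log10(expd), observed = -log10(obs))
  )
}
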
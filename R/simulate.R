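# Synthetic 450k-style methylation data with planted ground truth.
#
# The generator emulates the statistical structure of a paired-tissue obesity
# methylation study: a manifest with CpG-island context, gene-region and
# blacklist categories; trimodal beta-value baselines; two tissues sharing
# obese subjects (45 paired) with small, unequal non-obese groups (8 adipose,
# 10 leukocytes); planted case-only effects as logit-scale shifts that are
# either shared-direction across tissues or tissue specific; detection
# failures; and a truth ledger so power, false-discovery rate and direction
# accuracy of the downstream pipeline can be measured exactly.

# hg19-ish autosome lengths (Mb), used only to spread probes over chromosomes.
.chr_mb <- c(249, 243, 198, 191, 181, 171, 159, 146, 141, 135,
             135, 134, 115, 107, 103, 90, 81, 78, 59, 63, 48, 51)

.default_blacklist <- c(
  # fractions mirroring the platform's category sizes out of 485,577 probes
  chrX = 11234 / 485577, chrY = 416 / 485577, rs = 72 / 485577,
  ch = 3343 / 485577, snp10bp = 1179 / 485577, multimap = 0.006,
  detection_fail = 0.02
)

.default_context <- c(Island = 0.31, N_Shore = 0.12, S_Shore = 0.11,
                      N_Shelf = 0.05, S_Shelf = 0.05, OpenSea = 0.36)

.default_region <- c(TSS1500 = 0.14, TSS200 = 0.11, "5'UTR" = 0.12,
                     "1stExon" = 0.08, Body = 0.33, "3'UTR" = 0.04,
                     intergenic = 0.18)

#' Simulation configuration
#'
#' Collects and validates every parameter of the synthetic cohort: probe
#' counts, per-tissue group sizes (defaults 45 obese vs 8 non-obese adipose,
#' 45 vs 10 leukocytes), planted-effect fractions and magnitude, blacklist
#' category fractions, annotation category proportions, the trimodal baseline
#' mixture, noise scales and the seed.
#'
#' @param n_probes number of probes on the synthetic array.
#' @param n_case_adipose,n_control_adipose,n_case_leukocyte,n_control_leukocyte
#'   group sizes per tissue; obese (case) subjects are paired across tissues.
#' @param fraction_shared_effects fraction of probes carrying a same-direction
#'   effect in both tissues.
#' @param fraction_tissue_specific_effects fraction carrying an effect in one
#'   tissue only (split evenly between tissues).
#' @param target_mean_delta planted absolute difference in group-mean beta at
#'   affected probes; each probe's logit shift is calibrated so its true
#'   delta-beta equals this value (up to boundary clamping near 0/1).
#' @param effect_size_logit optional fixed logit-scale shift; overrides
#'   `target_mean_delta` calibration when supplied.
#' @param blacklist_fractions named fractions for categories
#'   chrX, chrY, rs, ch, snp10bp, multimap, detection_fail.
#' @param context_proportions,region_proportions named category proportions
#'   for CpG context and (primary) gene region.
#' @param baseline_weights weights of the low/mid/high modes of the trimodal
#'   baseline beta mixture.
#' @param sample_sd_logit per-sample noise SD on the logit scale (0.35 gives
#'   beta-scale SDs near 0.05-0.08 at mid-range probes).
#' @param subject_sd_logit part of the noise shared between tissues of the
#'   same subject (induces within-subject cross-tissue correlation).
#' @param tissue_sd_logit SD of the per-probe baseline offset between tissues.
#' @param seed integer RNG seed; every generator output is a pure function of
#'   the config.
#' @return validated config (class `sim_config`).
#' @export
sim_config <- function(n_probes = 20000L,
                       n_case_adipose = 45L, n_control_adipose = 8L,
                       n_case_leukocyte = 45L, n_control_leukocyte = 10L,
                       fraction_shared_effects = 0.01,
                       fraction_tissue_specific_effects = 0.02,
                       target_mean_delta = 0.15,
                       effect_size_logit = NULL,
                       blacklist_fractions = .default_blacklist,
                       context_proportions = .default_context,
                       region_proportions = .default_region,
                       baseline_weights = c(low = 0.35, mid = 0.30, high = 0.35),
                       sample_sd_logit = 0.35,
                       subject_sd_logit = 0.20,
                       tissue_sd_logit = 0.25,
                       seed = 1L) {
  n_probes <- as.integer(n_probes)
  if (is.na(n_probes) || n_probes < 1) stop("n_probes must be a positive count")
  counts <- c(n_case_adipose, n_control_adipose, n_case_leukocyte, n_control_leukocyte)
  if (any(counts < 1)) stop("group sizes must be positive counts")
  bl <- .default_blacklist
  bl[names(blacklist_fractions)] <- blacklist_fractions
  fracs <- c(fraction_shared_effects, fraction_tissue_specific_effects, bl)
  if (any(fracs < 0 | fracs > 1)) stop("all fractions must lie in [0, 1]")
  if (sum(bl[c("chrX", "chrY", "rs", "ch", "snp10bp", "multimap")]) > 1) {
    stop("blacklist category fractions must sum to at most 1")
  }
  eff_frac <- fraction_shared_effects + fraction_tissue_specific_effects
  if (eff_frac > 0) {
    if (!is.null(effect_size_logit) && effect_size_logit == 0) {
      stop("effect_size_logit must be nonzero when effect fractions are nonzero")
    }
    if (is.null(effect_size_logit) && target_mean_delta <= 0) {
      stop("target_mean_delta must be positive when effect fractions are nonzero")
    }
  }
  structure(list(
    n_probes = n_probes,
    n_case_adipose = as.integer(n_case_adipose),
    n_control_adipose = as.integer(n_control_adipose),
    n_case_leukocyte = as.integer(n_case_leukocyte),
    n_control_leukocyte = as.integer(n_control_leukocyte),
    fraction_shared_effects = fraction_shared_effects,
    fraction_tissue_specific_effects = fraction_tissue_specific_effects,
    target_mean_delta = target_mean_delta,
    effect_size_logit = effect_size_logit,
    blacklist_fractions = bl,
    context_proportions = context_proportions / sum(context_proportions),
    region_proportions = region_proportions / sum(region_proportions),
    baseline_weights = baseline_weights / sum(baseline_weights),
    sample_sd_logit = sample_sd_logit,
    subject_sd_logit = subject_sd_logit,
    tissue_sd_logit = tissue_sd_logit,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Generate a synthetic probe manifest
#'
#' Deterministic for a fixed seed. Category counts follow the configured
#' proportions to within one probe per category (largest-remainder
#' allocation): probe class (cg/rs/ch), chromosome (including the configured
#' chrX/chrY fractions), CpG context and primary gene region. SNP-adjacent and
#' multi-mapping flags are placed on disjoint sets of autosomal cg probes.
#' Probes with a non-intergenic primary region carry one to three
#' semicolon-joined gene annotations in the 450k manifest style
#' (e.g. "TSS1500;TSS1500" or "TSS200;Body").
#'
#' @param config a [sim_config()].
#' @return data frame with columns `probe_id`, `chromosome`, `position`,
#'   `gene_names`, `gene_regions`, `cpg_context`, `probe_class`,
#'   `snp_within_10bp`, `multi_mapping`.
#' @export
generate_manifest <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_probes
  if (n < 1) stop("n_probes must be positive")
  set.seed(config$seed)
  bl <- config$blacklist_fractions

  class_counts <- alloc_counts(n, c(rs = bl[["rs"]], ch = bl[["ch"]],
                                    cg = 1 - bl[["rs"]] - bl[["ch"]]))
  probe_class <- sample(rep(c("rs", "ch", "cg"), class_counts))

  chr_counts <- alloc_counts(n, c(X = bl[["chrX"]], Y = bl[["chrY"]],
                                  stats::setNames(.chr_mb / sum(.chr_mb) *
                                                    (1 - bl[["chrX"]] - bl[["chrY"]]),
                                                  as.character(1:22))))
  chromosome <- sample(rep(names(chr_counts), chr_counts))

  position <- integer(n)
  for (ch in unique(chromosome)) {
    i <- chromosome == ch
    len <- if (ch == "X") 155e6 else if (ch == "Y") 59e6
           else .chr_mb[as.integer(ch)] * 1e6
    position[i] <- sort(sample.int(len, sum(i)))
  }

  ctx_counts <- alloc_counts(n, config$context_proportions)
  cpg_context <- sample(rep(names(ctx_counts), ctx_counts))

  reg_counts <- alloc_counts(n, config$region_proportions)
  primary_region <- sample(rep(names(reg_counts), reg_counts))

  autosomal_cg <- which(probe_class == "cg" & !chromosome %in% c("X", "Y"))
  n_snp <- min(length(autosomal_cg), round(bl[["snp10bp"]] * n))
  n_mm <- min(length(autosomal_cg) - n_snp, round(bl[["multimap"]] * n))
  flagged <- sample(autosomal_cg, n_snp + n_mm)
  snp_within_10bp <- multi_mapping <- rep(FALSE, n)
  snp_within_10bp[flagged[seq_len(n_snp)]] <- TRUE
  if (n_mm > 0) multi_mapping[flagged[n_snp + seq_len(n_mm)]] <- TRUE

  pool <- sprintf("GENE%05d", seq_len(max(50L, round(n / 8))))
  gene_names <- gene_regions <- character(n)
  genic <- which(primary_region != "intergenic" & probe_class == "cg")
  n_annot <- sample(1:3, length(genic), replace = TRUE, prob = c(0.7, 0.2, 0.1))
  base_gene <- sample(pool, length(genic), replace = TRUE)
  non_ig <- setdiff(names(config$region_proportions), "intergenic")
  for (j in seq_along(genic)) {
    i <- genic[j]
    k <- n_annot[j]
    genes <- c(base_gene[j], ifelse(stats::runif(k - 1) < 0.3,
                                    sample(pool, max(k - 1, 1), replace = TRUE),
                                    base_gene[j])[seq_len(k - 1)])
    regions <- c(primary_region[i],
                 ifelse(stats::runif(k - 1) < 0.2,
                        sample(non_ig, max(k - 1, 1), replace = TRUE),
                        primary_region[i])[seq_len(k - 1)])
    gene_names[i] <- paste(genes, collapse = ";")
    gene_regions[i] <- paste(regions, collapse = ";")
  }

  probe_id <- character(n)
  is_cg <- probe_class == "cg"
  probe_id[is_cg] <- sprintf("cg%08d", sample.int(99999999L, sum(is_cg)))
  probe_id[probe_class == "rs"] <- sprintf("rs%07d", sample.int(9999999L, class_counts[["rs"]]))
  probe_id[probe_class == "ch"] <- sprintf("ch.%07d", sample.int(9999999L, class_counts[["ch"]]))

  data.frame(
    probe_id = probe_id, chromosome = chromosome, position = position,
    gene_names = gene_names, gene_regions = gene_regions,
    cpg_context = cpg_context, probe_class = probe_class,
    snp_within_10bp = snp_within_10bp, multi_mapping = multi_mapping,
    stringsAsFactors = FALSE
  )
}

# Logit shift that moves a baseline beta m to m + sgn * d, clamped away from
# the boundaries. Returns the (possibly clamped) achieved delta and the shift.
.plant_shift <- function(m, d, sgn) {
  target <- pmin(pmax(m + sgn * d, 0.02), 0.98)
  list(delta = target - m, shift = stats::qlogis(target) - stats::qlogis(m))
}

#' Generate a synthetic two-tissue cohort with planted effects
#'
#' Baseline per-probe methylation is drawn from a three-component mixture of
#' beta distributions (low/mid/high modes), giving the trimodal marginal
#' typical of array beta values. Leukocyte baselines are the adipose baselines
#' plus a per-probe logit offset. Case (obese) samples at affected probes are
#' shifted on the logit scale so that the true difference in group-mean beta
#' equals `target_mean_delta`; shared-effect probes shift with the same sign
#' in both tissues. Obese subjects are paired across tissues and share part of
#' their per-probe noise, inducing within-subject cross-tissue correlation.
#' Detection-failure probes receive detection p > 0.01 in at least one sample.
#'
#' @param manifest output of [generate_manifest()].
#' @param config the same [sim_config()].
#' @param tissues which tissues to generate.
#' @param include_intensities if TRUE, also return methylated/unmethylated
#'   intensity matrices consistent with beta = M / (M + U + 100).
#' @return list with `beta` (list of probes x samples matrices per tissue),
#'   `detection` (matching detection p-value matrices), `samples` (sample
#'   sheet: sample_id, subject_id, tissue, group, bmi, gender, age), `truth`
#'   (per-probe ledger: probe_id, tissue affected, direction, per-tissue true
#'   deltas, is_null), optional `intensities`, and the seeds used.
#' @export
generate_cohort <- function(manifest, config,
                            tissues = c("adipose", "leukocyte"),
                            include_intensities = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  tissues <- match.arg(tissues, several.ok = TRUE)
  eff_frac <- config$fraction_shared_effects + config$fraction_tissue_specific_effects
  if (eff_frac > 0 && !is.null(config$effect_size_logit) &&
      config$effect_size_logit == 0) {
    stop("effect_size_logit must be nonzero when effect fractions are nonzero")
  }
  n <- nrow(manifest)       # forces the manifest before reseeding the RNG
  ids <- manifest$probe_id
  set.seed(config$seed + 1L)

  comp <- sample(c("low", "mid", "high"), n, replace = TRUE,
                 prob = config$baseline_weights)
  m_adipose <- numeric(n)
  m_adipose[comp == "low"] <- stats::rbeta(sum(comp == "low"), 2, 14)
  m_adipose[comp == "mid"] <- stats::rbeta(sum(comp == "mid"), 12, 12)
  m_adipose[comp == "high"] <- stats::rbeta(sum(comp == "high"), 14, 2)
  m_adipose <- pmin(pmax(m_adipose, 0.01), 0.99)
  baseline <- list(
    adipose = m_adipose,
    leukocyte = stats::plogis(stats::qlogis(m_adipose) +
                                stats::rnorm(n, 0, config$tissue_sd_logit))
  )

  clean <- manifest$probe_class == "cg" &
    !manifest$chromosome %in% c("X", "Y") &
    !manifest$snp_within_10bp & !manifest$multi_mapping
  n_fail <- round(config$blacklist_fractions[["detection_fail"]] * n)
  fail_probes <- sample.int(n, n_fail)
  eligible <- setdiff(which(clean), fail_probes)

  n_shared <- round(config$fraction_shared_effects * n)
  n_spec <- round(config$fraction_tissue_specific_effects * n)
  if (length(tissues) == 1) {
    n_shared <- n_shared + n_spec   # all effects live in the single tissue
    n_spec <- 0
  }
  if (n_shared + n_spec > length(eligible)) {
    stop("not enough clean probes to plant the requested effects")
  }
  picked <- sample(eligible, n_shared + n_spec)
  shared_idx <- picked[seq_len(n_shared)]
  spec_idx <- picked[n_shared + seq_len(n_spec)]
  spec_tissue <- if (n_spec > 0) sample(rep(tissues, length.out = n_spec)) else character(0)

  d <- config$target_mean_delta
  use_fixed_shift <- !is.null(config$effect_size_logit)
  sgn <- numeric(n)
  sgn[picked] <- sample(c(-1, 1), length(picked), replace = TRUE)
  # shared probes must be shiftable in the same direction in every tissue
  for (i in shared_idx) {
    lo <- min(vapply(tissues, function(t) baseline[[t]][i], numeric(1)))
    hi <- max(vapply(tissues, function(t) baseline[[t]][i], numeric(1)))
    if (sgn[i] > 0 && hi + d > 0.98 && lo - d >= 0.02) sgn[i] <- -1
    if (sgn[i] < 0 && lo - d < 0.02 && hi + d <= 0.98) sgn[i] <- 1
  }

  affected_in <- function(tissue) {
    idx <- shared_idx
    if (n_spec > 0) idx <- c(idx, spec_idx[spec_tissue == tissue])
    idx
  }

  shift <- true_delta <- stats::setNames(
    rep(list(numeric(n)), length(tissues)), tissues)
  for (t in tissues) {
    idx <- affected_in(t)
    if (length(idx) > 0) {
      if (use_fixed_shift) {
        s <- sgn[idx] * config$effect_size_logit
        shift[[t]][idx] <- s
        true_delta[[t]][idx] <- stats::plogis(stats::qlogis(baseline[[t]][idx]) + s) -
          baseline[[t]][idx]
      } else {
        pl <- .plant_shift(baseline[[t]][idx], d, sgn[idx])
        shift[[t]][idx] <- pl$shift
        true_delta[[t]][idx] <- pl$delta
      }
    }
  }

  group_sizes <- list(
    adipose = c(case = config$n_case_adipose, control = config$n_control_adipose),
    leukocyte = c(case = config$n_case_leukocyte, control = config$n_control_leukocyte)
  )
  n_case_max <- max(vapply(tissues, function(t) group_sizes[[t]][["case"]], numeric(1)))
  sd_subj <- min(config$subject_sd_logit, config$sample_sd_logit)
  sd_eps <- sqrt(max(config$sample_sd_logit^2 - sd_subj^2, 1e-8))
  subj_noise <- matrix(stats::rnorm(n * n_case_max, 0, sd_subj), n, n_case_max)

  beta <- detection <- intensities <- list()
  samples <- list()
  for (t in tissues) {
    n_case <- group_sizes[[t]][["case"]]
    n_ctrl <- group_sizes[[t]][["control"]]
    case_ids <- sprintf("OB%02d_%s", seq_len(n_case), substr(t, 1, 1))
    ctrl_ids <- sprintf("NC%02d_%s", seq_len(n_ctrl), substr(t, 1, 1))
    loc <- stats::qlogis(baseline[[t]])
    mat <- matrix(NA_real_, n, n_case + n_ctrl,
                  dimnames = list(ids, c(case_ids, ctrl_ids)))
    for (j in seq_len(n_case)) {
      mat[, j] <- stats::plogis(loc + shift[[t]] + subj_noise[, j] +
                                  stats::rnorm(n, 0, sd_eps))
    }
    for (j in seq_len(n_ctrl)) {
      mat[, n_case + j] <- stats::plogis(loc + stats::rnorm(n, 0, config$sample_sd_logit))
    }
    beta[[t]] <- mat

    det <- matrix(stats::runif(n * ncol(mat), 0, 0.001), n, ncol(mat),
                  dimnames = dimnames(mat))
    if (n_fail > 0) {
      for (i in fail_probes) {
        bad <- stats::runif(ncol(mat)) < 0.7
        bad[sample.int(ncol(mat), 1)] <- TRUE    # at least one failing sample
        det[i, bad] <- stats::runif(sum(bad), 0.010001, 1)
      }
    }
    detection[[t]] <- det

    if (include_intensities) {
      total <- matrix(stats::rlnorm(n * ncol(mat), log(3000), 0.3), n, ncol(mat))
      M <- pmin(mat * (total + 100), total)
      intensities[[t]] <- list(M = M, U = total - M,
                               detection = det)
    }

    samples[[t]] <- data.frame(
      sample_id = c(case_ids, ctrl_ids),
      subject_id = c(sprintf("OB%02d", seq_len(n_case)),
                     sprintf("NC%02d_%s", seq_len(n_ctrl), substr(t, 1, 1))),
      tissue = t,
      group = rep(c("obese", "non-obese"), c(n_case, n_ctrl)),
      bmi = c(stats::runif(n_case, 26.2, 53.1), stats::runif(n_ctrl, 20.1, 24.3)),
      gender = c(rep(c("F", "M"), length.out = n_case),
                 rep(c("M", "F"), length.out = n_ctrl)),
      age = round(c(stats::runif(n_case, 20, 83), stats::runif(n_ctrl, 23, 79))),
      stringsAsFactors = FALSE
    )
  }

  tissue_of <- rep("none", n)
  tissue_of[spec_idx] <- spec_tissue
  tissue_of[shared_idx] <- if (length(tissues) == 2) "both" else tissues
  truth <- data.frame(
    probe_id = ids,
    tissue = tissue_of,
    direction = ifelse(tissue_of == "none", 0, sgn),
    is_null = tissue_of == "none",
    stringsAsFactors = FALSE
  )
  for (t in tissues) truth[[paste0("true_delta_", t)]] <- true_delta[[t]]

  out <- list(
    beta = beta, detection = detection,
    samples = do.call(rbind, samples), truth = truth,
    config = config,
    seeds = c(manifest = config$seed, cohort = config$seed + 1L)
  )
  if (include_intensities) out$intensities <- intensities
  out
}

#' Score differential methylation calls against the planted truth
#'
#' @param called_probes character vector of probes called significant.
#' @param truth truth ledger from [generate_cohort()].
#' @param tissue which tissue's planted effects count as true positives.
#' @param called_directions optional named vector ("hyper"/"hypo" or +1/-1,
#'   names = probe ids) to score direction accuracy over true positives.
#' @return list with `sensitivity` (TP / planted), `empirical_fdr`
#'   (FP / max(1, calls)) and `direction_accuracy` (NA when no true positives
#'   or no directions supplied).
#' @export
evaluate_recovery <- function(called_probes, truth, tissue = "adipose",
                              called_directions = NULL) {
  if (length(called_probes) > 0 && !all(called_probes %in% truth$probe_id)) {
    stop("called probes outside the truth ledger's probe universe")
  }
  planted <- truth$probe_id[truth$tissue %in% c(tissue, "both")]
  tp <- intersect(called_probes, planted)
  fp <- setdiff(called_probes, planted)
  dir_acc <- NA_real_
  if (!is.null(called_directions) && length(tp) > 0) {
    cd <- called_directions[tp]
    cd <- ifelse(cd %in% c("hyper", "1", 1), 1, -1)
    td <- truth$direction[match(tp, truth$probe_id)]
    dir_acc <- mean(cd == td)
  }
  list(
    sensitivity = if (length(planted) == 0) NA_real_ else length(tp) / length(planted),
    empirical_fdr = length(fp) / max(1, length(called_probes)),
    direction_accuracy = dir_acc
  )
}

#' Generate synthetic gene sets (GMT-style) over a gene universe
#'
#' Random, possibly overlapping gene sets used to exercise the hypergeometric
#' over-representation stage when no curated ontology is available.
#'
#' @param genes gene universe (character).
#' @param n_sets number of sets.
#' @param size_range set-size range (sampled uniformly).
#' @param seed RNG seed.
#' @return named list of character vectors (the in-memory GMT form).
#' @export
simulate_gene_sets <- function(genes, n_sets = 50, size_range = c(10, 100),
                               seed = 1L) {
  set.seed(seed)
  sizes <- sample(size_range[1]:min(size_range[2], length(genes)), n_sets,
                  replace = TRUE)
  sets <- lapply(sizes, function(s) sample(genes, s))
  names(sets) <- sprintf("BP_SET_%03d", seq_len(n_sets))
  sets
}

#' Simulate expression coupled to methylation
#'
#' Builds a genes x samples expression table whose per-gene values are a
#' linear function of the supplied per-gene methylation values (negative
#' coupling gives the inverse methylation-expression relationship typical of
#' promoter CpGs) plus Gaussian noise.
#'
#' @param meth genes x samples matrix of methylation summaries.
#' @param coupling slope on standardised methylation (default -0.8).
#' @param noise_sd residual SD.
#' @param seed RNG seed.
#' @return matrix of the same shape as `meth`.
#' @export
simulate_expression <- function(meth, coupling = -0.8, noise_sd = 0.6, seed = 1L) {
  stopifnot(is.matrix(meth))
  set.seed(seed)
  z <- t(scale(t(meth)))
  z[is.na(z)] <- 0
  expr <- coupling * z + matrix(stats::rnorm(length(meth), 0, noise_sd),
                                nrow(meth), ncol(meth))
  dimnames(expr) <- dimnames(meth)
  expr
}
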
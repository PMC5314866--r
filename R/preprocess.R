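# Beta-value computation and the probe-exclusion cascade applied before any
# differential analysis: detection failures, sex chromosomes, SNP-adjacent
# probes, rs (SNP control) and ch (non-CpG) probes, and multi-mapping probes.

#' Compute beta values from methylated/unmethylated intensities
#'
#' beta = M / (M + U + offset), the fluorescence intensity ratio of the
#' methylated allele to total signal, in \[0, 1\]. The offset (100 by
#' convention on this platform) stabilises low-intensity probes; `offset = 0`
#' recovers the plain ratio. An all-zero denominator yields a missing value.
#'
#' @param M,U nonnegative methylated / unmethylated signal (vectorised).
#' @param offset nonnegative stabilising constant added to the denominator.
#' @return beta values in \[0, 1\], `NA` where M + U + offset == 0.
#' @export
compute_beta <- function(M, U, offset = 100) {
  if (length(offset) != 1 || offset < 0) stop("offset must be a nonnegative scalar")
  if (any(M < 0, na.rm = TRUE) || any(U < 0, na.rm = TRUE)) {
    stop("intensities must be nonnegative")
  }
  denom <- M + U + offset
  beta <- M / denom
  beta[denom == 0] <- NA_real_
  beta
}

.filter_categories <- c("detection", "chrX", "chrY", "snp10bp", "rs", "ch", "multimap")

#' Apply the probe-exclusion cascade
#'
#' Removes, in a fixed order, probes that (1) fail detection (p > threshold in
#' any sample, or per-sample masking behind `per_sample_mask`), (2) map to
#' chromosome X, (3) chromosome Y, (4) carry a SNP within 10 bp of the 3' end,
#' (5) are rs SNP-control probes, (6) are ch non-CpG probes, (7) map to
#' multiple genomic locations. Each probe is counted against the first
#' category it hits, so the per-category counts plus the retained count equal
#' the input count exactly.
#'
#' @param beta numeric matrix (probes x samples) with probe ids as rownames.
#' @param ann probe annotation data frame with columns `probe_id`,
#'   `chromosome`, `probe_class`, `snp_within_10bp`, `multi_mapping`.
#' @param detection optional matrix of detection p-values, same shape and
#'   dimnames as `beta`.
#' @param detection_p_max detection threshold (default 0.01).
#' @param per_sample_mask if TRUE, failing entries are set to `NA` instead of
#'   removing whole probes; a probe is then only removed if all samples fail.
#' @return list with `beta` (retained matrix) and `report` (named removal
#'   counts per category plus `retained` and `input`).
#' @export
filter_probes <- function(beta, ann, detection = NULL, detection_p_max = 0.01,
                          per_sample_mask = FALSE) {
  stopifnot(is.matrix(beta))
  ids <- rownames(beta)
  if (is.null(ids)) {
    if (nrow(beta) > 0) stop("beta matrix must have probe ids as rownames")
    ids <- character(0)
  }
  idx <- match(ids, ann$probe_id)
  if (anyNA(idx)) {
    stop("probes missing from annotation: ", paste(utils::head(ids[is.na(idx)], 3), collapse = ", "))
  }
  ann <- ann[idx, , drop = FALSE]
  ok_chr <- ann$chromosome %in% c(as.character(1:22), "X", "Y")
  if (any(!ok_chr)) {
    bad <- which(!ok_chr)[1]
    stop(sprintf("probe %s has unknown chromosome label '%s'",
                 ann$probe_id[bad], ann$chromosome[bad]))
  }

  removed <- stats::setNames(integer(length(.filter_categories)), .filter_categories)
  alive <- rep(TRUE, nrow(beta))

  fails_detection <- rep(FALSE, nrow(beta))
  if (!is.null(detection)) {
    stopifnot(identical(dim(detection), dim(beta)))
    fail_mat <- detection > detection_p_max
    if (per_sample_mask) {
      beta[fail_mat] <- NA_real_
      fails_detection <- rowSums(!fail_mat) == 0
    } else {
      fails_detection <- rowSums(fail_mat) > 0
    }
  }

  hit <- list(
    detection = fails_detection,
    chrX = ann$chromosome == "X",
    chrY = ann$chromosome == "Y",
    snp10bp = as.logical(ann$snp_within_10bp),
    rs = ann$probe_class == "rs",
    ch = ann$probe_class == "ch",
    multimap = as.logical(ann$multi_mapping)
  )
  for (cat in .filter_categories) {
    drop <- alive & hit[[cat]]
    removed[cat] <- sum(drop)
    alive <- alive & !drop
  }

  list(
    beta = beta[alive, , drop = FALSE],
    report = c(as.list(removed), list(retained = sum(alive), input = nrow(beta)))
  )
}
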
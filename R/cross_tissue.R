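# The cross-tissue signature cascade: intersect the DMCpG sets of the two
# tissues (dropping multi-mapping probes), keep sites whose group difference
# has the same sign in both tissues, restrict to promoter-region probes in
# CpG islands/shores, then keep sites whose difference clears the magnitude
# rule in BOTH tissues. Each stage only ever shrinks the set.

#' Intersect two DMCpG sets, excluding multi-mapping probes
#'
#' @param dm_adipose,dm_leukocyte character vectors of significant probe ids
#'   (or data frames with a `probe_id` column).
#' @param multimap_blacklist probe ids flagged as mapping to multiple genomic
#'   locations; removed from the intersection.
#' @return character vector of common probes.
#' @export
overlap_dmcpgs <- function(dm_adipose, dm_leukocyte, multimap_blacklist = character(0)) {
  as_ids <- function(x) if (is.data.frame(x)) x$probe_id else as.character(x)
  setdiff(intersect(as_ids(dm_adipose), as_ids(dm_leukocyte)),
          as_ids(multimap_blacklist))
}

#' Keep common CpGs whose deltas share a strict sign in both tissues
#'
#' A zero delta in either tissue carries no direction and is excluded.
#'
#' @param common character vector of common probe ids.
#' @param dm_adipose,dm_leukocyte full DM record data frames (from
#'   [dm_test()]) covering every common probe.
#' @return data frame of candidates: `probe_id`, `delta_adipose`,
#'   `delta_leukocyte`, `direction` ("hyper"/"hypo").
#' @export
direction_consistent <- function(common, dm_adipose, dm_leukocyte) {
  ia <- match(common, dm_adipose$probe_id)
  il <- match(common, dm_leukocyte$probe_id)
  missing <- is.na(ia) | is.na(il)
  if (any(missing)) {
    stop("no DM record in both tissues for probe(s): ",
         paste(utils::head(common[missing], 3), collapse = ", "))
  }
  da <- dm_adipose$delta[ia]
  dl <- dm_leukocyte$delta[il]
  keep <- sign(da) == sign(dl) & da != 0
  data.frame(
    probe_id = common[keep],
    delta_adipose = da[keep],
    delta_leukocyte = dl[keep],
    direction = ifelse(da[keep] > 0, "hyper", "hypo"),
    stringsAsFactors = FALSE
  )
}

#' Restrict candidates to promoter-region probes in islands/shores
#'
#' A probe is kept iff at least one of its listed gene-region annotations is
#' in `promoter_regions` (any-hit rule, so "TSS200;Body" qualifies) AND its
#' CpG context is one of `contexts`.
#'
#' @param candidates data frame from [direction_consistent()].
#' @param ann probe annotation data frame.
#' @param promoter_regions gene-region classes counted as promoter.
#' @param contexts CpG-context classes retained.
#' @return the filtered candidates with `gene_names`, `gene_regions` and
#'   `cpg_context` columns attached.
#' @export
region_filter <- function(candidates, ann,
                          promoter_regions = c("TSS1500", "TSS200", "5'UTR", "1stExon"),
                          contexts = c("Island", "N_Shore", "S_Shore")) {
  idx <- match(candidates$probe_id, ann$probe_id)
  if (anyNA(idx)) {
    stop("unannotated candidate probe(s): ",
         paste(utils::head(candidates$probe_id[is.na(idx)], 3), collapse = ", "))
  }
  sub <- ann[idx, , drop = FALSE]
  in_promoter <- vapply(sub$gene_regions, function(r) {
    any(split_multi(r) %in% promoter_regions)
  }, logical(1), USE.NAMES = FALSE)
  keep <- in_promoter & sub$cpg_context %in% contexts
  out <- candidates[keep, , drop = FALSE]
  out$gene_names <- sub$gene_names[keep]
  out$gene_regions <- sub$gene_regions[keep]
  out$cpg_context <- sub$cpg_context[keep]
  rownames(out) <- NULL
  out
}

#' Select the final signature by per-tissue magnitude (and optional similarity)
#'
#' Keeps candidates whose absolute delta-beta is strictly greater than
#' `min_abs_delta_each` in BOTH tissues; if `similarity_tol` is given, the two
#' deltas must additionally differ by at most that amount. By default no
#' similarity tolerance is applied: the magnitude rule alone defines
#' "differences of similar magnitude in both tissues".
#'
#' @param candidates data frame carrying `delta_adipose` and `delta_leukocyte`.
#' @param min_abs_delta_each strict per-tissue magnitude threshold.
#' @param similarity_tol optional cap on |delta_adipose - delta_leukocyte|.
#' @return the selected signature rows.
#' @export
signature_select <- function(candidates, min_abs_delta_each = 0.05,
                             similarity_tol = NULL) {
  keep <- abs(candidates$delta_adipose) > min_abs_delta_each &
    abs(candidates$delta_leukocyte) > min_abs_delta_each
  if (!is.null(similarity_tol)) {
    keep <- keep &
      abs(candidates$delta_adipose - candidates$delta_leukocyte) <= similarity_tol
  }
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hierarchical clustering of samples on significant CpGs
#'
#' Agglomerative clustering (Euclidean distance, complete linkage) of the
#' sample columns, cut into `k` clusters. Columns are ordered
#' lexicographically by sample id before clustering so the result is
#' invariant to input column order.
#'
#' @param beta probes x samples matrix restricted to the significant CpGs.
#' @param k number of clusters to cut (default 2: obese vs non-obese).
#' @return list with `order` (sample ids in dendrogram order) and `labels`
#'   (named cluster memberships). A constant matrix yields a single cluster
#'   with a warning.
#' @export
hierarchical_cluster <- function(beta, k = 2) {
  stopifnot(is.matrix(beta), ncol(beta) >= 2, nrow(beta) >= 1)
  beta <- beta[, order(colnames(beta)), drop = FALSE]
  d <- stats::dist(t(beta))
  if (all(d == 0)) {
    warning("constant beta matrix: all samples identical, single cluster")
    return(list(order = colnames(beta),
                labels = stats::setNames(rep(1L, ncol(beta)), colnames(beta))))
  }
  hc <- stats::hclust(d, method = "complete")
  list(order = colnames(beta)[hc$order],
       labels = stats::cutree(hc, k = k))
}

#' Venn/cascade counts for the cross-tissue overlap
#'
#' @param dm_adipose,dm_leukocyte significant probe id vectors (or DM data
#'   frames) per tissue.
#' @param common output of [overlap_dmcpgs()].
#' @param consistent output of [direction_consistent()].
#' @return named list: `adipose_only`, `leukocyte_only`, `common`,
#'   `same_direction`, `hyper`, `hypo`.
#' @export
venn_counts <- function(dm_adipose, dm_leukocyte, common, consistent) {
  as_ids <- function(x) if (is.data.frame(x)) x$probe_id else as.character(x)
  a <- as_ids(dm_adipose)
  l <- as_ids(dm_leukocyte)
  list(
    adipose_only = length(setdiff(a, l)),
    leukocyte_only = length(setdiff(l, a)),
    common = length(common),
    same_direction = nrow(consistent),
    hyper = sum(consistent$direction == "hyper"),
    hypo = sum(consistent$direction == "hypo")
  )
}

#' Reference cross-tissue candidate CpGs (regression fixture)
#'
#' A curated table of cross-tissue obesity-associated differentially
#' methylated CpGs in promoter islands/shores, with the reported group
#' differences (obese minus non-obese) in adipose tissue and leukocytes.
#' Shipped as a plain-text fixture and used to regression-test the signature
#' cascade: every row is direction-consistent, all but one 3'UTR-annotated
#' row survive the promoter/island-shore filter, and the strict per-tissue
#' magnitude rule excludes rows whose leukocyte difference is exactly 0.05.
#'
#' @return data frame with columns `probe_id`, `chromosome`, `position`,
#'   `gene_names`, `gene_regions`, `cpg_context`, `delta_adipose`,
#'   `delta_leukocyte`.
#' @export
cross_tissue_candidates <- function() {
  path <- system.file("extdata", "cross_tissue_candidates.tsv",
                      package = "methylmirror", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chromosome = "character"))
  df
}
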
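# Hypergeometric over-representation of gene-set terms among the genes
# mapped by differentially methylated CpGs, BH-adjusted across terms.

#' Map probes to their unique gene set
#'
#' Union of all gene-name annotations across the probes, deduplicated with
#' case preserved; intergenic probes (no annotation) contribute nothing.
#'
#' @param probes character vector of probe ids.
#' @param ann probe annotation data frame.
#' @return character vector of unique gene names.
#' @export
map_probes_to_genes <- function(probes, ann) {
  idx <- match(probes, ann$probe_id)
  if (anyNA(idx)) {
    stop("unannotated probe(s): ",
         paste(utils::head(probes[is.na(idx)], 3), collapse = ", "))
  }
  unique(unlist(lapply(ann$gene_names[idx], split_multi), use.names = FALSE))
}

#' Read gene sets from a GMT file
#'
#' @param path path to a tab-separated GMT file (term, description, genes...).
#' @return named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#'
#' @param gene_sets named list of character vectors.
#' @param path output path.
#' @export
write_gene_sets <- function(gene_sets, path) {
  lines <- vapply(names(gene_sets), function(nm) {
    paste(c(nm, "synthetic", gene_sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric gene-set over-representation
#'
#' For each term, the upper-tail hypergeometric probability of observing at
#' least `k` of the `n` DM genes inside the term's `K` universe genes, given
#' a universe of `N` genes; p-values are BH-adjusted across the tested terms
#' and terms are significant at adjusted p < `alpha`. Terms with no universe
#' genes are skipped.
#'
#' @param dm_genes genes of interest (must be a subset of `universe_genes`).
#' @param universe_genes the background gene universe (typically all genes
#'   mapped by probes surviving preprocessing).
#' @param gene_sets named list of character vectors (see [read_gene_sets()]).
#' @param alpha adjusted-p significance level.
#' @return data frame with `term`, `k`, `K`, `n`, `N`, `p_value`,
#'   `adjusted_p`, `significant`, sorted by p-value.
#' @export
hypergeom_enrich <- function(dm_genes, universe_genes, gene_sets, alpha = 0.05) {
  dm_genes <- unique(dm_genes)
  universe_genes <- unique(universe_genes)
  outside <- setdiff(dm_genes, universe_genes)
  if (length(outside) > 0) {
    stop("DM gene(s) outside the universe: ",
         paste(utils::head(outside, 3), collapse = ", "))
  }
  n <- length(dm_genes)
  N <- length(universe_genes)
  rows <- lapply(names(gene_sets), function(term) {
    members <- intersect(gene_sets[[term]], universe_genes)
    K <- length(members)
    if (K == 0) return(NULL)
    k <- length(intersect(members, dm_genes))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, k = k, K = K, n = n, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(term = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p_value = numeric(0),
                      adjusted_p = numeric(0), significant = logical(0)))
  }
  out$adjusted_p <- bh_adjust(out$p_value)
  out$significant <- out$adjusted_p < alpha
  out[order(out$p_value), , drop = FALSE]
}
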
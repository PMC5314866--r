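# Genomic-context enrichment: are differentially methylated CpGs over- or
# under-represented, relative to all analysed sites, across gene regions,
# CpG-island context and chromosomes?

#' Category distribution of a probe set along one annotation dimension
#'
#' For `gene_region`, a probe listing several region annotations contributes
#' fractionally: 1/k to each of its k listed entries (so
#' "TSS1500;TSS1500;TSS1500" contributes 1 to TSS1500 and "TSS200;Body"
#' contributes 0.5 to each); probes with no gene annotation count as
#' `intergenic`. With `fractional = FALSE` each distinct region is instead
#' counted once per probe (any-hit counting; proportions are then relative to
#' the probe count and need not sum to 1).
#'
#' @param probes character vector of probe ids.
#' @param ann probe annotation data frame.
#' @param dimension one of "gene_region", "cpg_context", "chromosome".
#' @param fractional fractional (default) vs any-hit counting of
#'   multi-annotated probes; only relevant for `gene_region`.
#' @return data frame with `category`, `count`, `proportion`.
#' @export
category_distribution <- function(probes, ann,
                                  dimension = c("gene_region", "cpg_context", "chromosome"),
                                  fractional = TRUE) {
  dimension <- match.arg(dimension)
  idx <- match(probes, ann$probe_id)
  if (anyNA(idx)) {
    stop("unannotated probe(s): ", paste(utils::head(probes[is.na(idx)], 3), collapse = ", "))
  }
  sub <- ann[idx, , drop = FALSE]
  counts <- switch(dimension,
    cpg_context = table(sub$cpg_context),
    chromosome = table(sub$chromosome),
    gene_region = {
      acc <- new.env()
      add <- function(cat, w) {
        assign(cat, (get0(cat, envir = acc) %||% 0) + w, envir = acc)
      }
      for (i in seq_len(nrow(sub))) {
        regions <- split_multi(sub$gene_regions[i])
        if (length(regions) == 0) {
          add("intergenic", 1)
        } else if (fractional) {
          for (r in regions) add(r, 1 / length(regions))
        } else {
          for (r in unique(regions)) add(r, 1)
        }
      }
      vals <- sort(unlist(as.list(acc)))
      vals[order(names(vals))]
    }
  )
  df <- data.frame(
    category = names(counts),
    count = as.numeric(counts),
    stringsAsFactors = FALSE
  )
  df$proportion <- df$count / length(probes)
  df[order(df$category), , drop = FALSE]
}

#' Per-category chi-square enrichment of a DM set versus background
#'
#' Each category gets a 1-df goodness-of-fit chi-square comparing the observed
#' DM count in the category (vs outside it) with the expectation under the
#' background proportion, so every category receives its own over/under call.
#'
#' @param dm_counts named numeric vector (or `category_distribution()` output)
#'   of DM-set counts per category.
#' @param background_counts same for the background (all analysed sites).
#' @param alpha significance level for the over/under direction flag.
#' @return data frame with `category`, `observed`, `expected`,
#'   `dm_proportion`, `background_proportion`, `chi_square`, `p_value`,
#'   `direction` ("over"/"under"/"none").
#' @export
enrichment_test <- function(dm_counts, background_counts, alpha = 0.05) {
  as_named <- function(x) {
    if (is.data.frame(x)) stats::setNames(x$count, x$category) else x
  }
  dm <- as_named(dm_counts)
  bg <- as_named(background_counts)
  cats <- names(bg)
  n_dm <- sum(dm)
  n_bg <- sum(bg)
  if (n_bg < n_dm) stop("background must be at least as large as the DM set")
  out <- lapply(cats, function(cat) {
    p_bg <- bg[[cat]] / n_bg
    expd <- p_bg * n_dm
    obs <- if (cat %in% names(dm)) dm[[cat]] else 0
    if (expd == 0 || n_dm - expd == 0) {
      warning("category '", cat, "' skipped: zero expected count")
      return(NULL)
    }
    chi <- (obs - expd)^2 / expd +
      ((n_dm - obs) - (n_dm - expd))^2 / (n_dm - expd)
    p <- stats::pchisq(chi, df = 1, lower.tail = FALSE)
    data.frame(
      category = cat, observed = obs, expected = expd,
      dm_proportion = obs / n_dm, background_proportion = p_bg,
      chi_square = chi, p_value = p,
      direction = if (p < alpha) (if (obs > expd) "over" else "under") else "none",
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
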
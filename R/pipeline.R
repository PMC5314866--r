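# End-to-end orchestration: simulate (or load) -> probe filtering -> per-CpG
# differential testing per tissue -> genomic-context enrichment -> the
# cross-tissue signature cascade -> gene-set over-representation -> biomarker
# evaluation, with a machine-readable summary report.

#' Pipeline configuration
#'
#' Houses every threshold of the workflow with the study defaults: FDR < 0.05
#' per tissue, minimum absolute delta-beta 0.10 (adipose) / 0.05 (leukocyte),
#' detection p <= 0.01, beta offset 100, strict per-tissue magnitude 0.05 for
#' the final signature.
#'
#' @param seed integer seed driving every stochastic component.
#' @param synthetic if TRUE, data are simulated from `sim`; otherwise the
#'   file paths in `inputs` are read.
#' @param sim list of overrides passed to [sim_config()] (synthetic mode).
#' @param inputs named list of file paths (file mode): `manifest`, `samples`,
#'   `beta_adipose`, `beta_leukocyte`, optional `detection_adipose`,
#'   `detection_leukocyte`.
#' @param fdr_max FDR threshold (strict `<`).
#' @param min_delta_adipose,min_delta_leukocyte per-tissue delta-beta
#'   thresholds for DMCpG calling.
#' @param detection_p_max detection p-value threshold.
#' @param offset beta denominator offset (recorded; applies when computing
#'   beta from intensities).
#' @param signature_min_delta strict per-tissue magnitude for the final
#'   signature.
#' @param similarity_tol optional cap on the between-tissue delta difference.
#' @param gene_sets optional GMT path or named list; synthetic sets are
#'   generated when NULL.
#' @param n_gene_sets number of synthetic gene sets when `gene_sets` is NULL.
#' @param max_biomarkers cap on the number of signature CpGs taken into the
#'   biomarker stage.
#' @return validated config list (class `pipeline_config`).
#' @export
pipeline_config <- function(seed = 1L, synthetic = TRUE, sim = list(),
                            inputs = list(),
                            fdr_max = 0.05,
                            min_delta_adipose = 0.10,
                            min_delta_leukocyte = 0.05,
                            detection_p_max = 0.01, offset = 100,
                            signature_min_delta = 0.05,
                            similarity_tol = NULL,
                            gene_sets = NULL, n_gene_sets = 50,
                            max_biomarkers = 20) {
  thr <- c(fdr_max, min_delta_adipose, min_delta_leukocyte, detection_p_max)
  if (any(thr <= 0 | thr > 1)) stop("thresholds must lie in (0, 1]")
  if (!synthetic) {
    need <- c("manifest", "samples", "beta_adipose", "beta_leukocyte")
    missing <- setdiff(need, names(inputs))
    if (length(missing) > 0) {
      stop("file mode requires inputs: ", paste(missing, collapse = ", "))
    }
  }
  structure(list(
    seed = as.integer(seed), synthetic = synthetic, sim = sim, inputs = inputs,
    fdr_max = fdr_max, min_delta_adipose = min_delta_adipose,
    min_delta_leukocyte = min_delta_leukocyte,
    detection_p_max = detection_p_max, offset = offset,
    signature_min_delta = signature_min_delta,
    similarity_tol = similarity_tol,
    gene_sets = gene_sets, n_gene_sets = n_gene_sets,
    max_biomarkers = max_biomarkers
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys mirror the [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read YAML configs")
  }
  do.call(pipeline_config, yaml::read_yaml(path))
}

.stage <- function(name, expr) {
  message(sprintf("[%s] %s ...", format(Sys.time(), "%H:%M:%S"), name))
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
  })
  message(sprintf("[%s] %s done (%.1fs)", format(Sys.time(), "%H:%M:%S"),
                  name, as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the full cross-tissue differential methylation workflow
#'
#' Executes probe filtering, per-tissue Wilcoxon/BH/delta DMCpG calling with
#' inflation diagnostics, genomic-context enrichment, the cross-tissue
#' signature cascade with hierarchical clustering, gene-set
#' over-representation and biomarker evaluation. Deterministic given the
#' config seed. Progress is logged to stderr; results are returned (and can
#' be serialised with [write_report()]).
#'
#' @param config a [pipeline_config()].
#' @return summary list with per-stage tables and counts, the thresholds
#'   used, seeds and package version.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  tissues <- c("adipose", "leukocyte")

  if (config$synthetic) {
    sim_cfg <- do.call(sim_config, utils::modifyList(list(seed = config$seed),
                                                     config$sim))
    manifest <- .stage("simulate manifest", generate_manifest(sim_cfg))
    cohort <- .stage("simulate cohort", generate_cohort(manifest, sim_cfg))
    beta <- cohort$beta
    detection <- cohort$detection
    samples <- cohort$samples
    truth <- cohort$truth
  } else {
    manifest <- .stage("read manifest", read_manifest_csv(config$inputs$manifest))
    samples <- read_sample_sheet(config$inputs$samples)
    beta <- list(adipose = read_beta_tsv(config$inputs$beta_adipose),
                 leukocyte = read_beta_tsv(config$inputs$beta_leukocyte))
    detection <- list(
      adipose = if (!is.null(config$inputs$detection_adipose))
        read_beta_tsv(config$inputs$detection_adipose),
      leukocyte = if (!is.null(config$inputs$detection_leukocyte))
        read_beta_tsv(config$inputs$detection_leukocyte))
    truth <- NULL
  }

  filtered <- dm <- dmcpgs <- lambda <- global_p <- filter_reports <- list()
  min_delta <- c(adipose = config$min_delta_adipose,
                 leukocyte = config$min_delta_leukocyte)
  for (t in tissues) {
    f <- .stage(paste("filter", t),
                filter_probes(beta[[t]], manifest, detection = detection[[t]],
                              detection_p_max = config$detection_p_max))
    filtered[[t]] <- f$beta
    filter_reports[[t]] <- f$report
    is_case <- samples$group[match(colnames(f$beta), samples$sample_id)] == "obese"
    dm[[t]] <- .stage(paste("dm test", t), dm_test(f$beta, is_case))
    dmcpgs[[t]] <- call_dmcpgs(dm[[t]], fdr_max = config$fdr_max,
                               min_abs_delta = min_delta[[t]])
    lambda[[t]] <- inflation_lambda(dm[[t]]$p_value)$lambda
    global_p[[t]] <- global_methylation_compare(f$beta, is_case)$p_value
  }

  enrichment <- .stage("context enrichment", {
    lapply(stats::setNames(tissues, tissues), function(t) {
      bg_ids <- rownames(filtered[[t]])
      dm_ids <- dmcpgs[[t]]$probe_id
      lapply(stats::setNames(
        c("gene_region", "cpg_context", "chromosome"),
        c("gene_region", "cpg_context", "chromosome")), function(dim) {
          if (length(dm_ids) == 0) return(NULL)
          enrichment_test(category_distribution(dm_ids, manifest, dim),
                          category_distribution(bg_ids, manifest, dim))
        })
    })
  })

  cross <- .stage("cross-tissue cascade", {
    mm <- manifest$probe_id[manifest$multi_mapping]
    common <- overlap_dmcpgs(dmcpgs$adipose, dmcpgs$leukocyte, mm)
    consistent <- direction_consistent(common, dm$adipose, dm$leukocyte)
    promoter <- region_filter(consistent, manifest)
    signature <- signature_select(promoter,
                                  min_abs_delta_each = config$signature_min_delta,
                                  similarity_tol = config$similarity_tol)
    venn <- venn_counts(dmcpgs$adipose, dmcpgs$leukocyte, common, consistent)
    list(common = common, consistent = consistent, promoter = promoter,
         signature = signature, venn = venn)
  })

  clustering <- .stage("hierarchical clustering", {
    lapply(stats::setNames(tissues, tissues), function(t) {
      sig_ids <- dmcpgs[[t]]$probe_id
      if (length(sig_ids) < 1) return(NULL)
      cl <- hierarchical_cluster(filtered[[t]][sig_ids, , drop = FALSE], k = 2)
      grp <- samples$group[match(names(cl$labels), samples$sample_id)]
      list(labels = cl$labels, order = cl$order,
           rand_index_vs_group = rand_index(cl$labels, grp))
    })
  })

  go <- .stage("gene-set enrichment", {
    universe <- map_probes_to_genes(rownames(filtered$adipose), manifest)
    dm_genes <- map_probes_to_genes(dmcpgs$adipose$probe_id, manifest)
    sets <- config$gene_sets
    if (is.null(sets)) {
      sets <- simulate_gene_sets(universe, n_sets = config$n_gene_sets,
                                 seed = config$seed + 2L)
    } else if (is.character(sets)) {
      sets <- read_gene_sets(sets)
    }
    if (length(dm_genes) == 0) NULL
    else hypergeom_enrich(dm_genes, universe, sets)
  })

  biomarkers <- .stage("biomarker evaluation", if (nrow(cross$signature) > 0) {
    sig <- utils::head(cross$signature, config$max_biomarkers)
    subj <- function(t) samples$subject_id[match(colnames(filtered[[t]]),
                                                 samples$sample_id)]
    ctc <- cross_tissue_corr(filtered$adipose, filtered$leukocyte,
                             subj("adipose"), subj("leukocyte"),
                             probes = intersect(sig$probe_id,
                                                intersect(rownames(filtered$adipose),
                                                          rownames(filtered$leukocyte))))
    rows <- lapply(seq_len(nrow(sig)), function(i) {
      p <- sig$probe_id[i]
      per_tissue <- lapply(stats::setNames(tissues, tissues), function(t) {
        if (!p %in% rownames(filtered[[t]])) return(NULL)
        v <- filtered[[t]][p, ]
        meta <- samples[match(colnames(filtered[[t]]), samples$sample_id), ]
        roc <- roc_auc(v, meta$group == "obese")
        bmi <- pearson_corr(v, meta$bmi)
        adj <- adjusted_association(v, meta$bmi, meta$gender)
        list(roc = roc, bmi = bmi, adj = adj)
      })
      a <- per_tissue$adipose
      l <- per_tissue$leukocyte
      data.frame(
        probe_id = p, gene_names = sig$gene_names[i],
        auc_adipose = if (!is.null(a)) a$roc$auc else NA,
        band_adipose = if (!is.null(a)) a$roc$efficiency_band else NA,
        auc_p_adipose = if (!is.null(a)) a$roc$p_value else NA,
        auc_leukocyte = if (!is.null(l)) l$roc$auc else NA,
        band_leukocyte = if (!is.null(l)) l$roc$efficiency_band else NA,
        auc_p_leukocyte = if (!is.null(l)) l$roc$p_value else NA,
        bmi_r_adipose = if (!is.null(a)) a$bmi$r else NA,
        bmi_p_adipose = if (!is.null(a)) a$bmi$p_value else NA,
        bmi_slope_adj = if (!is.null(a)) a$adj$bmi_slope else NA,
        bmi_slope_adj_p = if (!is.null(a)) a$adj$bmi_p else NA,
        cross_tissue_r = if (p %in% ctc$probe_id) ctc$r[ctc$probe_id == p] else NA,
        cross_tissue_p = if (p %in% ctc$probe_id) ctc$p_value[ctc$probe_id == p] else NA,
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  })   # NULL when the signature is empty

  recovery <- NULL
  if (!is.null(truth)) {
    recovery <- lapply(stats::setNames(tissues, tissues), function(t) {
      dirs <- stats::setNames(dmcpgs[[t]]$direction, dmcpgs[[t]]$probe_id)
      evaluate_recovery(dmcpgs[[t]]$probe_id, truth, tissue = t,
                        called_directions = dirs)
    })
  }

  list(
    version = as.character(utils::packageVersion("methylmirror")),
    seed = config$seed,
    thresholds = list(
      fdr_max = config$fdr_max,
      min_delta_adipose = config$min_delta_adipose,
      min_delta_leukocyte = config$min_delta_leukocyte,
      detection_p_max = config$detection_p_max,
      offset = config$offset,
      signature_min_delta = config$signature_min_delta,
      similarity_tol = config$similarity_tol
    ),
    filter_reports = filter_reports,
    counts = list(
      input_probes = nrow(beta$adipose),
      retained_adipose = nrow(filtered$adipose),
      retained_leukocyte = nrow(filtered$leukocyte),
      dmcpgs_adipose = nrow(dmcpgs$adipose),
      dmcpgs_leukocyte = nrow(dmcpgs$leukocyte),
      common = length(cross$common),
      same_direction = nrow(cross$consistent),
      promoter_island_shore = nrow(cross$promoter),
      signature = nrow(cross$signature)
    ),
    lambda = lambda,
    global_methylation_p = global_p,
    dmcpgs = lapply(dmcpgs, function(d) d[order(d$q_value), , drop = FALSE]),
    enrichment = enrichment,
    venn = cross$venn,
    signature = cross$signature,
    clustering = lapply(clustering, function(cl)
      if (is.null(cl)) NULL else cl["rand_index_vs_group"]),
    go = go,
    biomarkers = biomarkers,
    recovery = recovery
  )
}

#' Serialise a pipeline summary to disk
#'
#' Writes `summary.json` (the counts, thresholds, Venn counts, lambda values
#' and recovery metrics; numbers survive a JSON round trip at full double
#' precision) plus TSV tables for the DMCpGs, enrichment, signature, gene-set
#' and biomarker results. Absent stages are recorded as explicit gaps rather
#' than omitted.
#'
#' @param summary output of [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return (invisibly) the paths written.
#' @export
write_report <- function(summary, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  js <- summary[c("version", "seed", "thresholds", "filter_reports", "counts",
                  "lambda", "global_methylation_p", "venn", "clustering",
                  "recovery")]
  js$signature_empty <- is.null(summary$signature) || nrow(summary$signature) == 0
  js$missing_stages <- names(Filter(is.null, summary[c("enrichment", "go", "biomarkers")]))
  p <- file.path(dir, "summary.json")
  jsonlite::write_json(js, p, auto_unbox = TRUE, digits = NA, null = "null")
  paths <- c(paths, p)

  wr <- function(df, name) {
    if (is.null(df) || nrow(df) == 0) return(invisible(NULL))
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", row.names = FALSE, quote = FALSE)
    paths <<- c(paths, p)
  }
  wr(summary$dmcpgs$adipose, "dmcpgs_adipose.tsv")
  wr(summary$dmcpgs$leukocyte, "dmcpgs_leukocyte.tsv")
  for (t in names(summary$enrichment)) {
    for (dim in names(summary$enrichment[[t]])) {
      wr(summary$enrichment[[t]][[dim]], sprintf("enrichment_%s_%s.tsv", t, dim))
    }
  }
  wr(summary$signature, "signature.tsv")
  wr(summary$go, "go_enrichment.tsv")
  wr(summary$biomarkers, "biomarkers.tsv")
  invisible(paths)
}
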
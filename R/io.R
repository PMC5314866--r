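# Readers/writers for the tabular interchange formats: manifest CSV in the
# 450k dialect, beta TSV (probes x samples), sample sheet CSV, truth TSV.
# All files carry headers, UTF-8, '.' decimal.

# internal <-> manifest-CSV column mapping
.manifest_cols <- c(
  probe_id = "IlmnID", chromosome = "CHR", position = "MAPINFO",
  gene_names = "UCSC_RefGene_Name", gene_regions = "UCSC_RefGene_Group",
  cpg_context = "Relation_to_UCSC_CpG_Island", probe_class = "Probe_Class",
  snp_within_10bp = "SNP_10bp_Flag", multi_mapping = "MultiMap_Flag"
)

#' Write a probe manifest as a 450k-dialect CSV
#'
#' Columns: IlmnID, CHR, MAPINFO, UCSC_RefGene_Name, UCSC_RefGene_Group,
#' Relation_to_UCSC_CpG_Island, Probe_Class, SNP_10bp_Flag, MultiMap_Flag;
#' multi-annotations are semicolon-joined.
#'
#' @param manifest data frame from [generate_manifest()].
#' @param path output path.
#' @export
write_manifest_csv <- function(manifest, path) {
  out <- manifest[, names(.manifest_cols)]
  names(out) <- unname(.manifest_cols)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a 450k-dialect manifest CSV
#'
#' @param path path to a CSV written by [write_manifest_csv()] (or any file
#'   with those columns).
#' @return manifest data frame in the internal column naming.
#' @export
read_manifest_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(CHR = "character"))
  missing <- setdiff(unname(.manifest_cols), names(raw))
  if (length(missing) > 0) {
    stop("manifest missing column(s): ", paste(missing, collapse = ", "))
  }
  out <- raw[, unname(.manifest_cols)]
  names(out) <- names(.manifest_cols)
  out$gene_names[is.na(out$gene_names)] <- ""
  out$gene_regions[is.na(out$gene_regions)] <- ""
  out$gene_regions <- gsub("′", "'", out$gene_regions)
  out$snp_within_10bp <- as.logical(out$snp_within_10bp)
  out$multi_mapping <- as.logical(out$multi_mapping)
  out
}

#' Write a beta (or detection) matrix as TSV, probes as rows
#'
#' @param mat numeric matrix with probe rownames and sample colnames.
#' @param path output path.
#' @export
write_beta_tsv <- function(mat, path) {
  df <- data.frame(probe_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a beta (or detection) matrix from TSV
#'
#' @param path TSV with a `probe_id` first column and one column per sample.
#' @return numeric matrix with probe rownames.
#' @export
read_beta_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write/read the sample sheet CSV
#'
#' @param samples sample sheet data frame.
#' @param path file path.
#' @export
write_sample_sheet <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write/read the planted-effect truth ledger TSV
#'
#' @param truth truth data frame from [generate_cohort()].
#' @param path file path.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_truth_tsv
#' @export
read_truth_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
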
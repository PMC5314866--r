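#' @keywords internal
"_PACKAGE"

# Largest-remainder allocation of n items to categories with given proportions.
# Guarantees |count_i - n * p_i| < 1 for every category and sum(counts) == n.
alloc_counts <- function(n, props) {
  stopifnot(n >= 0, all(props >= 0), sum(props) > 0)
  props <- props / sum(props)
  raw <- n * props
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  stats::setNames(as.integer(counts), names(props))
}

# Split a semicolon-joined annotation string into a character vector,
# normalising unicode primes to ASCII apostrophes. Empty string -> character(0).
split_multi <- function(x) {
  x <- gsub("′", "'", x)
  x <- trimws(x)
  if (is.na(x) || !nzchar(x)) return(character(0))
  trimws(strsplit(x, ";", fixed = TRUE)[[1]])
}

#' Rand index between two partitions
#'
#' Plain (unadjusted) Rand index: the fraction of sample pairs on which two
#' partitions agree (either both place the pair together or both apart).
#' Used to score cluster/group agreement in recovery experiments.
#'
#' @param a,b integer or factor labelings of the same samples.
#' @return Rand index in \[0, 1\].
#' @export
rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must label the same samples")
  n <- length(a)
  if (n < 2) return(1)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  s_both <- sum(comb2(tab))
  s_a <- sum(comb2(rowSums(tab)))
  s_b <- sum(comb2(colSums(tab)))
  total <- comb2(n)
  (total + 2 * s_both - s_a - s_b) / total
}

`%||%` <- function(x, y) if (is.null(x)) y else x
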
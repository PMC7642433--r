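#' @useDynLib immunophen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor kmeans hclust cutree as.dist dist median quantile rnbinom runif qnorm pnorm rnorm sd var predict
#' @importFrom utils read.delim write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(sprintf(...), call. = FALSE)

#' Derive per-stage seeds from a master seed
#'
#' The pipeline fans a single master seed out to its stages through a fixed
#' counter scheme, so that every stage is independently reproducible and
#' stages do not share RNG streams. Seeds stay below 2^31 - 1.
#'
#' @param master_seed single integer master seed.
#' @param stage stage name (character scalar).
#' @return a single integer seed for the stage.
#' @export
stage_seed <- function(master_seed, stage) {
  stopifnot(length(master_seed) == 1L, is.finite(master_seed))
  offsets <- c(
    simdata = 1L, ihc = 2L, histoquant = 3L, polar = 4L, exprprep = 5L,
    geneselect = 6L, consensus = 7L, nsc = 8L, workflow = 9L, test = 10L
  )
  if (!stage %in% names(offsets)) stop_input("unknown stage '%s'", stage)
  as.integer((as.numeric(master_seed) * 1009 + offsets[[stage]] * 9973) %% 2147483647)
}

# Truncated normal via inverse-CDF: exact, vectorized, reproducible under
# set.seed (one uniform per draw).
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same samples,
#' used to score cluster recovery against planted phenotype truth.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return numeric scalar in \[-1, 1\]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop_input("label vectors differ in length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

# --- TSV / JSON I/O -------------------------------------------------------
# All tabular interchange is plain TSV with a header row; matrices carry
# their row ids in a leading `gene_id` / `sample_id` column.

#' Write a data frame as TSV
#' @param df data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV file written by this package
#' @param path input file path.
#' @return data frame.
#' @export
read_tsv <- function(path) {
  read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write a gene-by-sample matrix as TSV (genes as rows, `gene_id` column)
#' @param mat numeric matrix with row and column names.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  write_tsv(df, path)
}

#' Read a gene-by-sample matrix from TSV
#' @param path input file path produced by [write_matrix_tsv()].
#' @return numeric matrix with gene ids as row names.
#' @export
read_matrix_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
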
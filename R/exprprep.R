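# Count-matrix preparation: low-expression filtering, TMM size factors,
# log2 CPM, and housekeeping-gene ratio normalization.
#
# The TMM implementation follows the canonical trimmed-mean-of-M-values
# construction: a reference sample is chosen as the one whose upper-quartile
# CPM is closest to the cohort mean upper-quartile; each sample's factor is
# 2^(weighted trimmed mean of gene-wise log2 ratios against the reference),
# genes with a zero in either sample excluded, doubly trimmed by M
# (log-ratio, 30%) and A (abundance, 5%), with inverse-asymptotic-variance
# weights; factors are rescaled to geometric mean 1.

#' Default housekeeping genes used for ratio normalization
#'
#' Four stable reference genes used to scale log2 CPM so that the classifier
#' ports across expression platforms. (A fifth pan-cancer candidate, EEF1A1,
#' is conventionally dropped for low expression in ovarian cohorts.)
#' @export
DEFAULT_HK_GENES <- c("ACTB", "ACTG1", "HSP90AB1", "UBC")

validate_counts <- function(counts) {
  if (!is.matrix(counts)) stop_input("counts must be a matrix")
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts))) {
    stop_input("counts must have unique gene ids as rownames")
  }
  if (is.null(colnames(counts)) || anyDuplicated(colnames(counts))) {
    stop_input("counts must have unique sample ids as colnames")
  }
  if (any(counts < 0)) stop_input("counts must be non-negative")
  invisible(counts)
}

raw_cpm <- function(counts) {
  lib <- colSums(counts)
  if (any(lib == 0)) stop_input("sample(s) with zero library size")
  sweep(counts, 2, lib, "/") * 1e6
}

#' Remove lowly expressed genes
#'
#' A gene is removed iff its CPM (computed on raw library sizes) falls below
#' `cpm_cutoff` in at least `frac_cutoff` of the samples; a fraction exactly
#' equal to `frac_cutoff` removes the gene.
#'
#' @param counts integer matrix, genes x samples, with dimnames.
#' @param cpm_cutoff CPM below which a gene counts as unexpressed in a
#'   sample (default 0.25).
#' @param frac_cutoff fraction of samples at which low expression triggers
#'   removal (default 0.10).
#' @param keep_genes gene ids exempt from removal (deployment use: a
#'   trained classifier's genes must survive preparation of new cohorts).
#' @return the filtered count matrix.
#' @export
filter_low_expression <- function(counts, cpm_cutoff = 0.25,
                                  frac_cutoff = 0.10,
                                  keep_genes = character(0)) {
  validate_counts(counts)
  if (ncol(counts) < 2) stop_input("need at least 2 samples")
  frac_low <- rowMeans(raw_cpm(counts) < cpm_cutoff)
  keep <- frac_low < frac_cutoff | rownames(counts) %in% keep_genes
  if (!any(keep)) stop_input("all genes removed by the low-expression filter")
  counts[keep, , drop = FALSE]
}

#' TMM scale factors
#'
#' @param counts filtered count matrix, genes x samples.
#' @param logratio_trim two-sided trim fraction on M values (default 0.30).
#' @param abs_trim two-sided trim fraction on A values (default 0.05).
#' @param a_cutoff lower A cutoff excluding vanishing abundances
#'   (default -1e10, i.e. effectively off).
#' @return named numeric vector of per-sample factors with geometric mean 1.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.30, abs_trim = 0.05,
                        a_cutoff = -1e10) {
  validate_counts(counts)
  lib <- colSums(counts)
  cpm <- raw_cpm(counts)
  # reference: sample whose upper-quartile CPM is closest to the mean
  f75 <- apply(cpm, 2, quantile, probs = 0.75, names = FALSE)
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    tmm_pair(counts[, j], counts[, ref], lib[j], lib[ref],
             logratio_trim, abs_trim, a_cutoff, colnames(counts)[j])
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

# One sample against the reference; mirrors the canonical weighted
# doubly trimmed mean of M values.
tmm_pair <- function(obs, ref, lib_obs, lib_ref, logratio_trim, abs_trim,
                     a_cutoff, sample_id) {
  keep <- obs > 0 & ref > 0
  if (!any(keep)) {
    stop_input("sample '%s' shares no expressed genes with the reference",
               sample_id)
  }
  po <- obs[keep] / lib_obs
  pr <- ref[keep] / lib_ref
  M <- log2(po / pr)
  A <- 0.5 * log2(po * pr)
  # inverse asymptotic variance of M under binomial sampling
  w <- (lib_obs - obs[keep]) / (lib_obs * obs[keep]) +
       (lib_ref - ref[keep]) / (lib_ref * ref[keep])
  ok <- is.finite(M) & is.finite(A) & A > a_cutoff
  M <- M[ok]; A <- A[ok]; w <- w[ok]
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  lo_m <- floor(n * logratio_trim) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * abs_trim) + 1
  hi_a <- n + 1 - lo_a
  rm_ <- rank(M); ra <- rank(A)
  keep2 <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
  f <- sum(M[keep2] / w[keep2], na.rm = TRUE) /
       sum(1 / w[keep2], na.rm = TRUE)
  if (!is.finite(f)) f <- 0
  2^f
}

#' log2 counts-per-million with TMM-adjusted library sizes
#'
#' `log2((count + prior) / (lib * factor + 2 * prior) * 1e6)`. The prior
#' keeps zeros finite; the doubled prior in the denominator keeps the values
#' bounded by the library proportion scale.
#'
#' @param counts count matrix, genes x samples.
#' @param factors per-sample TMM factors from [tmm_factors()]; default all 1.
#' @param prior prior count (default 0.5).
#' @return matrix of log2 CPM values, same dimnames as `counts`.
#' @export
log2_cpm <- function(counts, factors = NULL, prior = 0.5) {
  validate_counts(counts)
  lib <- colSums(counts)
  if (is.null(factors)) factors <- rep(1, ncol(counts))
  eff <- lib * factors
  if (any(eff <= 0)) stop_input("zero effective library size")
  log2(sweep(counts + prior, 2, eff + 2 * prior, "/") * 1e6)
}

#' Identify candidate housekeeping genes
#'
#' Highly expressed, low-variance genes: mean log2 CPM strictly above
#' `mean_cutoff` and variance strictly below the `var_quantile` quantile of
#' all gene variances.
#'
#' @param logcpm log2 CPM matrix, genes x samples (at least 4 genes).
#' @param mean_cutoff mean log2 CPM threshold (default 10).
#' @param var_quantile variance quantile threshold (default 0.25).
#' @return character vector of gene ids (possibly empty, with a warning).
#' @export
identify_housekeeping <- function(logcpm, mean_cutoff = 10,
                                  var_quantile = 0.25) {
  if (nrow(logcpm) < 4) stop_input("need at least 4 genes")
  mu <- rowMeans(logcpm)
  v <- apply(logcpm, 1, var)
  sel <- mu > mean_cutoff & v < quantile(v, var_quantile, names = FALSE)
  if (!any(sel)) warning("no genes pass the housekeeping criteria")
  rownames(logcpm)[sel]
}

#' Scale log2 CPM by per-sample housekeeping expression
#'
#' Divides each sample's log2 CPM column by that sample's mean log2 CPM over
#' the housekeeping genes, making the values platform-portable ratios.
#'
#' @param logcpm log2 CPM matrix, genes x samples.
#' @param hk_genes housekeeping gene ids, all present in `logcpm`
#'   (default [DEFAULT_HK_GENES]).
#' @return list of class `immunophen_normmat`: `values` (scaled matrix),
#'   `hk_genes`, `hk_means` (per-sample divisor), `provenance`.
#' @export
housekeeping_normalize <- function(logcpm, hk_genes = DEFAULT_HK_GENES) {
  missing <- setdiff(hk_genes, rownames(logcpm))
  if (length(missing)) {
    stop_input("housekeeping gene(s) missing: %s",
               paste(missing, collapse = ", "))
  }
  hk_mean <- colMeans(logcpm[hk_genes, , drop = FALSE])
  if (any(hk_mean <= 0)) {
    stop_input("non-positive housekeeping mean in sample(s): %s",
               paste(colnames(logcpm)[hk_mean <= 0], collapse = ", "))
  }
  structure(list(
    values = sweep(logcpm, 2, hk_mean, "/"),
    hk_genes = hk_genes,
    hk_means = hk_mean,
    provenance = list(transform = "log2cpm / per-sample mean hk log2cpm")
  ), class = "immunophen_normmat")
}

#' Full expression preparation pipeline
#'
#' Filter low-expression genes, compute TMM factors, log2 CPM, and
#' housekeeping-scale. Records every parameter in the provenance so a
#' classification run can verify it was prepared identically.
#'
#' @param counts raw count matrix, genes x samples.
#' @param cpm_cutoff,frac_cutoff,keep_genes see [filter_low_expression()].
#' @param prior see [log2_cpm()].
#' @param hk_genes see [housekeeping_normalize()].
#' @return an `immunophen_normmat` with fields `values`, `logcpm`,
#'   `tmm_factors`, `hk_genes`, `hk_means`, `pca` (per-sample scores and
#'   variance explained, as an outlier diagnostic; no automatic exclusion),
#'   and `provenance`.
#' @export
prepare_expression <- function(counts, cpm_cutoff = 0.25, frac_cutoff = 0.10,
                               prior = 0.5, hk_genes = DEFAULT_HK_GENES,
                               keep_genes = character(0)) {
  filtered <- filter_low_expression(counts, cpm_cutoff, frac_cutoff,
                                    keep_genes)
  factors <- tmm_factors(filtered)
  logcpm <- log2_cpm(filtered, factors, prior)
  norm <- housekeeping_normalize(logcpm, hk_genes)
  norm$logcpm <- logcpm
  norm$tmm_factors <- factors
  # PCA diagnostic on centred logcpm (samples as observations)
  pc <- stats::prcomp(t(logcpm), center = TRUE, scale. = FALSE, rank. = 2)
  norm$pca <- list(
    scores = pc$x,
    var_explained = (pc$sdev^2 / sum(pc$sdev^2))[1:2]
  )
  norm$provenance <- list(
    cpm_cutoff = cpm_cutoff, frac_cutoff = frac_cutoff, prior = prior,
    hk_genes = hk_genes,
    transforms = c("filter_low_expression", "tmm", "log2_cpm",
                   "housekeeping_normalize")
  )
  norm
}

#' @export
print.immunophen_normmat <- function(x, ...) {
  cat(sprintf("Normalized expression: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat("Housekeeping genes:", paste(x$hk_genes, collapse = ", "), "\n")
  invisible(x)
}
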
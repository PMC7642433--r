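# Signature-gene discovery: one random-forest regression per gene
# (gene ~ R + theta) with OOB permutation importance, then quantile-based
# partition into quantity- and distribution-associated gene sets.

#' Gene-selection thresholds and forest settings
#'
#' @param drop_quantile genes whose average importance falls in this bottom
#'   fraction are dropped before selection (default 0.25).
#' @param select_quantile quantile of per-metric importance above which a
#'   gene is called associated (default 0.75, i.e. the third quartile).
#' @param n_trees trees per gene forest (default 500).
#' @param min_node minimum node size for splitting (default 5).
#' @param min_samples minimum cohort size for fitting (default 20).
#' @param drop_rule `"avg_importance"` (default; drop genes whose mean
#'   permutation importance is in the bottom quartile, i.e. genes not
#'   associated with the metrics) or `"oob_mse"` (literal low-OOB-MSE
#'   variant).
#' @param seed RNG seed.
#' @return list of class `immunophen_selthresholds`.
#' @export
selection_thresholds <- function(drop_quantile = 0.25, select_quantile = 0.75,
                                 n_trees = 500L, min_node = 5L,
                                 min_samples = 20L,
                                 drop_rule = c("avg_importance", "oob_mse"),
                                 seed = 1L) {
  if (!(drop_quantile > 0 && drop_quantile < select_quantile &&
        select_quantile < 1)) {
    stop_input("need 0 < drop_quantile < select_quantile < 1")
  }
  structure(list(
    drop_quantile = drop_quantile, select_quantile = select_quantile,
    n_trees = as.integer(n_trees), min_node = as.integer(min_node),
    min_samples = as.integer(min_samples),
    drop_rule = match.arg(drop_rule), seed = as.integer(seed)
  ), class = "immunophen_selthresholds")
}

#' Fit a random-forest regression per gene and measure metric importance
#'
#' For each gene, a regression forest predicts its normalized expression
#' from the two polar metrics, with bootstrap resampling of patients and
#' both predictors candidate at every split. Importance of a metric is the
#' permutation increase in out-of-bag MSE, as a percentage of the forest's
#' OOB MSE. Degenerate-theta samples (flagged zero densities) enter with
#' their conventional theta of 0.
#'
#' @param values normalized expression matrix, genes x samples.
#' @param polar data frame with `sample_id`, `R`, `theta` covering every
#'   sample of `values`.
#' @param thresholds a [selection_thresholds()].
#' @return data frame (`immunophen_importance`): `gene_id`, `oob_mse`,
#'   `inc_mse_R`, `inc_mse_theta`, `avg_importance`, `note`.
#' @export
fit_gene_models <- function(values, polar, thresholds = selection_thresholds()) {
  stopifnot(inherits(thresholds, "immunophen_selthresholds"))
  if (!all(colnames(values) %in% polar$sample_id)) {
    stop_input("polar table does not cover all expression samples")
  }
  polar <- polar[match(colnames(values), polar$sample_id), ]
  n <- ncol(values)
  if (n < thresholds$min_samples) {
    stop_input("need at least %d samples, got %d", thresholds$min_samples, n)
  }
  set.seed(thresholds$seed)
  res <- rf_importance_cpp(values, polar$R, polar$theta,
                           thresholds$n_trees, thresholds$min_node)
  out <- data.frame(
    gene_id = rownames(values),
    oob_mse = res$oob_mse,
    inc_mse_R = res$inc_mse_1,
    inc_mse_theta = res$inc_mse_2,
    note = ifelse(res$constant, "constant response", "")
  )
  out$avg_importance <- (out$inc_mse_R + out$inc_mse_theta) / 2
  class(out) <- c("immunophen_importance", class(out))
  out
}

#' Partition genes into quantity/distribution-associated sets
#'
#' Drops the bottom `drop_quantile` of genes by average importance, then
#' calls genes above the `select_quantile` quantile (computed on retained
#' genes, strict `>`) of `inc_mse_R` quantity-associated, of
#' `inc_mse_theta` distribution-associated, of both "both". The signature
#' set is the union of the two exclusive sets (quantity-only and
#' distribution-only), mirroring the published 103 + 56 construction.
#' Quantiles use the inclusive linear-interpolation convention (R type 7).
#'
#' @param importance table from [fit_gene_models()].
#' @param thresholds a [selection_thresholds()].
#' @return list of class `immunophen_selection`: the annotated `table`
#'   (with `category`), per-category gene-id `sets`, `signature`,
#'   `cutoffs`, and `sizes`.
#' @export
select_genes <- function(importance, thresholds = selection_thresholds()) {
  tab <- importance
  drop_stat <- if (thresholds$drop_rule == "avg_importance") {
    tab$avg_importance
  } else {
    tab$oob_mse
  }
  drop_cut <- quantile(drop_stat, thresholds$drop_quantile, names = FALSE)
  dropped <- drop_stat < drop_cut
  retained <- tab[!dropped, , drop = FALSE]
  if (nrow(retained) < 4) stop_input("fewer than 4 genes retained")

  q3_R <- quantile(retained$inc_mse_R, thresholds$select_quantile,
                   names = FALSE)
  q3_theta <- quantile(retained$inc_mse_theta, thresholds$select_quantile,
                       names = FALSE)
  hi_R <- retained$inc_mse_R > q3_R
  hi_T <- retained$inc_mse_theta > q3_theta

  category <- rep("none", nrow(tab))
  category[dropped] <- "dropped"
  cat_ret <- ifelse(hi_R & hi_T, "both",
                    ifelse(hi_R, "quantity_only",
                           ifelse(hi_T, "distribution_only", "none")))
  category[!dropped] <- cat_ret
  tab$category <- category

  sets <- split(tab$gene_id, factor(tab$category, levels = c(
    "quantity_only", "distribution_only", "both", "none", "dropped")))
  signature <- c(sets$quantity_only, sets$distribution_only)
  if (length(signature) == 0) {
    stop_input(paste0(
      "empty signature: no gene exceeds the selection quantiles ",
      "(Q3(R)=%.4g, Q3(theta)=%.4g); importances may be degenerate/tied"),
      q3_R, q3_theta)
  }
  structure(list(
    table = tab,
    sets = sets,
    signature = signature,
    cutoffs = list(drop = drop_cut, q3_R = q3_R, q3_theta = q3_theta),
    sizes = vapply(sets, length, integer(1))
  ), class = "immunophen_selection")
}

#' @export
print.immunophen_selection <- function(x, ...) {
  cat("Gene selection:",
      sprintf("%s=%d", names(x$sizes), x$sizes), "\n")
  cat("Signature size:", length(x$signature), "\n")
  invisible(x)
}
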
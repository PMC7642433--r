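# Pipeline orchestration: prep -> polar -> gene selection -> consensus ->
# phenotype merge -> NSC training, plus deployment-time classification.
# Training labels are the consensus-derived phenotypes (ground truth, when
# available, is used for evaluation only). A master seed fans out to
# per-stage seeds via stage_seed().

#' Pipeline configuration
#'
#' @param master_seed master seed fanned out to every stage.
#' @param cpm_cutoff,frac_cutoff,prior,hk_genes expression prep (see
#'   [prepare_expression()]).
#' @param gene_selection `"rf"` (random-forest importance selection) or
#'   `"none"` (signature = all prepared non-housekeeping genes; useful for
#'   tiny cohorts below the forest's minimum cohort size).
#' @param n_trees,drop_quantile,select_quantile forest selection settings.
#' @param k,n_reps,sample_frac,n_restarts consensus clustering settings.
#' @param R_quantile cluster-merge desert threshold (cohort R quantile).
#' @param cv_folds NSC cross-validation folds.
#' @param hi,lo confidence-gate thresholds.
#' @return list of class `immunophen_config`.
#' @export
pipeline_config <- function(master_seed = 1L, cpm_cutoff = 0.25,
                            frac_cutoff = 0.10, prior = 0.5,
                            hk_genes = DEFAULT_HK_GENES,
                            gene_selection = c("rf", "none"),
                            n_trees = 500L, drop_quantile = 0.25,
                            select_quantile = 0.75,
                            k = 6L, n_reps = 1000L, sample_frac = 0.8,
                            n_restarts = 10L, R_quantile = 0.40,
                            cv_folds = 10L, hi = 0.7, lo = 0.5) {
  structure(list(
    master_seed = as.integer(master_seed), cpm_cutoff = cpm_cutoff,
    frac_cutoff = frac_cutoff, prior = prior, hk_genes = hk_genes,
    gene_selection = match.arg(gene_selection),
    n_trees = as.integer(n_trees), drop_quantile = drop_quantile,
    select_quantile = select_quantile, k = as.integer(k),
    n_reps = as.integer(n_reps), sample_frac = sample_frac,
    n_restarts = as.integer(n_restarts), R_quantile = R_quantile,
    cv_folds = as.integer(cv_folds), hi = hi, lo = lo
  ), class = "immunophen_config")
}

#' Run the full training pipeline
#'
#' @param counts raw count matrix, genes x samples.
#' @param densities data frame with `sample_id`, `cd8_tumour_density`,
#'   `cd8_stroma_density` for (at least) every count sample.
#' @param config a [pipeline_config()].
#' @param truth optional ground-truth list (as from [generate_cohort()]);
#'   used only to compute recovery metrics in the manifest.
#' @param out_dir optional directory; when given, every stage output is
#'   written (TSV/JSON) and md5 digests are recorded in the manifest.
#' @return list of class `immunophen_run`: `prep`, `polar`, `selection`
#'   (or `NULL`), `consensus`, `clusters`, `merge`, `labels`, `model`,
#'   `manifest`.
#' @export
run_training_pipeline <- function(counts, densities, config = pipeline_config(),
                                  truth = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "immunophen_config"))
  if (!all(colnames(counts) %in% densities$sample_id)) {
    stop_input("densities table does not cover all count samples")
  }
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }
  run_stage <- function(stage, expr) {
    message(sprintf("[immunophen] stage=%s", stage))
    res <- tryCatch(expr, error = function(e) {
      stop_input("stage '%s' failed: %s", stage, conditionMessage(e))
    })
    tick(stage)
    res
  }

  prep <- run_stage("exprprep", prepare_expression(
    counts, config$cpm_cutoff, config$frac_cutoff, config$prior,
    config$hk_genes))
  polar <- run_stage("polar", add_polar_metrics(
    densities[match(colnames(counts), densities$sample_id), ]))

  if (config$gene_selection == "rf") {
    thresholds <- selection_thresholds(
      drop_quantile = config$drop_quantile,
      select_quantile = config$select_quantile,
      n_trees = config$n_trees,
      seed = stage_seed(config$master_seed, "geneselect"))
    importance <- run_stage("geneselect",
                            fit_gene_models(prep$values, polar, thresholds))
    selection <- select_genes(importance, thresholds)
    signature <- selection$signature
  } else {
    selection <- NULL
    signature <- setdiff(rownames(prep$values), config$hk_genes)
    tick("geneselect")
  }

  cons <- run_stage("consensus", consensus_matrix(
    prep$values[signature, , drop = FALSE], k = config$k,
    n_reps = config$n_reps, sample_frac = config$sample_frac,
    n_restarts = config$n_restarts,
    seed = stage_seed(config$master_seed, "consensus")))
  clusters <- consensus_clusters(cons, k = config$k)
  merge <- merge_to_phenotypes(clusters, polar,
                               R_quantile = config$R_quantile)
  labels <- merge$phenotype

  model <- run_stage("nsc", train_nsc(
    prep$values[signature, , drop = FALSE], labels,
    cv_folds = config$cv_folds,
    seed = stage_seed(config$master_seed, "nsc")))
  model$provenance <- c(prep$provenance,
                        list(signature_size = length(signature)))

  self_pred <- predict_nsc(model, prep$values[signature, , drop = FALSE])
  self_calls <- confidence_gate(self_pred$posterior, config$hi, config$lo)

  manifest <- list(
    config = unclass(config),
    seeds = list(master = config$master_seed,
                 geneselect = stage_seed(config$master_seed, "geneselect"),
                 consensus = stage_seed(config$master_seed, "consensus"),
                 nsc = stage_seed(config$master_seed, "nsc")),
    n_samples = ncol(counts), n_genes_input = nrow(counts),
    n_genes_prepared = nrow(prep$values),
    signature_size = length(signature),
    chosen_delta = model$chosen_delta,
    cv_error = min(model$cv_error_curve$error),
    confident_fraction_train = mean(self_calls != "unclassified"),
    timings = as.list(timings)
  )
  if (!is.null(truth)) {
    tr <- truth$sample_phenotype[names(labels)]
    confident <- self_calls != "unclassified"
    manifest$recovery <- list(
      ari_vs_truth = adjusted_rand_index(labels, tr),
      phenotype_agreement = mean(labels == tr),
      confident_call_accuracy = if (any(confident))
        mean(self_calls[confident] == tr[confident]) else NA_real_
    )
    if (!is.null(selection) && !is.null(truth$gene_module)) {
      manifest$recovery$gene_selection <-
        gene_recovery_metrics(selection, truth$gene_module)
    }
  }

  run <- structure(list(
    prep = prep, polar = polar, selection = selection, consensus = cons,
    clusters = clusters, merge = merge, labels = labels, model = model,
    self_calls = self_calls, manifest = manifest
  ), class = "immunophen_run")

  if (!is.null(out_dir)) run$manifest$files <- write_run(run, out_dir)
  run
}

# sensitivity of planted signal recovery and noise false-positive rate
gene_recovery_metrics <- function(selection, gene_module) {
  tab <- selection$table
  module <- gene_module[tab$gene_id]
  quantity_cats <- c("quantity_only", "both")
  distribution_cats <- c("distribution_only", "both")
  selected_cats <- c("quantity_only", "distribution_only", "both")
  list(
    quantity_sensitivity =
      mean(tab$category[module == "cytotoxic"] %in% quantity_cats),
    distribution_sensitivity =
      mean(tab$category[module %in% c("tgfb_stroma", "antigen_presentation")]
           %in% distribution_cats),
    noise_fpr = mean(tab$category[module == "noise"] %in% selected_cats)
  )
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    normalized = file.path(out_dir, "normalized.tsv"),
    polar = file.path(out_dir, "polar.tsv"),
    labels = file.path(out_dir, "labels.tsv"),
    consensus = file.path(out_dir, "consensus.tsv"),
    model = file.path(out_dir, "model.json")
  )
  write_matrix_tsv(run$prep$values, paths[["normalized"]])
  write_tsv(run$polar, paths[["polar"]])
  write_tsv(data.frame(sample_id = names(run$labels),
                       cluster = as.integer(run$clusters),
                       phenotype = run$labels), paths[["labels"]])
  write_matrix_tsv(run$consensus$consensus, paths[["consensus"]])
  nsc_to_json(run$model, paths[["model"]])
  if (!is.null(run$selection)) {
    paths[["importance"]] <- file.path(out_dir, "importance.tsv")
    write_tsv(run$selection$table, paths[["importance"]])
    paths[["signature"]] <- file.path(out_dir, "signature.txt")
    writeLines(run$selection$signature, paths[["signature"]])
  }
  manifest_path <- file.path(out_dir, "manifest.json")
  digests <- as.list(tools::md5sum(paths))
  names(digests) <- basename(names(digests))
  run$manifest$digests <- digests
  jsonlite::write_json(run$manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  c(paths, manifest = manifest_path)
}

#' Classify new samples with a trained model
#'
#' Applies the model's stored expression preparation (verifying the
#' recorded housekeeping genes and parameters against `config`), predicts
#' posteriors for the model genes, and applies the confidence gate.
#'
#' @param model an `immunophen_nsc` with prep provenance (as produced by
#'   [run_training_pipeline()]).
#' @param counts raw count matrix for the new samples.
#' @param config a [pipeline_config()]; prep settings must match the
#'   model's provenance.
#' @return list: `calls` (data frame `sample_id`, per-class posteriors,
#'   `label`), `summary` (counts and fractions per label).
#' @export
run_classification <- function(model, counts, config = pipeline_config()) {
  prov <- model$provenance
  if (!is.null(prov)) {
    same <- isTRUE(all.equal(prov$cpm_cutoff, config$cpm_cutoff)) &&
      isTRUE(all.equal(prov$frac_cutoff, config$frac_cutoff)) &&
      isTRUE(all.equal(prov$prior, config$prior)) &&
      identical(as.character(prov$hk_genes), as.character(config$hk_genes))
    if (!same) {
      stop_input("prep configuration differs from the model's provenance")
    }
  }
  label_levels <- c(model$classes, "unclassified")
  if (ncol(counts) == 0) {
    empty <- as.data.frame(matrix(numeric(0), 0, length(model$classes),
                                  dimnames = list(NULL, paste0("p_", model$classes))))
    return(list(
      calls = cbind(data.frame(sample_id = character(0)), empty,
                    data.frame(label = character(0))),
      summary = data.frame(label = label_levels,
                           n = 0L, fraction = NA_real_)))
  }
  missing_raw <- setdiff(model$gene_ids, rownames(counts))
  if (length(missing_raw)) {
    stop_input("model gene(s) absent from input counts: %s",
               paste(head(missing_raw, 5), collapse = ", "))
  }
  prep <- prepare_expression(counts, config$cpm_cutoff, config$frac_cutoff,
                             config$prior, config$hk_genes,
                             keep_genes = model$gene_ids)
  pred <- predict_nsc(model, prep$values[model$gene_ids, , drop = FALSE])
  labels <- confidence_gate(pred$posterior, config$hi, config$lo)
  calls <- data.frame(sample_id = colnames(counts), check.names = FALSE)
  for (k in model$classes) calls[[paste0("p_", k)]] <- pred$posterior[, k]
  calls$label <- labels
  tab <- table(factor(labels, label_levels))
  list(calls = calls,
       summary = data.frame(label = label_levels, n = as.integer(tab),
                            fraction = as.numeric(tab) / length(labels)))
}

#' @export
print.immunophen_run <- function(x, ...) {
  cat(sprintf("immunophen run: %d samples, signature %d genes\n",
              x$manifest$n_samples, x$manifest$signature_size))
  cat("phenotypes:", paste(sprintf("%s=%d", names(table(x$labels)),
                                   table(x$labels)), collapse = " "), "\n")
  invisible(x)
}
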
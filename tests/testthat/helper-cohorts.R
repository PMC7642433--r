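# Shared fixtures, built in code and cached for the duration of the run.
# Small cohorts keep unit tests fast; the acceptance suite uses the default
# (2,000 genes x 150 samples) configuration through acc_artifacts().

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# compact cohort for unit tests: same structure, smaller everything
small_sim_config <- function(seed = 1L, n_samples = 60L, effect_size = 2) {
  sim_config(
    n_samples = n_samples, n_genes = 300L,
    module_sizes = c(cytotoxic = 45L, antigen_presentation = 25L,
                     tgfb_stroma = 25L, desert_program = 15L,
                     housekeeping = 10L, noise = 180L),
    effect_size = effect_size, seed = seed
  )
}

small_cohort <- function(seed = 1L) {
  cached(paste0("small_cohort_", seed), generate_cohort(small_sim_config(seed)))
}

small_prepped <- function(seed = 1L) {
  cached(paste0("small_prepped_", seed), {
    co <- small_cohort(seed)
    list(cohort = co,
         prep = prepare_expression(co$counts),
         polar = add_polar_metrics(co$densities))
  })
}

# small importance table (forest on the small cohort), reused across tests
small_importance <- function(seed = 1L) {
  cached(paste0("small_importance_", seed), {
    sp <- small_prepped(seed)
    th <- selection_thresholds(n_trees = 200L, seed = 42L)
    list(importance = fit_gene_models(sp$prep$values, sp$polar, th),
         thresholds = th, cohort = sp$cohort)
  })
}

# full default-scale artifacts for the acceptance suite, cached per seed
acc_artifacts <- function(seed) {
  cached(paste0("acc_", seed), {
    co <- generate_cohort(sim_config(seed = seed))
    prep <- prepare_expression(co$counts)
    polar <- add_polar_metrics(co$densities)
    th <- selection_thresholds(seed = seed + 1000L)
    imp <- fit_gene_models(prep$values, polar, th)
    sel <- select_genes(imp, th)
    list(cohort = co, prep = prep, polar = polar, selection = sel)
  })
}

# two-cloud control for clustering (genes x samples). The clouds differ by
# gene-wise *patterns* (not a constant shift, which per-sample profile
# standardization would cancel); `sep` scales the pattern amplitude
# relative to a within-cloud noise sd of 0.5.
two_cloud_data <- function(n_per = 30L, n_genes = 40L, sep = 6, seed = 1L) {
  set.seed(seed)
  centre <- matrix(rnorm(2 * n_genes, sd = sep / 6), n_genes, 2)
  x <- cbind(
    centre[, 1] + matrix(rnorm(n_genes * n_per, sd = 0.5), n_genes),
    centre[, 2] + matrix(rnorm(n_genes * n_per, sd = 0.5), n_genes)
  )
  colnames(x) <- sprintf("S%02d", seq_len(2 * n_per))
  rownames(x) <- sprintf("G%02d", seq_len(n_genes))
  list(x = x, truth = rep(1:2, each = n_per))
}
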
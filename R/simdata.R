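# Synthetic cohort generator: negative-binomial bulk RNA-seq counts plus
# compartmental CD8 densities with planted three-phenotype ground truth.
#
# Generative model
#   * Each sample draws a phenotype (infiltrated / excluded / desert) from
#     the prevalence vector, then latent polar metrics (R, theta) from
#     phenotype-specific truncated normals: desert has small R (a fraction
#     of deserts have R exactly 0, the degenerate no-CD8 case); infiltrated
#     and excluded share large R and are separated by theta (below vs above
#     pi/4). Compartment densities are back-computed as (R cos theta,
#     R sin theta), so the polar transform is exactly invertible on truth.
#   * Gene modules: cytotoxic genes track R on the log2 scale; TGF-beta /
#     stromal genes are up and antigen-presentation genes down in excluded
#     tumours only; a metabolic/neuroendocrine desert program is up in
#     desert tumours only; housekeeping genes are highly expressed with very
#     low dispersion; the remainder is noise.
#   * Counts are negative binomial with gene-wise means (per-sample
#     expression fractions times a log-uniform library size) and a global
#     dispersion (housekeeping genes get a much smaller dispersion so they
#     satisfy the usual high-mean / low-variance reference-gene criteria).

PHENOTYPES <- c("infiltrated", "excluded", "desert")

#' Construct a synthetic-cohort configuration
#'
#' Defaults describe the cohort the test-suite and acceptance experiments
#' run on: 150 samples, 2,000 genes, test-set phenotype prevalences
#' (0.30, 0.20, 0.41) renormalized, and a log2 effect size of 2.
#'
#' @param n_samples number of samples.
#' @param n_genes number of genes.
#' @param phenotype_prevalence length-3 vector (infiltrated, excluded,
#'   desert); renormalized to sum to 1.
#' @param module_sizes named counts for `cytotoxic`, `antigen_presentation`,
#'   `tgfb_stroma`, `desert_program`, `housekeeping`, `noise`; must sum to
#'   at most `n_genes` (leftover genes become extra noise genes).
#' @param effect_size log2-fold-change scale applied to every signal module.
#' @param dispersion negative-binomial dispersion of non-housekeeping genes.
#' @param hk_dispersion dispersion of housekeeping genes.
#' @param lib_size_range min/max expected library size (log-uniform draw).
#' @param degenerate_frac fraction of desert samples with exactly zero CD8.
#' @param seed integer RNG seed.
#' @return validated list of class `immunophen_simconfig`.
#' @export
sim_config <- function(n_samples = 150L,
                       n_genes = 2000L,
                       phenotype_prevalence = c(0.30, 0.20, 0.41),
                       module_sizes = c(cytotoxic = 300L,
                                        antigen_presentation = 150L,
                                        tgfb_stroma = 150L,
                                        desert_program = 100L,
                                        housekeeping = 40L,
                                        noise = 1260L),
                       effect_size = 2,
                       dispersion = 0.15,
                       hk_dispersion = 0.005,
                       lib_size_range = c(8e5, 2.5e6),
                       degenerate_frac = 0.1,
                       seed = 1L) {
  if (n_samples < 1 || n_genes < 1) stop_input("counts must be positive")
  if (length(phenotype_prevalence) != 3 || any(phenotype_prevalence <= 0)) {
    stop_input("phenotype_prevalence must be 3 positive fractions")
  }
  phenotype_prevalence <- phenotype_prevalence / sum(phenotype_prevalence)
  needed <- c("cytotoxic", "antigen_presentation", "tgfb_stroma",
              "desert_program", "housekeeping", "noise")
  if (!all(needed %in% names(module_sizes))) {
    stop_input("module_sizes must name: %s", paste(needed, collapse = ", "))
  }
  module_sizes <- module_sizes[needed]
  if (any(module_sizes < 0)) stop_input("module sizes must be non-negative")
  if (sum(module_sizes) > n_genes) {
    stop_input("module sizes (%d) exceed n_genes (%d)",
               sum(module_sizes), n_genes)
  }
  # unassigned genes are noise
  module_sizes[["noise"]] <-
    module_sizes[["noise"]] + (n_genes - sum(module_sizes))
  if (dispersion <= 0 || hk_dispersion <= 0) {
    stop_input("dispersions must be positive")
  }
  if (length(lib_size_range) != 2 || lib_size_range[1] <= 0 ||
      diff(lib_size_range) < 0) {
    stop_input("lib_size_range must be an increasing positive pair")
  }
  structure(list(
    n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
    phenotype_prevalence = stats::setNames(phenotype_prevalence, PHENOTYPES),
    module_sizes = module_sizes, effect_size = effect_size,
    dispersion = dispersion, hk_dispersion = hk_dispersion,
    lib_size_range = lib_size_range, degenerate_frac = degenerate_frac,
    seed = as.integer(seed)
  ), class = "immunophen_simconfig")
}

# Latent polar metric distributions per phenotype (densities in cells/mm^2).
# R of an infiltrated/excluded tumour sits around 220 cells/mm^2; deserts
# around 25. Theta separates infiltrated (< pi/4) from excluded (> pi/4).
draw_latents <- function(phenotype, degenerate_frac) {
  n <- length(phenotype)
  R <- numeric(n)
  theta <- numeric(n)
  inf <- phenotype == "infiltrated"
  exc <- phenotype == "excluded"
  des <- phenotype == "desert"
  R[inf] <- rtruncnorm(sum(inf), 220, 60, lower = 40)
  theta[inf] <- rtruncnorm(sum(inf), 0.40, 0.15, lower = 0, upper = pi / 4)
  R[exc] <- rtruncnorm(sum(exc), 220, 60, lower = 40)
  theta[exc] <- rtruncnorm(sum(exc), 1.15, 0.12, lower = pi / 4, upper = pi / 2)
  R[des] <- rtruncnorm(sum(des), 25, 15, lower = 1, upper = 80)
  theta[des] <- rtruncnorm(sum(des), pi / 4, 0.30, lower = 0, upper = pi / 2)
  zero <- des & runif(n) < degenerate_frac
  R[zero] <- 0
  theta[zero] <- 0
  list(R = R, theta = theta)
}

#' Generate a synthetic cohort
#'
#' @param config a [sim_config()].
#' @return list with elements:
#'   * `counts`: integer matrix, genes x samples;
#'   * `densities`: data frame `sample_id, cd8_tumour_density,
#'     cd8_stroma_density` (cells/mm^2);
#'   * `truth`: list with `sample_phenotype`, `true_R`, `true_theta`
#'     (named by sample) and `gene_module` (named by gene).
#' Same config (including seed) reproduces bit-identical output.
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "immunophen_simconfig"))
  set.seed(config$seed)
  n <- config$n_samples
  sample_ids <- sprintf("S%03d", seq_len(n))

  phenotype <- sample(PHENOTYPES, n, replace = TRUE,
                      prob = config$phenotype_prevalence)
  lat <- draw_latents(phenotype, config$degenerate_frac)
  densities <- data.frame(
    sample_id = sample_ids,
    cd8_tumour_density = lat$R * cos(lat$theta),
    cd8_stroma_density = lat$R * sin(lat$theta)
  )

  ms <- config$module_sizes
  gene_module <- rep(names(ms), times = ms)
  gene_ids <- module_gene_ids(ms)
  hk <- gene_module == "housekeeping"

  # baseline log2 relative abundance; housekeeping weight fixed so the
  # housekeeping module takes ~15% of the library (CPM ~ 3,750 per gene)
  base <- rnorm(config$n_genes, mean = 3, sd = 2)
  slope <- runif(config$n_genes, 0.7, 1.3)
  hk_weight_each <- if (any(hk)) {
    0.15 / 0.85 * sum(2^base[!hk]) / sum(hk)
  } else numeric(0)

  rscale <- lat$R / 220  # typical infiltrated magnitude
  eff <- config$effect_size
  shift <- matrix(0, config$n_genes, n)
  shift[gene_module == "cytotoxic", ] <-
    outer(eff * slope[gene_module == "cytotoxic"], rscale)
  shift[gene_module == "tgfb_stroma", ] <-
    outer(eff * slope[gene_module == "tgfb_stroma"],
          as.numeric(phenotype == "excluded"))
  shift[gene_module == "antigen_presentation", ] <-
    outer(-eff * slope[gene_module == "antigen_presentation"],
          as.numeric(phenotype == "excluded"))
  shift[gene_module == "desert_program", ] <-
    outer(eff * slope[gene_module == "desert_program"],
          as.numeric(phenotype == "desert"))

  w <- 2^(base + shift)
  w[hk, ] <- hk_weight_each
  frac <- sweep(w, 2, colSums(w), "/")

  lr <- log(config$lib_size_range)
  lib <- exp(runif(n, lr[1], lr[2]))
  mu <- sweep(frac, 2, lib, "*")

  size <- ifelse(hk, 1 / config$hk_dispersion, 1 / config$dispersion)
  counts <- matrix(
    rnbinom(length(mu), mu = as.vector(mu), size = rep(size, times = n)),
    nrow = config$n_genes,
    dimnames = list(gene_ids, sample_ids)
  )
  storage.mode(counts) <- "integer"

  list(
    counts = counts,
    densities = densities,
    truth = list(
      sample_phenotype = stats::setNames(phenotype, sample_ids),
      true_R = stats::setNames(lat$R, sample_ids),
      true_theta = stats::setNames(lat$theta, sample_ids),
      gene_module = stats::setNames(gene_module, gene_ids)
    )
  )
}

module_gene_ids <- function(ms) {
  prefix <- c(cytotoxic = "CYT", antigen_presentation = "AP",
              tgfb_stroma = "TGFB", desert_program = "DES",
              housekeeping = "HK", noise = "NOISE")
  ids <- unlist(lapply(names(ms), function(m) {
    if (ms[[m]] == 0) return(character(0))
    sprintf("%s_%04d", prefix[[m]], seq_len(ms[[m]]))
  }), use.names = FALSE)
  # the first four housekeeping genes carry the canonical reference names so
  # the default normalization gene list applies to synthetic cohorts
  if (ms[["housekeeping"]] >= 4) {
    ids[ids %in% sprintf("HK_%04d", 1:4)] <- DEFAULT_HK_GENES
  }
  ids
}

#' Small deterministic worked cohort (12 samples x 60 genes)
#'
#' Built from closed-form integer patterns rather than random draws, so each
#' count, CPM and density can be checked by hand. Sample S01's library sums
#' to exactly 1e6 and gene `NOISE_22` has count 1 there (CPM exactly 1).
#'
#' @return same structure as [generate_cohort()].
#' @export
worked_fixture <- function() {
  phen <- rep(c("infiltrated", "excluded", "desert"), times = c(4, 3, 5))
  sample_ids <- sprintf("S%02d", 1:12)
  dens <- data.frame(
    sample_id = sample_ids,
    cd8_tumour_density = c(180, 220, 160, 250,  40, 55, 30,  8, 5, 3, 10, 0),
    cd8_stroma_density = c( 70,  90,  50, 110, 200, 240, 170, 6, 4, 2,  7, 0)
  )
  gene_module <- rep(c("cytotoxic", "antigen_presentation", "tgfb_stroma",
                       "desert_program", "housekeeping", "noise"),
                     times = c(10, 8, 8, 8, 4, 22))
  gene_ids <- c(sprintf("CYT_%02d", 1:10), sprintf("AP_%02d", 1:8),
                sprintf("TGFB_%02d", 1:8), sprintf("DES_%02d", 1:8),
                DEFAULT_HK_GENES, sprintf("NOISE_%02d", 1:22))

  g <- length(gene_ids)
  base <- matrix(0, g, 12, dimnames = list(gene_ids, sample_ids))
  bg <- 200 + 40 * (seq_len(g) %% 7)          # per-gene baseline counts
  for (j in 1:12) base[, j] <- bg
  hot <- phen != "desert"
  base[gene_module == "cytotoxic", hot] <-
    base[gene_module == "cytotoxic", hot] * 8
  base[gene_module == "tgfb_stroma", phen == "excluded"] <-
    base[gene_module == "tgfb_stroma", phen == "excluded"] * 6
  base[gene_module == "antigen_presentation", phen == "excluded"] <-
    round(base[gene_module == "antigen_presentation", phen == "excluded"] / 6)
  base[gene_module == "desert_program", phen == "desert"] <-
    base[gene_module == "desert_program", phen == "desert"] * 6
  base[gene_module == "housekeeping", ] <- 30000
  # deterministic within-class jitter so no gene is constant within a class
  jit <- outer(seq_len(g), 1:12, function(i, j) 1 + 0.06 * (((i * 7 + j * 3) %% 5) - 2))
  counts <- round(base * jit)
  counts["NOISE_22", 1] <- 1
  filler <- 1e6 - sum(counts[rownames(counts) != "NOISE_21", 1])
  if (filler < 1) stop("fixture filler underflow")  # nocov
  counts["NOISE_21", 1] <- filler
  storage.mode(counts) <- "integer"

  pol <- to_polar(dens$cd8_tumour_density, dens$cd8_stroma_density)
  list(
    counts = counts,
    densities = dens,
    truth = list(
      sample_phenotype = stats::setNames(phen, sample_ids),
      true_R = stats::setNames(pol$R, sample_ids),
      true_theta = stats::setNames(pol$theta, sample_ids),
      gene_module = stats::setNames(gene_module, gene_ids)
    )
  )
}

#' Write a cohort to disk (counts TSV, densities TSV, truth JSON)
#' @param cohort list as returned by [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return named vector of file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             densities = file.path(dir, "densities.tsv"),
             truth = file.path(dir, "truth.json"))
  write_matrix_tsv(cohort$counts, paths[["counts"]])
  write_tsv(cohort$densities, paths[["densities"]])
  tr <- cohort$truth
  payload <- list(
    samples = data.frame(sample_id = names(tr$sample_phenotype),
                         phenotype = unname(tr$sample_phenotype),
                         true_R = unname(tr$true_R[names(tr$sample_phenotype)]),
                         true_theta = unname(tr$true_theta[names(tr$sample_phenotype)])),
    genes = data.frame(gene_id = names(tr$gene_module),
                       module = unname(tr$gene_module))
  )
  jsonlite::write_json(payload, paths[["truth"]], auto_unbox = FALSE,
                       digits = NA, dataframe = "columns")
  invisible(paths)
}

#' Read a cohort written by [write_cohort()]
#' @param dir directory containing `counts.tsv`, `densities.tsv`,
#'   `truth.json`.
#' @return list with `counts`, `densities`, `truth`.
#' @export
read_cohort <- function(dir) {
  counts <- read_matrix_tsv(file.path(dir, "counts.tsv"))
  storage.mode(counts) <- "integer"
  payload <- jsonlite::read_json(file.path(dir, "truth.json"),
                                 simplifyVector = TRUE)
  truth <- list(
    sample_phenotype = stats::setNames(payload$samples$phenotype,
                                       payload$samples$sample_id),
    true_R = stats::setNames(payload$samples$true_R,
                             payload$samples$sample_id),
    true_theta = stats::setNames(payload$samples$true_theta,
                                 payload$samples$sample_id),
    gene_module = stats::setNames(payload$genes$module,
                                  payload$genes$gene_id)
  )
  list(counts = counts,
       densities = read_tsv(file.path(dir, "densities.tsv")),
       truth = truth)
}
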
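# helper: polar table with independent metrics for null calibration
null_polar <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(sample_id = sprintf("S%03d", seq_len(n)),
             R = runif(n, 0, 300), theta = runif(n, 0, pi / 2))
}

null_matrix <- function(n_genes, n, seed = 2) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n), n_genes, n,
              dimnames = list(sprintf("G%04d", seq_len(n_genes)),
                              sprintf("S%03d", seq_len(n))))
  m
}

test_that("selection_thresholds validates ordering", {
  expect_error(selection_thresholds(drop_quantile = 0.8), "drop_quantile")
  expect_s3_class(selection_thresholds(), "immunophen_selthresholds")
})

test_that("a gene driven by R gets high R importance; theta stays null", {
  pol <- null_polar(80, seed = 3)
  vals <- null_matrix(40, 80, seed = 4)
  set.seed(5)
  vals[1, ] <- 2 * pol$R + rnorm(80, sd = 5)   # planted quantity gene
  th <- selection_thresholds(n_trees = 300L, seed = 6)
  imp <- fit_gene_models(vals, pol, th)
  expect_gt(imp$inc_mse_R[1], 10 * max(1, imp$inc_mse_theta[1]))
  expect_gt(imp$inc_mse_R[1],
            quantile(imp$inc_mse_R, 0.75, names = FALSE))
  sel <- select_genes(imp, th)
  expect_true(sel$table$category[1] %in% c("quantity_only", "both"))
})

test_that("a gene driven by theta resolves to a distribution category", {
  pol <- null_polar(80, seed = 13)
  vals <- null_matrix(30, 80, seed = 14)
  set.seed(15)
  vals[5, ] <- 3 * pol$theta + rnorm(80, sd = 0.3)
  th <- selection_thresholds(n_trees = 300L, seed = 16)
  sel <- select_genes(fit_gene_models(vals, pol, th), th)
  expect_identical(sel$table$category[5], "distribution_only")
})

test_that("null importances are centred at zero", {
  pol <- null_polar(60, seed = 21)
  vals <- null_matrix(300, 60, seed = 22)
  th <- selection_thresholds(n_trees = 150L, seed = 23)
  imp <- fit_gene_models(vals, pol, th)
  for (col in c("inc_mse_R", "inc_mse_theta")) {
    se <- sd(imp[[col]]) / sqrt(nrow(imp))
    expect_lt(abs(mean(imp[[col]])), 2 * se)
  }
})

test_that("the importance table is seed-deterministic", {
  pol <- null_polar(40, seed = 31)
  vals <- null_matrix(25, 40, seed = 32)
  th <- selection_thresholds(n_trees = 100L, seed = 33)
  expect_identical(fit_gene_models(vals, pol, th),
                   fit_gene_models(vals, pol, th))
})

test_that("categories are invariant to positive scaling of R", {
  pol <- null_polar(60, seed = 41)
  vals <- null_matrix(40, 60, seed = 42)
  set.seed(43)
  vals[2, ] <- pol$R / 50 + rnorm(60, sd = 0.5)
  th <- selection_thresholds(n_trees = 150L, seed = 44)
  sel1 <- select_genes(fit_gene_models(vals, pol, th), th)
  pol2 <- pol
  pol2$R <- pol2$R * 1000
  sel2 <- select_genes(fit_gene_models(vals, pol2, th), th)
  expect_identical(sel1$table$category, sel2$table$category)
})

test_that("contracts: sample minimum, constant genes, degenerate tables", {
  pol <- null_polar(10)
  vals <- null_matrix(5, 10)
  expect_error(fit_gene_models(vals, pol), "at least 20 samples")

  pol <- null_polar(30, seed = 51)
  vals <- null_matrix(6, 30, seed = 52)
  vals[3, ] <- 7  # constant response
  th <- selection_thresholds(n_trees = 50L, seed = 53)
  imp <- fit_gene_models(vals, pol, th)
  expect_identical(imp$note[3], "constant response")
  expect_identical(imp$inc_mse_R[3], 0)

  # identical importances: strict ">" leaves nothing above Q3 -> error
  fake <- data.frame(gene_id = sprintf("G%d", 1:20), oob_mse = 1,
                     inc_mse_R = 1, inc_mse_theta = 1, note = "",
                     avg_importance = 1)
  expect_error(select_genes(fake, selection_thresholds()), "empty signature")

  # a gene dominating both importances lands in `both`
  fake2 <- fake
  fake2$inc_mse_R <- c(50, 19:1)           # anti-correlated tails keep the
  fake2$inc_mse_theta <- c(60, 1:19)       # exclusive categories non-empty
  fake2$avg_importance <- (fake2$inc_mse_R + fake2$inc_mse_theta) / 2
  sel <- select_genes(fake2, selection_thresholds())
  expect_identical(sel$table$category[1], "both")
  expect_gt(length(sel$sets$quantity_only), 0)

  # dropping the bottom quartile can leave too few genes
  fake3 <- data.frame(gene_id = sprintf("G%d", 1:4), oob_mse = 1,
                      inc_mse_R = 1:4, inc_mse_theta = 4:1, note = "",
                      avg_importance = c(1, 2, 3, 4))
  expect_error(select_genes(fake3, selection_thresholds()),
               "fewer than 4")
})

test_that("planted modules are recovered on a small cohort", {
  si <- small_importance()
  sel <- select_genes(si$importance, si$thresholds)
  mod <- si$cohort$truth$gene_module[sel$table$gene_id]
  q_cats <- c("quantity_only", "both")
  d_cats <- c("distribution_only", "both")
  expect_gt(mean(sel$table$category[mod == "cytotoxic"] %in% q_cats), 0.7)
  expect_gt(mean(sel$table$category[mod %in%
    c("tgfb_stroma", "antigen_presentation")] %in% d_cats), 0.7)
  # lowering the selection quantile enlarges the selected set (the
  # exclusive-union signature itself need not grow: genes migrate into
  # the shared `both` category as both thresholds drop)
  looser <- selection_thresholds(select_quantile = 0.5)
  sel_l <- select_genes(si$importance, looser)
  n_selected <- function(s) sum(s$sizes[c("quantity_only",
                                          "distribution_only", "both")])
  expect_gt(n_selected(sel_l), n_selected(sel))
})
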
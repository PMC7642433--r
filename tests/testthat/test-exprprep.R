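make_counts <- function(m) {
  rownames(m) <- sprintf("G%02d", seq_len(nrow(m)))
  colnames(m) <- sprintf("S%02d", seq_len(ncol(m)))
  m
}

test_that("low-expression filter removes exactly the rule violators", {
  # 10 samples; library sizes 1e6 so CPM == count
  n_s <- 10
  base <- matrix(1000, 8, n_s)
  base[2, ] <- 0                      # all-zero: removed
  base[3, 1] <- 0.2 * 1               # G03 lowered below in exactly 1 sample
  base[3, 2:n_s] <- 1000
  counts <- make_counts(base)
  # pad a filler gene so each library is exactly 1e6
  filler <- 1e6 - colSums(counts)
  counts <- rbind(counts, FILL = filler)
  cpm <- sweep(counts, 2, colSums(counts), "/") * 1e6
  expect_true(all(abs(colSums(counts) - 1e6) == 0))
  expect_true(cpm["G03", 1] < 0.25 && all(cpm["G03", 2:n_s] >= 0.25))

  filtered <- filter_low_expression(counts)
  expect_false("G02" %in% rownames(filtered))   # zero everywhere
  # fraction exactly 10% removes (ties remove)
  expect_false("G03" %in% rownames(filtered))
  # CPM >= 0.25 everywhere is retained
  expect_true(all(c("G01", "G04", "FILL") %in% rownames(filtered)))
  # idempotence
  expect_identical(filter_low_expression(filtered), filtered)
  # keep_genes exemption
  kept <- filter_low_expression(counts, keep_genes = "G03")
  expect_true("G03" %in% rownames(kept))

  expect_error(filter_low_expression(make_counts(matrix(0, 2, 4))),
               "zero library size")
})

test_that("TMM factors match the edgeR oracle and its invariants", {
  skip_if_not_installed("edgeR")
  set.seed(5)
  for (rep in 1:5) {
    counts <- make_counts(matrix(rnbinom(300 * 8, mu = 200, size = 5), 300, 8))
    f <- tmm_factors(counts)
    oracle <- edgeR::calcNormFactors(counts, method = "TMM")
    expect_equal(unname(f), unname(oracle), tolerance = 1e-5)
    expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
  }
})

test_that("TMM symmetric and depth-only cases give unit factors", {
  counts <- make_counts(matrix(rep(c(10, 50, 200, 1000), 25), 100, 6))
  expect_equal(unname(tmm_factors(counts)), rep(1, 6))

  set.seed(9)
  col <- rnbinom(200, mu = 100, size = 10) + 1
  counts2 <- make_counts(cbind(col, 2 * col, col, 3 * col))
  expect_equal(unname(tmm_factors(counts2)), rep(1, 4), tolerance = 1e-9)
})

test_that("composition bias shifts the TMM factor the expected way", {
  set.seed(13)
  base <- rnbinom(400, mu = 500, size = 20) + 1
  doubled <- base
  doubled[1:200] <- 2 * doubled[1:200]  # half the genes doubled in sample 2
  counts <- make_counts(cbind(base, doubled, base, base))
  f <- tmm_factors(counts)
  expect_gt(f[2] / f[1], 1)
  # permutation invariance of factors
  perm <- c(3, 1, 4, 2)
  f_perm <- tmm_factors(counts[, perm])
  expect_equal(unname(f_perm), unname(f[perm]), tolerance = 1e-12)
})

test_that("log2_cpm matches its closed form and monotonicity", {
  counts <- make_counts(matrix(c(0, rep(999990, 1), 10), 3, 1))
  counts[, 1] <- c(0, 999990, 10)   # library 1e6
  lc <- log2_cpm(counts, factors = 1, prior = 0.5)
  expect_equal(lc["G01", 1], log2(0.5 / (1e6 + 1) * 1e6), tolerance = 1e-12)
  # large-library limit: doubling (count + prior) adds ~1.0
  big <- make_counts(matrix(c(1023.5 * 2 - 0.5, 1e8), 2, 1))
  lc2 <- log2_cpm(big, factors = 1, prior = 0.5)
  half <- make_counts(matrix(c(1023, 1e8), 2, 1))
  expect_equal(lc2["G01", 1] - log2_cpm(half, factors = 1)["G01", 1] - 1, 0,
               tolerance = 1e-4)
  # equal counts and effective libraries give identical columns
  eq <- make_counts(matrix(rep(c(3, 500, 80), 2), 3, 2))
  lce <- log2_cpm(eq, factors = c(1, 1))
  expect_identical(lce[, 1], lce[, 2])
})

test_that("housekeeping identification follows mean and variance rules", {
  set.seed(3)
  m <- matrix(rnorm(40 * 10, mean = 6, sd = 1), 40, 10)
  m[1, ] <- 12                 # constant, high mean -> selected
  m[2, ] <- rnorm(10, 9.9, 0.001)  # mean below 10 -> excluded
  rownames(m) <- sprintf("G%02d", 1:40)
  colnames(m) <- sprintf("S%02d", 1:10)
  hk <- identify_housekeeping(m)
  expect_true("G01" %in% hk)
  expect_false("G02" %in% hk)
  expect_warning(identify_housekeeping(m - 20), "no genes")
  expect_error(identify_housekeeping(m[1:3, ]), "4 genes")
})

test_that("housekeeping normalization is a per-sample ratio", {
  m <- matrix(5, 6, 2)
  rownames(m) <- c(DEFAULT_HK_GENES, "X1", "X2")
  colnames(m) <- c("A", "B")
  m[DEFAULT_HK_GENES, "A"] <- 1    # hk mean exactly 1 -> unchanged
  m[DEFAULT_HK_GENES, "B"] <- 10   # hk mean 10 -> divided by 10
  norm <- housekeeping_normalize(m)
  expect_equal(norm$values["X1", "A"], 5)
  expect_equal(norm$values["X1", "B"], 0.5)
  # scale consistency: adding c to a sample maps (v + c) / (m + c)
  c0 <- 3
  m2 <- m
  m2[, "B"] <- m2[, "B"] + c0
  norm2 <- housekeeping_normalize(m2)
  expect_equal(norm2$values["X1", "B"], (5 + c0) / (10 + c0), tolerance = 1e-12)

  expect_error(housekeeping_normalize(m[-1, ]), "ACTB")
  m3 <- m
  m3[DEFAULT_HK_GENES, "A"] <- -2
  expect_error(housekeeping_normalize(m3), "non-positive")
})

test_that("prepare_expression records provenance and PCA diagnostics", {
  sp <- small_prepped()
  prep <- sp$prep
  expect_s3_class(prep, "immunophen_normmat")
  expect_equal(exp(mean(log(prep$tmm_factors))), 1, tolerance = 1e-12)
  expect_identical(prep$provenance$hk_genes, DEFAULT_HK_GENES)
  expect_equal(nrow(prep$pca$scores), ncol(prep$values))
  expect_true(all(prep$pca$var_explained >= 0 & prep$pca$var_explained <= 1))
})

test_that("planted housekeeping genes pass the selection rule on a cohort", {
  sp <- small_prepped()
  hk <- identify_housekeeping(sp$prep$logcpm)
  truth_mod <- sp$cohort$truth$gene_module
  planted_hk <- names(truth_mod)[truth_mod == "housekeeping"]
  planted_hk <- intersect(planted_hk, rownames(sp$prep$logcpm))
  expect_true(all(planted_hk %in% hk))
  signal <- names(truth_mod)[truth_mod %in%
    c("cytotoxic", "antigen_presentation", "tgfb_stroma", "desert_program")]
  expect_length(intersect(hk, signal), 0)
})
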
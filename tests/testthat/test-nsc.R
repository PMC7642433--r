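# oracle_posteriors() and random_dataset() live in helper-nsc.R

test_that("delta = 0 predictions match the brute-force oracle", {
  worst <- 0
  for (seed in 1:50) {
    d <- random_dataset(seed)
    model <- train_nsc(d$x, d$labels, delta_grid = 0, cv_folds = 3,
                       seed = seed)
    pred <- predict_nsc(model, d$x, delta = 0)
    oracle <- oracle_posteriors(d$x, d$labels, d$x)
    worst <- max(worst, max(abs(pred$posterior - oracle)))
  }
  expect_lt(worst, 1e-9)
})

test_that("total shrinkage reduces prediction to the prior argmax", {
  d <- random_dataset(99)
  model <- train_nsc(d$x, d$labels, cv_folds = 3, seed = 1)
  big <- max(abs(model$d)) + 1
  pred <- predict_nsc(model, d$x, delta = big)
  prior_class <- model$classes[which.max(model$priors)]
  expect_true(all(pred$class == prior_class))
  expect_equal(unname(pred$posterior[1, ]), unname(model$priors),
               tolerance = 1e-12)

  # equal priors fully shrunk: uniform posteriors
  model$priors[] <- 1 / length(model$classes)
  pu <- predict_nsc(model, d$x[, 1], delta = big)
  expect_equal(unname(pu$posterior[1, ]),
               rep(1 / length(model$classes), length(model$classes)),
               tolerance = 1e-12)
})

test_that("hand-computed 2-gene 2-class toy matches to 1e-9", {
  # centroids at +/-1 on both genes, s_i = 1, s0 = 1, m_k = 1, priors 1/2
  model <- structure(list(
    gene_ids = c("g1", "g2"), classes = c("A", "B"),
    xbar = c(g1 = 0, g2 = 0),
    centroids = matrix(c(1, 1, -1, -1), 2,
                       dimnames = list(c("g1", "g2"), c("A", "B"))),
    s = c(g1 = 1, g2 = 1), s0 = 1, n_k = c(4, 4),
    priors = c(A = 0.5, B = 0.5), m_k = c(A = 1, B = 1),
    mk_convention = "se_diff", chosen_delta = 0.25
  ), class = "immunophen_nsc")
  model$d <- matrix(c(0.5, 0.5, -0.5, -0.5), 2,
                    dimnames = dimnames(model$centroids))
  x <- c(g1 = 1, g2 = 0.5)
  pred <- predict_nsc(model, x, delta = 0.25)
  # by hand: d' = +/-0.25, shrunken centroids at +/-0.5 on both genes;
  # delta_A = ((1-0.5)^2 + (0.5-0.5)^2)/4 - 2 log 0.5 = 0.0625 + 2 log 2
  # delta_B = ((1+0.5)^2 + (0.5+0.5)^2)/4 - 2 log 0.5 = 0.8125 + 2 log 2
  pA <- exp(-0.0625 / 2) / (exp(-0.0625 / 2) + exp(-0.8125 / 2))
  expect_equal(unname(pred$posterior[1, "A"]), pA, tolerance = 1e-9)
  expect_equal(sum(pred$posterior), 1, tolerance = 1e-12)
  # a sample at the class-B shrunken centroid is classified B
  pB <- predict_nsc(model, c(g1 = -0.5, g2 = -0.5), delta = 0.25)
  expect_identical(pB$class, "B")
})

test_that("the confidence gate applies strict printed inequalities", {
  post <- rbind(c(0.80, 0.15, 0.05),
                c(0.60, 0.30, 0.10),
                c(0.71, 0.29, 0.00),
                c(0.70, 0.20, 0.10),
                c(0.72, 0.50, -0.22 + 1))  # losing posterior at 0.5 exactly
  post[5, ] <- c(0.72, 0.50, 0.28) / sum(c(0.72, 0.50, 0.28))
  colnames(post) <- c("infiltrated", "excluded", "desert")
  labs <- confidence_gate(post)
  expect_identical(labs[1], "infiltrated")   # clears both gates
  expect_identical(labs[2], "unclassified")  # max <= 0.7
  expect_identical(labs[3], "infiltrated")   # 0.71 > 0.7, others < 0.5
  expect_identical(labs[4], "unclassified")  # 0.70 is not > 0.7
  expect_error(confidence_gate(c(0.5, 0.2)), "sum to 1")
})

test_that("cross-validation: separable data, determinism, curve shape", {
  d <- random_dataset(7)
  sep <- d$x
  sep[, d$labels == "a"] <- sep[, d$labels == "a"] + 25  # far separated
  cv <- cross_validate(sep, d$labels, delta_grid = 0, folds = 3, seed = 2)
  expect_equal(cv$error_curve$error, 0)

  model <- train_nsc(sep, d$labels, cv_folds = 3, seed = 5)
  err <- model$cv_error_curve$error
  expect_equal(err[1], 0)
  expect_equal(err[length(err)],
               1 - max(model$priors), tolerance = 0.1)
  # same seed twice: identical curve
  model2 <- train_nsc(sep, d$labels, cv_folds = 3, seed = 5)
  expect_identical(model$cv_error_curve, model2$cv_error_curve)
})

test_that("permuted labels calibrate CV error to 1 - max prior", {
  set.seed(61)
  g <- 40
  n <- 90
  x <- matrix(rnorm(g * n), g, n,
              dimnames = list(sprintf("G%02d", 1:g), sprintf("S%02d", 1:n)))
  labels <- rep(c("a", "b", "c"), each = 30)
  # each point of the CV curve is an unbiased error estimate; under the
  # null its expectation is chance (1 - max prior). The curve *minimum*
  # (the chosen delta) is selection-biased low by construction, so the
  # calibration check uses curve means and bounds the minimum separately.
  res <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    perm <- sample(labels)
    m <- train_nsc(x, perm, cv_folds = 5, seed = s)
    c(mean(m$cv_error_curve$error), min(m$cv_error_curve$error))
  }, numeric(2))
  target <- 1 - 1 / 3
  se <- sd(res[1, ]) / sqrt(ncol(res))
  expect_lt(abs(mean(res[1, ]) - target), 3 * se)
  expect_lt(mean(res[2, ]), target)          # selection can only bias down
  expect_gt(mean(res[2, ]), target - 0.15)   # but not implausibly far
})

test_that("gene survival is monotone in delta; labels permute consistently", {
  d <- random_dataset(17)
  model <- train_nsc(d$x, d$labels, cv_folds = 3, seed = 3)
  active <- model$cv_error_curve$n_genes_active
  expect_true(all(diff(active) <= 0))

  # permuting class names permutes outputs consistently
  map <- c(a = "z", b = "y", c = "x")
  relab <- unname(map[d$labels])
  m2 <- train_nsc(d$x, relab, delta_grid = model$delta_grid, cv_folds = 3,
                  seed = 3)
  p1 <- predict_nsc(model, d$x, delta = 0)
  p2 <- predict_nsc(m2, d$x, delta = 0)
  for (k in model$classes) {
    expect_equal(unname(p2$posterior[, map[k]]), unname(p1$posterior[, k]),
                 tolerance = 1e-12)
  }
})

test_that("models survive JSON serialization bit-for-bit in prediction", {
  d <- random_dataset(23)
  model <- train_nsc(d$x, d$labels, cv_folds = 3, seed = 9)
  path <- withr::local_tempfile(fileext = ".json")
  nsc_to_json(model, path)
  back <- nsc_from_json(path)
  p1 <- predict_nsc(model, d$x)
  p2 <- predict_nsc(back, d$x)
  expect_identical(p2$posterior, p1$posterior)
  expect_identical(back$chosen_delta, model$chosen_delta)
})

test_that("training contracts: small classes and missing genes error", {
  d <- random_dataset(29)
  bad <- d$labels
  bad[1] <- "rare"
  expect_error(train_nsc(d$x, bad, cv_folds = 3), "< 2 samples")
  model <- train_nsc(d$x, d$labels, cv_folds = 3, seed = 1)
  expect_error(predict_nsc(model, d$x[-1, , drop = FALSE]), "missing model")
  xx <- d$x
  xx[2, 3] <- NA
  expect_error(predict_nsc(model, xx), "non-finite")
})
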
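# Nearest-shrunken-centroid (PAM-style) classifier with cross-validated
# shrinkage selection and a posterior confidence gate.
#
# For gene i and class k with class mean xbar_ik, overall mean xbar_i,
# pooled within-class sd s_i and fudge s0 = median(s_i):
#   d_ik  = (xbar_ik - xbar_i) / (m_k * (s_i + s0)),   m_k = sqrt(1/n_k - 1/n)
#   d'_ik = sign(d_ik) * max(|d_ik| - Delta, 0)        (soft thresholding)
#   xbar'_ik = xbar_i + m_k * (s_i + s0) * d'_ik
# Discriminant for a sample x:
#   delta_k(x) = sum_i (x_i - xbar'_ik)^2 / (s_i + s0)^2 - 2 log pi_k
# Posteriors are proportional to exp(-delta_k / 2). Genes with d'_ik = 0
# for every k contribute a class-constant term and are inert in prediction.

nsc_stats <- function(x, labels, priors = NULL,
                      mk_convention = c("se_diff", "plus")) {
  mk_convention <- match.arg(mk_convention)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop_input("need at least 2 classes")
  n_k <- table(factor(labels, classes))
  if (any(n_k < 2)) {
    stop_input("class with < 2 samples: %s",
               paste(names(n_k)[n_k < 2], collapse = ", "))
  }
  n <- ncol(x)
  xbar <- rowMeans(x)
  centroids <- vapply(classes, function(k) {
    rowMeans(x[, labels == k, drop = FALSE])
  }, numeric(nrow(x)))
  ss <- 0
  for (k in classes) {
    xc <- x[, labels == k, drop = FALSE] - centroids[, k]
    ss <- ss + rowSums(xc^2)
  }
  s <- sqrt(ss / (n - length(classes)))
  s0 <- median(s)
  if (s0 + max(s) == 0) stop_input("all genes constant; cannot standardize")
  m_k <- if (mk_convention == "se_diff") {
    sqrt(pmax(1 / as.numeric(n_k) - 1 / n, 0))
  } else {
    sqrt(1 / as.numeric(n_k) + 1 / n)
  }
  names(m_k) <- classes
  if (is.null(priors)) priors <- as.numeric(n_k) / n
  priors <- priors / sum(priors)
  names(priors) <- classes
  d <- sweep(centroids - xbar, 2, m_k, "/") / (s + s0)
  list(gene_ids = rownames(x), classes = classes, xbar = xbar,
       centroids = centroids, s = s, s0 = s0, n_k = as.numeric(n_k),
       priors = priors, m_k = m_k, d = d,
       mk_convention = mk_convention)
}

soft_threshold <- function(d, delta) sign(d) * pmax(abs(d) - delta, 0)

nsc_discriminant <- function(stats, x, delta) {
  dprime <- soft_threshold(stats$d, delta)
  shrunk <- stats$xbar +
    sweep(dprime, 2, stats$m_k, "*") * (stats$s + stats$s0)
  denom <- (stats$s + stats$s0)^2
  scores <- vapply(seq_along(stats$classes), function(k) {
    colSums((x - shrunk[, k])^2 / denom) - 2 * log(stats$priors[k])
  }, numeric(ncol(x)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  dimnames(scores) <- list(colnames(x), stats$classes)
  scores
}

scores_to_posterior <- function(scores) {
  z <- -scores / 2
  z <- z - apply(z, 1, max)
  p <- exp(z)
  p / rowSums(p)
}

#' Train a nearest-shrunken-centroid classifier
#'
#' Computes centroid statistics, evaluates stratified cross-validation
#' error over a grid of shrinkage values, and fixes the shrinkage at the
#' CV-minimal value (ties broken toward the largest, most parsimonious
#' Delta). The confidence gate is not applied inside CV; it is a
#' deployment-time rule.
#'
#' @param x expression matrix (signature genes x samples).
#' @param labels class label per sample (length `ncol(x)`).
#' @param delta_grid shrinkage grid; default 30 evenly spaced values from 0
#'   to `max(abs(d_ik))`.
#' @param cv_folds stratified folds (default 10; reduced with a warning if
#'   the smallest class is smaller).
#' @param seed RNG seed for fold assignment.
#' @param priors class priors; default observed class frequencies.
#' @param mk_convention `"se_diff"` for m_k = sqrt(1/n_k - 1/n) (the
#'   standard error of the centroid difference; default) or `"plus"` for
#'   the sqrt(1/n_k + 1/n) variant.
#' @return object of class `immunophen_nsc` with the model statistics,
#'   `cv_error_curve` (data frame `delta`, `error`, `n_genes_active`) and
#'   `chosen_delta`.
#' @export
train_nsc <- function(x, labels, delta_grid = NULL, cv_folds = 10L,
                      seed = 1L, priors = NULL,
                      mk_convention = c("se_diff", "plus")) {
  mk_convention <- match.arg(mk_convention)
  stats <- nsc_stats(x, labels, priors, mk_convention)
  if (is.null(delta_grid)) {
    delta_grid <- seq(0, max(abs(stats$d)), length.out = 30)
  }
  cv <- cross_validate(x, labels, delta_grid, cv_folds, seed,
                       priors = priors, mk_convention = mk_convention)
  err <- cv$error_curve$error
  chosen <- delta_grid[max(which(err == min(err)))]
  active <- vapply(delta_grid, function(dl) {
    sum(rowSums(abs(soft_threshold(stats$d, dl)) > 0) > 0)
  }, integer(1))
  model <- c(stats, list(
    delta_grid = delta_grid,
    cv_error_curve = data.frame(delta = delta_grid, error = err,
                                n_genes_active = active),
    cv_folds = cv$folds_used,
    chosen_delta = chosen,
    seed = as.integer(seed)
  ))
  class(model) <- "immunophen_nsc"
  model
}

#' Predict with a nearest-shrunken-centroid model
#'
#' @param model an `immunophen_nsc`.
#' @param x expression matrix (genes x samples) or single named vector;
#'   must contain every model gene.
#' @param delta shrinkage; defaults to the model's `chosen_delta`.
#' @return list: `scores` (discriminant per class), `posterior` (rows sum
#'   to 1), `class` (argmax posterior per sample).
#' @export
predict_nsc <- function(model, x, delta = model$chosen_delta) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1, dimnames = list(names(x), "sample"))
  missing <- setdiff(model$gene_ids, rownames(x))
  if (length(missing)) {
    stop_input("missing model gene(s): %s",
               paste(head(missing, 5), collapse = ", "))
  }
  x <- x[model$gene_ids, , drop = FALSE]
  if (!all(is.finite(x))) stop_input("non-finite expression values")
  scores <- nsc_discriminant(model, x, delta)
  post <- scores_to_posterior(scores)
  list(scores = scores, posterior = post,
       class = model$classes[max.col(post, ties.method = "first")])
}

#' Apply the posterior confidence gate
#'
#' A sample is assigned its top phenotype only when that posterior strictly
#' exceeds `hi` and both other posteriors are strictly below `lo`;
#' otherwise it is `"unclassified"`.
#'
#' @param posterior matrix (samples x classes) or single probability
#'   vector; rows must sum to 1 within `1e-6`.
#' @param hi upper gate on the winning posterior (default 0.7).
#' @param lo upper bound on every losing posterior (default 0.5).
#' @return character vector of labels.
#' @export
confidence_gate <- function(posterior, hi = 0.7, lo = 0.5) {
  if (is.null(dim(posterior))) posterior <- matrix(posterior, nrow = 1,
    dimnames = list(NULL, names(posterior)))
  if (any(abs(rowSums(posterior) - 1) > 1e-6)) {
    stop_input("posterior rows must sum to 1")
  }
  classes <- colnames(posterior)
  vapply(seq_len(nrow(posterior)), function(i) {
    p <- posterior[i, ]
    w <- which.max(p)
    if (p[w] > hi && all(p[-w] < lo)) classes[w] else "unclassified"
  }, character(1))
}

#' Stratified cross-validation of the shrinkage grid
#'
#' @param x expression matrix (genes x samples).
#' @param labels class labels.
#' @param delta_grid shrinkage values to evaluate.
#' @param folds requested fold count.
#' @param seed RNG seed for fold assignment.
#' @param priors,mk_convention as in [train_nsc()].
#' @return list: `error_curve` (data frame `delta`, `error`), `confusion`
#'   (list of per-delta confusion matrices summed over folds),
#'   `folds_used`.
#' @export
cross_validate <- function(x, labels, delta_grid, folds = 10L, seed = 1L,
                           priors = NULL,
                           mk_convention = c("se_diff", "plus")) {
  mk_convention <- match.arg(mk_convention)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  min_class <- min(table(labels))
  if (min_class < folds) {
    warning(sprintf("reducing folds from %d to %d (smallest class)",
                    folds, min_class))
    folds <- min_class
  }
  if (folds < 2) stop_input("cannot stratify: a class has < 2 samples")
  set.seed(seed)
  fold_of <- integer(ncol(x))
  for (k in classes) {
    idx <- which(labels == k)
    fold_of[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  n_err <- numeric(length(delta_grid))
  confusion <- lapply(delta_grid, function(.) {
    matrix(0L, length(classes), length(classes),
           dimnames = list(truth = classes, predicted = classes))
  })
  for (f in seq_len(folds)) {
    test <- fold_of == f
    st <- nsc_stats(x[, !test, drop = FALSE], labels[!test], priors,
                    mk_convention)
    for (j in seq_along(delta_grid)) {
      sc <- nsc_discriminant(st, x[, test, drop = FALSE], delta_grid[j])
      pred <- st$classes[max.col(-sc, ties.method = "first")]
      n_err[j] <- n_err[j] + sum(pred != labels[test])
      for (i in seq_along(pred)) {
        confusion[[j]][labels[test][i], pred[i]] <-
          confusion[[j]][labels[test][i], pred[i]] + 1L
      }
    }
  }
  list(error_curve = data.frame(delta = delta_grid,
                                error = n_err / ncol(x)),
       confusion = confusion, folds_used = folds)
}

#' Serialize / restore an NSC model as versioned JSON
#' @param model an `immunophen_nsc`.
#' @param path output (input) file path.
#' @return `path` invisibly (`nsc_to_json`); the model (`nsc_from_json`).
#' @export
nsc_to_json <- function(model, path) {
  payload <- list(
    format = "immunophen_nsc", version = 1L,
    gene_ids = model$gene_ids, classes = model$classes,
    xbar = model$xbar, centroids = model$centroids,
    s = model$s, s0 = model$s0, n_k = model$n_k,
    priors = as.numeric(model$priors), m_k = as.numeric(model$m_k),
    mk_convention = model$mk_convention,
    chosen_delta = model$chosen_delta,
    delta_grid = model$delta_grid,
    cv_error = model$cv_error_curve$error,
    provenance = model$provenance
  )
  # 17 significant digits: doubles survive the round trip bit-for-bit
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname nsc_to_json
#' @export
nsc_from_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "immunophen_nsc")) {
    stop_input("not an immunophen_nsc model file")
  }
  centroids <- matrix(unlist(p$centroids), ncol = length(p$classes),
                      dimnames = list(p$gene_ids, p$classes))
  model <- list(
    gene_ids = p$gene_ids, classes = p$classes,
    xbar = stats::setNames(p$xbar, p$gene_ids),
    centroids = centroids,
    s = stats::setNames(p$s, p$gene_ids), s0 = p$s0, n_k = p$n_k,
    priors = stats::setNames(p$priors, p$classes),
    m_k = stats::setNames(p$m_k, p$classes),
    mk_convention = p$mk_convention,
    chosen_delta = p$chosen_delta,
    delta_grid = p$delta_grid,
    cv_error_curve = data.frame(delta = p$delta_grid, error = p$cv_error),
    provenance = p$provenance
  )
  model$d <- sweep(centroids - model$xbar, 2, model$m_k, "/") /
    (model$s + model$s0)
  class(model) <- "immunophen_nsc"
  model
}

#' @export
print.immunophen_nsc <- function(x, ...) {
  cat(sprintf("NSC model: %d genes, classes: %s\n", length(x$gene_ids),
              paste(x$classes, collapse = ", ")))
  cat(sprintf("chosen delta = %.4g (CV error %.3f), %d genes active\n",
              x$chosen_delta,
              min(x$cv_error_curve$error),
              sum(rowSums(abs(soft_threshold(x$d, x$chosen_delta)) > 0) > 0)))
  invisible(x)
}
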
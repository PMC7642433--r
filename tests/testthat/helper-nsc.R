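# Independent brute-force nearest-centroid oracle (delta = 0): recomputes
# every statistic from first principles, loop-style, sharing no code with
# the implementation under test. Used by test-nsc.R and test-acceptance.R.
oracle_posteriors <- function(x_train, labels, x_test) {
  classes <- sort(unique(labels))
  n <- ncol(x_train)
  K <- length(classes)
  s2 <- rep(0, nrow(x_train))
  centroids <- matrix(0, nrow(x_train), K)
  for (k in seq_len(K)) {
    cols <- which(labels == classes[k])
    centroids[, k] <- apply(x_train[, cols, drop = FALSE], 1, mean)
    for (j in cols) s2 <- s2 + (x_train[, j] - centroids[, k])^2
  }
  s <- sqrt(s2 / (n - K))
  s0 <- median(s)
  prior <- as.numeric(table(factor(labels, classes))) / n
  post <- matrix(0, ncol(x_test), K)
  for (m in seq_len(ncol(x_test))) {
    delta_k <- numeric(K)
    for (k in seq_len(K)) {
      delta_k[k] <- sum((x_test[, m] - centroids[, k])^2 / (s + s0)^2) -
        2 * log(prior[k])
    }
    w <- exp(-(delta_k - min(delta_k)) / 2)
    post[m, ] <- w / sum(w)
  }
  post
}

random_dataset <- function(seed) {
  set.seed(seed)
  n <- sample(24:40, 1)
  g <- sample(5:25, 1)
  K <- sample(2:3, 1)
  labels <- sample(letters[1:K], n, replace = TRUE)
  while (min(table(labels)) < 3) labels <- sample(letters[1:K], n, TRUE)
  x <- matrix(rnorm(g * n), g, n,
              dimnames = list(sprintf("G%02d", 1:g), sprintf("S%02d", 1:n)))
  for (k in seq_len(K)) {
    x[, labels == letters[k]] <- x[, labels == letters[k]] + rnorm(g)
  }
  list(x = x, labels = labels)
}
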
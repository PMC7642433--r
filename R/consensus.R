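# Consensus clustering of samples on the signature genes, and rule-based
# merging of the k = 6 clusters into the three immune phenotypes.
#
# "Pearson distance + k-means" is realized as k-means on row-standardized
# sample profiles: after each sample's gene vector is centred and scaled to
# unit norm, squared Euclidean distance is proportional to one minus the
# Pearson correlation, so the named combination is well defined.

#' Consensus matrix by subsampled k-means
#'
#' @param values expression matrix (signature genes x samples).
#' @param k number of clusters per replicate (default 6).
#' @param n_reps subsampling replicates (default 1000).
#' @param sample_frac fraction of samples drawn (without replacement) per
#'   replicate (default 0.8).
#' @param n_restarts k-means restarts per replicate (k-means++ style
#'   initialization; default 10).
#' @param iter_max Lloyd iteration cap per run (default 300).
#' @param seed RNG seed.
#' @return list of class `immunophen_consensus`: `consensus` (samples x
#'   samples, entries in \[0,1\], unit diagonal), `cosample_counts`,
#'   `cocluster_counts`, and the call parameters.
#' @export
consensus_matrix <- function(values, k = 6L, n_reps = 1000L,
                             sample_frac = 0.8, n_restarts = 10L,
                             iter_max = 300L, seed = 1L) {
  n <- ncol(values)
  if (n < 3 * k) stop_input("need at least 3*k samples (%d < %d)", n, 3 * k)
  x <- standardize_profiles(values)
  set.seed(seed)
  m <- floor(sample_frac * n)
  co_cluster <- matrix(0, n, n)
  co_sample <- matrix(0, n, n)
  for (rep in seq_len(n_reps)) {
    idx <- sort(sample.int(n, m))
    cl <- kmeans_pp(x[idx, , drop = FALSE], k, n_restarts, iter_max)
    co_sample[idx, idx] <- co_sample[idx, idx] + 1
    for (g in seq_len(k)) {
      members <- idx[cl == g]
      co_cluster[members, members] <- co_cluster[members, members] + 1
    }
  }
  if (any(co_sample[upper.tri(co_sample)] == 0)) {
    stop_input("some sample pairs were never co-sampled; increase n_reps")
  }
  consensus <- co_cluster / co_sample
  diag(consensus) <- 1
  dimnames(consensus) <- list(colnames(values), colnames(values))
  structure(list(
    consensus = consensus, cosample_counts = co_sample,
    cocluster_counts = co_cluster,
    k = k, n_reps = n_reps, sample_frac = sample_frac, seed = seed
  ), class = "immunophen_consensus")
}

# centre and unit-normalize each sample's gene vector
standardize_profiles <- function(values) {
  x <- t(values)
  x <- x - rowMeans(x)
  nrm <- sqrt(rowSums(x^2))
  if (any(nrm == 0)) {
    stop_input("sample(s) with constant expression profile: %s",
               paste(rownames(x)[nrm == 0], collapse = ", "))
  }
  x / nrm
}

# k-means with k-means++ seeding and multiple restarts; smallest total
# within-cluster SS wins. Uses Lloyd iterations via stats::kmeans.
kmeans_pp <- function(x, k, n_restarts, iter_max) {
  best <- NULL
  for (r in seq_len(n_restarts)) {
    centers <- kpp_init(x, k)
    km <- suppressWarnings(
      kmeans(x, centers = centers, iter.max = iter_max, algorithm = "Lloyd")
    )
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  best$cluster
}

kpp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  i <- sample.int(n, 1)
  centers[1, ] <- x[i, ]
  d2 <- rowSums((x - rep(centers[1, ], each = n))^2)
  for (j in seq_len(k - 1)) {
    prob <- d2 / sum(d2)
    if (!all(is.finite(prob)) || sum(d2) == 0) {
      i <- sample.int(n, 1)
    } else {
      i <- sample.int(n, 1, prob = prob)
    }
    centers[j + 1, ] <- x[i, ]
    d2 <- pmin(d2, rowSums((x - rep(centers[j + 1, ], each = n))^2))
  }
  # duplicated centres make stats::kmeans error; swap in unused distinct
  # rows, or jitter when the data itself has too few distinct rows
  for (j in which(duplicated(centers))) {
    spare <- which(!duplicated(x) &
                   !apply(x, 1, function(r) any(apply(centers, 1, identical, r))))
    if (length(spare)) {
      centers[j, ] <- x[spare[1], ]
    } else {
      centers[j, ] <- centers[j, ] + stats::rnorm(ncol(x), sd = 1e-8)
    }
  }
  centers
}

#' Final consensus clusters
#'
#' Average-linkage hierarchical clustering of the consensus dissimilarity
#' (1 - M), cut at `k`.
#'
#' @param cons an `immunophen_consensus` or a bare consensus matrix.
#' @param k number of clusters (default 6).
#' @return integer cluster labels (1..k) named by sample.
#' @export
consensus_clusters <- function(cons, k = 6L) {
  M <- if (inherits(cons, "immunophen_consensus")) cons$consensus else cons
  n <- ncol(M)
  if (k > n) stop_input("k (%d) exceeds number of samples (%d)", k, n)
  off <- M[upper.tri(M)]
  if (k > 1 && all(off == 1)) {
    stop_input("uniform consensus matrix: cannot form %d non-empty clusters", k)
  }
  hc <- hclust(as.dist(1 - M), method = "average")
  cutree(hc, k = k)
}

#' Merge fine-grained clusters into the three immune phenotypes
#'
#' Reconstruction of the manual cluster-to-phenotype reduction as an
#' explicit rule on cluster-level polar metrics: clusters whose mean R
#' falls below the cohort `R_quantile` quantile are desert; of the rest,
#' clusters whose mean theta exceeds the median theta of non-desert samples
#' are excluded; the remainder are infiltrated.
#'
#' @param clusters integer labels per sample (named, as from
#'   [consensus_clusters()]).
#' @param polar data frame with `sample_id`, `R`, `theta` covering all
#'   samples.
#' @param R_quantile cohort R quantile below which a cluster is desert
#'   (default 0.40).
#' @return list: `phenotype` (character per sample, named), `merge_map`
#'   (data frame with per-cluster statistics and assigned phenotype), and
#'   the thresholds used.
#' @export
merge_to_phenotypes <- function(clusters, polar, R_quantile = 0.40) {
  ids <- names(clusters)
  if (is.null(ids)) stop_input("clusters must be named by sample id")
  if (!all(ids %in% polar$sample_id)) {
    stop_input("polar table does not cover all clustered samples")
  }
  polar <- polar[match(ids, polar$sample_id), ]
  mean_R <- tapply(polar$R, clusters, mean)
  mean_theta <- tapply(polar$theta, clusters, mean)
  R_thresh <- quantile(polar$R, R_quantile, names = FALSE)
  desert_cluster <- mean_R < R_thresh
  nondesert_samples <- !clusters %in% as.integer(names(which(desert_cluster)))
  theta_thresh <- if (any(nondesert_samples)) {
    median(polar$theta[nondesert_samples])
  } else {
    median(polar$theta)
  }
  phen_by_cluster <- ifelse(desert_cluster, "desert",
                            ifelse(mean_theta > theta_thresh,
                                   "excluded", "infiltrated"))
  phenotype <- stats::setNames(
    as.character(phen_by_cluster[as.character(clusters)]), ids)
  missing <- setdiff(PHENOTYPES, unique(phenotype))
  if (length(missing)) {
    warning("phenotype(s) with no cluster assigned: ",
            paste(missing, collapse = ", "))
  }
  list(
    phenotype = phenotype,
    merge_map = data.frame(
      cluster = as.integer(names(mean_R)),
      mean_R = as.numeric(mean_R),
      mean_theta = as.numeric(mean_theta),
      phenotype = as.character(phen_by_cluster)
    ),
    R_threshold = R_thresh,
    theta_threshold = theta_thresh
  )
}
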
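#' Cluster-number selection by BIC on PLV vectors
#'
#' Fits Gaussian finite-mixture models to the participants' 4-D PLV vectors
#' for `k = 1 ... k_max` components and selects the `k` minimizing the BIC
#' (`-2 log L + p log n`). Cluster labels are relabelled so cluster 1
#' ("high") has the larger mean PLV. `r_squared` is the between-cluster sum
#' of squares over the total sum of squares of the vectors.
#'
#' PLV-valued data are bounded on `[0, 1]` and accumulate near the ceiling,
#' so by default the mixture is fitted on the Fisher-z scale
#' (`atanh`), the standard variance-stabilizing transform for
#' correlation-like quantities; inputs with values outside `[0, 1]` are
#' fitted untransformed. `r_squared` is always computed from the final
#' labels on the original scale.
#'
#' An alternative mode (`method = "rf"`) clusters the unsupervised
#' random-forest proximity matrix with partitioning around medoids, choosing
#' `k` by average silhouette width; it is provided for comparison and does
#' not drive BIC selection.
#'
#' @param vectors numeric matrix of synchrony vectors (rows = participants)
#'   or a `sync_cohort`.
#' @param k_max largest number of clusters considered.
#' @param seed RNG seed (used by the `"rf"` mode; GMM fitting is
#'   deterministic).
#' @param method `"gmm"` (default) or `"rf"`.
#' @param transform `"auto"` (Fisher-z for `[0, 1]` data, identity
#'   otherwise), `"fisher_z"` or `"none"`.
#' @param regularize use mclust's conjugate prior (`priorControl()`) to
#'   regularize component covariances; prevents degenerate tiny-variance
#'   components at small sample sizes (default `TRUE`).
#' @param standardize scale columns to unit variance first (default `FALSE`:
#'   all PLV dimensions already share the `[0, 1]` scale).
#' @return an object of class `sync_clusters`: `n_clusters`, `labels`
#'   (1 = high-PLV cluster), `bic_by_k` (named, minimized), `r_squared`,
#'   `cluster_means`, `method`.
#' @importFrom mclust Mclust mclustBIC
#' @export
select_clusters_bic <- function(vectors, k_max = 5, seed = 1,
                                method = c("gmm", "rf"),
                                transform = c("auto", "fisher_z", "none"),
                                standardize = FALSE, regularize = TRUE) {
  method <- match.arg(method)
  transform <- match.arg(transform)
  X <- if (inherits(vectors, "sync_cohort")) plv_matrix(vectors)
       else as.matrix(vectors)
  if (!all(is.finite(X))) stop_invalid("synchrony vectors must be finite")
  n <- nrow(X)
  if (n < 2 * k_max)
    stop_invalid("need at least 2*k_max participants for clustering")
  if (transform == "auto")
    transform <- if (all(X >= 0 & X <= 1)) "fisher_z" else "none"
  Z <- if (transform == "fisher_z") atanh(pmin(pmax(X, 0), 1 - 1e-6)) else X
  if (standardize) Z <- scale(Z)
  if (all(apply(Z, 2, stats::sd) < 1e-12)) {
    warning("degenerate (zero-variance) data: returning a single cluster")
    return(structure(list(n_clusters = 1L, labels = rep(1L, n),
                          bic_by_k = c(`1` = NA_real_), r_squared = 0,
                          cluster_means = colMeans(X), method = method,
                          transform = transform),
                     class = "sync_clusters"))
  }
  fit <- suppressWarnings(mclust::Mclust(
    Z, G = seq_len(k_max),
    prior = if (regularize) mclust::priorControl() else NULL,
    verbose = FALSE))
  # mclust's BIC is 2 log L - p log n (maximized); convert to the
  # conventional minimized form.
  bic_by_k <- -apply(fit$BIC, 1, max, na.rm = TRUE)
  names(bic_by_k) <- rownames(fit$BIC)
  if (method == "gmm") {
    k <- fit$G
    labels <- fit$classification
  } else {
    if (!requireNamespace("randomForest", quietly = TRUE) ||
        !requireNamespace("cluster", quietly = TRUE))
      stop_invalid("method 'rf' needs the randomForest and cluster packages")
    prox <- with_seed(seed,
      randomForest::randomForest(x = as.data.frame(Z), proximity = TRUE,
                                 ntree = 1000)$proximity)
    d <- stats::as.dist(1 - prox)
    sil <- vapply(2:k_max, function(kk) {
      p <- cluster::pam(d, kk)
      p$silinfo$avg.width
    }, numeric(1))
    k <- (2:k_max)[which.max(sil)]
    labels <- cluster::pam(d, k)$clustering
  }
  # relabel so cluster 1 has the highest mean synchrony
  means <- tapply(rowMeans(X), labels, mean)
  ord <- order(means, decreasing = TRUE)
  labels <- match(labels, as.integer(names(means))[ord])
  centers <- do.call(rbind, lapply(seq_len(k), function(g)
    colMeans(X[labels == g, , drop = FALSE])))
  grand <- colMeans(X)
  ss_tot <- sum(sweep(X, 2, grand)^2)
  ss_betw <- sum(vapply(seq_len(k), function(g)
    sum(labels == g) * sum((centers[g, ] - grand)^2), numeric(1)))
  structure(list(n_clusters = as.integer(k), labels = as.integer(labels),
                 bic_by_k = bic_by_k,
                 r_squared = if (ss_tot > 0) ss_betw / ss_tot else 0,
                 cluster_means = centers, method = method,
                 transform = transform),
            class = "sync_clusters")
}

#' @export
print.sync_clusters <- function(x, ...) {
  cat(sprintf("Cluster solution (%s): %d cluster(s), R^2 = %.3f\n",
              x$method, x$n_clusters, x$r_squared))
  cat("BIC by k (minimized):\n")
  print(round(x$bic_by_k, 1))
  cat("Cluster sizes:", paste(tabulate(x$labels), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.sync_clusters <- function(x, ...) {
  k <- as.integer(names(x$bic_by_k))
  plot(k, x$bic_by_k, type = "b", xlab = "number of clusters",
       ylab = "BIC", ...)
  graphics::points(x$n_clusters, x$bic_by_k[as.character(x$n_clusters)],
                   pch = 19)
  invisible(x)
}
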
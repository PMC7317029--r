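# Phenotype-profile clustering: row scaling for display, model-based choice
# of the number of clusters (spherical Gaussian mixture + BIC), agglomerative
# clustering on Euclidean distance, and resampling-based consensus clustering
# of categories.

#' Center and scale matrix rows
#'
#' Each row is centered to mean 0 and divided by its population standard
#' deviation (divisor `n`, matching classical heatmap row scaling). Constant
#' rows map to all zeros and are flagged in the `constant_rows` attribute.
#'
#' @param m numeric matrix with >= 2 columns.
#' @return scaled matrix with attribute `constant_rows` (character).
#' @export
row_scale <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2L) stop("row scaling needs >= 2 columns", call. = FALSE)
  mu <- rowMeans(m)
  centered <- m - mu
  sd_pop <- sqrt(rowMeans(centered^2))
  const <- sd_pop == 0
  sd_pop[const] <- 1
  out <- centered / sd_pop
  attr(out, "constant_rows") <-
    if (is.null(rownames(m))) as.character(which(const)) else
      rownames(m)[const]
  out
}

# Spherical-covariance Gaussian mixture fitted by EM (kmeans init). The
# spherical variance is shared across components, which keeps singleton
# components from collapsing the likelihood (the classic GMM singularity)
# and matches the model-selection role this fit plays. Returns the
# maximized log-likelihood.
fit_spherical_gmm <- function(X, K, max_iter = 200, tol = 1e-8) {
  n <- nrow(X); d <- ncol(X)
  km <- suppressWarnings(stats::kmeans(X, centers = K, nstart = 5,
                                       iter.max = 50))
  mu <- km$centers
  pi_k <- pmax(tabulate(km$cluster, K) / n, 1e-10)
  sig2 <- max(km$tot.withinss / (n * d), 1e-9)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    # E step on log densities
    logd <- vapply(seq_len(K), function(k) {
      dist2 <- rowSums(sweep(X, 2L, mu[k, ])^2)
      log(pi_k[k]) - 0.5 * d * log(2 * pi * sig2) - dist2 / (2 * sig2)
    }, numeric(n))
    if (n == 1L) logd <- base::matrix(logd, nrow = 1L)
    mx <- apply(logd, 1L, max)
    ll <- sum(mx + log(rowSums(exp(logd - mx))))
    r <- exp(logd - mx)
    r <- r / rowSums(r)
    # M step
    nk <- pmax(colSums(r), 1e-10)
    pi_k <- nk / n
    mu <- crossprod(r, X) / nk
    sig2 <- max(sum(vapply(seq_len(K), function(k) {
      sum(r[, k] * rowSums(sweep(X, 2L, mu[k, ])^2))
    }, 0)) / (n * d), 1e-9)
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
  }
  ll
}

#' Model-based choice of the number of clusters
#'
#' Fits a finite mixture of spherical-covariance Gaussian components to the
#' rows for each K in `k_min:k_max` and returns the K minimizing the Bayesian
#' information criterion. The per-K criterion curve is returned for audit.
#' A matrix whose rows are all identical yields `K = 1` directly.
#'
#' @param m numeric matrix (items x features).
#' @param k_min,k_max K range; `k_max` is clamped to the number of distinct
#'   rows and must be below the number of rows.
#' @param seed integer seed (kmeans initialisation).
#' @param scale_rows apply [row_scale()] first.
#' @return list of class `k_selection`: `K`, `criterion` (data.frame
#'   `K, bic, loglik`), `k_range`.
#' @export
select_k <- function(m, k_min = 2, k_max = 15, seed = 1, scale_rows = FALSE) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("degenerate matrix: need >= 2 rows", call. = FALSE)
  if (scale_rows) m <- row_scale(m)
  n_distinct <- nrow(unique(m))
  if (n_distinct == 1L) {
    return(structure(list(K = 1L, criterion = NULL,
                          k_range = c(NA_integer_, NA_integer_),
                          note = "all rows identical"),
                     class = "k_selection"))
  }
  k_min <- check_count(k_min, "k_min")
  k_max <- check_count(k_max, "k_max")
  k_max <- min(k_max, n_distinct, nrow(m) - 1L)
  if (k_min > k_max) k_min <- k_max
  n <- nrow(m); d <- ncol(m)
  with_seed(seed, {
    ks <- seq.int(k_min, k_max)
    fits <- vapply(ks, function(K) fit_spherical_gmm(m, K), 0)
    npar <- ks * d + 1 + (ks - 1)  # means + shared variance + weights
    bic <- -2 * fits + npar * log(n)
    structure(list(K = ks[which.min(bic)],
                   criterion = data.frame(K = ks, bic = bic, loglik = fits),
                   k_range = c(k_min, k_max)),
              class = "k_selection")
  })
}

#' @export
print.k_selection <- function(x, ...) {
  cat(sprintf("<k_selection> K = %d (BIC over K = %s..%s)\n", x$K,
              x$k_range[1L], x$k_range[2L]))
  invisible(x)
}

#' Hierarchical clustering of profiles
#'
#' Agglomerative clustering on Euclidean distance with the declared linkage,
#' cut into K clusters. The leaf order is returned for heatmap export.
#'
#' @param m numeric matrix (items x features).
#' @param K number of clusters (<= rows).
#' @param linkage one of `"average"` (default), `"single"`, `"complete"`,
#'   `"ward"` (Ward's D2).
#' @param scale_rows cluster on row-scaled values (display scaling) instead
#'   of raw values.
#' @return list of class `clustering_result`: `K, labels, hclust, order,
#'   distance, linkage, matrix` (the matrix actually clustered).
#' @export
cluster_hierarchical <- function(m, K, linkage = "average",
                                 scale_rows = FALSE) {
  m <- as.matrix(m)
  method <- switch(linkage,
                   average = "average", single = "single",
                   complete = "complete", ward = "ward.D2",
                   stopf("unknown linkage: '%s'", linkage))
  K <- check_count(K, "K")
  if (K > nrow(m)) stop("K exceeds the number of items", call. = FALSE)
  used <- if (scale_rows) row_scale(m) else m
  hc <- stats::hclust(stats::dist(used, method = "euclidean"),
                      method = method)
  labels <- stats::cutree(hc, k = K)
  structure(list(K = K, labels = labels, hclust = hc, order = hc$order,
                 distance = "euclidean", linkage = linkage, matrix = used),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("<clustering_result> %d items in K = %d clusters (%s linkage, %s distance)\n",
              length(x$labels), x$K, x$linkage, x$distance))
  invisible(x)
}

# Area under the empirical CDF of consensus entries (pairs i < j), on [0, 1].
consensus_cdf_area <- function(M) {
  x <- sort(M[upper.tri(M)])
  m <- length(x)
  if (m == 0L) return(NA_real_)
  xs <- c(0, x, 1)
  cdf <- c(0, seq_len(m) / m)
  sum(diff(xs) * cdf)
}

#' Consensus clustering of categories
#'
#' Resampling-based clustering stability analysis: for each K, items (rows)
#' are repeatedly subsampled and clustered with [cluster_hierarchical()];
#' the consensus matrix records how often each pair co-clusters, normalized
#' by how often it was co-sampled. K is chosen by the largest relative
#' increase of the area under the consensus CDF, and final labels come from
#' clustering `1 - consensus` at the chosen K.
#'
#' @param m numeric matrix (items x features); for category clustering pass
#'   the transposed line-score matrix (categories as rows).
#' @param k_min,k_max K range to evaluate.
#' @param n_resamples number of subsamples per K (>= 10).
#' @param subsample_frac fraction of items per subsample, in (0, 1]. With 1
#'   every resample uses all items and consensus entries are exactly 0/1.
#' @param linkage linkage for the inner and final clusterings.
#' @param seed integer seed; subsample sets are drawn once and shared by all
#'   K so the per-K matrices are comparable.
#' @return list of class `consensus_result`: `K, labels, consensus` (list of
#'   matrices by K), `area`, `delta` (relative CDF-area increase), plus the
#'   resampling parameters.
#' @export
consensus_cluster <- function(m, k_min = 2, k_max = 6, n_resamples = 1000,
                              subsample_frac = 0.8, linkage = "average",
                              seed = 1) {
  m <- as.matrix(m)
  n <- nrow(m)
  if (is.null(rownames(m))) rownames(m) <- sprintf("item%02d", seq_len(n))
  k_min <- check_count(k_min, "k_min")
  k_max <- check_count(k_max, "k_max")
  n_resamples <- check_count(n_resamples, "n_resamples", 10L)
  check_proportion(subsample_frac, "subsample_frac")
  if (subsample_frac <= 0) stop("`subsample_frac` must be > 0", call. = FALSE)
  s <- max(2L, ceiling(subsample_frac * n))
  if (k_max > s) stop("`k_max` exceeds the subsample size", call. = FALSE)

  with_seed(seed, {
    idx_sets <- if (s == n) {
      replicate(n_resamples, seq_len(n), simplify = FALSE)
    } else {
      replicate(n_resamples, sort(sample.int(n, s)), simplify = FALSE)
    }
    cosample <- base::matrix(0, n, n)
    for (idx in idx_sets) cosample[idx, idx] <- cosample[idx, idx] + 1
    never <- which(cosample == 0 & upper.tri(cosample), arr.ind = TRUE)
    if (nrow(never)) {
      stopf("%d item pair(s) never co-sampled (e.g. rows %d and %d); increase n_resamples or subsample_frac",
            nrow(never), never[1L, 1L], never[1L, 2L])
    }
    ks <- seq.int(k_min, k_max)
    consensus <- vector("list", length(ks))
    names(consensus) <- as.character(ks)
    for (kk in seq_along(ks)) {
      cocluster <- base::matrix(0, n, n)
      for (idx in idx_sets) {
        cl <- cluster_hierarchical(m[idx, , drop = FALSE], K = ks[kk],
                                   linkage = linkage)$labels
        same <- outer(cl, cl, "==")
        cocluster[idx, idx] <- cocluster[idx, idx] + same
      }
      M <- cocluster / cosample
      diag(M) <- 1
      dimnames(M) <- list(rownames(m), rownames(m))
      consensus[[kk]] <- M
    }
    area <- vapply(consensus, consensus_cdf_area, 0)
    delta <- c(area[1L],
               if (length(area) > 1L) diff(area) / pmax(utils::head(area, -1L),
                                                        .Machine$double.eps))
    names(delta) <- names(area)
    K <- ks[which.max(delta)]
    final <- stats::hclust(stats::as.dist(1 - consensus[[as.character(K)]]),
                           method = if (linkage == "ward") "ward.D2" else linkage)
    labels <- stats::cutree(final, k = K)
    structure(list(K = K, labels = labels, consensus = consensus,
                   area = area, delta = delta, n_resamples = n_resamples,
                   subsample_frac = subsample_frac, linkage = linkage,
                   seed = seed),
              class = "consensus_result")
  })
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("<consensus_result> chosen K = %d over K = %s (from %d resamples at %.0f%% subsampling)\n",
              x$K, paste(range(as.integer(names(x$area))), collapse = ".."),
              x$n_resamples, 100 * x$subsample_frac))
  invisible(x)
}

#' Export a clustered, row-scaled matrix for heatmap display
#'
#' Writes the reordered (leaf-order) row-scaled matrix plus a cluster-label
#' column, the plain-text equivalent of the screen's phenotype heatmaps.
#'
#' @param result a `clustering_result`.
#' @param path output TSV path.
#' @export
write_heatmap_tsv <- function(result, path) {
  stopifnot(inherits(result, "clustering_result"))
  m <- result$matrix[result$order, , drop = FALSE]
  df <- data.frame(item = rownames(m), cluster = result$labels[result$order],
                   as.data.frame(m, check.names = FALSE),
                   check.names = FALSE)
  write_tsv(df, path)
}
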
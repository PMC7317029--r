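# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the package's own code paths.

# --- type-7 quantile, written from the interpolation formula ---------------
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  idx <- 1 + (n - 1) * p
  lo <- floor(idx)
  hi <- ceiling(idx)
  if (idx > lo && x[hi] != x[lo]) {
    h <- idx - lo
    (1 - h) * x[lo] + h * x[hi]
  } else {
    x[lo]
  }
}

# brute-force IQR-rule hit calls for one category vector
oracle_calls <- function(x) {
  med <- oracle_quantile7(x, 0.5)
  iqr <- oracle_quantile7(x, 0.75) - oracle_quantile7(x, 0.25)
  unname(ifelse(x > med + iqr, "enhancer",
                ifelse(x < med - iqr, "suppressor", "none")))
}

# --- exhaustive neighbourhood k-core search (graphs <= 8 nodes) ------------
# adj: symmetric logical adjacency matrix
oracle_mcode_weight <- function(adj, v) {
  nb <- sort(unique(c(v, which(adj[v, ]))))
  m <- length(nb)
  sub <- adj[nb, nb, drop = FALSE]
  if (sum(sub) == 0) return(0)
  k_max <- 0L
  for (mask in seq_len(2^m - 1L)) {
    S <- which(bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0)
    if (length(S) < 2L) next
    degs <- rowSums(sub[S, S, drop = FALSE])
    k_max <- max(k_max, min(degs))
  }
  # the k_max-core is the union of all subsets attaining min degree k_max
  core <- logical(m)
  for (mask in seq_len(2^m - 1L)) {
    S <- which(bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0)
    if (length(S) < 2L) next
    if (min(rowSums(sub[S, S, drop = FALSE])) >= k_max) core[S] <- TRUE
  }
  S <- which(core)
  e <- sum(sub[S, S]) / 2
  dens <- e / (length(S) * (length(S) - 1) / 2)
  k_max * dens
}

# --- exact hypergeometric upper tail from binomial coefficients ------------
oracle_hyper_tail <- function(k, K, N, n) {
  ks <- seq.int(max(0, k), min(K, n))
  if (k > min(K, n)) return(0)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# --- adjusted Rand index ---------------------------------------------------
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  tot <- choose(length(a), 2)
  expected <- sum_a * sum_b / tot
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# --- fixtures --------------------------------------------------------------

# minimal valid score data.frame (one line, one animal, two scorers)
tiny_score_df <- function() {
  expand.grid(line_id = c("L1", "L2"), animal_id = c("a1", "a2"),
              scorer_id = c("s1", "s2"),
              category = c("invasion", "multilayering"),
              stringsAsFactors = FALSE) |>
    transform(gene_id = ifelse(line_id == "L1", "gA", "gB"),
              score = 1L)
}

# planted 3-group profile matrix: separation `sep` times within-group sd 1
planted_groups <- function(n_per = 10, d = 6, sep = 5, seed = 1) {
  centers <- diag(sep, 3, d)
  set.seed(seed)
  X <- do.call(rbind, lapply(1:3, function(g)
    sweep(matrix(rnorm(n_per * d), n_per), 2, centers[g, ], "+")))
  rownames(X) <- sprintf("it%02d", seq_len(3 * n_per))
  attr(X, "labels") <- rep(1:3, each = n_per)
  X
}

random_adjacency <- function(n, p) {
  adj <- matrix(FALSE, n, n)
  adj[upper.tri(adj)] <- runif(n * (n - 1) / 2) < p
  adj | t(adj)
}

adj_to_igraph <- function(adj) {
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- paste0("n", seq_len(nrow(adj)))
  g
}
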
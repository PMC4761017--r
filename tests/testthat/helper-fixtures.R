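# Small graphs and independent oracles used across the suite.

path_network <- function(ids = c("A", "B", "C")) {
  proteinNetwork(ids, cbind(ids[-length(ids)], ids[-1]))
}

triangle_network <- function(ids = c("A", "B", "C")) {
  proteinNetwork(ids, rbind(c(ids[1], ids[2]), c(ids[2], ids[3]),
                            c(ids[1], ids[3])))
}

k4_network <- function(ids = c("A", "B", "C", "D")) {
  e <- t(combn(ids, 2))
  proteinNetwork(ids, e)
}

# Connected random graph: random spanning tree plus `extra` random edges.
random_connected_network <- function(n, extra, seed) {
  set.seed(seed)
  ids <- sprintf("N%03d", seq_len(n))
  tree <- cbind(ids[vapply(2:n, function(i) sample.int(i - 1L, 1L),
                           integer(1))], ids[2:n])
  pool <- t(combn(ids, 2))
  key <- paste(pmin(pool[, 1], pool[, 2]), pmax(pool[, 1], pool[, 2]))
  tkey <- paste(pmin(tree[, 1], tree[, 2]), pmax(tree[, 1], tree[, 2]))
  pool <- pool[!(key %in% tkey), , drop = FALSE]
  extra <- min(extra, nrow(pool))
  more <- pool[sample.int(nrow(pool), extra), , drop = FALSE]
  proteinNetwork(ids, rbind(tree, more))
}

# Floyd-Warshall all-pairs hop distances, independent of igraph.
fw_distances <- function(net) {
  ids <- nodeIds(net)
  n <- length(ids)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  e <- edges(net)
  if (nrow(e) > 0) {
    i <- match(e[, 1], ids)
    j <- match(e[, 2], ids)
    d[cbind(i, j)] <- 1
    d[cbind(j, i)] <- 1
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  dimnames(d) <- list(ids, ids)
  d
}

edge_index_matrix <- function(e, ids) {
  cbind(match(e[, 1], ids), match(e[, 2], ids))
}

# Brute-force pairwise-comparison AUC with midrank tie credit.
brute_auc <- function(pos, neg) {
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Truncated power series sum_{k=0..K} alpha^k (-L)^k for the RL kernel.
rl_series <- function(values, alpha, K = 200) {
  L <- diag(rowSums(values)) - values
  n <- nrow(L)
  acc <- diag(n)
  term <- diag(n)
  for (k in seq_len(K)) {
    term <- term %*% (-alpha * L)
    acc <- acc + term
  }
  acc
}

# A symmetric uniform kernel built by hand (independent of the generator).
hand_noise_kernel <- function(ids, seed, name = "hand") {
  set.seed(seed)
  n <- length(ids)
  u <- matrix(0, n, n)
  u[upper.tri(u)] <- runif(n * (n - 1) / 2)
  u <- u + t(u)
  new("KernelMatrix", nodeIds = ids, values = u, name = name)
}

# Small benchmark used by the sampler unit tests (fast to optimise).
small_benchmark <- function(seed) {
  generateBenchmark(nNodes = 60L, attachment = 2L, nExtra = 8L,
                    nValidation = 10L, nTest = 30L, seed = seed)
}

small_config <- function(seed, ...) {
  samplerConfig(populationSize = 20L, maxGenerations = 5L, seed = seed, ...)
}
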
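# Independent brute-force oracles, kept deliberately separate from the
# implementation paths they check.

# KL divergence by direct summation over an explicit support vector.
oracle_kl <- function(p, q, base = exp(1)) {
  s <- 0
  for (i in seq_along(p)) {
    if (p[i] > 0) {
      if (q[i] == 0) return(Inf)
      s <- s + p[i] * log(p[i] / q[i], base = base)
    }
  }
  s
}

# JSD from two aligned mass vectors via the definition, base-2 logs.
oracle_jsd <- function(pv, qv) {
  m <- (pv + qv) / 2
  0.5 * oracle_kl(pv, m, 2) + 0.5 * oracle_kl(qv, m, 2)
}

# Exhaustive threshold scan: try every unique off-diagonal value from
# strict to lenient and return the first meeting the coverage.
oracle_threshold <- function(sim, coverage) {
  vals <- sim$values
  n <- nrow(vals)
  cand <- sort(unique(vals[upper.tri(vals)]))
  if (sim$direction == "higher_is_similar") cand <- rev(cand)
  need <- ceiling(coverage * n)
  for (th in cand) {
    ok <- if (sim$direction == "lower_is_similar") vals <= th else vals >= th
    diag(ok) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(ok, mode = "undirected")
    if (max(igraph::components(g)$csize) >= need) return(th)
  }
  NA_real_
}

# All-pairs shortest paths by Floyd-Warshall on an adjacency matrix.
oracle_floyd_warshall <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj > 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# Pareto MLE by grid search over the log-likelihood.
oracle_pareto_grid <- function(x, xmin, grid = seq(1.01, 10, by = 1e-4)) {
  n <- length(x)
  slog <- sum(log(x / xmin))
  ll <- n * log((grid - 1) / xmin) - grid * slog
  grid[which.max(ll)]
}

# One-way ANOVA by explicit sums of squares.
oracle_anova <- function(groups) {
  all <- unlist(groups)
  gm <- mean(all)
  ssb <- sum(lengths(groups) * (vapply(groups, mean, numeric(1)) - gm)^2)
  ssw <- sum(unlist(lapply(groups, function(g) (g - mean(g))^2)))
  df1 <- length(groups) - 1
  df2 <- length(all) - length(groups)
  f <- (ssb / df1) / (ssw / df2)
  list(f = f, df1 = df1, df2 = df2, p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

# Random probability distribution over a small named vocabulary.
random_distribution <- function(n_lemmas, lemmas = letters[seq_len(n_lemmas)]) {
  p <- stats::rgamma(n_lemmas, 1)
  setNames(p / sum(p), lemmas)
}

# Draws from a continuous Pareto with density exponent alpha, support >= xmin.
rpareto <- function(n, alpha, xmin = 1) xmin * stats::runif(n)^(-1 / (alpha - 1))
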
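#' Generate a topic-clustered synthetic corpus
#'
#' Emulates the clustered structure of an encyclopedic corpus: each topic
#' gets its own base lemma distribution (a symmetric Dirichlet draw over a
#' shared vocabulary), and each document samples its tokens i.i.d. from its
#' topic's distribution. Documents of the same topic therefore have lower
#' pairwise Jensen-Shannon divergence than documents of different topics —
#' the property the thresholding pipeline presumes. Single-membership only:
#' no mixed-topic documents.
#'
#' @param n_topics,docs_per_topic,vocab_size,tokens_per_doc Counts (>= 1).
#' @param concentration Positive Dirichlet concentration for topic base
#'   distributions; large values make all topics near-uniform (and so near-
#'   identical), small values make them sharply distinct.
#' @param seed Integer seed; the same seed reproduces the corpus exactly.
#' @return Data frame with columns `doc_id`, `text`, `topic`; token streams
#'   are space-separated lemma strings, ready for [normalize_corpus()] with
#'   an identity lemmatizer.
#' @export
generate_topic_corpus <- function(n_topics, docs_per_topic, vocab_size,
                                  tokens_per_doc, concentration = 0.1, seed = 1) {
  stopifnot_scalar_count(n_topics, "n_topics")
  stopifnot_scalar_count(docs_per_topic, "docs_per_topic")
  stopifnot_scalar_count(vocab_size, "vocab_size")
  stopifnot_scalar_count(tokens_per_doc, "tokens_per_doc")
  if (!is.numeric(concentration) || concentration <= 0)
    stop("`concentration` must be positive", call. = FALSE)
  vocab <- sprintf("w%05d", seq_len(vocab_size))
  with_seed(seed, {
    rows <- vector("list", n_topics * docs_per_topic)
    k <- 0L
    for (t in seq_len(n_topics)) {
      g <- stats::rgamma(vocab_size, shape = concentration)
      if (all(g == 0)) g <- rep(1, vocab_size)   # underflow guard at tiny concentration
      base <- g / sum(g)
      for (d in seq_len(docs_per_topic)) {
        k <- k + 1L
        toks <- sample(vocab, tokens_per_doc, replace = TRUE, prob = base)
        rows[[k]] <- data.frame(doc_id = sprintf("t%02d_d%03d", t, d),
                                text = paste(toks, collapse = " "),
                                topic = t, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

# Mean of the truncated discrete power law P(d) ~ d^-exponent on d_min..d_max.
truncated_powerlaw_mean <- function(exponent, d_min, d_max) {
  d <- d_min:d_max
  w <- d^(-exponent)
  sum(d * w) / sum(w)
}

# Smallest d_max whose truncated power-law mean reaches `target`; the mean is
# monotone increasing in d_max, so a bisection suffices.
solve_dmax <- function(exponent, d_min, target, n_nodes) {
  hi <- n_nodes - 1L
  if (truncated_powerlaw_mean(exponent, d_min, hi) < target)
    stop("target mean degree unreachable with d_max < n_nodes", call. = FALSE)
  lo <- d_min
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (truncated_powerlaw_mean(exponent, d_min, mid) >= target) hi <- mid
    else lo <- mid + 1L
  }
  hi
}

#' Generate a scale-free network with a truncated power-law degree sequence
#'
#' Stand-in for an empirically scale-free *semantic* network: node degrees
#' are sampled from \eqn{P(d) \propto d^{-\beta}} truncated to
#' `[d_min, d_max]`, and a simple graph is assembled by configuration-model
#' stub pairing; the largest connected component is returned. With shallow
#' exponents (the empirical slope for encyclopedic animal networks is near
#' 1.14) the upper cutoff `d_max` is the free knob controlling the mean
#' degree; pass `target_mean_degree` to have it solved numerically.
#'
#' By default the stubs are paired globally ([igraph::sample_degseq()]),
#' i.e. the classic configuration model: it realizes the degree sequence
#' exactly but is locally tree-like, with none of the topical clustering of
#' a similarity-thresholded network. With `clustered = TRUE` the generator
#' adds such clustering while keeping the same degree sequence: nodes are
#' grouped, in degree order, into topical blocks whose size tracks their
#' members' degrees (so block sizes inherit the power law), each stub
#' crosses blocks with probability `mixing`, and within-block degree
#' sequences are realized exactly as dense simple subgraphs while the
#' sparse between-block stubs are paired globally. Note that at shallow
#' exponents most connection mass lies on high-degree nodes whose blocks
#' are large and internally well mixed, so clustering leaves short-range
#' walk dynamics largely unchanged.
#'
#' @param n_nodes Number of nodes to sample degrees for (the returned
#'   component is usually slightly smaller).
#' @param exponent Degree-distribution exponent \eqn{\beta} (> 0).
#' @param d_min,d_max Degree truncation bounds; `d_max = NULL` requires
#'   `target_mean_degree` and solves for the cutoff.
#' @param target_mean_degree Desired mean of the degree distribution.
#' @param clustered Add topical near-clique structure (default `FALSE`:
#'   plain configuration model).
#' @param mixing Probability that a stub connects outside its block
#'   (default 0.02); ignored when `clustered = FALSE`.
#' @param seed Integer seed.
#' @param max_tries Attempts at simple-graph realization before failing.
#' @return A [semnet()] with `provenance = "synthetic"`; attributes `d_max`
#'   (cutoff used) and, for `clustered = TRUE`, a `community` vertex
#'   attribute on the graph recording block membership.
#' @export
generate_scalefree_network <- function(n_nodes, exponent = 1.14, d_min = 1,
                                       d_max = NULL, target_mean_degree = NULL,
                                       clustered = FALSE, mixing = 0.02,
                                       seed = 1, max_tries = 10) {
  stopifnot_scalar_count(n_nodes, "n_nodes", min = 2)
  if (!is.numeric(exponent) || exponent <= 0) stop("`exponent` must be > 0", call. = FALSE)
  d_min <- stopifnot_scalar_count(d_min, "d_min")
  if (!is.numeric(mixing) || mixing < 0 || mixing > 1)
    stop("`mixing` must be in [0, 1]", call. = FALSE)
  if (is.null(d_max)) {
    if (is.null(target_mean_degree))
      stop("supply either `d_max` or `target_mean_degree`", call. = FALSE)
    d_max <- solve_dmax(exponent, d_min, target_mean_degree, n_nodes)
  }
  d_max <- stopifnot_scalar_count(d_max, "d_max", min = d_min)
  if (d_max >= n_nodes) stop("`d_max` must be below `n_nodes`", call. = FALSE)

  support <- d_min:d_max
  w <- support^(-exponent)
  membership <- NULL
  g <- with_seed(seed, {
    degs <- support[sample.int(length(support), n_nodes, replace = TRUE, prob = w)]
    if (sum(degs) %% 2L == 1L) {
      if (length(support) == 1L)
        stop("n_nodes * d_min is odd: no even-sum degree sequence exists",
             call. = FALSE)
      repeat {                            # resample one degree to even the sum
        degs[1L] <- support[sample.int(length(support), 1L, prob = w)]
        if (sum(degs) %% 2L == 0L) break
      }
    }
    if (!isTRUE(clustered)) {
      res <- NULL
      methods <- rep(c("vl", "edge.switching.simple"), length.out = max_tries)
      for (try in seq_len(max_tries)) {
        res <- tryCatch(
          igraph::sample_degseq(degs, method = methods[try]),
          error = function(e) NULL)
        if (!is.null(res)) break
      }
      if (is.null(res))
        stop("configuration-model pairing failed after ", max_tries,
             " attempts; try a different degree spec", call. = FALSE)
      res
    } else {
      membership <- assortative_blocks(degs)
      block_configuration_graph(degs, membership, mixing)
    }
  })
  igraph::V(g)$name <- sprintf("n%05d", seq_len(n_nodes))
  if (!is.null(membership)) igraph::V(g)$community <- membership
  comp <- igraph::components(g)
  keep <- which(comp$membership == which.max(comp$csize))
  g <- igraph::induced_subgraph(g, keep)
  out <- semnet(igraph::simplify(g), provenance = "synthetic")
  attr(out, "d_max") <- d_max
  out
}

# Group nodes, in descending degree order, into blocks whose size is one
# more than the largest degree in the block — the topology of a thresholded
# similarity graph, where a node's connections are mostly its topical
# cluster and so its degree is roughly the cluster size minus one. Block
# sizes thereby inherit the power law of the degree sequence.
assortative_blocks <- function(degs) {
  n <- length(degs)
  ord <- order(degs, decreasing = TRUE)
  membership <- integer(n)
  b <- 0L
  i <- 1L
  while (i <= n) {
    b <- b + 1L
    size <- min(degs[ord[i]] + 1L, n - i + 1L)
    membership[ord[i:(i + size - 1L)]] <- b
    i <- i + size
  }
  membership
}

# Block-structured configuration model: each node's stubs cross blocks with
# probability `mixing`. Within-block degree sequences are realized exactly
# as simple graphs (within-block degrees are comparable to the block size,
# so erased pairing would lose a large share of edges to multi-edge
# collisions); the sparse between-block stubs are paired by erased
# matching, where collisions are negligible.
block_configuration_graph <- function(degs, membership, mixing) {
  n <- length(degs)
  between <- stats::rbinom(n, degs, mixing)
  within <- degs - between
  el <- vector("list", max(membership) + 1L)
  for (b in seq_len(max(membership))) {
    nodes <- which(membership == b)
    wd <- within[nodes]
    over <- wd > length(nodes) - 1L      # a simple graph caps within-degree
    between[nodes[over]] <- between[nodes[over]] + wd[over] - (length(nodes) - 1L)
    wd[over] <- length(nodes) - 1L
    if (sum(between[nodes]) == 0L && length(nodes) < n) {
      i <- which.max(wd)                 # keep every block attached to the rest
      if (wd[i] > 0L) {
        wd[i] <- wd[i] - 1L
        between[nodes[i]] <- between[nodes[i]] + 1L
      }
    }
    if (sum(wd) %% 2L == 1L) {           # move one stub across to even the block
      i <- which.max(wd)
      wd[i] <- wd[i] - 1L
      between[nodes[i]] <- between[nodes[i]] + 1L
    }
    # shave the largest entries until the block sequence is realizable
    while (!igraph::is_graphical(wd[wd > 0L])) {
      i <- which.max(wd)
      wd[i] <- wd[i] - 2L
      between[nodes[i]] <- between[nodes[i]] + 2L
    }
    pos <- which(wd > 0L)
    if (length(pos) < 2L) next
    sub <- NULL
    for (m in c("vl", "edge.switching.simple")) {
      # tiny blocks often have a unique realization; igraph warns, harmlessly
      sub <- tryCatch(suppressWarnings(igraph::sample_degseq(wd[pos], method = m)),
                      error = function(e) NULL)
      if (!is.null(sub)) break
    }
    if (is.null(sub))
      stop("within-block degree sequence not realizable as a simple graph",
           call. = FALSE)
    sel <- igraph::as_edgelist(sub, names = FALSE)
    el[[b]] <- cbind(nodes[pos][sel[, 1]], nodes[pos][sel[, 2]])
  }
  stubs <- rep(seq_len(n), between)
  stubs <- stubs[sample.int(length(stubs))]
  if (length(stubs) %% 2L == 1L) stubs <- stubs[-length(stubs)]
  el[[length(el)]] <- matrix(stubs, ncol = 2L, byrow = TRUE)
  el <- do.call(rbind, el)
  el <- el[el[, 1] != el[, 2], , drop = FALSE]
  g <- igraph::make_empty_graph(n, directed = FALSE)
  igraph::simplify(igraph::add_edges(g, as.vector(t(el))))
}

#' Generate a uniform random simple network
#'
#' Uniform G(N, M) graph: exactly `n_edges` connections assigned at random
#' among `n_nodes` nodes, avoiding duplicates and self-connections. Same
#' contract as [scramble_network()] but without a template network; used as
#' the size-matched control condition.
#'
#' @param n_nodes,n_edges Counts; `n_edges` must not exceed `n(n-1)/2`.
#' @param seed Integer seed.
#' @return A [semnet()] with `provenance = "synthetic"`.
#' @export
generate_random_network <- function(n_nodes, n_edges, seed = 1) {
  stopifnot_scalar_count(n_nodes, "n_nodes")
  stopifnot_scalar_count(n_edges, "n_edges", min = 0)
  if (n_edges > n_nodes * (n_nodes - 1) / 2)
    stop("`n_edges` exceeds the number of distinct node pairs", call. = FALSE)
  g <- with_seed(seed, igraph::sample_gnm(n_nodes, n_edges, directed = FALSE))
  igraph::V(g)$name <- sprintf("n%05d", seq_len(n_nodes))
  semnet(g, provenance = "synthetic")
}
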
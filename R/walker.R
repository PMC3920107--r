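#' Random walk with retrieval memory over a semantic network
#'
#' Simulates category recall as a walker that hops from node to node along
#' network connections, choosing a neighbor uniformly at random at each
#' step. On arriving at a node the walker retrieves it with probability
#' `retrieval_prob` if it has not been retrieved before, and with
#' probability 0 if it has (retrieved nodes are marked, so no item is ever
#' recalled twice). The walk starts at a uniformly random node of the
#' largest connected component, is confined to that component, and runs
#' until `n_retrievals` items have been retrieved or `max_steps` hops have
#' been taken.
#'
#' Two inter-response interval (IRI) measures are recorded per retrieval:
#' the *hop* measure — the number of hops since the previous retrieval,
#' including the hop landing on the retrieved node (so every IRI is >= 1) —
#' and the *cumulative-degree* measure — the sum of degrees of every node
#' arrived at in that span, the retrieved node included. The start node is
#' not eligible for retrieval before the first hop: retrieval happens upon
#' arrival.
#'
#' @param network A [semnet()].
#' @param retrieval_prob Probability of retrieving an unmarked node on
#'   arrival (default 0.10).
#' @param n_retrievals Number of retrievals to collect (default 400).
#' @param seed Integer seed.
#' @param max_steps Hop budget safeguard (default `10000 * n_retrievals`);
#'   if exhausted, a partial trace is returned with `truncated = TRUE` and
#'   a warning.
#' @return Object of class `walk_trace`: list with `retrieved_ids`,
#'   `hop_iris`, `degree_iris` (parallel vectors, one entry per retrieval),
#'   `steps_total`, `truncated`, `config`, and `network_provenance`.
#' @export
walk <- function(network, retrieval_prob = 0.1, n_retrievals = 400, seed = 1,
                 max_steps = 10000 * n_retrievals) {
  if (!inherits(network, "semnet")) stop("`network` must be a semnet", call. = FALSE)
  if (!is.numeric(retrieval_prob) || retrieval_prob <= 0 || retrieval_prob > 1)
    stop("`retrieval_prob` must be in (0, 1]", call. = FALSE)
  n_retrievals <- stopifnot_scalar_count(n_retrievals, "n_retrievals")
  max_steps <- stopifnot_scalar_count(max_steps, "max_steps", min = n_retrievals)

  g <- network$graph
  comp <- igraph::components(g)
  members <- which(comp$membership == which.max(comp$csize))
  if (length(members) < n_retrievals)
    stop(sprintf("largest component has %d nodes but %d retrievals were requested",
                 length(members), n_retrievals), call. = FALSE)
  sub <- igraph::induced_subgraph(g, members)   # degrees unchanged within a component
  ids <- igraph::V(sub)$name
  adj <- lapply(igraph::as_adj_list(sub), as.integer)
  deg <- as.integer(igraph::degree(sub))
  n <- length(ids)

  with_seed(seed, {
    cur <- sample.int(n, 1L)
    marked <- logical(n)
    retrieved <- integer(n_retrievals)
    hop_iris <- integer(n_retrievals)
    degree_iris <- numeric(n_retrievals)
    k <- 0L
    steps <- 0L
    span_hops <- 0L
    span_deg <- 0
    truncated <- FALSE
    while (k < n_retrievals) {
      if (steps >= max_steps) { truncated <- TRUE; break }
      nb <- adj[[cur]]
      cur <- nb[1L + floor(stats::runif(1) * length(nb))]
      steps <- steps + 1L
      span_hops <- span_hops + 1L
      span_deg <- span_deg + deg[cur]
      if (!marked[cur] && stats::runif(1) < retrieval_prob) {
        k <- k + 1L
        marked[cur] <- TRUE
        retrieved[k] <- cur
        hop_iris[k] <- span_hops
        degree_iris[k] <- span_deg
        span_hops <- 0L
        span_deg <- 0
      }
    }
    if (truncated) {
      warning(sprintf("walk truncated at %d steps with %d/%d retrievals",
                      steps, k, n_retrievals), call. = FALSE)
      retrieved <- retrieved[seq_len(k)]
      hop_iris <- hop_iris[seq_len(k)]
      degree_iris <- degree_iris[seq_len(k)]
    }
    structure(list(retrieved_ids = ids[retrieved],
                   hop_iris = hop_iris,
                   degree_iris = degree_iris,
                   steps_total = steps,
                   truncated = truncated,
                   config = list(retrieval_prob = retrieval_prob,
                                 n_retrievals = n_retrievals,
                                 seed = as.integer(seed),
                                 max_steps = max_steps),
                   network_provenance = network$provenance),
              class = "walk_trace")
  })
}

#' @export
print.walk_trace <- function(x, ...) {
  cat(sprintf("Walk trace (%s network): %d retrievals in %d hops%s\n",
              x$network_provenance, length(x$retrieved_ids), x$steps_total,
              if (x$truncated) " [TRUNCATED]" else ""))
  if (length(x$hop_iris))
    cat(sprintf("Hop IRIs: mean %.2f, max %d; degree IRIs: mean %.1f\n",
                mean(x$hop_iris), max(x$hop_iris), mean(x$degree_iris)))
  invisible(x)
}

#' Extract inter-response intervals from a trace or batch
#'
#' @param x A `walk_trace` or `walk_batch`.
#' @param measure `"hop"` (hops between retrievals) or `"degree"`
#'   (cumulative degree between retrievals).
#' @return For a trace, a numeric vector; for a batch, a list of vectors
#'   (one per run).
#' @export
iris <- function(x, measure = c("hop", "degree")) {
  measure <- match.arg(measure)
  pick <- function(tr) if (measure == "hop") as.numeric(tr$hop_iris) else tr$degree_iris
  if (inherits(x, "walk_trace")) return(pick(x))
  if (inherits(x, "walk_batch")) return(lapply(x, pick))
  stop("`x` must be a walk_trace or walk_batch", call. = FALSE)
}

#' Run a batch of independent walks
#'
#' Runs `n_runs` walks with per-run seeds derived deterministically from the
#' master seed (drawn as one block, so the batch is order-independent and a
#' single run can be reproduced in isolation with its derived seed).
#'
#' @inheritParams walk
#' @param n_runs Number of independent walks (default 20).
#' @param seed Master seed.
#' @return Object of class `walk_batch`: a list of `walk_trace` objects,
#'   with attribute `run_seeds`.
#' @export
run_batch <- function(network, retrieval_prob = 0.1, n_retrievals = 400,
                      n_runs = 20, seed = 1,
                      max_steps = 10000 * n_retrievals) {
  n_runs <- stopifnot_scalar_count(n_runs, "n_runs")
  run_seeds <- derive_seeds(seed, n_runs)
  traces <- lapply(seq_len(n_runs), function(i)
    walk(network, retrieval_prob = retrieval_prob, n_retrievals = n_retrievals,
         seed = run_seeds[i], max_steps = max_steps))
  structure(traces, run_seeds = run_seeds, class = "walk_batch")
}

#' @export
print.walk_batch <- function(x, ...) {
  cat(sprintf("Walk batch: %d runs of %d retrievals (%s network)\n",
              length(x), x[[1]]$config$n_retrievals, x[[1]]$network_provenance))
  invisible(x)
}
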
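#' Semantic network container
#'
#' Thin wrapper around an undirected simple [igraph::igraph] graph whose
#' vertices are named by concept/document id, tagged with the network's
#' provenance (`thresholded`, `scrambled`, or `synthetic`).
#'
#' @param graph An undirected igraph graph with named vertices, no self-loops
#'   and no multi-edges.
#' @param provenance How the network was obtained.
#' @return Object of class `semnet` with elements `graph` and `provenance`.
#' @export
semnet <- function(graph, provenance = c("thresholded", "scrambled", "synthetic")) {
  provenance <- match.arg(provenance)
  if (!igraph::is_igraph(graph)) stop("`graph` must be an igraph graph", call. = FALSE)
  if (igraph::is_directed(graph)) stop("network must be undirected", call. = FALSE)
  if (igraph::any_loop(graph) || igraph::any_multiple(graph))
    stop("network must be a simple graph (no loops or duplicate edges)", call. = FALSE)
  nm <- igraph::V(graph)$name
  if (is.null(nm) || anyDuplicated(nm))
    stop("vertices must carry unique names", call. = FALSE)
  structure(list(graph = graph, provenance = provenance), class = "semnet")
}

#' @export
print.semnet <- function(x, ...) {
  g <- x$graph
  n <- igraph::vcount(g); m <- igraph::ecount(g)
  cat(sprintf("Semantic network (%s): %d nodes, %d edges\n", x$provenance, n, m))
  if (n > 0) {
    comp <- igraph::components(g)
    cat(sprintf("Largest component: %d nodes (%d component(s)); mean degree %.2f\n",
                max(comp$csize), comp$no, 2 * m / n))
  }
  invisible(x)
}

#' Node ids of a semantic network
#' @param net A `semnet` object.
#' @return Character vector of node ids.
#' @export
semnet_nodes <- function(net) igraph::V(net$graph)$name

#' Edge list of a semantic network
#' @param net A `semnet` object.
#' @return Two-column character matrix (`source`, `target`), one row per
#'   undirected edge.
#' @export
semnet_edges <- function(net) {
  e <- igraph::as_edgelist(net$graph, names = TRUE)
  colnames(e) <- c("source", "target")
  e
}

#' Per-node degrees of a semantic network
#'
#' The degree multiset of the network: one count per node, named by node id.
#' Its mean equals 2E/N exactly and its sum equals twice the edge count.
#'
#' @param net A `semnet` object.
#' @return Named integer vector of node degrees.
#' @export
node_degrees <- function(net) {
  d <- igraph::degree(net$graph)
  storage.mode(d) <- "integer"
  d
}

is_similar_enough <- function(values, threshold, direction) {
  # Ties at the threshold are included: the threshold is a retention bound.
  if (direction == "lower_is_similar") values <= threshold else values >= threshold
}

largest_component_ids <- function(adj_ok, ids) {
  g <- igraph::graph_from_adjacency_matrix(adj_ok, mode = "undirected", diag = FALSE)
  comp <- igraph::components(g)
  which_comp <- which.max(comp$csize)
  ids[comp$membership == which_comp]
}

#' Coverage-targeted similarity threshold search
#'
#' Finds the strictest threshold (smallest divergence for
#' `lower_is_similar`, largest score for `higher_is_similar`) at which the
#' largest connected component of the thresholded graph covers at least
#' `ceiling(coverage * n)` nodes. Because relaxing the threshold only adds
#' edges, coverage is monotone in threshold leniency, so the search is a
#' bisection over the sorted unique off-diagonal values (component structure
#' only changes at observed values).
#'
#' @param matrix A [similarity_matrix()].
#' @param coverage Required fraction of nodes in the largest component
#'   (default 0.9; nodes outside it are discarded as unconnected outliers).
#' @return Object of class `threshold_result`: list with `threshold`,
#'   `coverage_achieved`, `retained_nodes`, `discarded_nodes`, `direction`.
#' @export
find_threshold <- function(matrix, coverage = 0.9) {
  if (!inherits(matrix, "similarity_matrix"))
    stop("`matrix` must be a similarity_matrix", call. = FALSE)
  if (!is.numeric(coverage) || length(coverage) != 1L || coverage <= 0 || coverage > 1)
    stop("`coverage` must be in (0, 1]", call. = FALSE)
  vals <- matrix$values
  ids <- rownames(vals)
  n <- length(ids)
  if (n < 2L) stop("similarity matrix must have at least 2 nodes", call. = FALSE)
  need <- ceiling(coverage * n)

  cand <- sort(unique(vals[upper.tri(vals)]))
  # order candidates strict -> lenient
  if (matrix$direction == "higher_is_similar") cand <- rev(cand)

  lcc_size <- function(th) {
    ok <- is_similar_enough(vals, th, matrix$direction)
    diag(ok) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(ok, mode = "undirected", diag = FALSE)
    max(igraph::components(g)$csize)
  }

  if (lcc_size(cand[length(cand)]) < need) {
    stop(sprintf(
      "coverage %.3f unreachable: maximum achievable coverage is %.3f even with all edges",
      coverage, lcc_size(cand[length(cand)]) / n), call. = FALSE)
  }
  lo <- 1L; hi <- length(cand)           # invariant: cand[hi] meets coverage
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (lcc_size(cand[mid]) >= need) hi <- mid else lo <- mid + 1L
  }
  th <- cand[hi]
  ok <- is_similar_enough(vals, th, matrix$direction)
  diag(ok) <- FALSE
  retained <- largest_component_ids(ok, ids)
  structure(list(threshold = th,
                 coverage_achieved = length(retained) / n,
                 retained_nodes = retained,
                 discarded_nodes = setdiff(ids, retained),
                 direction = matrix$direction),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("Threshold %.6g (%s): %d retained, %d discarded (coverage %.1f%%)\n",
              x$threshold, x$direction, length(x$retained_nodes),
              length(x$discarded_nodes), 100 * x$coverage_achieved))
  invisible(x)
}

#' Build a semantic network from a similarity matrix at a threshold
#'
#' Connects every retained pair whose score is at least as similar as the
#' threshold (`<=` for divergences, `>=` for similarities); all less-similar
#' connections and self-connections are discarded.
#'
#' @param matrix A [similarity_matrix()].
#' @param threshold Retention bound, in the matrix's units; pairs exactly at
#'   the threshold are connected.
#' @param retained Node ids to keep (default all); typically
#'   `find_threshold(...)$retained_nodes`.
#' @return A [semnet()] with `provenance = "thresholded"`.
#' @export
build_network <- function(matrix, threshold, retained = rownames(matrix$values)) {
  if (!inherits(matrix, "similarity_matrix"))
    stop("`matrix` must be a similarity_matrix", call. = FALSE)
  if (length(retained) == 0L) stop("`retained` must be non-empty", call. = FALSE)
  ids <- rownames(matrix$values)
  missing <- setdiff(retained, ids)
  if (length(missing))
    stop("retained nodes absent from matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  vals <- matrix$values[retained, retained, drop = FALSE]
  ok <- is_similar_enough(vals, threshold, matrix$direction)
  diag(ok) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(ok, mode = "undirected", diag = FALSE)
  semnet(g, provenance = "thresholded")
}

#' Scrambled control network
#'
#' Returns a control network with the same node set and the same number of
#' connections, but with connections assigned uniformly at random (avoiding
#' duplicates and self-connections) — an Erdős–Rényi G(N, M) twin that
#' destroys the semantic structure while matching size.
#'
#' @param network A `semnet` to size-match.
#' @param seed Integer seed; the same seed reproduces the same scramble.
#' @return A [semnet()] with `provenance = "scrambled"`.
#' @export
scramble_network <- function(network, seed) {
  n <- igraph::vcount(network$graph)
  m <- igraph::ecount(network$graph)
  g <- with_seed(seed, igraph::sample_gnm(n, m, directed = FALSE))
  igraph::V(g)$name <- semnet_nodes(network)
  semnet(g, provenance = "scrambled")
}
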
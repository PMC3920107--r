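#' Lag-based similarity gradient of recall sequences
#'
#' Tests whether items produced close together in a recall sequence are more
#' semantically similar than items produced far apart. Divergence values are
#' Z-normalized per sequence by the mean and standard deviation of all
#' pairwise values among the distinct items of that sequence, then averaged
#' over all ordered pairs exactly `lag` positions apart, for lags 1 to
#' `max_lag`. Multiple sequences (e.g. a `walk_batch`) are pooled after
#' per-sequence normalization.
#'
#' The stored quantity is the Z of the divergence: on a divergence matrix
#' (lower = more similar) a rising `mean_z` over lags is a similarity
#' gradient.
#'
#' @param sequences A character vector of node ids in retrieval order, a
#'   `walk_trace`, a `walk_batch`, or a list of id vectors.
#' @param matrix A [similarity_matrix()] covering every id used.
#' @param max_lag Largest positional distance examined (default 10).
#' @return Object of class `gradient_result`: data frame with columns
#'   `lag`, `mean_z`, `n_pairs`.
#' @export
similarity_gradient <- function(sequences, matrix, max_lag = 10) {
  max_lag <- stopifnot_scalar_count(max_lag, "max_lag")
  if (!inherits(matrix, "similarity_matrix"))
    stop("`matrix` must be a similarity_matrix", call. = FALSE)
  seqs <- as_sequences(sequences)
  vals <- matrix$values
  z_by_lag <- vector("list", max_lag)
  for (s in seqs) {
    if (length(s) < max_lag + 1L)
      stop("sequence length must exceed max_lag", call. = FALSE)
    missing <- setdiff(s, rownames(vals))
    if (length(missing))
      stop("sequence ids absent from matrix: ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    items <- unique(s)
    sub <- vals[items, items, drop = FALSE]
    pop <- sub[upper.tri(sub)]
    mu <- mean(pop)
    sd0 <- stats::sd(pop)
    if (!is.finite(sd0) || sd0 == 0)
      stop("degenerate similarity structure: all pairwise values equal", call. = FALSE)
    idx <- match(s, items)
    L <- length(s)
    for (lag in seq_len(max_lag)) {
      a <- idx[seq_len(L - lag)]
      b <- idx[seq_len(L - lag) + lag]
      z <- (sub[cbind(a, b)] - mu) / sd0
      z_by_lag[[lag]] <- c(z_by_lag[[lag]], z)
    }
  }
  structure(data.frame(lag = seq_len(max_lag),
                       mean_z = vapply(z_by_lag, mean, numeric(1)),
                       n_pairs = vapply(z_by_lag, length, integer(1))),
            class = c("gradient_result", "data.frame"))
}

as_sequences <- function(x) {
  if (inherits(x, "walk_trace")) return(list(x$retrieved_ids))
  if (inherits(x, "walk_batch")) return(lapply(x, function(tr) tr$retrieved_ids))
  if (is.character(x)) return(list(x))
  if (is.list(x) && all(vapply(x, is.character, logical(1)))) return(x)
  stop("`sequences` must be node ids, a walk_trace, walk_batch, or list of id vectors",
       call. = FALSE)
}

#' Minimal path lengths between node pairs
#'
#' Breadth-first shortest-path distance (fewest hops) for each requested
#' pair. Unreachable pairs are reported as `NA`, not infinite.
#'
#' @param network A [semnet()].
#' @param pairs Two-column character matrix (or data frame) of node ids.
#' @return Integer vector of path lengths, `NA` where no path exists.
#' @export
min_path_lengths <- function(network, pairs) {
  if (!inherits(network, "semnet")) stop("`network` must be a semnet", call. = FALSE)
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L) stop("`pairs` must have two columns", call. = FALSE)
  ids <- semnet_nodes(network)
  unknown <- setdiff(unique(c(pairs)), ids)
  if (length(unknown))
    stop("unknown node id(s): ", paste(utils::head(unknown, 5), collapse = ", "),
         call. = FALSE)
  from <- unique(pairs[, 1])
  d <- igraph::distances(network$graph, v = from, to = unique(pairs[, 2]))
  out <- d[cbind(match(pairs[, 1], rownames(d)), match(pairs[, 2], colnames(d)))]
  out[!is.finite(out)] <- NA
  as.integer(out)
}

#' One-way analysis of variance over groups
#'
#' Classical between/within mean-square F ratio with exact degrees of
#' freedom (`groups - 1`, `total - groups`) and the p-value from the F
#' distribution. Degenerate input in which all group means coincide yields
#' F = 0, p = 1.
#'
#' @param groups List of numeric vectors, at least 2 groups of at least 2
#'   values each.
#' @return List with `f`, `df1`, `df2`, `p`.
#' @export
anova_oneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("`groups` must be a list of at least 2 numeric groups", call. = FALSE)
  sizes <- lengths(groups)
  if (any(sizes < 2L)) stop("every group must contain at least 2 values", call. = FALSE)
  values <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(seq_along(groups), sizes))
  means <- vapply(groups, mean, numeric(1))
  df1 <- length(groups) - 1L
  df2 <- length(values) - length(groups)
  if (stats::var(means) == 0 || stats::var(values) == 0)
    return(list(f = 0, df1 = df1, df2 = df2, p = 1))
  ft <- stats::oneway.test(values ~ fac, var.equal = TRUE)
  list(f = unname(ft$statistic), df1 = unname(ft$parameter[1]),
       df2 = unname(ft$parameter[2]), p = unname(ft$p.value))
}

#' Effect of minimal path length on inter-response intervals
#'
#' For every pair of consecutive retrievals in the traces, computes the
#' minimal path length between the two retrieved nodes and groups the
#' log10-transformed IRIs by path length 1..`max_length` (longer paths are
#' excluded as rare). Pairs retrieved with no intervening search — hop IRI
#' of 1, i.e. the second item was retrieved on the very next arrival — are
#' excluded: they force path length 1 mechanically (an edge was just
#' traversed), which would couple IRI to distance even on a structureless
#' control, and they carry no information about how search time scales
#' with distance. The path-length effect is then tested with a one-way
#' ANOVA across length groups. With `aggregate = "run_mean"` (default) the
#' ANOVA observations are the per-run mean log IRIs at each length — so a
#' batch of 20 runs with lengths 1..4 gives df (3, 76); with
#' `aggregate = "pool"` every retrieval pair is an observation. Empty
#' length groups are dropped with a warning and the degrees of freedom
#' adjust accordingly.
#'
#' @param traces A `walk_trace`, `walk_batch`, or list of traces. Run-mean
#'   aggregation needs at least 2 traces; a single trace is pooled.
#' @param network The [semnet()] the traces were generated on.
#' @param max_length Largest path length analysed (default 4).
#' @param measure IRI measure to analyse, `"hop"` or `"degree"`.
#' @param aggregate `"run_mean"` (one observation per run and length) or
#'   `"pool"` (one observation per retrieval pair).
#' @return Object of class `pathlength_result`: list with `lengths`,
#'   `log_iris_by_length` (named list of log10 IRI groups), `group_means`,
#'   `f_stat`, `df_between`, `df_within`, `p_value`, `aggregate`.
#' @export
iri_by_pathlength <- function(traces, network, max_length = 4,
                              measure = c("hop", "degree"),
                              aggregate = c("run_mean", "pool")) {
  measure <- match.arg(measure)
  aggregate <- match.arg(aggregate)
  max_length <- stopifnot_scalar_count(max_length, "max_length", min = 2)
  if (inherits(traces, "walk_trace")) traces <- list(traces)
  if (length(traces) < 2L) aggregate <- "pool"
  lens <- seq_len(max_length)
  per_run <- lapply(traces, function(tr) {
    s <- tr$retrieved_ids
    if (length(s) < 2L) return(NULL)
    pl <- min_path_lengths(network, cbind(s[-length(s)], s[-1]))
    iri <- iris(tr, measure)[-1]
    keep <- !is.na(pl) & pl >= 1 & pl <= max_length & tr$hop_iris[-1] > 1L
    list(len = pl[keep], log_iri = log10(iri[keep]))
  })
  per_run <- per_run[!vapply(per_run, is.null, logical(1))]
  if (!length(per_run)) stop("no usable retrieval pairs", call. = FALSE)
  if (aggregate == "run_mean") {
    groups <- lapply(lens, function(L)
      unlist(lapply(per_run, function(r) {
        v <- r$log_iri[r$len == L]
        if (length(v)) mean(v) else NULL
      })))
  } else {
    all_len <- unlist(lapply(per_run, `[[`, "len"))
    all_iri <- unlist(lapply(per_run, `[[`, "log_iri"))
    groups <- lapply(lens, function(L) all_iri[all_len == L])
  }
  names(groups) <- lens
  empty <- lengths(groups) < 2L
  if (any(empty)) {
    warning("dropping path-length group(s) with fewer than 2 observations: ",
            paste(lens[empty], collapse = ", "), call. = FALSE)
    groups <- groups[!empty]
    lens <- lens[!empty]
  }
  av <- anova_oneway(groups)
  structure(list(lengths = lens,
                 log_iris_by_length = groups,
                 group_means = vapply(groups, mean, numeric(1)),
                 f_stat = av$f, df_between = av$df1, df_within = av$df2,
                 p_value = av$p, aggregate = aggregate),
            class = "pathlength_result")
}

#' @export
print.pathlength_result <- function(x, ...) {
  cat("Effect of minimal path length on log10 IRIs\n")
  for (i in seq_along(x$lengths))
    cat(sprintf("  length %d: n = %4d, mean log10 IRI = %.3f\n",
                x$lengths[i], length(x$log_iris_by_length[[i]]), x$group_means[i]))
  cat(sprintf("  F(%d, %d) = %.2f, p = %.3g\n",
              x$df_between, x$df_within, x$f_stat, x$p_value))
  invisible(x)
}
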
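#' Default English stopword list
#'
#' Function words removed before building lemma distributions. Shipped as a
#' plain-text file (one word per line) so it can be inspected or replaced;
#' pass any character vector to [normalize_corpus()] to override it.
#'
#' @return Character vector of lowercase stopwords.
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "semnetwalk")
  readLines(path, encoding = "UTF-8", warn = FALSE)
}

#' Default rule-based lemmatizer
#'
#' Lowercases a token and strips common English inflectional suffixes
#' (plural -s/-es/-ies, -ing, -ed) with light guards against over-stripping
#' short stems. Deliberately simple and deterministic: the pipeline treats
#' the lemmatizer as pluggable, so any `function(tokens) -> lemmas` mapping
#' each token to a non-empty string can be supplied instead.
#'
#' @param tokens Character vector of raw tokens.
#' @return Character vector of lemmas, same length as `tokens`.
#' @examples
#' default_lemmatizer(c("Cats", "foxes", "berries", "running", "jumped"))
#' @export
default_lemmatizer <- function(tokens) {
  x <- tolower(tokens)
  n <- nchar(x)
  # -ies -> -y (berries -> berry), only for stems long enough
  i <- n > 4 & endsWith(x, "ies")
  x[i] <- paste0(substr(x[i], 1L, n[i] - 3L), "y")
  n <- nchar(x)
  # -sses -> -ss, -xes/-ches/-shes -> drop "es"
  i <- n > 4 & (endsWith(x, "xes") | endsWith(x, "sses") |
                  endsWith(x, "ches") | endsWith(x, "shes") | endsWith(x, "zes"))
  x[i] <- substr(x[i], 1L, nchar(x[i]) - 2L)
  n <- nchar(x)
  # plain plural -s (not -ss, -us, -is)
  i <- n > 3 & endsWith(x, "s") & !endsWith(x, "ss") &
    !endsWith(x, "us") & !endsWith(x, "is")
  x[i] <- substr(x[i], 1L, nchar(x[i]) - 1L)
  n <- nchar(x)
  i <- n > 5 & endsWith(x, "ing")
  x[i] <- substr(x[i], 1L, nchar(x[i]) - 3L)
  n <- nchar(x)
  i <- n > 4 & endsWith(x, "ed")
  x[i] <- substr(x[i], 1L, nchar(x[i]) - 2L)
  x
}

tokenize <- function(text) {
  toks <- regmatches(text, gregexpr("[A-Za-z][A-Za-z0-9'-]*", text))[[1]]
  toks[nzchar(toks)]
}

#' Convert documents to lemma probability distributions
#'
#' Tokenizes each document, drops documents with fewer than `min_words`
#' content tokens (counted before stopword removal), removes stopwords,
#' lemmatizes the remainder, and normalizes lemma frequencies into a
#' probability distribution per document.
#'
#' @param documents Data frame with character columns `doc_id` (unique,
#'   non-empty) and `text`, e.g. from [read_corpus()] or
#'   [generate_topic_corpus()].
#' @param min_words Minimum content-token count for a document to be kept
#'   (default 500, matching the usual curation cutoff for encyclopedic text).
#' @param stopwords Character vector of words removed before counting lemmas
#'   (compared case-insensitively).
#' @param lemmatizer Function mapping a character vector of tokens to a same-
#'   length character vector of lemmas. Tokens whose lemma comes back empty
#'   or NA are skipped and counted.
#' @return Object of class `lemma_distributions`: a named list, one element
#'   per surviving document, each a named numeric vector of strictly positive
#'   probabilities summing to 1. Attributes `dropped` (ids of documents
#'   removed by the `min_words` filter or emptied by stopword removal) and
#'   `n_token_skips` (tokens the lemmatizer failed on) report the filtering.
#' @export
normalize_corpus <- function(documents, min_words = 500,
                             stopwords = default_stopwords(),
                             lemmatizer = default_lemmatizer) {
  stopifnot_scalar_count(min_words, "min_words", min = 1)
  if (!is.data.frame(documents) || !all(c("doc_id", "text") %in% names(documents)))
    stop("`documents` must be a data frame with columns doc_id and text", call. = FALSE)
  ids <- as.character(documents$doc_id)
  if (any(!nzchar(ids)) || anyNA(ids)) stop("doc_id entries must be non-empty", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate doc_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  stop_set <- tolower(stopwords)

  dropped <- character(0)
  skips <- 0L
  out <- vector("list", length(ids))
  names(out) <- ids
  for (k in seq_along(ids)) {
    toks <- tokenize(documents$text[[k]])
    if (length(toks) < min_words) {
      dropped <- c(dropped, ids[k])
      next
    }
    toks <- toks[!(tolower(toks) %in% stop_set)]
    if (length(toks) == 0L) {
      dropped <- c(dropped, ids[k])
      next
    }
    lem <- tryCatch(lemmatizer(toks), error = function(e) rep(NA_character_, length(toks)))
    bad <- is.na(lem) | !nzchar(lem)
    skips <- skips + sum(bad)
    lem <- lem[!bad]
    if (length(lem) == 0L) {
      dropped <- c(dropped, ids[k])
      next
    }
    tab <- table(lem)
    out[[k]] <- setNames(as.numeric(tab) / sum(tab), names(tab))
  }
  keep <- !vapply(out, is.null, logical(1))
  if (!any(keep)) stop("no usable documents after filtering", call. = FALSE)
  if (skips > 0L) message(skips, " token(s) skipped by the lemmatizer")
  structure(out[keep], dropped = dropped, n_token_skips = skips,
            class = "lemma_distributions")
}

#' @export
print.lemma_distributions <- function(x, ...) {
  cat("Lemma distributions for", length(x), "document(s)\n")
  dropped <- attr(x, "dropped")
  if (length(dropped)) cat("Dropped:", length(dropped), "document(s)\n")
  v <- sum(vapply(x, length, integer(1)))
  cat("Total lemma entries:", v, "\n")
  invisible(x)
}

check_distribution <- function(p, name = "p") {
  if (!is.numeric(p) || is.null(names(p)) || length(p) < 1L)
    stop(sprintf("`%s` must be a named numeric probability vector", name), call. = FALSE)
  if (any(p <= 0)) stop(sprintf("`%s` must have strictly positive masses", name), call. = FALSE)
  if (abs(sum(p) - 1) > 1e-9)
    stop(sprintf("`%s` probabilities must sum to 1", name), call. = FALSE)
  invisible(p)
}

#' Kullback-Leibler divergence between two lemma distributions
#'
#' \eqn{D(P \parallel Q) = \sum_i P(i) \log(P(i)/Q(i))}, taken over the
#' support of `p`. Where `q` assigns zero mass to a lemma carrying positive
#' `p` mass the divergence is `Inf` (returned, not raised): no smoothing is
#' applied, because the Jensen-Shannon construction never needs it.
#'
#' @param p,q Named numeric probability vectors (names are lemmas).
#' @param base Logarithm base; natural log by default.
#' @return Non-negative number (possibly `Inf`), 0 iff `p == q`.
#' @examples
#' p <- c(a = 0.5, b = 0.5); q <- c(a = 0.25, b = 0.75)
#' kl_divergence(p, q)            # 0.5*log(2) + 0.5*log(2/3)
#' @export
kl_divergence <- function(p, q, base = exp(1)) {
  check_distribution(p, "p"); check_distribution(q, "q")
  qm <- q[names(p)]
  if (anyNA(qm) || any(qm == 0)) return(Inf)
  sum(p * (log(p) - log(qm))) / log(base)
}

#' Jensen-Shannon divergence between two lemma distributions
#'
#' \eqn{JSD(P \parallel Q) = \tfrac12 D(P \parallel M) + \tfrac12
#' D(Q \parallel M)} with \eqn{M = \tfrac12 (P + Q)}, computed with base-2
#' logarithms so the value lies exactly in \[0, 1\]: 0 for identical
#' distributions, 1 for disjoint supports. Always finite because M covers
#' both supports. Lemmas present in only one document contribute through M.
#'
#' @inheritParams kl_divergence
#' @return Number in \[0, 1\]; symmetric in its arguments.
#' @export
jsd <- function(p, q) {
  check_distribution(p, "p"); check_distribution(q, "q")
  lemmas <- union(names(p), names(q))
  pv <- qv <- numeric(length(lemmas))
  pv[match(names(p), lemmas)] <- p
  qv[match(names(q), lemmas)] <- q
  m <- (pv + qv) / 2
  ip <- pv > 0
  iq <- qv > 0
  d <- 0.5 * sum(pv[ip] * (log2(pv[ip]) - log2(m[ip]))) +
    0.5 * sum(qv[iq] * (log2(qv[iq]) - log2(m[iq])))
  min(max(d, 0), 1)
}

#' Construct a similarity matrix object
#'
#' Symmetric container for pairwise divergence or similarity scores with an
#' explicit direction flag, so downstream thresholding knows whether lower
#' (JSD) or higher (cosine) values mean "more similar".
#'
#' @param values Symmetric numeric matrix with row/column names = doc ids.
#' @param direction `"lower_is_similar"` (divergences) or
#'   `"higher_is_similar"` (similarity scores).
#' @param measure Free-text label for the score (e.g. `"jsd"`, `"cosine"`).
#' @return Object of class `similarity_matrix`.
#' @export
similarity_matrix <- function(values, direction = c("lower_is_similar", "higher_is_similar"),
                              measure = "jsd") {
  direction <- match.arg(direction)
  if (!is.matrix(values) || nrow(values) != ncol(values))
    stop("`values` must be a square matrix", call. = FALSE)
  ids <- rownames(values)
  if (is.null(ids) || is.null(colnames(values)) || !identical(ids, colnames(values)))
    stop("`values` must carry identical row and column names (doc ids)", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate doc_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  if (max(abs(values - t(values))) > 1e-12)
    stop("`values` must be symmetric within 1e-12", call. = FALSE)
  structure(list(values = values, direction = direction, measure = measure),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("Similarity matrix: %d x %d (%s, %s)\n", nrow(x$values), ncol(x$values),
              x$measure, x$direction))
  off <- x$values[upper.tri(x$values)]
  cat(sprintf("Off-diagonal range: [%.4g, %.4g], median %.4g\n",
              min(off), max(off), stats::median(off)))
  invisible(x)
}

#' All pairwise Jensen-Shannon divergences for a corpus
#'
#' @param distributions A `lemma_distributions` object (or named list of
#'   probability vectors) with at least two documents and unique ids.
#' @return A [similarity_matrix()] of JSD values, `direction =
#'   "lower_is_similar"`, zero diagonal.
#' @export
pairwise_similarity <- function(distributions) {
  ids <- names(distributions)
  n <- length(distributions)
  if (n < 2L) stop("need at least 2 distributions", call. = FALSE)
  if (is.null(ids) || anyDuplicated(ids))
    stop("duplicate doc_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  vals <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      v <- jsd(distributions[[i]], distributions[[j]])
      vals[i, j] <- v
      vals[j, i] <- v
    }
  }
  similarity_matrix(vals, direction = "lower_is_similar", measure = "jsd")
}
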
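#' Read a corpus of documents
#'
#' Accepts either a directory of UTF-8 `.txt` files (the filename stem is
#' the doc id) or a JSONL file with one `{"doc_id": ..., "text": ...}`
#' object per line.
#'
#' @param path Directory or `.jsonl` file path.
#' @return Data frame with columns `doc_id` and `text`.
#' @export
read_corpus <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
    if (!length(files)) stop("no .txt files found in ", path, call. = FALSE)
    data.frame(
      doc_id = sub("\\.txt$", "", basename(files)),
      text = vapply(files, function(f)
        paste(readLines(f, encoding = "UTF-8", warn = FALSE), collapse = "\n"),
        character(1), USE.NAMES = FALSE),
      stringsAsFactors = FALSE)
  } else if (file.exists(path)) {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(lines)]
    recs <- lapply(lines, jsonlite::fromJSON)
    data.frame(doc_id = vapply(recs, `[[`, character(1), "doc_id"),
               text = vapply(recs, `[[`, character(1), "text"),
               stringsAsFactors = FALSE)
  } else stop("path not found: ", path, call. = FALSE)
}

#' Write/read lemma distributions as TSV
#'
#' Long format with header `doc_id<TAB>lemma<TAB>prob`.
#'
#' @param distributions A `lemma_distributions` object.
#' @param path TSV file path.
#' @return `write_distributions` returns `path` invisibly;
#'   `read_distributions` returns a `lemma_distributions` object.
#' @export
write_distributions <- function(distributions, path) {
  df <- do.call(rbind, lapply(names(distributions), function(id) {
    p <- distributions[[id]]
    data.frame(doc_id = id, lemma = names(p), prob = as.numeric(p),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distributions
#' @export
read_distributions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(split(df, factor(df$doc_id, levels = unique(df$doc_id))),
                function(d) setNames(d$prob, d$lemma))
  structure(out, dropped = character(0), n_token_skips = 0L,
            class = "lemma_distributions")
}

#' Write/read a similarity matrix as TSV plus a JSON sidecar
#'
#' The TSV carries doc ids as the first row and column; the sidecar
#' `<path>.json` records `direction`, `measure` and any parameters so the
#' orientation of the scores survives the round-trip.
#'
#' @param matrix A [similarity_matrix()].
#' @param path TSV file path (sidecar written to `paste0(path, ".json")`).
#' @param parameters Optional named list recorded in the sidecar.
#' @return `write_similarity` returns `path` invisibly; `read_similarity`
#'   returns a [similarity_matrix()].
#' @export
write_similarity <- function(matrix, path, parameters = list()) {
  utils::write.table(matrix$values, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  jsonlite::write_json(list(direction = matrix$direction, measure = matrix$measure,
                            parameters = parameters),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_similarity
#' @export
read_similarity <- function(path) {
  m <- as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  # re-symmetrize: text round-trips can perturb the last digit
  m <- (m + t(m)) / 2
  similarity_matrix(m, direction = meta$direction, measure = meta$measure)
}

#' Write/read a semantic network as plain text
#'
#' Writes `edges.tsv` (header `source<TAB>target`), `nodes.txt` (one id per
#' line, so isolated nodes survive the round-trip), and `meta.json`
#' (provenance) into a directory.
#'
#' @param network A [semnet()].
#' @param dir Output directory (created if absent).
#' @return `write_network` returns `dir` invisibly; `read_network` returns
#'   a [semnet()].
#' @export
write_network <- function(network, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  e <- semnet_edges(network)
  utils::write.table(as.data.frame(e), file.path(dir, "edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(semnet_nodes(network), file.path(dir, "nodes.txt"))
  jsonlite::write_json(list(provenance = network$provenance),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_network
#' @export
read_network <- function(dir) {
  nodes <- readLines(file.path(dir, "nodes.txt"))
  e <- utils::read.delim(file.path(dir, "edges.tsv"), stringsAsFactors = FALSE,
                         colClasses = "character")
  meta <- jsonlite::fromJSON(file.path(dir, "meta.json"))
  g <- igraph::graph_from_data_frame(e, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  semnet(g, provenance = meta$provenance)
}

#' Serialize a threshold-search result to JSON
#'
#' @param result A `threshold_result` from [find_threshold()].
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_threshold <- function(result, path) {
  jsonlite::write_json(
    list(threshold = result$threshold,
         coverage_achieved = result$coverage_achieved,
         n_retained = length(result$retained_nodes),
         n_discarded = length(result$discarded_nodes),
         discarded_ids = result$discarded_nodes),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write/read a walk trace as JSONL
#'
#' First line is a header object carrying the walk config and network
#' provenance; each subsequent line is one retrieval event
#' `{"k", "node", "hop_iri", "degree_iri"}`. The round-trip is lossless.
#'
#' @param trace A `walk_trace`.
#' @param path JSONL file path.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns a
#'   `walk_trace`.
#' @export
write_trace <- function(trace, path) {
  header <- jsonlite::toJSON(
    list(config = trace$config, network_provenance = trace$network_provenance,
         steps_total = trace$steps_total, truncated = trace$truncated),
    auto_unbox = TRUE, digits = NA)
  events <- vapply(seq_along(trace$retrieved_ids), function(k)
    as.character(jsonlite::toJSON(list(k = k, node = trace$retrieved_ids[k],
                                       hop_iri = trace$hop_iris[k],
                                       degree_iri = trace$degree_iris[k]),
                                  auto_unbox = TRUE, digits = NA)),
    character(1))
  writeLines(c(as.character(header), events), path)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path, warn = FALSE)
  header <- jsonlite::fromJSON(lines[1])
  ev <- lapply(lines[-1], jsonlite::fromJSON)
  structure(list(
    retrieved_ids = vapply(ev, function(e) as.character(e$node), character(1)),
    hop_iris = vapply(ev, function(e) as.integer(e$hop_iri), integer(1)),
    degree_iris = vapply(ev, function(e) as.numeric(e$degree_iri), numeric(1)),
    steps_total = as.integer(header$steps_total),
    truncated = isTRUE(header$truncated),
    config = header$config,
    network_provenance = header$network_provenance), class = "walk_trace")
}

#' Write a batch of traces to a directory
#'
#' One JSONL file per run (`run_01.jsonl`, ...).
#'
#' @param batch A `walk_batch`.
#' @param dir Output directory.
#' @return `write_traces` returns `dir` invisibly; `read_traces` returns a
#'   `walk_batch`.
#' @export
write_traces <- function(batch, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_along(batch))
    write_trace(batch[[i]], file.path(dir, sprintf("run_%02d.jsonl", i)))
  invisible(dir)
}

#' @rdname write_traces
#' @export
read_traces <- function(dir) {
  files <- sort(list.files(dir, pattern = "^run_.*\\.jsonl$", full.names = TRUE))
  if (!length(files)) stop("no trace files found in ", dir, call. = FALSE)
  structure(lapply(files, read_trace), class = "walk_batch")
}
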
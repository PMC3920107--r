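# Shared fixtures, built once per test session and memoized: the
# study-scale networks and walk batches are reused by several files.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, build(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# Size-matched uniform random control at study scale (5131 nodes, 175198
# edges) and its 20-run walk batch.
fx_control <- function() fixture("control", function()
  generate_random_network(5131, 175198, seed = 101))

fx_control_batch <- function() fixture("control_batch", function()
  run_batch(fx_control(), retrieval_prob = 0.1, n_retrievals = 400,
            n_runs = 20, seed = 2024))

# Scale-free stand-in at study conditions (exponent 1.14, mean degree near
# 68.3) and its 20-run batch.
fx_scalefree <- function() fixture("scalefree", function()
  generate_scalefree_network(5131, exponent = 1.14, d_min = 1,
                             target_mean_degree = 68.3, seed = 102))

fx_scalefree_batch <- function() fixture("scalefree_batch", function()
  run_batch(fx_scalefree(), retrieval_prob = 0.1, n_retrievals = 400,
            n_runs = 20, seed = 2025))

# Topic-clustered corpus pipeline fixture: 4 topics x 25 docs, pairwise
# JSD, 0.9-coverage threshold network, scrambled twin, and 20-run walk
# batches of 30 retrievals on each.
fx_topic <- function() fixture("topic", function() {
  docs <- generate_topic_corpus(n_topics = 4, docs_per_topic = 25,
                                vocab_size = 200, tokens_per_doc = 1000,
                                concentration = 0.1, seed = 7)
  dists <- normalize_corpus(docs, min_words = 10, stopwords = character(0),
                            lemmatizer = identity)
  sim <- pairwise_similarity(dists)
  th <- find_threshold(sim, coverage = 0.9)
  net <- build_network(sim, th$threshold, th$retained_nodes)
  scr <- scramble_network(net, seed = 77)
  list(docs = docs, dists = dists, sim = sim, th = th, net = net, scr = scr,
       topic = docs$topic[match(names(dists), docs$doc_id)],
       batch_net = run_batch(net, 0.1, 30, n_runs = 20, seed = 55),
       batch_scr = run_batch(scr, 0.1, 30, n_runs = 20, seed = 56))
})

# Small named semnet from an explicit edge list (plus optional isolates).
mk_semnet <- function(edges, nodes = NULL, provenance = "synthetic") {
  g <- igraph::graph_from_data_frame(
    as.data.frame(edges, stringsAsFactors = FALSE), directed = FALSE,
    vertices = if (is.null(nodes)) NULL else data.frame(name = nodes))
  semnet(g, provenance = provenance)
}
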
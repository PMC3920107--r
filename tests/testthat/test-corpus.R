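test_that("normalize_corpus turns token frequencies into probabilities", {
  docs <- data.frame(doc_id = "d1", text = "cats cat CAT dog")
  out <- normalize_corpus(docs, min_words = 1, stopwords = character(0))
  expect_equal(sort(names(out$d1)), c("cat", "dog"))
  expect_equal(unname(out$d1[["cat"]]), 0.75)
  expect_equal(unname(out$d1[["dog"]]), 0.25)
})

test_that("documents below the word cutoff are dropped and reported", {
  long <- paste(rep("lemma word token text", 150), collapse = " ")  # 600 tokens
  docs <- data.frame(doc_id = c("a", "b", "c"),
                     text = c(long, "just two", long))
  out <- normalize_corpus(docs, min_words = 500, stopwords = character(0))
  expect_length(out, 2)
  expect_equal(attr(out, "dropped"), "b")
  expect_setequal(names(out), c("a", "c"))
})

test_that("stopword-only and empty corpora fail with a clear message", {
  docs <- data.frame(doc_id = "only", text = "the and of the")
  expect_error(normalize_corpus(docs, min_words = 1), "no usable documents")
  expect_error(normalize_corpus(docs[0, , drop = FALSE], min_words = 1),
               "no usable documents")
})

test_that("probabilities sum to one for every document in a random corpus", {
  docs <- generate_topic_corpus(3, 5, 50, 300, seed = 11)
  out <- normalize_corpus(docs, min_words = 1, stopwords = character(0),
                          lemmatizer = identity)
  sums <- vapply(out, sum, numeric(1))
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(unlist(out) > 0))
})

test_that("lemmatizer failures skip tokens and duplicate ids are rejected", {
  flaky <- function(toks) ifelse(toks == "bad", NA_character_, tolower(toks))
  docs <- data.frame(doc_id = "d", text = "good bad good good")
  expect_message(out <- normalize_corpus(docs, min_words = 1,
                                         stopwords = character(0),
                                         lemmatizer = flaky),
                 "skipped")
  expect_equal(attr(out, "n_token_skips"), 1L)
  expect_equal(unname(out$d[["good"]]), 1)

  dup <- data.frame(doc_id = c("x", "x"), text = c("one two", "three four"))
  expect_error(normalize_corpus(dup, min_words = 1), "duplicate")
})

test_that("kl_divergence matches direct summation and handles zero mass", {
  p <- c(a = 0.5, b = 0.5)
  q <- c(a = 0.25, b = 0.75)
  expect_equal(kl_divergence(p, q), 0.5 * log(2) + 0.5 * log(2 / 3),
               tolerance = 1e-12)
  expect_equal(kl_divergence(p, p), 0)
  # q missing a lemma carrying p-mass -> infinite divergence, not an error
  expect_identical(kl_divergence(c(a = 1), c(b = 1)), Inf)
  # single-term sum in the requested base
  expect_equal(kl_divergence(c(a = 1), c(a = 0.5, b = 0.5), base = 2), 1)
  expect_equal(kl_divergence(c(a = 1), c(a = 0.5, b = 0.5)), log(2))
})

test_that("jsd matches its definition on hand-checked cases", {
  p <- c(a = 1)
  q <- c(a = 0.5, b = 0.5)
  # brute force: M = (0.75, 0.25)
  expect_equal(jsd(p, q), oracle_jsd(c(1, 0), c(0.5, 0.5)), tolerance = 1e-12)
  expect_equal(jsd(p, q), 0.311278, tolerance = 1e-6)
  expect_equal(jsd(q, q), 0)
  expect_equal(jsd(c(a = 0.5, b = 0.5), c(x = 0.3, y = 0.7)), 1)
})

test_that("jsd is symmetric, bounded, and agrees with brute force", {
  set.seed(42)
  for (i in 1:25) {
    n1 <- sample(2:10, 1)
    n2 <- sample(2:10, 1)
    vocab <- letters[1:10]
    p <- random_distribution(n1, sample(vocab, n1))
    q <- random_distribution(n2, sample(vocab, n2))
    d <- jsd(p, q)
    expect_equal(d, jsd(q, p), tolerance = 1e-12)
    expect_gte(d, 0)
    expect_lte(d, 1)
    # align both on the vocabulary union and compare to the oracle
    lem <- union(names(p), names(q))
    pv <- qv <- numeric(length(lem))
    pv[match(names(p), lem)] <- p
    qv[match(names(q), lem)] <- q
    expect_equal(d, oracle_jsd(pv, qv), tolerance = 1e-12)
    if (setequal(names(p), names(q)))
      expect_lt(d, 1)
  }
  # zero iff equal, one iff disjoint supports
  p <- random_distribution(5)
  expect_equal(jsd(p, p), 0)
  q <- setNames(p, LETTERS[1:5])
  expect_equal(jsd(p, q), 1)
})

test_that("pairwise_similarity fills a symmetric lower-is-similar matrix", {
  set.seed(9)
  dists <- list(a = random_distribution(4), b = random_distribution(6),
                c = random_distribution(5))
  sim <- pairwise_similarity(dists)
  expect_s3_class(sim, "similarity_matrix")
  expect_equal(sim$direction, "lower_is_similar")
  expect_equal(diag(sim$values), c(a = 0, b = 0, c = 0))
  expect_equal(sim$values, t(sim$values))
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(sim$values[i, j], jsd(dists[[i]], dists[[j]]))
  # identical distributions give an all-zero matrix
  two <- list(x = dists$a, y = dists$a)
  expect_true(all(pairwise_similarity(two)$values == 0))
  expect_error(pairwise_similarity(setNames(dists, c("a", "a", "b"))),
               "duplicate")
})
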
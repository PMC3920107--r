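two_cluster_matrix <- function() {
  # 6 items in two tight clusters: within-JSD 0.1, between-JSD 0.9
  ids <- c("a1", "a2", "a3", "b1", "b2", "b3")
  v <- matrix(0.9, 6, 6, dimnames = list(ids, ids))
  v[1:3, 1:3] <- 0.1
  v[4:6, 4:6] <- 0.1
  diag(v) <- 0
  similarity_matrix(v, "lower_is_similar")
}

test_that("similarity gradient rises with lag on a clustered sequence", {
  sim <- two_cluster_matrix()
  seq6 <- c("a1", "a2", "a3", "b1", "b2", "b3")
  gr <- similarity_gradient(seq6, sim, max_lag = 5)
  expect_equal(gr$lag, 1:5)
  expect_equal(gr$n_pairs, 5:1)
  expect_lt(gr$mean_z[1], gr$mean_z[5])
  # direct enumeration: lag-5 pair (a1,b3) is between-cluster, z > 0
  pop <- sim$values[seq6, seq6][upper.tri(diag(6))]
  z <- (0.9 - mean(pop)) / stats::sd(pop)
  expect_equal(gr$mean_z[5], z, tolerance = 1e-12)
})

test_that("degenerate similarity structure is rejected", {
  ids <- c("x", "y", "z", "w")
  v <- matrix(0.5, 4, 4, dimnames = list(ids, ids)); diag(v) <- 0
  sim <- similarity_matrix(v, "lower_is_similar")
  expect_error(similarity_gradient(ids, sim, max_lag = 2), "degenerate")
  expect_error(similarity_gradient(c(ids, "nope"), sim, max_lag = 2), "absent")
  expect_error(similarity_gradient(ids[1:2], sim, max_lag = 3),
               "exceed max_lag")
})

test_that("walker traces show a similarity gradient only with structure", {
  fx <- fx_topic()
  gr <- similarity_gradient(fx$batch_net, fx$sim, max_lag = 10)
  expect_gt(stats::cor(gr$lag, gr$mean_z, method = "spearman"), 0)
  expect_gt(gr$mean_z[10] - gr$mean_z[1], 0.2)
  expect_true(all(diff(gr$n_pairs) <= 0))

  flat <- similarity_gradient(fx$batch_scr, fx$sim, max_lag = 10)
  expect_lt(max(abs(flat$mean_z)), 0.1)
})

test_that("min_path_lengths equals breadth-first truth and Floyd-Warshall", {
  path4 <- mk_semnet(cbind(c("p1", "p2", "p3"), c("p2", "p3", "p4")))
  expect_equal(min_path_lengths(path4, cbind("p1", "p4")), 3L)
  expect_equal(min_path_lengths(path4, cbind("p2", "p3")), 1L)
  expect_error(min_path_lengths(path4, cbind("p1", "nope")), "unknown")

  # unreachable pairs come back NA
  two <- mk_semnet(cbind("a", "b"), nodes = c("a", "b", "c"))
  expect_true(is.na(min_path_lengths(two, cbind("a", "c"))))

  set.seed(13)
  for (i in 1:5) {
    n <- sample(10:50, 1)
    g <- igraph::sample_gnp(n, 0.1)
    igraph::V(g)$name <- sprintf("v%02d", 1:n)
    net <- semnet(g, "synthetic")
    d <- oracle_floyd_warshall(as.matrix(igraph::as_adjacency_matrix(g)))
    pairs <- cbind(sprintf("v%02d", sample(n, 20, replace = TRUE)),
                   sprintf("v%02d", sample(n, 20, replace = TRUE)))
    got <- min_path_lengths(net, pairs)
    want <- d[cbind(match(pairs[, 1], sprintf("v%02d", 1:n)),
                    match(pairs[, 2], sprintf("v%02d", 1:n)))]
    want[!is.finite(want)] <- NA
    expect_equal(got, as.integer(want))
  }
})

test_that("anova_oneway reproduces hand-computed and oracle F statistics", {
  av <- anova_oneway(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  expect_equal(av$f, 3)           # SSB = 6, SSW = 6, df (2, 6)
  expect_equal(av$df1, 2)
  expect_equal(av$df2, 6)
  expect_equal(av$p, stats::pf(3, 2, 6, lower.tail = FALSE))

  set.seed(21)
  groups <- lapply(1:4, function(i) stats::rnorm(sample(5:12, 1), mean = i / 2))
  av <- anova_oneway(groups)
  want <- oracle_anova(groups)
  expect_equal(av$f, want$f, tolerance = 1e-6)
  expect_equal(av$p, want$p, tolerance = 1e-6)
  expect_equal(av$df1, want$df1)
  expect_equal(av$df2, want$df2)

  ident <- anova_oneway(list(c(2, 2, 2), c(2, 2, 2)))
  expect_equal(ident$f, 0)
  expect_equal(ident$p, 1)
  expect_error(anova_oneway(list(1:3, 4)), "at least 2 values")
})

test_that("anova_oneway is invariant to shifts and scalings", {
  set.seed(22)
  groups <- lapply(1:3, function(i) stats::rnorm(8, mean = i))
  f0 <- anova_oneway(groups)$f
  expect_equal(anova_oneway(lapply(groups, `+`, 100))$f, f0, tolerance = 1e-9)
  expect_equal(anova_oneway(lapply(groups, `*`, 7))$f, f0, tolerance = 1e-9)
})

test_that("path length predicts IRIs on structured networks only", {
  fx <- fx_topic()
  ps <- suppressWarnings(iri_by_pathlength(fx$batch_net, fx$net))
  expect_lt(ps$p_value, 0.01)
  expect_gt(stats::cor(seq_along(ps$group_means), ps$group_means,
                       method = "spearman"), 0)
  expect_equal(ps$df_between, length(ps$lengths) - 1)
  expect_equal(ps$df_within,
               sum(lengths(ps$log_iris_by_length)) - length(ps$lengths))

  pc <- suppressWarnings(iri_by_pathlength(fx$batch_scr, fx$scr))
  expect_gt(pc$p_value, 0.05)
})

test_that("run-mean aggregation gives the run-by-length degrees of freedom", {
  fx <- fx_topic()
  ps <- suppressWarnings(iri_by_pathlength(fx$batch_net, fx$net))
  # 20 runs contributing a mean per observed length
  expect_equal(ps$aggregate, "run_mean")
  expect_true(all(lengths(ps$log_iris_by_length) <= 20))
  pooled <- suppressWarnings(iri_by_pathlength(fx$batch_net, fx$net,
                                               aggregate = "pool"))
  expect_gt(sum(lengths(pooled$log_iris_by_length)),
            sum(lengths(ps$log_iris_by_length)))
})
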
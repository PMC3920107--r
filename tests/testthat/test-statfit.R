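test_that("log_bin produces normalized densities on geometric bins", {
  set.seed(1)
  v <- rpareto(2000, 2.2)
  b <- log_bin(v, 5)
  expect_equal(sum(b$densities * diff(b$bin_edges)), 1, tolerance = 1e-9)
  expect_true(all(diff(b$bin_edges) > 0))
  expect_equal(length(b$bin_edges), length(b$densities) + 1)
  expect_equal(sum(b$counts), 2000)

  # all values identical: one occupied bin integrating to 1
  b1 <- log_bin(rep(3.7, 10), 5)
  expect_equal(sum(b1$counts > 0), 1)
  expect_equal(sum(b1$densities * diff(b1$bin_edges)), 1)

  expect_error(log_bin(c(1, -2, 3)), "index 2")
})

test_that("log-binned Pareto samples show their exponent as a slope", {
  set.seed(2)
  v <- rpareto(10000, 2)
  sl <- slope_estimate(log_bin(v, 5))
  expect_equal(sl$slope, -2, tolerance = 0.15)
  expect_gt(sl$r_squared, 0.9)
})

test_that("slope_estimate is exact on analytic power-law densities", {
  edges <- 10^(seq(0, 3, by = 0.2))
  centers <- sqrt(edges[-length(edges)] * edges[-1])
  dens <- centers^(-1.5)
  dens <- dens / sum(dens * diff(edges))
  b <- structure(list(bin_edges = edges, densities = dens,
                      counts = rep(1L, length(dens))),
                 class = "binned_distribution")
  sl <- slope_estimate(b)
  expect_equal(sl$slope, -1.5, tolerance = 1e-6)
  expect_equal(sl$r_squared, 1, tolerance = 1e-9)

  # flat densities give slope 0
  b$densities <- rep(1 / sum(diff(edges)), length(dens))
  expect_equal(slope_estimate(b)$slope, 0, tolerance = 1e-9)

  b$counts <- c(1L, 1L, rep(0L, length(dens) - 2))
  b$densities[3:length(dens)] <- 0
  expect_error(slope_estimate(b), "3 occupied")
})

test_that("slope is scale-equivariant", {
  set.seed(3)
  v <- rpareto(5000, 1.8)
  s1 <- slope_estimate(log_bin(v, 5))
  s2 <- slope_estimate(log_bin(v * 37, 5))
  expect_equal(s1$slope, s2$slope, tolerance = 0.02)
  expect_false(isTRUE(all.equal(s1$intercept, s2$intercept)))
})

test_that("closed-form MLEs match hand arithmetic", {
  f <- fit_iri(c(1, 2, 3, 1, 2, 3, 1, 2, 3, 1, 2, 3), "exponential")
  expect_equal(unname(coef(f)[["rate"]]), 0.5)

  x <- rep(c(1, 2, 4, 8), 3)
  f <- fit_iri(x, "pareto", xmin = 1)
  expect_equal(unname(coef(f)[["alpha"]]), 1 + 4 / (6 * log(2)),
               tolerance = 1e-12)

  # AIC identity: 2k - 2 logL with k = 1 (xmin fixed)
  expect_equal(f$aic, 2 - 2 * f$log_likelihood)
  expect_equal(AIC(f), f$aic)
})

test_that("each family recovers its parameters at n = 5000", {
  set.seed(4)
  v <- stats::rlnorm(5000, meanlog = 1, sdlog = 0.5)
  f <- fit_iri(v, "lognormal")
  expect_equal(unname(coef(f)[["meanlog"]]), 1, tolerance = 0.05)
  expect_equal(unname(coef(f)[["sdlog"]]), 0.5, tolerance = 0.1)

  v <- stats::rexp(5000, rate = 2)
  expect_equal(unname(coef(fit_iri(v, "exponential"))[["rate"]]), 2,
               tolerance = 0.05)

  v <- rpareto(5000, 2.5)
  expect_equal(unname(coef(fit_iri(v, "pareto", xmin = 1))[["alpha"]]), 2.5,
               tolerance = 0.05)
})

test_that("the Pareto MLE matches a grid-search maximizer", {
  set.seed(5)
  for (i in 1:10) {
    x <- rpareto(20, stats::runif(1, 1.5, 4))
    a_closed <- unname(coef(fit_iri(x, "pareto", xmin = min(x)))[["alpha"]])
    a_grid <- oracle_pareto_grid(x, min(x))
    expect_equal(a_closed, a_grid, tolerance = 1e-3)
  }
})

test_that("degenerate samples fail loudly where the family is undefined", {
  same <- rep(5, 20)
  expect_error(fit_iri(same, "lognormal"), "degenerate")
  expect_error(fit_iri(same, "pareto"), "degenerate")
  expect_error(fit_iri(1:5, "exponential"), "at least 10")
})

test_that("model selection ranks the generating family first", {
  wins <- function(gen, family, n_seeds = 100) {
    mean(vapply(seq_len(n_seeds), function(s) {
      set.seed(s)
      best_family(select_iri_model(gen(1000))) == family
    }, logical(1)))
  }
  expect_gte(wins(function(n) stats::rexp(n, 1), "exponential"), 0.95)
  expect_gte(wins(function(n) stats::rlnorm(n, 0, 1), "lognormal"), 0.95)
})

test_that("Akaike weights are normalized, ordered, and shift-invariant", {
  set.seed(6)
  v <- stats::rlnorm(500, 1, 0.7)
  ms <- select_iri_model(v)
  w <- vapply(ms, function(f) f$akaike_weight, numeric(1))
  aic <- vapply(ms, function(f) f$aic, numeric(1))
  expect_equal(sum(w), 1, tolerance = 1e-9)
  expect_true(all(diff(aic) >= 0))
  expect_true(all(diff(w) <= 1e-12))
  # adding a constant to every AIC leaves deltas, hence weights, unchanged
  delta <- (aic + 123) - min(aic + 123)
  expect_equal(exp(-delta / 2) / sum(exp(-delta / 2)), w, tolerance = 1e-12)

  one <- select_iri_model(v, families = "lognormal")
  expect_equal(one[[1]]$akaike_weight, 1)
  expect_equal(best_family(one), "lognormal")
})

test_that("node_degrees reports the exact degree multiset", {
  g <- igraph::make_full_graph(3)
  igraph::V(g)$name <- c("a", "b", "c")
  expect_equal(sort(as.integer(node_degrees(semnet(g, "synthetic")))),
               c(2, 2, 2))
  net <- fx_control()
  deg <- node_degrees(net)
  expect_equal(mean(deg), 68.29, tolerance = 1e-3)
  expect_equal(stats::sd(deg), 8.22, tolerance = 0.05)
})
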
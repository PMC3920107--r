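#' Logarithmic binning of positive values
#'
#' Histograms heavy-tailed data with geometrically spaced bin edges spanning
#' `[min(values), max(values)]` at a fixed number of bins per decade, and
#' normalizes counts to densities (probability per unit x), so that
#' `sum(density * width) == 1`. Empty bins are retained with density 0.
#'
#' @param values Strictly positive numeric values.
#' @param bins_per_decade Bins per factor-of-10 of x (default 5).
#' @return Object of class `binned_distribution`: list with `bin_edges`
#'   (length one more than the bins), `densities`, and `counts`.
#' @export
log_bin <- function(values, bins_per_decade = 5) {
  bins_per_decade <- stopifnot_scalar_count(bins_per_decade, "bins_per_decade")
  if (length(values) < 1L) stop("need at least one value", call. = FALSE)
  bad <- which(!is.finite(values) | values <= 0)
  if (length(bad))
    stop("nonpositive or non-finite value at index ", bad[1], call. = FALSE)
  lo <- min(values); hi <- max(values)
  n_bins <- if (hi > lo) ceiling(log10(hi / lo) * bins_per_decade) else 1L
  edges <- lo * 10^((0:n_bins) / bins_per_decade)
  edges[1] <- lo                       # guard rounding at the ends
  if (edges[n_bins + 1L] < hi) edges[n_bins + 1L] <- hi
  idx <- findInterval(values, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  widths <- diff(edges)
  structure(list(bin_edges = edges,
                 densities = counts / (length(values) * widths),
                 counts = counts),
            class = "binned_distribution")
}

#' @export
print.binned_distribution <- function(x, ...) {
  cat(sprintf("Log-binned distribution: %d bins on [%.4g, %.4g], %d occupied\n",
              length(x$counts), x$bin_edges[1], x$bin_edges[length(x$bin_edges)],
              sum(x$counts > 0)))
  invisible(x)
}

#' Power-law slope of a log-binned distribution
#'
#' Ordinary least squares of `log10(density)` on `log10(bin center)`
#' (geometric centers), excluding empty bins. For a power-law density
#' \eqn{P(x) \propto x^{-\beta}} the fitted slope is \eqn{-\beta}, so the
#' exponent is estimated by the negative of the slope.
#'
#' @param binned A [log_bin()] result with at least 3 occupied bins.
#' @return List with `slope`, `intercept`, `r_squared`.
#' @export
slope_estimate <- function(binned) {
  if (!inherits(binned, "binned_distribution"))
    stop("`binned` must be a binned_distribution", call. = FALSE)
  occ <- binned$densities > 0
  if (sum(occ) < 3L) stop("need at least 3 occupied bins", call. = FALSE)
  e <- binned$bin_edges
  centers <- sqrt(e[-length(e)] * e[-1])[occ]
  y <- log10(binned$densities[occ])
  x <- log10(centers)
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       # exact power laws fit perfectly; the lm summary warning is expected
       r_squared = suppressWarnings(summary(fit)$r.squared))
}

# family -> number of free parameters (Pareto's xmin is fixed, not estimated)
iri_family_df <- c(pareto = 1L, lognormal = 2L, exponential = 1L)

#' Maximum-likelihood fit of one heavy-tail candidate family
#'
#' Fits one of the three candidate IRI distribution families by maximum
#' likelihood under a continuous density (intervals are treated as
#' continuous times even when measured in integer hops):
#' \describe{
#'   \item{exponential}{\eqn{\lambda e^{-\lambda (x - x_{min})}} with rate
#'     \eqn{\hat\lambda = 1/\overline{(x - x_{min})}}; the default
#'     `xmin = 0` is the classic unshifted fit with support from 0.}
#'   \item{lognormal}{\eqn{\hat\mu = \mathrm{mean}(\log x)},
#'     \eqn{\hat\sigma^2 = \mathrm{mean}((\log x - \hat\mu)^2)} (MLE
#'     denominator n); fitted on raw values, `xmin` ignored.}
#'   \item{pareto}{\eqn{P(x) \propto x^{-\alpha}} for \eqn{x \ge x_{min}};
#'     \eqn{\hat\alpha = 1 + n / \sum \log(x_i/x_{min})} with `xmin` fixed
#'     at the minimum observed value unless given explicitly.}
#' }
#'
#' @param values Positive numeric values (at least 10).
#' @param family `"pareto"`, `"lognormal"`, or `"exponential"`.
#' @param xmin Lower support bound: for Pareto, `NULL` (default) uses
#'   `min(values)`; for exponential, the location offset (default 0, i.e.
#'   no shift).
#' @return Object of class `iri_fit` with elements `family`, `params`
#'   (named vector), `log_likelihood`, `aic`, `n_obs`. Has `coef`,
#'   `logLik` and `AIC` methods.
#' @export
fit_iri <- function(values, family = c("pareto", "lognormal", "exponential"),
                    xmin = NULL) {
  family <- match.arg(family)
  values <- as.numeric(values)
  if (length(values) < 10L) stop("need at least 10 values to fit", call. = FALSE)
  if (any(!is.finite(values) | values <= 0))
    stop("all values must be positive and finite", call. = FALSE)
  n <- length(values)
  if (family == "exponential") {
    if (is.null(xmin)) xmin <- 0
    if (any(values < xmin))
      stop("all values must be >= xmin for a shifted exponential fit", call. = FALSE)
    offset <- mean(values) - xmin
    if (offset == 0)
      stop("degenerate data: all values equal xmin, exponential rate diverges",
           call. = FALSE)
    rate <- 1 / offset
    ll <- n * log(rate) - rate * sum(values - xmin)
    params <- c(rate = rate, xmin = xmin)
  } else if (family == "lognormal") {
    lx <- log(values)
    mu <- mean(lx)
    s2 <- mean((lx - mu)^2)
    if (s2 == 0)
      stop("degenerate data: all values equal, lognormal sd is 0", call. = FALSE)
    s <- sqrt(s2)
    ll <- sum(stats::dlnorm(values, meanlog = mu, sdlog = s, log = TRUE))
    params <- c(meanlog = mu, sdlog = s)
  } else {
    if (is.null(xmin)) xmin <- min(values)
    if (any(values < xmin)) stop("all values must be >= xmin for a Pareto fit",
                                 call. = FALSE)
    slog <- sum(log(values / xmin))
    if (slog == 0)
      stop("degenerate data: all values equal xmin, Pareto exponent diverges",
           call. = FALSE)
    alpha <- 1 + n / slog
    # density p(x) = (alpha-1)/xmin * (x/xmin)^(-alpha), x >= xmin
    ll <- n * log((alpha - 1) / xmin) - alpha * slog
    params <- c(alpha = alpha, xmin = xmin)
  }
  k <- iri_family_df[[family]]
  structure(list(family = family, params = params, log_likelihood = ll,
                 aic = 2 * k - 2 * ll, n_obs = n),
            class = "iri_fit")
}

#' @export
print.iri_fit <- function(x, ...) {
  cat(sprintf("IRI fit: %s(%s), n = %d\n", x$family,
              paste(sprintf("%s = %.4g", names(x$params), x$params), collapse = ", "),
              x$n_obs))
  cat(sprintf("logLik = %.3f, AIC = %.3f\n", x$log_likelihood, x$aic))
  invisible(x)
}

#' @export
coef.iri_fit <- function(object, ...) object$params

#' @export
logLik.iri_fit <- function(object, ...) {
  structure(object$log_likelihood, df = iri_family_df[[object$family]],
            nobs = object$n_obs, class = "logLik")
}

#' Multi-model inference over candidate IRI families
#'
#' Fits each candidate family by maximum likelihood, ranks by AIC
#' (\eqn{2k - 2\log L}) ascending, and attaches Akaike weights
#' \eqn{w_i = \exp(-\Delta_i/2) / \sum_j \exp(-\Delta_j/2)}. AIC ties
#' (below 1e-9) are broken toward the family with fewer parameters.
#'
#' The comparison uses a common lower support bound `xmin` (the minimum
#' observed value by default): the Pareto is fitted above it and the
#' exponential is fitted with its location shifted to it, as is standard
#' when candidate tail models are compared on data bounded away from zero;
#' the lognormal is fitted on the raw values in its standard form.
#'
#' @inheritParams fit_iri
#' @param xmin Common lower support bound; `NULL` (default) uses
#'   `min(values)`.
#' @param families Candidate set, a subset of
#'   `c("pareto", "lognormal", "exponential")`.
#' @return Object of class `iri_model_set`: list of `iri_fit` objects, best
#'   first, each with an `akaike_weight` element added.
#' @export
select_iri_model <- function(values,
                             families = c("pareto", "lognormal", "exponential"),
                             xmin = NULL) {
  families <- match.arg(families, c("pareto", "lognormal", "exponential"),
                        several.ok = TRUE)
  if (length(families) == 0L) stop("`families` must be non-empty", call. = FALSE)
  if (is.null(xmin)) xmin <- min(values)
  fits <- lapply(families, function(f) fit_iri(values, family = f, xmin = xmin))
  aics <- vapply(fits, function(f) f$aic, numeric(1))
  ks <- vapply(fits, function(f) iri_family_df[[f$family]], integer(1))
  ord <- order(aics + ks * 1e-9)        # epsilon tie-break toward fewer params
  fits <- fits[ord]
  aics <- aics[ord]
  delta <- aics - min(aics)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  for (i in seq_along(fits)) fits[[i]]$akaike_weight <- w[i]
  structure(fits, class = "iri_model_set")
}

#' @export
print.iri_model_set <- function(x, ...) {
  cat("Multi-model inference over", length(x), "famil(ies):\n")
  for (f in x)
    cat(sprintf("  %-11s AIC = %10.2f  weight = %.3f  (%s)\n", f$family, f$aic,
                f$akaike_weight,
                paste(sprintf("%s=%.3g", names(f$params), f$params), collapse = ", ")))
  invisible(x)
}

#' Best-fitting family of a model set
#' @param x An `iri_model_set`.
#' @return The name of the lowest-AIC family.
#' @export
best_family <- function(x) {
  if (!inherits(x, "iri_model_set")) stop("`x` must be an iri_model_set", call. = FALSE)
  x[[1]]$family
}

#' Per-run best-fit family counts for a walk batch
#'
#' Applies [select_iri_model()] to the IRIs of every run in a batch and
#' tabulates which family wins by AIC — the summary used to compare
#' structured networks against scrambled controls.
#'
#' @param batch A `walk_batch`.
#' @param measure IRI measure, `"hop"` or `"degree"`.
#' @inheritParams select_iri_model
#' @return Named integer vector of winning-run counts, one entry per family.
#' @export
best_family_counts <- function(batch, measure = c("hop", "degree"),
                               families = c("pareto", "lognormal", "exponential")) {
  measure <- match.arg(measure)
  wins <- vapply(iris(batch, measure),
                 function(v) best_family(select_iri_model(v, families = families)),
                 character(1))
  out <- setNames(integer(length(families)), families)
  tab <- table(wins)
  out[names(tab)] <- as.integer(tab)
  out
}
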
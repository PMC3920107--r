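---
title: "Semantic networks, memory-bearing walks, and inter-response intervals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semantic networks, memory-bearing walks, and inter-response intervals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

semnetwalk models category recall — naming as many members of a semantic
category as possible — as a random walk with retrieval memory over a
semantic network, and provides the statistical machinery to relate the
network's structure to the timing of recalls. This vignette explains the
models, the parameter choices, and the numerical and design decisions, so
that a user can judge what the package's results do and do not show.

## From documents to a semantic network

Each concept is represented by a document (for animal knowledge, an
encyclopedic page per species). A document becomes a probability
distribution over lemmas: tokens are extracted, documents with fewer than
`min_words` content tokens are dropped (default 500, the usual curation
cutoff for encyclopedic text), function words are removed (a plain-text
stopword list ships with the package and can be replaced), and the
remaining tokens are lemmatized and counted. The lemmatizer is pluggable;
the shipped default lowercases and strips common inflectional suffixes
with light guards. Exact token-level agreement with any specific NLP
toolkit is deliberately not a goal — the downstream statistics depend on
distributional overlap, not on individual lemma choices.

Two distributions $P$ and $Q$ are compared by the Jensen–Shannon
divergence,

$$\mathrm{JSD}(P \| Q) = \tfrac12 D(P \| M) + \tfrac12 D(Q \| M), \qquad
M = \tfrac12 (P + Q),$$

with $D$ the Kullback–Leibler divergence $\sum_i P(i) \log P(i)/Q(i)$.
JSD is computed with base-2 logarithms so that it is exactly bounded in
$[0, 1]$ — 0 for identical distributions, 1 for disjoint supports; only
that base gives the unit bound. `kl_divergence()` keeps an explicit
`base` argument (natural log by default) since KL itself is
base-conventional. JSD needs no smoothing: $M$ covers both supports, so
it is finite for any pair; lemmas present in only one document contribute
through $M$. `kl_divergence()` returns `Inf`, documented, when the
second distribution misses mass — we do not smooth, because the package
never divides by unseen-lemma mass on the JSD path.

The network is built by thresholding the pairwise JSD matrix:
`find_threshold()` searches for the *strictest* threshold whose largest
connected component covers at least a requested fraction of the nodes
(default 0.9), and `build_network()` connects every retained pair at
least as similar as the threshold (ties included — the threshold is a
retention bound). Because relaxing a threshold only adds edges, coverage
is monotone in leniency and the search is a bisection over the sorted
unique observed values; the component structure cannot change between
observed values, so nothing finer is needed. Nodes outside the covering
component are discarded, mirroring the curation step in which the
unconnected tail of a corpus (lists, anomalous entries) is dropped.
"Covers" is interpreted as membership in the largest connected component;
for outcomes where the component spans the requested fraction this
coincides with the spanning-connectivity reading, and the component
reading extends naturally to the discarded remainder.

A *scrambled control* (`scramble_network()`) keeps the node set and edge
count but redraws the edges uniformly at random without duplicates — an
Erdős–Rényi $G(N, M)$ twin. Uniform resampling rather than
degree-preserving rewiring is deliberate: the control should destroy
*all* structure beyond size, and its binomial-shaped degree distribution
(mean $2E/N$, small SD) is itself one of the package's checked
quantities. On the study-scale control (5131 nodes, 175,198 edges) the
degree mean is 68.29 exactly and the SD concentrates near 8.2.

## The walker

`walk()` simulates recall: a walker starts at a uniformly random node of
the largest component, hops to a uniformly random neighbor each step,
and, on arriving at a node never retrieved before, retrieves it with
probability `retrieval_prob` (default 0.10). Retrieved nodes are marked
and never retrieved again — the model's only memory. The walk ends after
`n_retrievals` retrievals (default 400) or a step budget
(`max_steps`, default 10,000 per requested retrieval; exhaustion returns
a flagged partial trace, never a silent one).

Two inter-response interval (IRI) measures are recorded per retrieval:
the **hop** measure — hops since the previous retrieval, *including* the
hop landing on the retrieved node — and the **cumulative-degree**
measure — the summed degrees of every node arrived at in the span,
retrieved node included, counting revisited nodes each time. Two
conventions had to be fixed where the verbal model is ambiguous: the
start node is not eligible for retrieval before the first hop (retrieval
happens *upon arrival*), and the landing hop is counted inside the IRI,
so every hop IRI is at least 1. On a $d$-regular graph the two measures
coincide up to the factor $d$, which is one of the test suite's exact
checks.

Batches (`run_batch()`, default 20 runs) derive per-run seeds from the
master seed in a single block, so runs are order-independent and any
single run can be reproduced in isolation.

## Fitting the interval distributions

`log_bin()` histograms positive values into geometric bins (default 5
per decade), normalized to densities so they integrate to 1; empty bins
are kept at density 0 but excluded from regression. `slope_estimate()`
fits `log10(density)` on `log10(geometric bin center)` by ordinary least
squares; for a power-law density the exponent is the negative slope.

`fit_iri()` fits one of three candidate families by maximum likelihood
under continuous densities — exponential, lognormal, and Pareto
($P(x) \propto x^{-\alpha}$ above a fixed $x_{min}$, the Hill estimator
$\hat\alpha = 1 + n / \sum \log(x_i/x_{min})$). Continuous likelihoods
are used although hop IRIs are integers: intervals are modeled as times,
and the candidate set is compared on a common footing; this is a known
approximation, sharpest at small values. `select_iri_model()` performs
the multi-model comparison: AIC ($2k - 2\log L$; $k$ = 1, 2, 1) with
Akaike weights $e^{-\Delta_i/2}/\sum_j e^{-\Delta_j/2}$, ties broken
toward fewer parameters. AICc changes nothing at $n \ge 400$ and is not
used.

One fitting convention matters enough to spell out. In the comparison,
the exponential is fitted *above the common lower support bound*
($\lambda e^{-\lambda(x - x_{min})}$ with $x_{min}$ the minimum observed
value, as in the bounded fits standard in the foraging model-selection
literature), while the lognormal keeps its standard unshifted form. For
data bounded away from zero — hop IRIs are never below 1 — the unshifted
exponential wastes probability mass below the support and loses to the
lognormal *even on geometric data*, turning the comparison into an
artifact of the support mismatch; the bounded form removes that
artifact. Standalone `fit_iri()` keeps the classic unshifted default
(`xmin = 0`), so `fit_iri(x, "exponential")` is the textbook
$\hat\lambda = 1/\bar x$.

## Structure–dynamics analyses

`similarity_gradient()` asks whether items recalled close together are
more similar: divergences are Z-normalized per sequence by the mean and
SD of *all* pairwise values among that sequence's distinct items (not
all network pairs — the normalization population is what the sequence
could have produced), then averaged over ordered pairs at each lag 1–10.
The stored quantity is the Z of the divergence, so a *rising* curve is a
similarity gradient; a plotting layer may negate it for a similarity
axis.

`iri_by_pathlength()` relates IRIs to network distance: for consecutive
retrieval pairs, the minimal path length (breadth-first distance) is
computed, log10 IRIs are grouped by length 1–4 (longer paths are rare
and excluded), and a one-way ANOVA tests the effect. Two design points:

* Pairs retrieved with *no intervening search* (hop IRI = 1) are
  excluded. Such pairs force path length 1 mechanically — an edge was
  just traversed — and with them included even a structureless control
  shows an enormous "effect". They carry no information about how search
  time scales with distance.
* The default ANOVA observations are per-run mean log IRIs at each
  length (`aggregate = "run_mean"`), giving the run-by-length degrees of
  freedom (20 runs × 4 lengths → df 3, 76); pooling every pair is
  available as an option. Run means are the natural unit when runs are
  the independent replicates.

`anova_oneway()` wraps the classical equal-variance F test and defines
the all-groups-identical degenerate case as $F = 0$, $p = 1$.

## Synthetic data: what it emulates and what it does not

Three generators make every stage testable without any corpus download.

`generate_topic_corpus()` emulates topic clustering: each topic draws a
base lemma distribution from a symmetric Dirichlet (concentration 0.1 by
default — sharply distinct topics; large concentrations collapse all
topics toward uniform), and each document samples its tokens i.i.d. from
its topic. Documents are single-topic by design — the simplest structure
that yields the within-topic < between-topic JSD contrast the pipeline
presumes. Real text differs in every linguistic respect (no Zipfian
vocabulary, no syntax, no length variation); none of that matters for
the divergence-thresholding machinery under test.

`generate_random_network()` is the uniform $G(N, M)$ simple graph — the
control condition and the degree-spread reference.

`generate_scalefree_network()` draws degrees from
$P(d) \propto d^{-\beta}$ truncated to $[d_{min}, d_{max}]$ and realizes
them as a simple graph by configuration-model pairing (the
Viger–Latapy realization, with an edge-switching fallback), returning
the largest component. A truncated power law is used instead of
preferential attachment because a shallow exponent ($\beta \approx
1.14$) and a fixed mean degree (68.3) cannot be jointly reached by
standard preferential attachment; the upper cutoff $d_{max}$ is the free
knob and is solved numerically from the target mean (for the default
conditions, $d_{max} \approx 723$). An optional `clustered = TRUE`
variant keeps the same degree sequence but groups nodes into topical
blocks whose sizes track their members' degrees, with a small fraction
(`mixing`, default 0.02) of block-crossing stubs — emulating the
near-clique topology of a thresholded similarity graph (on matched
specs the clustering coefficient roughly triples).

### A limitation worth stating plainly

The scale-free stand-in reproduces the *degree* statistics of an
empirical semantic network, not its full topology, and the difference is
visible in the walk dynamics. At a shallow exponent with a fixed mean
degree, the great bulk of connection mass lies on high-degree nodes: any
simple graph at these conditions is hub-dominated and well mixed at the
walk's timescale, and a walk that retrieves 400 of 5131 nodes never
comes close to exhausting its neighborhood. Its hop IRIs are therefore
only mildly overdispersed, and the bounded-exponential fit wins the
model comparison on *both* the stand-in and the random control. Once the
walk genuinely depletes the network — the test suite checks this with
2000-retrieval walks on the same stand-in — the IRI distribution
broadens dramatically and the lognormal wins, which is the behavior
reported for empirical semantic networks. Passing
the package's synthetic tests therefore shows the machinery is correct;
it does not show that a truncated-power-law configuration model is an
adequate surrogate for a real semantic network's recall dynamics, and at
the study-scale conditions it demonstrably is not. For the same reason
the path-length and gradient property tests run on thresholded
topic-corpus networks (genuine distance structure, distances 1–6) rather
than on the stand-in (diameter ≈ 3).

The analysis fixtures use 4 topics × 25 documents, a 0.9-coverage
threshold network of ~100 nodes, and 20 walks of 30 retrievals — a 30%
retrieval fraction, larger than the study protocol's 8% so that
sequences stay long enough for lag-10 gradients while keeping the
analyses inside a few seconds.

## Numerical choices and degenerate inputs

* Threshold ties are *included*; bisection runs over observed values
  only.
* `log_bin()` extends the last bin edge to cover the maximum exactly;
  an all-equal sample occupies a single bin whose density integrates
  to 1.
* Lognormal fits use the MLE (denominator $n$) variance; all-equal
  samples are rejected for lognormal and Pareto (the estimators
  diverge) with explicit messages.
* `similarity_gradient()` rejects sequences whose pairwise values have
  zero SD ("degenerate similarity structure").
* Walks on disconnected networks are confined to the largest component,
  with an upfront size check against `n_retrievals`.
* All randomness is drawn under locally scoped seeds (`with_seed()`),
  so library calls never disturb the caller's RNG state, and every
  batch, generator, and pipeline run is bit-reproducible from its seed.

## Known limitations

* Continuous likelihoods on integer hop counts (see above).
* No Pareto $x_{min}$ optimization; $x_{min}$ is the minimum observed
  value unless supplied.
* The comparison set is exactly {Pareto, lognormal, exponential}; no
  truncated power law, no bootstrap goodness-of-fit.
* The shipped lemmatizer is rule-based English; corpus-identical
  replication of any specific toolkit's lemmas is out of scope.
* Participant-level human data are not modeled; IRIs here are model
  units (hops or summed degrees), never seconds.
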
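---
title: "Consensus-encoded clinical event vectors: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus-encoded clinical event vectors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccevector)
```

## The problem

Clinical decision support for operational concerns — documentation
prioritization, resource utilization, revenue cycle — works from per-encounter
feature vectors of counts, ratios and flags. Which of those features *matter*,
and how much, is expert knowledge that is usually elicited on n-point Likert
scales. Likert responses are ordinal: taking their arithmetic mean and
treating the result as an interval quantity is statistically unsound, the
ranks are not equidistant across raters, and a mean hides whether the panel
agreed at all. `ccevector` encodes a rating sample into continuous, interval
statistics of *agreement* that can sit next to quantitative features in one
machine-learning-ready vector.

## The consensus statistics

For a sample of `q` ratings on an ordered scale with rank values
$x_1 < \dots < x_n$, rank probabilities $p_i$ (the observed frequencies),
mean $\mu = \sum_i p_i x_i$ and scale width $d_x = x_n - x_1$, the consensus
statistic is

$$\mathrm{Cns} = 1 + \sum_{i=1}^{n} p_i \log_2\!\left(1 - \frac{|x_i - \mu|}{d_x}\right).$$

It is 1 when the panel is unanimous and 0 for an even split across the two
extreme ranks; its complement (dissension) measures disagreement. Replacing
the mean by a chosen reference rank $r$ and doubling the width to keep the
logarithm bounded gives the strength of consensus at $r$:

$$\mathrm{SoC}(r) = 1 + \sum_{i=1}^{n} p_i \log_2\!\left(1 - \frac{|x_i - r|}{2\,d_x}\right),$$

which answers "how strongly does the panel agree that the answer is $r$?".
Evaluating it at every rank yields the SoC profile, the qualitative block of
a feature vector: a 5-point scale turns one rated question into five
continuous values that retain both the location and the shape of the panel's
response distribution.

```{r}
panel <- list(
  polarized  = response_sample(c(5, 0, 0, 0, 5)),
  uniform    = response_sample(c(2, 2, 2, 2, 2)),
  peaked     = response_sample(c(0, 3, 4, 3, 0)),
  unanimous  = response_sample(c(0, 0, 10, 0, 0))
)
knitr::kable(consensus_report(panel), digits = 3)
```

All four samples share the same mean (3), yet the statistics separate them
cleanly — exactly the failure mode of mean-based Likert aggregation.

Conventions that matter:

* $d_x$ is the **full scale width** (4 for a 1–5 scale), not the observed
  response range. With this choice every strength-of-consensus value in the
  worked table above reproduces to 3 decimals.
* The standard deviation reported alongside is the **population** form
  (divisor $q$); the sample form would not reproduce the reference values.
* Terms with $p_i = 0$ contribute exactly 0 — no logarithm is evaluated, so
  the extremes never produce `log(0)`.
* Statistics are computed in double precision and reported unrounded;
  3-decimal rounding (round-half-even, R's `round()`) is applied only in
  displayed tables.
* SoC lies in $[0, 1]$. The lower boundary is attainable: a panel unanimous
  on one extreme, evaluated at the opposite extreme, gives
  $1 + \log_2(1/2) = 0$ exactly. It equals 1 only when all mass sits on the
  reference rank.
* Both statistics depend on the sample only through its counts and are
  invariant under affine relabeling of the rank values, since
  $|x_i - \mu| / d_x$ is scale-free.

## Sample-size weighting

Twenty experts agreeing is not two hundred experts agreeing. The consensus
statistics are blind to $q$, so an optional Gompertz sigmoid weight

$$w(q) = e^{-\alpha e^{-\beta q}}$$

multiplies them. With the defaults $\alpha = 0.725$, $\beta = 0.05$ the
weight is `r round(exp(-0.725), 3)` at $q = 0$ (roughly a 50% penalty) and
at least 0.995 from $q = 100$ on, i.e. large panels are effectively
unpenalized. Both parameters are exposed (`gompertz_params()`) because the
penalty schedule is a context choice, not a constant of the method; the
defaults implement the "half weight at zero, no penalty above 100" rule.
Note $e^{-0.725} \approx 0.484$, so the floor is a 51.6% penalty rather than
exactly 50% — the stated rule is approximate by construction. Per-rank
weights (`apply_rank_weights()`) multiply the SoC profile element-wise with
no renormalization: unit weights are the identity, zero weights mask ranks,
and any published profile value can be recovered by dividing the weight back
out.

## The encounter vector

A `cce_schema()` fixes an ordered, versioned layout mixing the two metric
kinds; `build_cce_vector()` fills it per encounter. The demonstration schema
(`fig_schema()`) carries three quantitative metrics (consult count, LOS/PLOS
ratio, readmission flag) and four rated metrics on the 5-point scale, giving
$3 + 4 \times 5 = 23$ dimensions. Quantitative values come first, then the
SoC blocks, both in schema order, ranks ascending; the layout is written
into a JSON sidecar next to every serialized cohort. A schema flag can
append the scalar consensus after a metric's SoC block (off by default, which
keeps the 23-dimension layout).

Cohorts are min-max normalized per dimension to $[0, 1]$ before distance
work. Dimensions constant across the cohort map to 0.5: a constant
contributes nothing to any distance, and centring it avoids manufacturing
fake extremes. The normalization statistics are frozen and reused for new
encounters (`apply_normalization()`), because a reference-based scorer must
place one new vector at a time on the training cohort's coordinate scale;
out-of-range values are deliberately not clipped, so a novel encounter keeps
its full distance. Binary flags are carried as 0/1 and survive min-max
unchanged.

## Reference-based similarity

`cce_reference()` freezes a reference vector (an artificial ideal, the
cohort mean, or an actual encounter — none is privileged), the normalization
state, and the population covariance of the normalized cohort;
`predict()` then ranks encounters by ascending distance with ties broken
lexicographically by encounter id, so rankings are deterministic and
independent of input order. Four distances are available: Euclidean, cosine,
Canberra (sensitive to small differences near zero) and Mahalanobis
$\sqrt{(x-y)^\top S^{-1} (x-y)}$, which accounts for correlated dimensions
and reduces to Euclidean when $S = I$.

SoC blocks are highly correlated by construction (symmetric samples give
palindromic profiles), so a near-singular $S$ is the expected case, not a
pathology. The covariance is therefore ridge-regularized as
$S + \lambda\,\overline{\mathrm{diag}(S)}\,I$ with relative $\lambda =
10^{-6}$ by default; $\lambda = 0$ disables it, in which case a singular
matrix is a hard error. An encounter used as the reference is excluded from
the covariance estimate.

## KNN and k-means

Both learners are implemented from first principles at desk scale, because
their tie-breaking and initialization rules are part of the tool's
determinism contract rather than details to inherit:

* `knn_classify()` votes among the $k$ nearest training vectors; vote ties
  break first by smaller mean neighbour distance, then by lexicographically
  smaller class id.
* `kmeans_cce()` runs Lloyd iterations from a greedy farthest-point
  initialization (random first centre under an explicit seed, each next
  centre the point farthest from those chosen). Convergence is an assignment
  fixed point; the within-cluster sum of squares is asserted non-increasing
  at every iteration; empty clusters are re-seeded at the point farthest
  from its centroid; `max_iter` defaults to 300. Results are bit-reproducible
  given the seed.

Both default to Euclidean distance on normalized vectors and accept a
covariance for Mahalanobis geometry, implemented as a whitening transform.
`extract_dimensions()` projects a cohort onto chosen metrics (whole SoC
blocks for rated metrics) for within-vector cluster analysis. Tests check
`kmeans_cce` against exhaustive enumeration of all partitions on cohorts of
up to 8 points and against `stats::kmeans` on separated data.

## The synthetic generator

Real encounter data cannot be shipped, so every pipeline stage is exercised
on synthetic inputs with known structure.

*Surveys.* Rank probabilities follow a Gaussian kernel over the rank values,
$p_i \propto \exp(-c\,(x_i - \mathrm{mode})^2/2)$ with concentration $c$.
This family was chosen over a rounded continuous Gaussian because it hits
both calibration anchors exactly: $c = 0$ is *exactly* uniform (a rounded
Gaussian never is, detectably so at large $q$), and $c \to \infty$ is
unanimity at the mode; empirical consensus increases monotonically along the
way.

*Cohorts.* `cohort_scenario()` plants cluster structure over the
demonstration schema: Poisson consult counts, log-normal LOS/PLOS ratios
(default within-cluster `sdlog` 0.05, cluster medians 0.7 / 1.3 / 2.4 —
at least ten within-cluster standard deviations apart on the log scale),
Bernoulli readmission, and per-encounter patient-experience surveys centred
on a per-cluster modal rank (panel size 25, concentration 3). The three
importance metrics are rated once per cohort by a shared panel, mirroring a
single expert elicitation, and are therefore constant dimensions. Balanced,
shuffled labels are returned for recovery testing. The generator emulates
separation and mixed metric kinds; it makes no claim of epidemiological
realism — real LOS distributions, correlated comorbidities and rater drift
are all absent, so recovery results demonstrate the pipeline's correctness,
not clinical performance.

## Problem sizes and verification

The test suite works at desk scale, chosen to keep the full run under a
minute while covering the property space: exhaustive oracle comparison over
all 5-rank count vectors with $q \le 6$ (461 compositions, tolerance
1e-12), 1000 random pairs for the Mahalanobis/Euclidean identity (1e-10),
random full-rank transforms for Mahalanobis invariance (1e-8), cohorts of
5–8 points for the exhaustive k-means oracle, and 24–40 encounters over 20
seeds for cluster recovery (adjusted Rand $\ge$ 0.99 against planted
labels).

## Known limitations

* The consensus statistics assume a single shared scale per metric; mixed
  scale widths within one metric are rejected, not reconciled.
* Min-max normalization is outlier-sensitive; a single extreme encounter
  compresses everyone else. Robust scaling is out of scope here.
* The Gompertz weight treats $q$ as exchangeable rater count; it cannot
  express rater quality or correlation between raters.
* Trend analysis over time-sequenced encounter vectors is out of scope; the
  containers store one time point.
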
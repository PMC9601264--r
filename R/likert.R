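#' Ordered rating scale
#'
#' An n-point ordinal scale with numeric rank values and display labels,
#' e.g. a 5-point importance scale 1 = unimportant (U) through
#' 5 = very important (V). The scale width `d_x = max(values) - min(values)`
#' is the normalizing constant of the consensus statistics.
#'
#' @param values Strictly increasing numeric rank values (length >= 2).
#' @param labels Display labels, one per rank; defaults to the values.
#' @return An object of class `rank_scale` with elements `values`, `labels`
#'   and `width`.
#' @examples
#' likert5()
#' rank_scale(1:7)
#' @export
rank_scale <- function(values = 1:5, labels = NULL) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("invalid scale: at least two ranks are required")
  if (any(!is.finite(values)) || any(diff(values) <= 0))
    stop("invalid scale: rank values must be finite and strictly increasing")
  if (is.null(labels)) labels <- as.character(values)
  labels <- as.character(labels)
  if (length(labels) != length(values))
    stop("invalid scale: labels must have one entry per rank value")
  structure(
    list(values = values, labels = labels, width = max(values) - min(values)),
    class = "rank_scale"
  )
}

#' Five-point importance scale
#'
#' The conventional 1-5 importance scale: U(nimportant), M(arginally
#' important), N(eutral), I(mportant), V(ery important).
#'
#' @return A [rank_scale()] on values 1..5 with labels U, M, N, I, V.
#' @export
likert5 <- function() rank_scale(1:5, c("U", "M", "N", "I", "V"))

#' @export
print.rank_scale <- function(x, ...) {
  cat(sprintf("<rank_scale> %d ranks, width %g\n", length(x$values), x$width))
  print(stats::setNames(x$values, x$labels))
  invisible(x)
}

#' @export
length.rank_scale <- function(x) length(x$values)

#' Multi-rater response sample for one metric
#'
#' Holds the rank-frequency vector obtained when `q` raters each place one
#' response on an ordinal scale. Raw response vectors are reduced to counts
#' immediately; all downstream statistics depend on the sample only through
#' its counts.
#'
#' @param counts Non-negative integer count per rank (same length as the
#'   scale). Supply either `counts` or `responses`, not both.
#' @param responses Raw rank responses, one per rater; each must be a value
#'   on the scale.
#' @param scale A [rank_scale()]; defaults to [likert5()].
#' @return An object of class `response_sample` with elements `scale`,
#'   `counts` and `q` (total respondents).
#' @examples
#' response_sample(c(5, 0, 0, 0, 5))            # polarized panel
#' response_sample(responses = c(3, 3, 4, 2, 3))
#' @export
response_sample <- function(counts = NULL, responses = NULL, scale = likert5()) {
  stopifnot(inherits(scale, "rank_scale"))
  if (is.null(counts) == is.null(responses))
    stop("invalid sample: supply exactly one of 'counts' or 'responses'")
  if (!is.null(responses)) {
    responses <- as.numeric(responses)
    idx <- match(responses, scale$values)
    if (anyNA(idx))
      stop("invalid sample: responses contain values not on the scale")
    counts <- tabulate(idx, nbins = length(scale$values))
  }
  counts <- as.numeric(counts)
  if (length(counts) != length(scale$values))
    stop("invalid sample: counts must have one entry per rank")
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("invalid sample: counts must be non-negative integers")
  q <- sum(counts)
  if (q < 1)
    stop("invalid sample: at least one response is required (q >= 1)")
  structure(list(scale = scale, counts = counts, q = q),
            class = "response_sample")
}

#' @export
print.response_sample <- function(x, ...) {
  cat(sprintf("<response_sample> q = %d raters\n", as.integer(x$q)))
  print(stats::setNames(x$counts, x$scale$labels))
  invisible(x)
}

# Rank probabilities p_i = counts / q.
rank_probs <- function(sample) sample$counts / sample$q

as_response_sample <- function(x) {
  if (!inherits(x, "response_sample"))
    stop("invalid sample: expected a 'response_sample' object")
  x
}

#' Mean of the rank values
#'
#' The probability-weighted mean of a response sample's rank values,
#' `sum(p_i * x_i)`.
#'
#' @param sample A [response_sample()].
#' @return A numeric scalar within the scale's value range.
#' @export
sample_mean <- function(sample) {
  sample <- as_response_sample(sample)
  sum(rank_probs(sample) * sample$scale$values)
}

#' Population standard deviation of the rank values
#'
#' Computed with divisor `q` (population form), `sqrt(sum(p_i * (x_i - mu)^2))`.
#'
#' @inheritParams sample_mean
#' @return A non-negative numeric scalar.
#' @export
sample_std <- function(sample) {
  sample <- as_response_sample(sample)
  p <- rank_probs(sample)
  mu <- sum(p * sample$scale$values)
  sqrt(sum(p * (sample$scale$values - mu)^2))
}

#' Shannon entropy of a response sample
#'
#' `-sum(p_i * log2(p_i))` over ranks with positive probability, in bits.
#' Measures dispersion of the rating distribution without reference to the
#' rank values themselves; bounded by `log2(n)` for an n-rank scale.
#'
#' @inheritParams sample_mean
#' @return Entropy in bits, in `[0, log2(n)]`.
#' @export
shannon_entropy <- function(sample) {
  sample <- as_response_sample(sample)
  p <- rank_probs(sample)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Consensus of a response sample about its mean
#'
#' The entropy-derived agreement statistic
#' `1 + sum(p_i * log2(1 - |x_i - mu| / d_x))`,
#' where `mu` is the rank-value mean and `d_x` the full scale width.
#' It equals 1 when every rater chose the same rank and 0 for an even split
#' across the two extreme ranks; ranks with `p_i = 0` contribute exactly 0.
#' Unlike Shannon entropy it accounts for *where* on the scale the mass
#' sits, not just how dispersed it is.
#'
#' @inheritParams sample_mean
#' @param gompertz Optional [gompertz_params()]; when supplied, the value is
#'   multiplied by the sample-size weight [gompertz_weight()] at the
#'   sample's `q`.
#' @return A numeric scalar in `[0, 1]`.
#' @seealso [dissension()], [strength_of_consensus()]
#' @examples
#' consensus(response_sample(c(5, 0, 0, 0, 5)))   # 0: extreme split
#' consensus(response_sample(c(0, 0, 10, 0, 0)))  # 1: unanimity
#' @export
consensus <- function(sample, gompertz = NULL) {
  sample <- as_response_sample(sample)
  sc <- sample$scale
  if (sc$width <= 0) stop("degenerate scale: width must be positive")
  p <- rank_probs(sample)
  mu <- sum(p * sc$values)
  keep <- p > 0
  value <- 1 + sum(p[keep] * log2(1 - abs(sc$values[keep] - mu) / sc$width))
  if (!is.null(gompertz)) value <- value * gompertz_weight(sample$q, gompertz)
  value
}

#' Dissension of a response sample
#'
#' The complement `1 - consensus(sample)`: 0 for unanimity, 1 for an even
#' split across the scale extremes.
#'
#' @inheritParams consensus
#' @return A numeric scalar in `[0, 1]`.
#' @export
dissension <- function(sample, gompertz = NULL) {
  1 - consensus(sample, gompertz = gompertz)
}

#' Strength of consensus at a reference rank
#'
#' Consensus evaluated against a chosen reference rank `r` instead of the
#' sample mean: `1 + sum(p_i * log2(1 - |x_i - r| / (2 * d_x)))`. The
#' doubled width keeps the log argument at or above 1/2, so the statistic is
#' always finite and lies in `(0, 1]`, reaching 1 only when all mass sits on
#' the reference rank. Asking for the strength of consensus at rank r
#' answers "how strongly does the panel agree that the answer is r?".
#'
#' @inheritParams consensus
#' @param reference A rank value on the sample's scale.
#' @return A numeric scalar in `(0, 1]`.
#' @examples
#' s <- response_sample(c(0, 3, 4, 3, 0))
#' strength_of_consensus(s, 3)
#' @export
strength_of_consensus <- function(sample, reference, gompertz = NULL) {
  sample <- as_response_sample(sample)
  sc <- sample$scale
  if (sc$width <= 0) stop("degenerate scale: width must be positive")
  if (length(reference) != 1L || !reference %in% sc$values)
    stop("invalid reference: reference rank must be a single value on the scale")
  p <- rank_probs(sample)
  keep <- p > 0
  value <- 1 + sum(p[keep] * log2(1 - abs(sc$values[keep] - reference) / (2 * sc$width)))
  if (!is.null(gompertz)) value <- value * gompertz_weight(sample$q, gompertz)
  value
}

#' Strength-of-consensus profile over all ranks
#'
#' Evaluates [strength_of_consensus()] at every rank of the sample's scale,
#' in scale order. The profile is the qualitative block that a rated metric
#' contributes to a CCE vector.
#'
#' @inheritParams consensus
#' @return An object of class `soc_profile`: list with the `scale` and the
#'   named numeric vector `soc`.
#' @examples
#' soc_profile(response_sample(c(2, 2, 2, 2, 2)))
#' @export
soc_profile <- function(sample, gompertz = NULL) {
  sample <- as_response_sample(sample)
  soc <- vapply(sample$scale$values, function(r)
    strength_of_consensus(sample, r, gompertz = gompertz), numeric(1))
  names(soc) <- sample$scale$labels
  structure(list(scale = sample$scale, soc = soc), class = "soc_profile")
}

#' @export
print.soc_profile <- function(x, digits = 3, ...) {
  cat("<soc_profile>\n")
  print(round(x$soc, digits))
  invisible(x)
}

#' Consensus report for one or more response samples
#'
#' Summarizes each sample with its mean, population standard deviation,
#' Shannon entropy, consensus, dissension and per-rank strength-of-consensus
#' values — one row per metric, the layout used to compare rated variables
#' side by side.
#'
#' @param samples A single [response_sample()] or a named list of them.
#' @param gompertz Optional [gompertz_params()] applied to the consensus and
#'   strength-of-consensus columns.
#' @return A `data.frame` with columns `metric_id`, `q`, `mean`, `std`,
#'   `entropy`, `consensus`, `dissension` and one `soc_<label>` column per
#'   rank.
#' @examples
#' panel <- list(
#'   polarized = response_sample(c(5, 0, 0, 0, 5)),
#'   unanimous = response_sample(c(0, 0, 10, 0, 0))
#' )
#' consensus_report(panel)
#' @export
consensus_report <- function(samples, gompertz = NULL) {
  if (inherits(samples, "response_sample")) samples <- list(samples)
  if (!is.list(samples) || !all(vapply(samples, inherits, logical(1), "response_sample")))
    stop("invalid input: expected a response_sample or a list of them")
  ids <- names(samples)
  if (is.null(ids)) ids <- paste0("metric_", seq_along(samples))
  rows <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    prof <- soc_profile(s, gompertz = gompertz)
    soc <- as.list(prof$soc)
    names(soc) <- paste0("soc_", s$scale$labels)
    c(list(metric_id = ids[i], q = s$q,
           mean = sample_mean(s), std = sample_std(s),
           entropy = shannon_entropy(s),
           consensus = consensus(s, gompertz = gompertz),
           dissension = dissension(s, gompertz = gompertz)),
      soc)
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

#' @export
summary.response_sample <- function(object, ...) {
  consensus_report(object)
}
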
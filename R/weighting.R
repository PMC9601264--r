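#' Gompertz weighting parameters
#'
#' Parameters of the Gompertz sigmoid `exp(-alpha * exp(-beta * q))` used to
#' down-weight consensus statistics from small rater panels. `alpha`
#' controls the left asymptote (the weight at `q = 0` is `exp(-alpha)`);
#' `beta` controls the knee and slope. The defaults penalize a panel of
#' zero raters to roughly half weight and leave panels of 100 or more
#' raters effectively unpenalized.
#'
#' @param alpha Positive left-asymptote control; default 0.725.
#' @param beta Positive knee/slope control; default 0.05.
#' @return An object of class `gompertz_params`.
#' @export
gompertz_params <- function(alpha = 0.725, beta = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop("invalid parameters: alpha must be a positive number")
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0)
    stop("invalid parameters: beta must be a positive number")
  structure(list(alpha = alpha, beta = beta), class = "gompertz_params")
}

#' @export
print.gompertz_params <- function(x, ...) {
  cat(sprintf("<gompertz_params> alpha = %g, beta = %g\n", x$alpha, x$beta))
  invisible(x)
}

#' Gompertz sample-size weight
#'
#' `exp(-alpha * exp(-beta * q))` for a panel of `q` respondents: strictly
#' increasing in `q`, bounded in `(exp(-alpha), 1)`.
#'
#' @param q Respondent count(s), non-negative; vectorized.
#' @param params A [gompertz_params()].
#' @return Weights in `(0, 1)`, same length as `q`.
#' @examples
#' gompertz_weight(c(0, 10, 100))
#' @export
gompertz_weight <- function(q, params = gompertz_params()) {
  stopifnot(inherits(params, "gompertz_params"))
  if (any(!is.finite(q)) || any(q < 0))
    stop("invalid quantity: q must be non-negative")
  exp(-params$alpha * exp(-params$beta * q))
}

#' Sample-size-weighted strength of consensus
#'
#' [strength_of_consensus()] multiplied by the Gompertz weight at the
#' sample's respondent count, so that small panels cannot claim full
#' strength. Always less than or equal to the unweighted value.
#'
#' @inheritParams strength_of_consensus
#' @param params A [gompertz_params()].
#' @return A numeric scalar in `(0, 1)`.
#' @export
weighted_soc <- function(sample, reference, params = gompertz_params()) {
  strength_of_consensus(sample, reference, gompertz = params)
}

#' Apply per-rank weights to a strength-of-consensus profile
#'
#' Element-wise multiplication of a [soc_profile()] by non-negative rank
#' weights, letting one rank's agreement count more than another's in the
#' assembled feature vector. Unit weights are the identity; there is no
#' renormalization.
#'
#' @param profile A [soc_profile()].
#' @param weights Non-negative numeric weights, one per rank, not all zero.
#' @return A new `soc_profile` with weighted values.
#' @examples
#' p <- soc_profile(response_sample(c(0, 0, 10, 0, 0)))
#' apply_rank_weights(p, c(0, 0, 1, 0, 0))  # keep only the central rank
#' @export
apply_rank_weights <- function(profile, weights) {
  if (!inherits(profile, "soc_profile"))
    stop("invalid input: expected a 'soc_profile'")
  weights <- as.numeric(weights)
  if (length(weights) != length(profile$soc))
    stop("schema error: rank weights must have one entry per rank")
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("invalid weights: rank weights must be non-negative")
  if (all(weights == 0))
    stop("invalid weights: rank weights must not all be zero")
  out <- profile
  out$soc <- profile$soc * weights
  out
}
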
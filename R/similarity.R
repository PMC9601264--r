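#' Pairwise distances between CCE vectors
#'
#' Elementary distances used for reference-based scoring of encounter
#' vectors. All take two numeric vectors of equal length.
#'
#' `dist_euclidean` is `sqrt(sum((a - b)^2))`. `dist_cosine` is
#' `1 - cos(angle)` between the vectors, in `[0, 2]`, undefined for a zero
#' vector. `dist_canberra` is `sum(|a - b| / (|a| + |b|))` with
#' zero-denominator terms contributing 0; it is sensitive to small
#' differences near zero. `dist_mahalanobis` is
#' `sqrt((a - b)' S^-1 (a - b))` for a covariance matrix `S`, and reduces
#' to the Euclidean distance when `S` is the identity.
#'
#' @param a,b Numeric vectors of equal length.
#' @param cov Covariance matrix `S` for `dist_mahalanobis`.
#' @return A non-negative scalar distance.
#' @name distances
#' @examples
#' dist_euclidean(c(0, 0, 0), c(1, 2, 2))
#' dist_cosine(c(1, 0), c(0, 1))
#' dist_mahalanobis(c(2, 0), c(0, 0), diag(c(4, 1)))
NULL

check_pair <- function(a, b) {
  if (length(a) != length(b))
    stop("schema error: vectors must have equal dimension")
  invisible(NULL)
}

#' @rdname distances
#' @export
dist_euclidean <- function(a, b) {
  check_pair(a, b)
  sqrt(sum((a - b)^2))
}

#' @rdname distances
#' @export
dist_cosine <- function(a, b) {
  check_pair(a, b)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop("undefined angle: cosine distance requires non-zero vectors")
  1 - sum(a * b) / (na * nb)
}

#' @rdname distances
#' @export
dist_canberra <- function(a, b) {
  check_pair(a, b)
  den <- abs(a) + abs(b)
  num <- abs(a - b)
  sum(ifelse(den > 0, num / den, 0))
}

#' @rdname distances
#' @export
dist_mahalanobis <- function(a, b, cov) {
  check_pair(a, b)
  if (!is.matrix(cov) || nrow(cov) != ncol(cov) || nrow(cov) != length(a))
    stop("schema error: covariance must be square and match the vector dimension")
  d2 <- tryCatch(stats::mahalanobis(matrix(a, nrow = 1), b, cov),
                 error = function(e)
                   stop("singular covariance: supply a regularized matrix (see ridge_covariance)"))
  sqrt(max(d2, 0))
}

cce_metrics <- c("euclidean", "cosine", "canberra", "mahalanobis")

dist_fun <- function(metric) {
  switch(metric,
         euclidean = dist_euclidean,
         cosine = dist_cosine,
         canberra = dist_canberra,
         mahalanobis = dist_mahalanobis,
         stop(sprintf("config error: unknown distance metric '%s'", metric)))
}

#' Population covariance of a cohort
#'
#' Covariance of the encounter-by-dimension matrix with divisor `n`
#' (population form), the estimator used for Mahalanobis scoring.
#'
#' @param x A `cce_cohort` or numeric matrix (rows = encounters).
#' @return A symmetric dimension-by-dimension matrix.
#' @export
cohort_covariance <- function(x) {
  m <- cohort_matrix(x)
  centered <- sweep(m, 2, colMeans(m), "-")
  crossprod(centered) / nrow(m)
}

#' Ridge-regularize a covariance matrix
#'
#' Adds `lambda * mean(diag(S)) * I` to a covariance matrix. CCE vectors
#' have highly correlated dimensions by construction (the palindromic
#' strength-of-consensus blocks), so near-singular covariances are the
#' expected case rather than the exception; a small ridge keeps the inverse
#' well defined while leaving well-conditioned matrices essentially
#' unchanged.
#'
#' @param cov Symmetric covariance matrix.
#' @param lambda Relative ridge, default `1e-6`; `0` disables
#'   regularization.
#' @return The regularized matrix.
#' @export
ridge_covariance <- function(cov, lambda = 1e-6) {
  if (lambda < 0) stop("invalid parameters: lambda must be non-negative")
  if (lambda == 0) return(cov)
  cov + diag(lambda * mean(diag(cov)), nrow(cov))
}

#' Fit a reference model for encounter scoring
#'
#' Freezes everything needed to score encounters against a baseline: the
#' reference vector (an artificial ideal, the cohort mean, or an actual
#' encounter), the cohort's min-max normalization state, and the
#' (regularized) population covariance of the normalized cohort for
#' Mahalanobis scoring. An encounter used as the reference is excluded from
#' the covariance estimate.
#'
#' @param cohort A `cce_cohort` (see [build_cohort()]); normalized
#'   internally unless `normalize = FALSE`.
#' @param reference `"mean"` (default) for the normalized cohort mean, the
#'   `encounter_id` of a cohort member, or a numeric vector of schema
#'   dimension giving an artificial ideal *on the raw scale* (it is passed
#'   through the same normalization).
#' @param metric Default distance metric, one of `"euclidean"`, `"cosine"`,
#'   `"canberra"`, `"mahalanobis"`.
#' @param normalize Normalize the cohort (and reference) before fitting?
#'   Default `TRUE`; disable for raw-space analysis.
#' @param lambda Relative ridge for the covariance (see
#'   [ridge_covariance()]).
#' @return An object of class `cce_reference` with elements `reference`
#'   (named numeric), `covariance`, `norm`, `metric`, `schema` and
#'   `normalized`.
#' @seealso [predict.cce_reference()], [rank_encounters()]
#' @export
cce_reference <- function(cohort, reference = "mean",
                          metric = c("mahalanobis", "euclidean", "cosine", "canberra"),
                          normalize = TRUE, lambda = 1e-6) {
  stopifnot(inherits(cohort, "cce_cohort"))
  metric <- match.arg(metric)
  norm <- NULL
  work <- cohort
  if (normalize) {
    work <- normalize_cohort(cohort)
    norm <- work$norm
  }
  v <- work$values
  est_rows <- rep(TRUE, nrow(v))
  if (is.character(reference) && length(reference) == 1L) {
    if (identical(reference, "mean")) {
      ref <- colMeans(v)
    } else {
      if (!reference %in% rownames(v))
        stop(sprintf("invalid reference: encounter '%s' is not in the cohort", reference))
      ref <- v[reference, ]
      est_rows <- rownames(v) != reference
    }
  } else if (is.numeric(reference)) {
    if (length(reference) != ncol(v))
      stop("schema error: reference vector dimension does not match the schema")
    ref <- reference
    if (normalize) ref <- apply_normalization(ref, norm)
    names(ref) <- colnames(v)
  } else {
    stop("invalid reference: supply 'mean', an encounter_id, or a numeric vector")
  }
  if (sum(est_rows) < 2L)
    stop("invalid input: at least two non-reference encounters are needed for covariance")
  covariance <- ridge_covariance(cohort_covariance(v[est_rows, , drop = FALSE]), lambda)
  structure(list(reference = ref, covariance = covariance, norm = norm,
                 metric = metric, schema = cohort$schema,
                 normalized = isTRUE(normalize)),
            class = "cce_reference")
}

#' @export
print.cce_reference <- function(x, ...) {
  cat(sprintf("<cce_reference> %d dimensions, metric '%s'%s\n",
              length(x$reference), x$metric,
              if (x$normalized) ", min-max normalized" else ""))
  invisible(x)
}

#' Score encounters against a fitted reference
#'
#' Computes the chosen distance from every encounter vector to the
#' reference, on the reference model's coordinate scale (new cohorts built
#' on the raw scale are placed there with the frozen normalization), and
#' ranks encounters by ascending distance. Ties are broken
#' lexicographically by `encounter_id`, so the ranking is deterministic and
#' independent of input order.
#'
#' @param object A fitted [cce_reference()].
#' @param cohort A `cce_cohort` (raw or already normalized) to score.
#' @param metric Distance metric; defaults to the model's.
#' @param ... Unused.
#' @return A `data.frame` with columns `encounter_id`, `metric`,
#'   `distance`, `rank`, ordered by rank.
#' @export
predict.cce_reference <- function(object, cohort, metric = object$metric, ...) {
  stopifnot(inherits(cohort, "cce_cohort"))
  metric <- match.arg(metric, cce_metrics)
  if (object$normalized && !cohort$normalized)
    cohort <- apply_normalization(cohort, object$norm)
  v <- cohort$values
  if (ncol(v) != length(object$reference))
    stop("schema error: cohort dimension does not match the reference model")
  f <- dist_fun(metric)
  d <- if (metric == "mahalanobis") {
    apply(v, 1, f, b = object$reference, cov = object$covariance)
  } else {
    apply(v, 1, f, b = object$reference)
  }
  ids <- rownames(v)
  ord <- order(d, ids, method = "radix")
  out <- data.frame(encounter_id = ids[ord], metric = metric,
                    distance = unname(d[ord]), rank = seq_along(ord),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Rank encounters by distance from a reference
#'
#' Convenience wrapper around [predict.cce_reference()] with the cohort
#' first, matching the "score this cohort against that model" phrasing.
#'
#' @param cohort A `cce_cohort`.
#' @param model A fitted [cce_reference()].
#' @param metric Distance metric; defaults to the model's.
#' @return See [predict.cce_reference()].
#' @export
rank_encounters <- function(cohort, model, metric = model$metric) {
  predict(model, cohort, metric = metric)
}
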
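# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Whitening transform for Mahalanobis geometry: x %*% W has Euclidean
# geometry equal to the Mahalanobis geometry under `cov`.
whitener <- function(cov) {
  r <- tryCatch(chol(cov), error = function(e)
    stop("singular covariance: supply a regularized matrix (see ridge_covariance)"))
  backsolve(r, diag(nrow(cov)))
}

squared_dists_to <- function(m, centers) {
  # n x k matrix of squared Euclidean distances from rows of m to rows of centers
  nm <- rowSums(m^2)
  nc <- rowSums(centers^2)
  outer(nm, nc, "+") - 2 * m %*% t(centers)
}

#' k-nearest-neighbour classification of CCE vectors
#'
#' Classifies query vectors by majority vote among their `k` nearest
#' training vectors. Ties in the vote are broken deterministically: first
#' by the smaller mean neighbour distance among the tied classes, then by
#' the lexicographically smaller class identifier.
#'
#' @param query A `cce_cohort`, numeric matrix (rows = queries) or a single
#'   numeric vector.
#' @param train A `cce_cohort` or numeric matrix of training vectors.
#' @param labels Class identifier per training vector.
#' @param k Number of neighbours, `1 <= k <= nrow(train)`.
#' @param metric `"euclidean"` (default) or `"mahalanobis"` (a whitening
#'   transform under `cov` is applied to both sets first).
#' @param cov Covariance matrix, required for `metric = "mahalanobis"`.
#' @return Character vector of predicted labels, one per query.
#' @examples
#' train <- rbind(c(0, 0), c(0, 1), c(5, 5))
#' knn_classify(c(0, 0.4), train, c("A", "A", "B"), k = 3)
#' @export
knn_classify <- function(query, train, labels, k,
                         metric = c("euclidean", "mahalanobis"), cov = NULL) {
  metric <- match.arg(metric)
  tm <- cohort_matrix(train)
  qm <- cohort_matrix(query)
  if (ncol(qm) != ncol(tm))
    stop("schema error: query and training vectors must share a dimension")
  if (nrow(tm) < 1L) stop("invalid input: empty training cohort")
  labels <- as.character(labels)
  if (length(labels) != nrow(tm))
    stop("invalid input: one label per training vector is required")
  if (length(k) != 1L || k < 1 || k > nrow(tm) || k != round(k))
    stop("config error: k must be an integer in [1, cohort size]")
  if (metric == "mahalanobis") {
    if (is.null(cov)) stop("config error: mahalanobis metric requires a covariance")
    w <- whitener(cov)
    tm <- tm %*% w
    qm <- qm %*% w
  }
  d2 <- squared_dists_to(qm, tm)
  vapply(seq_len(nrow(qm)), function(i) {
    ord <- order(d2[i, ], seq_len(ncol(d2)), method = "radix")[seq_len(k)]
    votes <- table(labels[ord])
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1L) {
      meand <- vapply(top, function(cl)
        mean(sqrt(pmax(d2[i, ord[labels[ord] == cl]], 0))), numeric(1))
      top <- top[order(meand, top, method = "radix")]
    }
    top[1L]
  }, character(1))
}

#' k-means clustering of CCE vectors
#'
#' Lloyd's algorithm authored at desk scale: greedy farthest-point
#' initialization (the first centre is drawn at random under `seed`, each
#' further centre is the point farthest from the centres chosen so far),
#' then alternating nearest-centroid assignment and mean updates until the
#' assignment is a fixed point or `max_iter` is reached. The within-cluster
#' sum of squares (inertia) is checked to be non-increasing at every
#' iteration. Results are reproducible given `seed`.
#'
#' @param x A `cce_cohort` or numeric matrix (rows = encounters).
#' @param k Number of clusters, `1 <= k <= nrow(x)`.
#' @param seed Integer seed for the initialization draw(s).
#' @param max_iter Iteration cap, default 300.
#' @param nstart Number of random restarts; the run with the lowest inertia
#'   is returned. Default 1.
#' @param metric `"euclidean"` (default) or `"mahalanobis"` with `cov`
#'   (clustering then happens in the whitened space).
#' @param cov Covariance for `metric = "mahalanobis"`.
#' @return An object of class `cce_kmeans`: `assignments` (integer cluster
#'   per vector, named by encounter id where available), `centroids`
#'   (k x d, in the input space), `inertia`, `iterations`, `k`.
#' @export
kmeans_cce <- function(x, k, seed = 1L, max_iter = 300L, nstart = 1L,
                       metric = c("euclidean", "mahalanobis"), cov = NULL) {
  metric <- match.arg(metric)
  m0 <- cohort_matrix(x)
  n <- nrow(m0)
  if (length(k) != 1L || k < 1 || k > n || k != round(k))
    stop("config error: k must be an integer in [1, cohort size]")
  m <- m0
  if (metric == "mahalanobis") {
    if (is.null(cov)) stop("config error: mahalanobis metric requires a covariance")
    m <- m0 %*% whitener(cov)
  }
  runs <- with_seed(seed, {
    lapply(seq_len(nstart), function(s) kmeans_once(m, k, max_iter))
  })
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "inertia"))]]
  centroids <- do.call(rbind, lapply(seq_len(k), function(j)
    colMeans(m0[best$assignments == j, , drop = FALSE])))
  colnames(centroids) <- colnames(m0)
  assignments <- best$assignments
  names(assignments) <- rownames(m0)
  structure(list(k = as.integer(k), assignments = assignments,
                 centroids = centroids, inertia = best$inertia,
                 iterations = best$iterations),
            class = "cce_kmeans")
}

kmeans_once <- function(m, k, max_iter) {
  n <- nrow(m)
  # greedy farthest-point initialization: random first centre, then repeatedly
  # the point farthest from all chosen centres
  centers_idx <- sample.int(n, 1L)
  while (length(centers_idx) < k) {
    d2 <- squared_dists_to(m, m[centers_idx, , drop = FALSE])
    mind <- apply(d2, 1, min)
    mind[centers_idx] <- -Inf
    centers_idx <- c(centers_idx, which.max(mind))
  }
  centroids <- m[centers_idx, , drop = FALSE]
  assignments <- integer(n)
  inertia <- Inf
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    d2 <- pmax(squared_dists_to(m, centroids), 0)
    new_assign <- max.col(-d2, ties.method = "first")
    # re-seed any emptied cluster at the point farthest from its own centroid
    cur <- d2[cbind(seq_len(n), new_assign)]
    for (j in seq_len(k)) {
      if (!any(new_assign == j)) {
        far <- which.max(cur)
        new_assign[far] <- j
        cur[far] <- -Inf
      }
    }
    converged <- identical(new_assign, assignments)
    assignments <- new_assign
    centroids <- do.call(rbind, lapply(seq_len(k), function(j)
      colMeans(m[assignments == j, , drop = FALSE])))
    d2c <- pmax(squared_dists_to(m, centroids), 0)
    new_inertia <- sum(d2c[cbind(seq_len(n), assignments)])
    if (new_inertia > inertia + 1e-8 * max(1, inertia))
      stop("internal error: k-means inertia increased")
    inertia <- new_inertia
    if (converged) break
  }
  list(assignments = assignments, inertia = inertia, iterations = iter)
}

#' @export
print.cce_kmeans <- function(x, ...) {
  cat(sprintf("<cce_kmeans> k = %d, inertia = %g, %d iterations\n",
              x$k, x$inertia, x$iterations))
  print(table(cluster = x$assignments))
  invisible(x)
}

#' Restrict a cohort to selected metrics
#'
#' Projects a cohort onto the dimensions belonging to the named metrics —
#' whole strength-of-consensus blocks for qualitative metrics — updating
#' the schema (and any normalization state) consistently, e.g. to cluster
#' on a subset of the vector.
#'
#' @param cohort A `cce_cohort`.
#' @param metric_ids Metric identifiers to keep, in schema order.
#' @return A `cce_cohort` over the reduced schema.
#' @export
extract_dimensions <- function(cohort, metric_ids) {
  stopifnot(inherits(cohort, "cce_cohort"))
  unknown <- setdiff(metric_ids, names(cohort$schema$metrics))
  if (length(unknown))
    stop(sprintf("schema error: unknown metric_id '%s'", unknown[1]))
  keep <- names(cohort$schema$metrics)[names(cohort$schema$metrics) %in% metric_ids]
  sub_schema <- cce_schema(cohort$schema$metrics[keep])
  dims <- cce_dimnames(sub_schema)
  norm <- cohort$norm
  if (!is.null(norm))
    norm <- list(min = norm$min[dims], range = norm$range[dims])
  new_cohort(cohort$values[, dims, drop = FALSE], sub_schema,
             normalized = cohort$normalized, norm = norm)
}
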
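# Reference fixtures: the four worked frequency rows on the 1-5 importance
# scale (10 raters each) and their published summary statistics.
table1_counts <- list(
  V1 = c(5, 0, 0, 0, 5),
  V2 = c(2, 2, 2, 2, 2),
  V3 = c(0, 3, 4, 3, 0),
  V4 = c(0, 0, 10, 0, 0)
)

table1_soc <- rbind(
  V1 = c(0.500, 0.565, 0.585, 0.565, 0.500),
  V2 = c(0.543, 0.704, 0.757, 0.704, 0.543),
  V3 = c(0.573, 0.798, 0.884, 0.798, 0.573),
  V4 = c(0.585, 0.807, 1.000, 0.807, 0.585)
)
colnames(table1_soc) <- c("U", "M", "N", "I", "V")

table1_samples <- function() lapply(table1_counts, response_sample)

# Term-by-term brute-force oracles, written as explicit scalar loops so they
# share no code path with the package implementation.
oracle_consensus <- function(counts, values = 1:5) {
  q <- sum(counts)
  dx <- max(values) - min(values)
  mu <- 0
  for (i in seq_along(values)) mu <- mu + (counts[i] / q) * values[i]
  acc <- 1
  for (i in seq_along(values)) {
    p <- counts[i] / q
    if (p > 0) acc <- acc + p * log2(1 - abs(values[i] - mu) / dx)
  }
  acc
}

oracle_soc <- function(counts, reference, values = 1:5) {
  q <- sum(counts)
  dx <- max(values) - min(values)
  acc <- 1
  for (i in seq_along(values)) {
    p <- counts[i] / q
    if (p > 0) acc <- acc + p * log2(1 - abs(values[i] - reference) / (2 * dx))
  }
  acc
}

# All count vectors of total q over n ranks (compositions of q into n parts).
compositions <- function(q, n) {
  if (n == 1L) return(matrix(q, ncol = 1))
  out <- list()
  for (first in 0:q) {
    rest <- compositions(q - first, n - 1L)
    out[[length(out) + 1L]] <- cbind(first, rest)
  }
  do.call(rbind, out)
}

# Exhaustive k-means oracle: the minimum within-cluster sum of squares over
# every partition of the rows of m into exactly k non-empty clusters.
oracle_best_inertia <- function(m, k) {
  n <- nrow(m)
  best <- Inf
  assign <- rep(1L, n)
  repeat {
    if (length(unique(assign)) == k) {
      inertia <- 0
      for (j in unique(assign)) {
        rows <- m[assign == j, , drop = FALSE]
        ctr <- colMeans(rows)
        inertia <- inertia + sum(sweep(rows, 2, ctr)^2)
      }
      if (inertia < best) best <- inertia
    }
    i <- 1L
    while (i <= n && assign[i] == k) { assign[i] <- 1L; i <- i + 1L }
    if (i > n) break
    assign[i] <- assign[i] + 1L
  }
  best
}

# Small deterministic cohort of raw records for reuse across tests.
toy_cohort <- function(n = 12, seed = 42) {
  syn <- generate_cohort(cohort_scenario(n = n), seed = seed)
  build_cohort(syn$records, syn$schema)
}
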
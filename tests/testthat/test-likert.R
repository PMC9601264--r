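test_that("scale and sample constructors enforce their invariants", {
  expect_error(rank_scale(1), "at least two ranks")
  expect_error(rank_scale(c(1, 1, 2)), "strictly increasing")
  expect_error(rank_scale(1:3, c("a", "b")), "one entry per rank")
  expect_error(response_sample(c(1, 2)), "one entry per rank")
  expect_error(response_sample(c(0, 0, 0, 0, 0)), "q >= 1")
  expect_error(response_sample(c(-1, 2, 0, 0, 0)), "non-negative")
  expect_error(response_sample(responses = c(1, 9)), "not on the scale")
  expect_error(response_sample(c(1, 1), responses = c(1, 2)), "exactly one")

  # raw responses reduce to counts immediately
  s <- response_sample(responses = c(3, 5, 3, 1, 3))
  expect_equal(s$counts, c(1, 0, 3, 0, 1))
  expect_equal(s$q, 5)
})

test_that("mean, std and entropy match hand-computed and published values", {
  samples <- table1_samples()
  expect_equal(vapply(samples, sample_mean, numeric(1)),
               c(V1 = 3, V2 = 3, V3 = 3, V4 = 3))
  expect_equal(round(vapply(samples, sample_std, numeric(1)), 3),
               c(V1 = 2.000, V2 = 1.414, V3 = 0.775, V4 = 0.000))
  expect_equal(sample_mean(response_sample(c(10, 0, 0, 0, 0))), 1)
  expect_equal(sample_mean(response_sample(c(1, 0, 0, 0, 3))), 4)

  expect_equal(shannon_entropy(samples$V2), log2(5))
  expect_equal(shannon_entropy(samples$V4), 0)
  expect_equal(shannon_entropy(samples$V1), 1)
})

test_that("consensus hits its anchors and its hand-derived midpoint case", {
  samples <- table1_samples()
  expect_equal(consensus(samples$V1), 0)
  expect_equal(consensus(samples$V4), 1)
  # even split on ranks 2 and 4: both terms p = 1/2, |x - 3|/4 = 1/4
  expect_equal(consensus(response_sample(c(0, 5, 0, 5, 0))),
               1 + log2(0.75), tolerance = 1e-12)
  expect_equal(dissension(response_sample(c(0, 5, 0, 5, 0))),
               -log2(0.75), tolerance = 1e-12)
  expect_equal(dissension(samples$V4), 0)
  expect_equal(dissension(samples$V1), 1)
})

test_that("strength-of-consensus reproduces every published profile cell", {
  samples <- table1_samples()
  for (v in names(samples)) {
    prof <- soc_profile(samples[[v]])
    expect_equal(round(unname(prof$soc), 3), unname(table1_soc[v, ]),
                 info = v)
  }
  expect_equal(strength_of_consensus(samples$V1, 1), 0.5)
  expect_equal(strength_of_consensus(samples$V4, 3), 1)
  expect_error(strength_of_consensus(samples$V1, 2.5), "on the scale")
})

test_that("consensus statistics match the brute-force oracle on all small samples", {
  # every 5-rank count vector with 1 <= q <= 6
  for (q in 1:6) {
    cm <- compositions(q, 5)
    for (r in seq_len(nrow(cm))) {
      counts <- as.numeric(cm[r, ])
      s <- response_sample(counts)
      expect_equal(consensus(s), oracle_consensus(counts), tolerance = 1e-12)
      for (ref in 1:5)
        expect_equal(strength_of_consensus(s, ref), oracle_soc(counts, ref),
                     tolerance = 1e-12)
    }
  }
})

test_that("consensus family is bounded, permutation- and affine-invariant", {
  set.seed(101)
  for (i in 1:50) {
    counts <- as.numeric(rmultinom(1, sample(1:30, 1), runif(5)))
    if (sum(counts) == 0) next
    s <- response_sample(counts)
    cns <- consensus(s)
    expect_gte(cns, -1e-12); expect_lte(cns, 1 + 1e-12)
    # soc lies in [0, 1]; the 0 boundary is attained only when all mass sits
    # a full scale-width away from the reference rank
    soc <- soc_profile(s)$soc
    expect_true(all(soc >= -1e-12 & soc <= 1 + 1e-12))

    # depends on the sample only through counts: raw responses in any order
    pool <- rep(1:5, counts)
    resp <- pool[sample.int(length(pool))]
    expect_equal(consensus(response_sample(responses = resp)), cns)

    # affine relabeling x -> a x + b leaves both statistics unchanged
    a <- runif(1, 0.5, 3); b <- runif(1, -2, 2)
    s2 <- response_sample(counts, scale = rank_scale(a * (1:5) + b))
    expect_equal(consensus(s2), cns, tolerance = 1e-10)
    expect_equal(unname(soc_profile(s2)$soc), unname(soc), tolerance = 1e-10)
  }
})

test_that("symmetric samples give palindromic profiles and soc = 1 iff unanimous", {
  sym <- list(c(5, 0, 0, 0, 5), c(2, 2, 2, 2, 2), c(0, 3, 4, 3, 0), c(1, 2, 0, 2, 1))
  for (counts in sym) {
    soc <- unname(soc_profile(response_sample(counts))$soc)
    expect_equal(soc, rev(soc))
  }
  for (r in 1:5) {
    counts <- rep(0, 5); counts[r] <- 7
    prof <- soc_profile(response_sample(counts))$soc
    expect_equal(unname(prof[r]), 1)
    expect_true(all(prof[-r] < 1))
  }
})

test_that("central-rank strength of consensus orders samples by concentration", {
  soc_n <- vapply(table1_samples(), function(s) strength_of_consensus(s, 3),
                  numeric(1))
  expect_true(all(diff(soc_n) > 0))  # V1 < V2 < V3 < V4
})

test_that("consensus report collects all statistics per metric", {
  rep <- consensus_report(table1_samples())
  expect_equal(rep$metric_id, c("V1", "V2", "V3", "V4"))
  expect_equal(rep$consensus + rep$dissension, rep(1, 4), tolerance = 1e-12)
  expect_equal(round(rep$soc_N, 3), unname(table1_soc[, "N"]))
  expect_equal(rep$q, rep(10, 4))
  # summary of one sample is the one-row report
  expect_equal(summary(table1_samples()$V3)[, -1], rep[3, -1],
               ignore_attr = TRUE)
})
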
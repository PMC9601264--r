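test_that("schema bookkeeping: dimensions, names, duplicate detection", {
  sch <- fig_schema()
  expect_equal(cce_dimension(sch), 23)  # 3 quantitative + 4 x 5 ranks
  expect_equal(length(cce_dimnames(sch)), 23)
  expect_equal(cce_dimnames(sch)[1:4], c("consults", "los_plos_ratio",
                                         "readmission", "importance_consults_U"))
  expect_error(cce_schema(metric_quantitative("a"), metric_quantitative("a")),
               "duplicate")
  expect_error(cce_schema(), "at least one")
  # consensus scalar flag adds one dimension per qualitative metric
  sch2 <- cce_schema(metric_qualitative("exp", include_consensus = TRUE))
  expect_equal(cce_dimension(sch2), 6)
  expect_equal(cce_dimnames(sch2)[6], "exp_cns")
})

test_that("build_cce_vector lays out quantitative values then soc blocks", {
  sch <- fig_schema()
  unanimous <- response_sample(c(0, 0, 10, 0, 0))
  rec <- encounter_record(
    "e1",
    quantitative = c(consults = 4, los_plos_ratio = 1.2, readmission = 1),
    qualitative = list(importance_consults = unanimous,
                       importance_los_plos = unanimous,
                       importance_readmission = unanimous,
                       patient_experience = unanimous))
  v <- build_cce_vector(rec, sch)
  expect_length(v$values, 23)
  expect_false(v$normalized)
  expect_equal(unname(v$values[1:3]), c(4, 1.2, 1))
  block <- c(0.585, 0.807, 1.000, 0.807, 0.585)
  for (m in c("importance_consults", "importance_los_plos",
              "importance_readmission", "patient_experience"))
    expect_equal(round(unname(v$values[paste(m, c("U","M","N","I","V"), sep = "_")]), 3),
                 block, info = m)

  # purely quantitative schema passes values through unchanged
  qsch <- cce_schema(metric_quantitative("a"), metric_quantitative("b"))
  qv <- build_cce_vector(encounter_record("e2", c(a = -3, b = 7)), qsch)
  expect_equal(unname(qv$values), c(-3, 7))

  # contract violations
  expect_error(build_cce_vector(encounter_record("e3", c(consults = 1)), sch),
               "missing")
  bad <- rec; bad$qualitative$patient_experience <-
    response_sample(c(1, 1, 1), scale = rank_scale(1:3))
  expect_error(build_cce_vector(bad, sch), "does not match the schema")
})

test_that("vector length equals schema dimension over randomized schemas", {
  set.seed(31)
  for (i in 1:20) {
    nq <- sample(0:4, 1); nl <- sample(1:4, 1)
    specs <- c(
      lapply(seq_len(nq), function(j) metric_quantitative(paste0("q", j))),
      lapply(seq_len(nl), function(j) {
        npt <- sample(2:7, 1)
        metric_qualitative(paste0("m", j), scale = rank_scale(seq_len(npt)),
                           include_consensus = runif(1) < 0.5)
      }))
    sch <- cce_schema(specs)
    qual <- lapply(seq_len(nl), function(j) {
      s <- sch$metrics[[paste0("m", j)]]$scale
      response_sample(responses = sample(s$values, 8, replace = TRUE), scale = s)
    })
    names(qual) <- paste0("m", seq_len(nl))
    quant <- if (nq > 0) stats::setNames(rnorm(nq), paste0("q", seq_len(nq))) else numeric()
    rec <- encounter_record("e", quant, qual)
    v <- build_cce_vector(rec, sch)
    expect_length(v$values, cce_dimension(sch))
    # qualitative dimensions land in (0, 1] before normalization
    qual_dims <- setdiff(names(v$values), paste0("q", seq_len(nq)))
    soc_dims <- qual_dims[!grepl("_cns$", qual_dims)]
    expect_true(all(v$values[soc_dims] > 0 & v$values[soc_dims] <= 1 + 1e-12))
  }
})

test_that("min-max normalization scales, centres constants, and is idempotent", {
  sch <- cce_schema(metric_quantitative("a"), metric_quantitative("b"))
  recs <- lapply(1:3, function(i)
    encounter_record(paste0("e", i), c(a = c(2, 4, 6)[i], b = 5)))
  cohort <- build_cohort(recs, sch)
  nc <- normalize_cohort(cohort)
  expect_equal(unname(nc$values[, "a"]), c(0, 0.5, 1))
  expect_equal(unname(nc$values[, "b"]), rep(0.5, 3))  # constant dimension
  expect_true(nc$normalized)
  # idempotent
  expect_equal(normalize_cohort(nc)$values, nc$values)
  # order of encounters preserved per dimension
  cohort2 <- toy_cohort(n = 15, seed = 5)
  nc2 <- normalize_cohort(cohort2)
  for (j in seq_len(ncol(nc2$values)))
    expect_equal(order(nc2$values[, j]), order(cohort2$values[, j]))
  expect_true(all(nc2$values >= 0 & nc2$values <= 1))
})

test_that("frozen normalization state reuses the cohort scale for new vectors", {
  cohort <- toy_cohort(n = 10, seed = 9)
  nc <- normalize_cohort(cohort)
  again <- apply_normalization(cohort, nc$norm)
  expect_equal(again$values, nc$values)
  one <- apply_normalization(cohort$values[3, ], nc$norm)
  expect_equal(unname(one), unname(nc$values[3, ]))
  expect_error(apply_normalization(cohort$values[, 1:5], nc$norm), "mismatch")
})

test_that("cohort serialization round-trips bit-exactly with its schema", {
  cohort <- toy_cohort(n = 8, seed = 13)
  tmp <- file.path(tempdir(), "cohort_rt.csv")
  write_cohort(cohort, tmp)
  back <- read_cohort(tmp)
  expect_identical(back$values, cohort$values)
  expect_equal(cce_dimnames(back$schema), cce_dimnames(cohort$schema))
  expect_false(back$normalized)

  # normalization state survives the round trip
  nc <- normalize_cohort(cohort)
  write_cohort(nc, tmp)
  back2 <- read_cohort(tmp)
  expect_identical(back2$values, nc$values)
  expect_true(back2$normalized)
  expect_equal(back2$norm$min, nc$norm$min)

  # header/schema mismatch is a format error
  df <- utils::read.csv(tmp, check.names = FALSE)
  utils::write.csv(df[, -2], tmp, row.names = FALSE)
  expect_error(read_cohort(tmp), "format error")

  # schema JSON round trip, including weighting metadata
  sch <- cce_schema(
    metric_quantitative("consults"),
    metric_qualitative("exp", gompertz = gompertz_params(0.5, 0.1),
                       rank_weights = c(1, 1, 2, 1, 1), include_consensus = TRUE))
  sch2 <- read_schema(write_schema(sch))
  expect_equal(cce_dimnames(sch2), cce_dimnames(sch))
  expect_equal(sch2$metrics$exp$gompertz$alpha, 0.5)
  expect_equal(sch2$metrics$exp$rank_weights, c(1, 1, 2, 1, 1))
})
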
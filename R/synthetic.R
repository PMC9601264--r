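#' Example encounter schema: three quantitative and four rated metrics
#'
#' The canonical demonstration layout: consult count, LOS/PLOS ratio and a
#' readmission flag as quantitative metrics, plus four expert-rated
#' qualitative metrics (the importance of each quantitative metric and a
#' patient experience score) on the 5-point importance scale — a
#' 23-dimension vector in total.
#'
#' @return A [cce_schema()] of dimension 23.
#' @export
fig_schema <- function() {
  cce_schema(
    metric_quantitative("consults", "number of clinical consultations"),
    metric_quantitative("los_plos_ratio", "length-of-stay over prescribed length-of-stay"),
    metric_quantitative("readmission", "readmission flag (0/1)"),
    metric_qualitative("importance_consults",
                       description = "expert-rated importance of the consult count"),
    metric_qualitative("importance_los_plos",
                       description = "expert-rated importance of the LOS/PLOS ratio"),
    metric_qualitative("importance_readmission",
                       description = "expert-rated importance of readmission"),
    metric_qualitative("patient_experience",
                       description = "rated patient experience score")
  )
}

# Rank-response probabilities: a Gaussian kernel over the rank values,
# exactly uniform at concentration 0 and degenerate at the mode as
# concentration grows.
survey_probs <- function(mode, concentration, scale) {
  w <- exp(-concentration * (scale$values - mode)^2 / 2)
  w / sum(w)
}

#' Generate a synthetic multi-rater survey
#'
#' Draws `q` independent rank responses with probabilities proportional to
#' a Gaussian kernel over the rank values,
#' `p_i` proportional to `exp(-concentration * (x_i - mode)^2 / 2)`.
#' `concentration = 0` gives uniform responses; large values concentrate
#' all responses on `mode`. Deterministic given `seed`.
#'
#' @param q Number of raters (>= 1).
#' @param mode The rank value the panel centres on; must lie on the scale.
#' @param concentration Non-negative dispersion control; default 1.
#' @param scale A [rank_scale()]; default [likert5()].
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return A [response_sample()].
#' @examples
#' generate_survey(10, mode = 4, concentration = 3, seed = 1)
#' @export
generate_survey <- function(q, mode, concentration = 1, scale = likert5(),
                            seed = NULL) {
  if (q < 1 || q != round(q)) stop("invalid scenario: q must be a positive integer")
  if (!mode %in% scale$values) stop("invalid scenario: mode must be a rank on the scale")
  if (!is.finite(concentration) || concentration < 0)
    stop("invalid scenario: concentration must be non-negative")
  p <- survey_probs(mode, concentration, scale)
  responses <- with_seed(seed, sample(scale$values, q, replace = TRUE, prob = p))
  response_sample(responses = responses, scale = scale)
}

#' Synthetic cohort scenario
#'
#' Declares an encounter cohort with planted cluster structure over the
#' [fig_schema()] metrics. Each cluster has a Poisson mean for the consult
#' count, a median LOS/PLOS ratio (log-normal within-cluster noise), a
#' readmission probability, and a modal rank for the per-encounter patient
#' experience survey. The three importance metrics are rated once by a
#' shared expert panel and repeated across encounters. The default
#' clusters are separated by at least ten within-cluster standard
#' deviations on the LOS/PLOS axis and carry opposed experience modes, so
#' the planted labels are recoverable essentially without error.
#'
#' @param n Number of encounters (>= number of clusters).
#' @param clusters `data.frame` with one row per cluster and columns
#'   `consults` (Poisson mean >= 0), `los_plos` (median ratio > 0),
#'   `readmission` (probability in `[0, 1]`), `experience_mode` (rank on
#'   the scale).
#' @param los_sdlog Within-cluster log-scale standard deviation of the
#'   LOS/PLOS ratio; default 0.05.
#' @param raters Panel size for every survey; default 25.
#' @param concentration Survey concentration (see [generate_survey()]);
#'   default 3.
#' @param importance_modes Named modal ranks for the shared importance
#'   panel.
#' @return An object of class `cohort_scenario`.
#' @export
cohort_scenario <- function(n = 60,
                            clusters = data.frame(
                              consults = c(3, 30, 90),
                              los_plos = c(0.7, 1.3, 2.4),
                              readmission = c(0.05, 0.5, 0.95),
                              experience_mode = c(5, 3, 1)),
                            los_sdlog = 0.05, raters = 25, concentration = 3,
                            importance_modes = c(importance_consults = 4,
                                                 importance_los_plos = 3,
                                                 importance_readmission = 5)) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("invalid scenario: n must be a positive integer")
  if (!is.data.frame(clusters) || nrow(clusters) < 1L ||
      !all(c("consults", "los_plos", "readmission", "experience_mode") %in% names(clusters)))
    stop("invalid scenario: clusters needs columns consults, los_plos, readmission, experience_mode")
  if (n < nrow(clusters))
    stop("invalid scenario: n must be at least the number of clusters")
  if (any(clusters$consults < 0) || any(clusters$los_plos <= 0))
    stop("invalid scenario: consults must be >= 0 and los_plos > 0")
  if (any(clusters$readmission < 0 | clusters$readmission > 1))
    stop("invalid scenario: readmission probabilities must lie in [0, 1]")
  scale <- likert5()
  if (!all(clusters$experience_mode %in% scale$values))
    stop("invalid scenario: experience_mode must be a rank on the scale")
  if (!all(importance_modes %in% scale$values))
    stop("invalid scenario: importance modes must be ranks on the scale")
  structure(list(n = as.integer(n), clusters = clusters, los_sdlog = los_sdlog,
                 raters = as.integer(raters), concentration = concentration,
                 importance_modes = importance_modes, scale = scale),
            class = "cohort_scenario")
}

#' Generate a synthetic encounter cohort with planted clusters
#'
#' Draws encounter records under a [cohort_scenario()]: cluster labels are
#' balanced and shuffled, quantitative metrics are drawn per cluster
#' (Poisson consults, log-normal LOS/PLOS, Bernoulli readmission), the
#' patient experience survey is drawn per encounter around its cluster's
#' modal rank, and the three importance metrics come from one shared panel
#' drawn once per cohort. Deterministic given `seed`.
#'
#' @param scenario A [cohort_scenario()].
#' @param seed Integer seed.
#' @return A list with `records` (list of [encounter_record()]), `labels`
#'   (planted cluster index per record) and `schema` ([fig_schema()]).
#' @examples
#' syn <- generate_cohort(cohort_scenario(n = 12), seed = 1)
#' cohort <- build_cohort(syn$records, syn$schema)
#' @export
generate_cohort <- function(scenario, seed = 1L) {
  stopifnot(inherits(scenario, "cohort_scenario"))
  k <- nrow(scenario$clusters)
  schema <- fig_schema()
  with_seed(seed, {
    labels <- sample(rep_len(seq_len(k), scenario$n))
    importance <- lapply(scenario$importance_modes, function(mode)
      generate_survey(scenario$raters, mode, scenario$concentration,
                      scale = scenario$scale))
    records <- lapply(seq_len(scenario$n), function(i) {
      cl <- scenario$clusters[labels[i], ]
      experience <- generate_survey(scenario$raters, cl$experience_mode,
                                    scenario$concentration, scale = scenario$scale)
      encounter_record(
        sprintf("enc_%03d", i),
        quantitative = c(consults = stats::rpois(1, cl$consults),
                         los_plos_ratio = stats::rlnorm(1, log(cl$los_plos),
                                                        scenario$los_sdlog),
                         readmission = stats::rbinom(1, 1, cl$readmission)),
        qualitative = c(importance, list(patient_experience = experience))
      )
    })
    list(records = records, labels = labels, schema = schema)
  })
}
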
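#' Serialize a CCE schema to JSON
#'
#' Writes the full schema — metric order, kinds, scales, weighting
#' parameters and flags — so a serialized cohort's layout is never
#' implicit.
#'
#' @param schema A [cce_schema()].
#' @param path Output path; when `NULL` the JSON string is returned.
#' @return The path (invisibly) or, with `path = NULL`, a JSON string.
#' @export
write_schema <- function(schema, path = NULL) {
  stopifnot(inherits(schema, "cce_schema"))
  metrics <- lapply(unname(schema$metrics), function(m) {
    out <- list(metric_id = m$metric_id, kind = m$kind,
                description = m$description)
    if (m$kind == "qualitative") {
      out$scale <- list(values = m$scale$values, labels = m$scale$labels)
      out$include_consensus <- m$include_consensus
      if (!is.null(m$gompertz))
        out$gompertz <- list(alpha = m$gompertz$alpha, beta = m$gompertz$beta)
      if (!is.null(m$rank_weights)) out$rank_weights <- m$rank_weights
    }
    out
  })
  obj <- list(format = "cce_schema", version = 1L, metrics = metrics)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}

#' Read a CCE schema from JSON
#'
#' @param path Path to a JSON file written by [write_schema()] (or a JSON
#'   string).
#' @return A [cce_schema()].
#' @export
read_schema <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE, simplifyVector = TRUE)
  if (!identical(obj$format, "cce_schema"))
    stop("format error: not a cce_schema JSON document")
  specs <- lapply(obj$metrics, function(m) {
    if (identical(m$kind, "quantitative")) {
      metric_quantitative(m$metric_id, description = m$description %||% "")
    } else if (identical(m$kind, "qualitative")) {
      metric_qualitative(
        m$metric_id,
        scale = rank_scale(m$scale$values, m$scale$labels),
        gompertz = if (!is.null(m$gompertz))
          gompertz_params(m$gompertz$alpha, m$gompertz$beta),
        rank_weights = m$rank_weights,
        include_consensus = isTRUE(m$include_consensus),
        description = m$description %||% ""
      )
    } else stop("format error: unknown metric kind in schema")
  })
  cce_schema(specs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sidecar_path <- function(path) paste0(path, ".schema.json")

#' Write a cohort of CCE vectors
#'
#' Writes the cohort to CSV with header `encounter_id,<dim_1>,...,<dim_k>`
#' plus a JSON sidecar (`<path>.schema.json`) carrying the schema, the
#' normalized flag and any normalization state. Values are written with 17
#' significant digits, so the round trip through [read_cohort()] is exact
#' for doubles.
#'
#' @param cohort A `cce_cohort`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cce_cohort"))
  v <- cohort$values
  df <- data.frame(encounter_id = rownames(v), stringsAsFactors = FALSE)
  for (j in seq_len(ncol(v))) df[[colnames(v)[j]]] <- sprintf("%.17g", v[, j])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(format = "cce_cohort", version = 1L,
               normalized = cohort$normalized,
               schema = jsonlite::fromJSON(write_schema(cohort$schema),
                                           simplifyDataFrame = FALSE))
  if (!is.null(cohort$norm))
    meta$norm <- list(min = unname(cohort$norm$min),
                      range = unname(cohort$norm$range))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA, pretty = TRUE),
             sidecar_path(path))
  invisible(path)
}

#' Read a cohort of CCE vectors
#'
#' Reads a CSV written by [write_cohort()] together with its JSON schema
#' sidecar, validating that the CSV columns match the schema's dimensions
#' exactly.
#'
#' @param path CSV path (the sidecar `<path>.schema.json` must exist).
#' @return A `cce_cohort`.
#' @export
read_cohort <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    stop(sprintf("format error: schema sidecar '%s' not found", sp))
  meta <- jsonlite::fromJSON(sp, simplifyDataFrame = FALSE, simplifyVector = TRUE)
  if (!identical(meta$format, "cce_cohort"))
    stop("format error: sidecar is not a cce_cohort document")
  schema <- read_schema(jsonlite::toJSON(meta$schema, auto_unbox = TRUE, digits = NA))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  dims <- cce_dimnames(schema)
  if (!identical(colnames(df), c("encounter_id", dims)))
    stop("format error: CSV header does not match the schema's dimensions")
  values <- as.matrix(df[, dims, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- df$encounter_id
  norm <- NULL
  if (!is.null(meta[["norm"]]))
    norm <- list(min = stats::setNames(as.numeric(meta[["norm"]]$min), dims),
                 range = stats::setNames(as.numeric(meta[["norm"]]$range), dims))
  new_cohort(values, schema, normalized = isTRUE(meta$normalized), norm = norm)
}

#' Read survey responses in long format
#'
#' Parses a CSV with header `rater_id,metric_id,rank` (one row per rating)
#' into one [response_sample()] per metric. Rank values must be values on
#' the declared scale.
#'
#' @param path CSV path.
#' @param scale A [rank_scale()] shared by all metrics.
#' @return Named list of `response_sample` objects, one per `metric_id`,
#'   in first-appearance order.
#' @export
read_survey_long <- function(path, scale = likert5()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("rater_id", "metric_id", "rank")
  if (!all(need %in% colnames(df)))
    stop("format error: long survey CSV needs columns rater_id, metric_id, rank")
  ids <- unique(df$metric_id)
  samples <- lapply(ids, function(id)
    response_sample(responses = df$rank[df$metric_id == id], scale = scale))
  stats::setNames(samples, ids)
}

#' Read survey responses as rank-frequency rows
#'
#' Parses a wide CSV with header `metric_id,count_1,...,count_n` (one row
#' per metric, one count column per rank in ascending scale order) into
#' [response_sample()] objects.
#'
#' @inheritParams read_survey_long
#' @return Named list of `response_sample` objects, one per row.
#' @export
read_survey_counts <- function(path, scale = likert5()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  n <- length(scale$values)
  need <- c("metric_id", paste0("count_", seq_len(n)))
  if (!all(need %in% colnames(df)))
    stop(sprintf("format error: frequency CSV needs columns %s",
                 paste(need, collapse = ", ")))
  samples <- lapply(seq_len(nrow(df)), function(i)
    response_sample(as.numeric(df[i, need[-1]]), scale = scale))
  stats::setNames(samples, df$metric_id)
}
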
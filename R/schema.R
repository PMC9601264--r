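#' Quantitative metric specification
#'
#' Declares one quantitative dimension of a CCE vector: a count, ratio or
#' binary flag recorded per encounter (e.g. number of consults, LOS/PLOS
#' ratio, readmission flag). Its value is copied into the vector verbatim.
#'
#' @param metric_id Unique identifier.
#' @param description Free-text description.
#' @return An object of class `metric_spec` with `kind = "quantitative"`.
#' @export
metric_quantitative <- function(metric_id, description = "") {
  check_metric_id(metric_id)
  structure(list(metric_id = metric_id, kind = "quantitative",
                 description = description),
            class = "metric_spec")
}

#' Qualitative metric specification
#'
#' Declares one expert-rated dimension block of a CCE vector. The metric's
#' multi-rater response sample is expanded into its strength-of-consensus
#' profile (one vector element per rank, in ascending rank order),
#' optionally Gompertz-weighted for panel size, optionally rank-weighted,
#' and optionally followed by the scalar consensus value.
#'
#' @param metric_id Unique identifier.
#' @param scale A [rank_scale()]; default [likert5()].
#' @param gompertz Optional [gompertz_params()] applied to this metric's
#'   consensus statistics.
#' @param rank_weights Optional non-negative weights, one per rank.
#' @param include_consensus Append the scalar consensus of the sample after
#'   the strength-of-consensus block? Default `FALSE`.
#' @param description Free-text description.
#' @return An object of class `metric_spec` with `kind = "qualitative"`.
#' @export
metric_qualitative <- function(metric_id, scale = likert5(), gompertz = NULL,
                               rank_weights = NULL, include_consensus = FALSE,
                               description = "") {
  check_metric_id(metric_id)
  stopifnot(inherits(scale, "rank_scale"))
  if (!is.null(gompertz)) stopifnot(inherits(gompertz, "gompertz_params"))
  if (!is.null(rank_weights)) {
    rank_weights <- as.numeric(rank_weights)
    if (length(rank_weights) != length(scale$values))
      stop("schema error: rank_weights must have one entry per rank")
    if (any(rank_weights < 0) || all(rank_weights == 0))
      stop("schema error: rank_weights must be non-negative and not all zero")
  }
  structure(list(metric_id = metric_id, kind = "qualitative", scale = scale,
                 gompertz = gompertz, rank_weights = rank_weights,
                 include_consensus = isTRUE(include_consensus),
                 description = description),
            class = "metric_spec")
}

check_metric_id <- function(metric_id) {
  if (!is.character(metric_id) || length(metric_id) != 1L || !nzchar(metric_id))
    stop("schema error: metric_id must be a non-empty string")
  invisible(metric_id)
}

#' CCE vector schema
#'
#' An ordered collection of metric specifications that fixes the layout of
#' every vector built from it: quantitative metrics contribute one dimension
#' each, qualitative metrics contribute one dimension per rank (plus one if
#' the consensus scalar is enabled). The order of metrics and of ranks is
#' fixed by the schema and recorded alongside serialized cohorts, so a
#' vector's layout is never implicit.
#'
#' @param ... [metric_quantitative()] / [metric_qualitative()] specs, or a
#'   single list of them.
#' @return An object of class `cce_schema`.
#' @examples
#' sch <- cce_schema(
#'   metric_quantitative("consults"),
#'   metric_qualitative("importance_consults")
#' )
#' cce_dimension(sch)
#' @export
cce_schema <- function(...) {
  specs <- list(...)
  if (length(specs) == 1L && is.list(specs[[1]]) && !inherits(specs[[1]], "metric_spec"))
    specs <- specs[[1]]
  if (length(specs) == 0L)
    stop("schema error: at least one metric is required")
  if (!all(vapply(specs, inherits, logical(1), "metric_spec")))
    stop("schema error: all entries must be metric specifications")
  ids <- vapply(specs, `[[`, character(1), "metric_id")
  if (anyDuplicated(ids))
    stop("schema error: duplicate metric_id")
  names(specs) <- ids
  structure(list(metrics = specs), class = "cce_schema")
}

#' Dimension of a schema
#'
#' Total vector length implied by a schema: one per quantitative metric plus
#' the scale length (and optional consensus scalar) per qualitative metric.
#'
#' @param schema A [cce_schema()].
#' @return Integer dimension.
#' @export
cce_dimension <- function(schema) {
  stopifnot(inherits(schema, "cce_schema"))
  sum(vapply(schema$metrics, function(m) {
    if (m$kind == "quantitative") 1L
    else length(m$scale$values) + as.integer(m$include_consensus)
  }, integer(1)))
}

#' Dimension names of a schema
#'
#' Quantitative metrics name their single dimension `metric_id`; qualitative
#' metrics name each rank dimension `metric_id_<label>` (plus
#' `metric_id_cns` when the consensus scalar is enabled).
#'
#' @param schema A [cce_schema()].
#' @return Character vector of length [cce_dimension()].
#' @export
cce_dimnames <- function(schema) {
  stopifnot(inherits(schema, "cce_schema"))
  unlist(lapply(schema$metrics, function(m) {
    if (m$kind == "quantitative") m$metric_id
    else c(paste(m$metric_id, m$scale$labels, sep = "_"),
           if (m$include_consensus) paste(m$metric_id, "cns", sep = "_"))
  }), use.names = FALSE)
}

#' @export
print.cce_schema <- function(x, ...) {
  kinds <- vapply(x$metrics, `[[`, character(1), "kind")
  cat(sprintf("<cce_schema> %d metrics (%d quantitative, %d qualitative), dimension %d\n",
              length(x$metrics), sum(kinds == "quantitative"),
              sum(kinds == "qualitative"), cce_dimension(x)))
  for (m in x$metrics) {
    if (m$kind == "quantitative")
      cat(sprintf("  %s: quantitative\n", m$metric_id))
    else
      cat(sprintf("  %s: qualitative, %d ranks (%s)%s\n", m$metric_id,
                  length(m$scale$values), paste(m$scale$labels, collapse = ","),
                  if (m$include_consensus) " + consensus" else ""))
  }
  invisible(x)
}

#' Single-encounter record
#'
#' The raw inputs for one encounter: a value for every quantitative metric
#' of the schema and a multi-rater [response_sample()] for every qualitative
#' metric.
#'
#' @param encounter_id Unique identifier.
#' @param quantitative Named numeric vector of quantitative metric values.
#' @param qualitative Named list of [response_sample()] objects.
#' @return An object of class `encounter_record`.
#' @export
encounter_record <- function(encounter_id, quantitative = numeric(), qualitative = list()) {
  if (!is.character(encounter_id) || length(encounter_id) != 1L || !nzchar(encounter_id))
    stop("invalid record: encounter_id must be a non-empty string")
  quantitative <- unlist(quantitative)
  if (length(quantitative) && is.null(names(quantitative)))
    stop("invalid record: quantitative values must be named by metric_id")
  if (length(qualitative)) {
    if (is.null(names(qualitative)) ||
        !all(vapply(qualitative, inherits, logical(1), "response_sample")))
      stop("invalid record: qualitative entries must be named response_sample objects")
  }
  structure(list(encounter_id = encounter_id,
                 quantitative = quantitative, qualitative = qualitative),
            class = "encounter_record")
}

#' Build one CCE vector
#'
#' Assembles the ordered numeric vector for one encounter under a schema:
#' quantitative values are copied verbatim in schema order; each qualitative
#' metric is expanded to its (optionally Gompertz- and rank-weighted)
#' strength-of-consensus profile in ascending rank order, followed by the
#' consensus scalar if the spec requests it.
#'
#' @param record An [encounter_record()].
#' @param schema A [cce_schema()].
#' @return An object of class `cce_vector`: list with `encounter_id`,
#'   named numeric `values` of length [cce_dimension()], and a `normalized`
#'   flag (always `FALSE` for freshly built vectors).
#' @examples
#' sch <- cce_schema(metric_quantitative("consults"),
#'                   metric_qualitative("importance_consults"))
#' rec <- encounter_record("e1", c(consults = 4),
#'   list(importance_consults = response_sample(c(0, 0, 10, 0, 0))))
#' build_cce_vector(rec, sch)
#' @export
build_cce_vector <- function(record, schema) {
  stopifnot(inherits(record, "encounter_record"), inherits(schema, "cce_schema"))
  parts <- lapply(schema$metrics, function(m) {
    if (m$kind == "quantitative") {
      if (!m$metric_id %in% names(record$quantitative))
        stop(sprintf("schema error: encounter '%s' is missing quantitative metric '%s'",
                     record$encounter_id, m$metric_id))
      v <- record$quantitative[[m$metric_id]]
      if (!is.finite(v))
        stop(sprintf("invalid record: non-finite value for metric '%s'", m$metric_id))
      v
    } else {
      if (!m$metric_id %in% names(record$qualitative))
        stop(sprintf("schema error: encounter '%s' is missing qualitative metric '%s'",
                     record$encounter_id, m$metric_id))
      s <- record$qualitative[[m$metric_id]]
      if (!identical(s$scale$values, m$scale$values))
        stop(sprintf("schema error: sample scale for metric '%s' does not match the schema",
                     m$metric_id))
      prof <- soc_profile(s, gompertz = m$gompertz)
      if (!is.null(m$rank_weights)) prof <- apply_rank_weights(prof, m$rank_weights)
      c(unname(prof$soc),
        if (m$include_consensus) consensus(s, gompertz = m$gompertz))
    }
  })
  values <- unlist(parts, use.names = FALSE)
  names(values) <- cce_dimnames(schema)
  structure(list(encounter_id = record$encounter_id, values = values,
                 normalized = FALSE),
            class = "cce_vector")
}

#' @export
print.cce_vector <- function(x, digits = 3, ...) {
  cat(sprintf("<cce_vector> encounter '%s', %d dimensions%s\n", x$encounter_id,
              length(x$values), if (x$normalized) " (normalized)" else ""))
  print(round(x$values, digits))
  invisible(x)
}

#' Build a cohort of CCE vectors
#'
#' Applies [build_cce_vector()] to a list of encounter records and stacks
#' the results into an encounters-by-dimensions matrix container.
#'
#' @param records List of [encounter_record()] objects with unique ids.
#' @param schema A [cce_schema()].
#' @return An object of class `cce_cohort`: list with the numeric matrix
#'   `values` (rownames = encounter ids, colnames = dimension names), the
#'   `schema`, a `normalized` flag and the min-max `norm` state (`NULL`
#'   until [normalize_cohort()] is applied).
#' @export
build_cohort <- function(records, schema) {
  if (inherits(records, "encounter_record")) records <- list(records)
  if (!length(records)) stop("invalid input: at least one encounter is required")
  vecs <- lapply(records, build_cce_vector, schema = schema)
  ids <- vapply(vecs, `[[`, character(1), "encounter_id")
  if (anyDuplicated(ids)) stop("invalid input: duplicate encounter_id")
  values <- do.call(rbind, lapply(vecs, `[[`, "values"))
  rownames(values) <- ids
  new_cohort(values, schema, normalized = FALSE, norm = NULL)
}

new_cohort <- function(values, schema, normalized, norm) {
  structure(list(values = values, schema = schema,
                 normalized = normalized, norm = norm),
            class = "cce_cohort")
}

#' @export
print.cce_cohort <- function(x, ...) {
  cat(sprintf("<cce_cohort> %d encounters x %d dimensions%s\n",
              nrow(x$values), ncol(x$values),
              if (x$normalized) " (normalized)" else ""))
  invisible(x)
}

#' Extract the encounters-by-dimensions matrix of a cohort
#'
#' @param x A `cce_cohort`.
#' @param ... Unused.
#' @return Numeric matrix with encounter ids as rownames.
#' @export
as.matrix.cce_cohort <- function(x, ...) x$values

# Accept a cohort or a bare matrix/vector and return a matrix.
cohort_matrix <- function(x) {
  if (inherits(x, "cce_cohort")) return(x$values)
  if (inherits(x, "cce_vector")) return(matrix(x$values, nrow = 1,
                                               dimnames = list(x$encounter_id, names(x$values))))
  if (is.matrix(x)) return(x)
  if (is.numeric(x)) return(matrix(x, nrow = 1))
  stop("invalid input: expected a cce_cohort, cce_vector or numeric matrix")
}

#' Min-max normalize a cohort
#'
#' Scales every dimension to `[0, 1]` across the cohort
#' (`(v - min) / (max - min)`). Dimensions that are constant across the
#' cohort map to 0.5: a constant contributes nothing to any distance, and
#' centring it avoids spurious extremes. The per-dimension minima and ranges
#' are retained in the returned cohort's `norm` state so new encounters can
#' be placed on the same coordinate scale with [apply_normalization()].
#' Normalizing an already-normalized cohort is the identity.
#'
#' @param cohort A `cce_cohort` (see [build_cohort()]).
#' @return The normalized `cce_cohort` with `normalized = TRUE` and `norm`
#'   set to `list(min, range)`.
#' @export
normalize_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cce_cohort"))
  if (cohort$normalized) return(cohort)
  v <- cohort$values
  mins <- apply(v, 2, min)
  maxs <- apply(v, 2, max)
  range <- maxs - mins
  scaled <- sweep(v, 2, mins, "-")
  pos <- range > 0
  scaled[, pos] <- sweep(scaled[, pos, drop = FALSE], 2, range[pos], "/")
  scaled[, !pos] <- 0.5
  new_cohort(scaled, cohort$schema, normalized = TRUE,
             norm = list(min = mins, range = range))
}

#' Place new vectors on a previously fitted normalization scale
#'
#' Applies frozen min-max statistics (from [normalize_cohort()] or a fitted
#' [cce_reference()]) to new vectors. Values outside the original cohort's
#' range fall outside `[0, 1]`; they are deliberately not clipped, so an
#' out-of-range encounter keeps its full distance from the reference.
#'
#' @param x A `cce_cohort`, `cce_vector`, numeric matrix or vector.
#' @param norm A `list(min, range)` as stored by [normalize_cohort()].
#' @return Object of the same shape with scaled values (cohorts/vectors are
#'   flagged `normalized`).
#' @export
apply_normalization <- function(x, norm) {
  if (is.null(norm)) stop("invalid input: no normalization state supplied")
  scale_mat <- function(m) {
    if (ncol(m) != length(norm$min))
      stop("schema error: dimension mismatch with normalization state")
    out <- sweep(m, 2, norm$min, "-")
    pos <- norm$range > 0
    out[, pos] <- sweep(out[, pos, drop = FALSE], 2, norm$range[pos], "/")
    out[, !pos] <- 0.5
    out
  }
  if (inherits(x, "cce_cohort")) {
    if (x$normalized) return(x)
    return(new_cohort(scale_mat(x$values), x$schema, normalized = TRUE, norm = norm))
  }
  if (inherits(x, "cce_vector")) {
    if (x$normalized) return(x)
    x$values <- drop(scale_mat(matrix(x$values, nrow = 1)))
    names(x$values) <- names(norm$min)
    x$normalized <- TRUE
    return(x)
  }
  if (is.matrix(x)) return(scale_mat(x))
  drop(scale_mat(matrix(x, nrow = 1)))
}
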
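# Structured capture of expert elicitation sessions.
#
# One expert contributes three elicited normal distributions on the QoL
# elicitation scale (EQ-5D utility x 100, bounded to [-20, 100]):
#   * the score of a typical non-responder in the open-repair arm,
#   * the score of a typical non-responder in the endovascular (eEVAR) arm,
#   * the eEVAR score again, conditional on a stated open-arm score,
# plus role metadata used for community-of-priors subgrouping.

.ROLES <- c("doctor", "nurse", "other")
.VENUES <- c("email", "conference", "face_to_face")
.YEARS_BANDS <- c("2-3", "4-6", "7-10", ">10", "unknown")
.FAMILIARITY <- c("some", "read_paper", "unknown")
.CORR_CATEGORIES <- c("positive", "zero", "negative")

#' Elicited normal distribution on the QoL scale
#'
#' One slider answer: the most likely QoL score (`mode`, the mean of the
#' expert's normal distribution) and the uncertainty about it (`sd`), both
#' on the elicitation scale (utility times 100, from -20 to 100).
#'
#' @param mode Most likely QoL score, in `[-20, 100]`.
#' @param sd Uncertainty standard deviation on the same scale, `> 0`.
#' @return An object of class `elicited_normal`.
#' @examples
#' elicited_normal(61, 16)
#' @export
elicited_normal <- function(mode, sd) {
  mode <- as.numeric(mode)
  sd <- as.numeric(sd)
  if (length(mode) != 1L || length(sd) != 1L || !is.finite(mode) || !is.finite(sd))
    stopf("elicited_normal: 'mode' and 'sd' must be single finite numbers")
  structure(list(mode = mode, sd = sd), class = "elicited_normal")
}

#' @export
print.elicited_normal <- function(x, ...) {
  cat(sprintf("Elicited N(mode = %g, sd = %g) on the [-20, 100] QoL scale\n",
              x$mode, x$sd))
  invisible(x)
}

#' Probability mass of an elicited normal outside an interval
#'
#' Elicited distributions are fitted as untruncated normals on a bounded
#' scale; this computes the fraction of their mass escaping the bounds,
#' used for soft validation warnings.
#'
#' @param x An [elicited_normal()].
#' @param lower,upper Interval bounds (defaults: the elicitation scale).
#' @return Probability in `[0, 1]`.
#' @export
outside_mass <- function(x, lower = .QOL_MIN, upper = .QOL_MAX) {
  if (x$sd <= 0) return(as.numeric(x$mode < lower || x$mode > upper))
  stats::pnorm(lower, x$mode, x$sd) + stats::pnorm(upper, x$mode, x$sd, lower.tail = FALSE)
}

#' Conditional elicitation record
#'
#' The third question: the expert's distribution for the eEVAR
#' non-responder's score given a stated open-arm score
#' (`conditioning_value`).  This supplies the information needed to derive
#' the correlation between the two sensitivity parameters.
#'
#' @param conditioning_value Open-arm score shown to the expert, in
#'   `[-20, 100]`.
#' @param distribution An [elicited_normal()] for the eEVAR score given that
#'   value.
#' @return An object of class `conditional_elicitation`.
#' @export
conditional_elicitation <- function(conditioning_value, distribution) {
  conditioning_value <- as.numeric(conditioning_value)
  if (length(conditioning_value) != 1L || !is.finite(conditioning_value))
    stopf("conditional_elicitation: 'conditioning_value' must be a single finite number")
  if (!inherits(distribution, "elicited_normal"))
    stopf("conditional_elicitation: 'distribution' must be an elicited_normal")
  structure(list(conditioning_value = conditioning_value,
                 distribution = distribution),
            class = "conditional_elicitation")
}

#' Anchor scores displayed during elicitation
#'
#' The observed-responder QoL scores marked on the elicitation scale, one
#' per arm.  Sensitivity parameters are offsets of the elicited
#' non-responder scores from these anchors, so they are required input with
#' no default.
#'
#' @param open_observed Score shown for the typical open-repair responder.
#' @param evar_observed Score shown for the typical eEVAR responder.
#' @return An object of class `anchor_scores`.
#' @examples
#' anchor_scores(open_observed = 65, evar_observed = 73)
#' @export
anchor_scores <- function(open_observed, evar_observed) {
  open_observed <- as.numeric(open_observed)
  evar_observed <- as.numeric(evar_observed)
  for (v in c(open_observed, evar_observed)) {
    if (length(v) != 1L || !is.finite(v) || v < .QOL_MIN || v > .QOL_MAX)
      stopf("anchor_scores: anchors must be single values in [%g, %g]", .QOL_MIN, .QOL_MAX)
  }
  structure(list(open_observed = open_observed, evar_observed = evar_observed),
            class = "anchor_scores")
}

#' One expert's complete elicitation session
#'
#' @param expert_id Opaque unique identifier.
#' @param role One of `"doctor"`, `"nurse"`, `"other"`.
#' @param open_missing [elicited_normal()] for the open-arm non-responder.
#' @param evar_missing [elicited_normal()] for the eEVAR non-responder.
#' @param evar_given_open [conditional_elicitation()] for the eEVAR score
#'   given a stated open-arm score.
#' @param venue How the response was captured.
#' @param years_band Years-in-role band.
#' @param familiarity Familiarity with the published trial results.
#' @param correlation_category Optional categorical answer about the
#'   correlation between the two non-responder scores (`"positive"`,
#'   `"zero"`, `"negative"`), or `NA`.
#' @param complete Whether all three distributions were answered.
#' @return An object of class `expert_response`.
#' @export
expert_response <- function(expert_id, role,
                            open_missing, evar_missing, evar_given_open,
                            venue = "email", years_band = "unknown",
                            familiarity = "unknown",
                            correlation_category = NA_character_,
                            complete = TRUE) {
  expert_id <- as.character(expert_id)
  if (length(expert_id) != 1L || is.na(expert_id) || !nzchar(expert_id))
    stopf("expert_response: 'expert_id' must be a non-empty string")
  role <- match.arg(role, .ROLES)
  venue <- match.arg(venue, .VENUES)
  years_band <- match.arg(years_band, .YEARS_BANDS)
  familiarity <- match.arg(familiarity, .FAMILIARITY)
  if (!is.na(correlation_category))
    correlation_category <- match.arg(correlation_category, .CORR_CATEGORIES)
  complete <- isTRUE(complete)
  if (complete) {
    if (!inherits(open_missing, "elicited_normal") ||
        !inherits(evar_missing, "elicited_normal") ||
        !inherits(evar_given_open, "conditional_elicitation"))
      stopf("expert_response: a complete response needs all three elicited distributions")
  }
  structure(list(expert_id = expert_id, role = role, venue = venue,
                 years_band = years_band, familiarity = familiarity,
                 open_missing = open_missing, evar_missing = evar_missing,
                 evar_given_open = evar_given_open,
                 correlation_category = correlation_category,
                 complete = complete),
            class = "expert_response")
}

#' A set of expert responses plus shared anchors
#'
#' @param responses List of [expert_response()] objects with unique
#'   `expert_id`s.
#' @param anchors An [anchor_scores()] object, or `NULL` if supplied later.
#' @param schema_version Schema version string stored with the set.
#' @return An object of class `elicitation_set`.
#' @export
elicitation_set <- function(responses, anchors = NULL, schema_version = "1.0") {
  if (!is.list(responses) || (length(responses) &&
      !all(vapply(responses, inherits, logical(1), "expert_response"))))
    stopf("elicitation_set: 'responses' must be a list of expert_response objects")
  ids <- vapply(responses, `[[`, character(1), "expert_id")
  if (anyDuplicated(ids))
    stopf("elicitation_set: duplicate expert_id: %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (!is.null(anchors) && !inherits(anchors, "anchor_scores"))
    stopf("elicitation_set: 'anchors' must be anchor_scores or NULL")
  structure(list(responses = responses, anchors = anchors,
                 schema_version = as.character(schema_version)),
            class = "elicitation_set")
}

#' @export
print.elicitation_set <- function(x, ...) {
  roles <- table(factor(vapply(x$responses, `[[`, character(1), "role"), .ROLES))
  cat(sprintf("Elicitation set: %d expert response(s) (%s)\n",
              length(x$responses),
              paste(sprintf("%s: %d", names(roles), roles), collapse = ", ")))
  if (!is.null(x$anchors))
    cat(sprintf("Anchors: OPEN %g, eEVAR %g (QoL scale)\n",
                x$anchors$open_observed, x$anchors$evar_observed))
  invisible(x)
}

#' @export
length.elicitation_set <- function(x) length(x$responses)

#' Validation policy for elicitation records
#'
#' Hard violations (out-of-scale mode, non-positive SD, bad conditioning
#' value) reject a record; soft flags mark it for analyst review without
#' rejection.  A response whose uncertainty SD exceeds `flag_sd` is flagged
#' as near-total uncertainty — such responses are excluded from analysis
#' only by the explicit opt-in filter [filter_high_uncertainty()], never
#' silently.
#'
#' @param scale_min,scale_max Bounds of the elicitation scale.
#' @param flag_sd SD (scale units) above which a response is flagged as
#'   expressing near-total uncertainty.  Default 40: a normal with SD 40
#'   spreads its mass over essentially the whole 120-unit scale.
#' @param outside_mass_warn Fraction of normal mass outside the scale that
#'   triggers a soft flag.
#' @return An object of class `validation_policy`.
#' @export
validation_policy <- function(scale_min = .QOL_MIN, scale_max = .QOL_MAX,
                              flag_sd = 40, outside_mass_warn = 0.05) {
  structure(list(scale_min = scale_min, scale_max = scale_max,
                 flag_sd = flag_sd, outside_mass_warn = outside_mass_warn),
            class = "validation_policy")
}

violation <- function(field, severity, message) {
  data.frame(field = field, severity = severity, message = message,
             stringsAsFactors = FALSE)
}

check_elicited <- function(x, field, policy) {
  v <- list()
  if (!inherits(x, "elicited_normal")) {
    return(violation(field, "error", "missing elicited distribution"))
  }
  if (x$mode < policy$scale_min || x$mode > policy$scale_max)
    v <- c(v, list(violation(paste0(field, ".mode"), "error",
                             sprintf("mode %g out of range [%g, %g]",
                                     x$mode, policy$scale_min, policy$scale_max))))
  if (x$sd <= 0)
    v <- c(v, list(violation(paste0(field, ".sd"), "error",
                             sprintf("sd %g must be > 0", x$sd))))
  else {
    if (x$sd > policy$flag_sd)
      v <- c(v, list(violation(paste0(field, ".sd"), "flag",
                               sprintf("sd %g exceeds %g: near-total uncertainty",
                                       x$sd, policy$flag_sd))))
    m <- outside_mass(x, policy$scale_min, policy$scale_max)
    if (m > policy$outside_mass_warn)
      v <- c(v, list(violation(field, "flag",
                               sprintf("%.1f%% of mass outside [%g, %g]",
                                       100 * m, policy$scale_min, policy$scale_max))))
  }
  do.call(rbind, v)
}

#' Validate one expert response
#'
#' Validation is total: every structurally complete record yields a
#' (possibly empty) violation table, never an error.  Rows with severity
#' `"error"` are hard invariant violations; `"flag"` rows mark soft issues
#' such as near-total uncertainty or heavy mass outside the scale.
#'
#' @param r An [expert_response()].
#' @param policy A [validation_policy()].
#' @return A data frame with columns `field`, `severity`, `message`
#'   (zero rows when the record is clean).
#' @examples
#' r <- expert_response("e1", "doctor",
#'   elicited_normal(61, 16), elicited_normal(72, 15),
#'   conditional_elicitation(70, elicited_normal(74, 12)))
#' validate_response(r)
#' @export
validate_response <- function(r, policy = validation_policy()) {
  if (!inherits(r, "expert_response"))
    stopf("validate_response: 'r' must be an expert_response")
  empty <- violation(character(0), character(0), character(0))
  if (!r$complete)
    return(rbind(empty, violation("complete", "flag", "incomplete response")))
  v <- rbind(
    check_elicited(r$open_missing, "open_missing", policy),
    check_elicited(r$evar_missing, "evar_missing", policy),
    check_elicited(r$evar_given_open$distribution, "evar_given_open", policy)
  )
  cv <- r$evar_given_open$conditioning_value
  if (cv < policy$scale_min || cv > policy$scale_max)
    v <- rbind(v, violation("evar_given_open.conditioning_value", "error",
                            sprintf("conditioning value %g out of range", cv)))
  if (is.null(v)) empty else v
}

#' Validate every response in a set
#'
#' @param set An [elicitation_set()].
#' @param policy A [validation_policy()].
#' @return A data frame with columns `expert_id`, `field`, `severity`,
#'   `message`.
#' @export
validate_set <- function(set, policy = validation_policy()) {
  out <- lapply(set$responses, function(r) {
    v <- validate_response(r, policy)
    if (nrow(v)) cbind(expert_id = r$expert_id, v) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(expert_id = character(0), field = character(0),
                      severity = character(0), message = character(0))
  out
}

#' Drop near-total-uncertainty responses (explicit opt-in filter)
#'
#' Removes responses flagged by the validation policy's `flag_sd`
#' threshold, reporting which experts were dropped.  Mirrors the analyst
#' decision to exclude an expert who expressed almost complete uncertainty;
#' exclusion is never silent.
#'
#' @param set An [elicitation_set()].
#' @param policy A [validation_policy()]; only `flag_sd` is used.
#' @return The filtered `elicitation_set`; dropped ids in attribute
#'   `"dropped"`.
#' @export
filter_high_uncertainty <- function(set, policy = validation_policy()) {
  flagged <- vapply(set$responses, function(r) {
    r$complete && (r$open_missing$sd > policy$flag_sd ||
                   r$evar_missing$sd > policy$flag_sd)
  }, logical(1))
  dropped <- vapply(set$responses[flagged], `[[`, character(1), "expert_id")
  if (length(dropped))
    message("filter_high_uncertainty: dropping ", length(dropped),
            " response(s): ", paste(dropped, collapse = ", "))
  out <- elicitation_set(set$responses[!flagged], set$anchors, set$schema_version)
  attr(out, "dropped") <- dropped
  out
}

# ---- serialisation ---------------------------------------------------------

response_to_list <- function(r) {
  list(expert_id = r$expert_id, role = r$role, venue = r$venue,
       years_band = r$years_band, familiarity = r$familiarity,
       correlation_category = if (is.na(r$correlation_category)) NULL else r$correlation_category,
       complete = r$complete,
       open_missing = list(mode = r$open_missing$mode, sd = r$open_missing$sd),
       evar_missing = list(mode = r$evar_missing$mode, sd = r$evar_missing$sd),
       evar_given_open = list(
         conditioning_value = r$evar_given_open$conditioning_value,
         distribution = list(mode = r$evar_given_open$distribution$mode,
                             sd = r$evar_given_open$distribution$sd)))
}

num_field <- function(rec, path, where) {
  x <- rec
  for (p in path) {
    x <- x[[p]]
    if (is.null(x)) stopf("%s: missing field '%s'", where, paste(path, collapse = "."))
  }
  if (!is.numeric(x) || length(x) != 1L)
    stopf("%s: field '%s' must be a single number", where, paste(path, collapse = "."))
  x
}

response_from_list <- function(rec, where) {
  id <- rec$expert_id
  if (is.null(id)) stopf("%s: missing field 'expert_id'", where)
  expert_response(
    expert_id = id,
    role = rec$role %||% "other",
    venue = rec$venue %||% "email",
    years_band = rec$years_band %||% "unknown",
    familiarity = rec$familiarity %||% "unknown",
    correlation_category = rec$correlation_category %||% NA_character_,
    complete = rec$complete %||% TRUE,
    open_missing = elicited_normal(num_field(rec, c("open_missing", "mode"), where),
                                   num_field(rec, c("open_missing", "sd"), where)),
    evar_missing = elicited_normal(num_field(rec, c("evar_missing", "mode"), where),
                                   num_field(rec, c("evar_missing", "sd"), where)),
    evar_given_open = conditional_elicitation(
      num_field(rec, c("evar_given_open", "conditioning_value"), where),
      elicited_normal(num_field(rec, c("evar_given_open", "distribution", "mode"), where),
                      num_field(rec, c("evar_given_open", "distribution", "sd"), where))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.CSV_COLS <- c("expert_id", "role", "venue", "years_band", "familiarity",
               "correlation_category", "complete",
               "open_mode", "open_sd", "evar_mode", "evar_sd",
               "cond_value", "cond_mode", "cond_sd",
               "anchor_open", "anchor_evar")

guess_format <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
  else if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv"
  else stopf("cannot guess format of '%s'; pass format = \"json\" or \"csv\"", path)
}

#' Read an elicitation set from file
#'
#' Supports the package's JSON layout (nested records, shared anchors; a
#' JSON Schema ships in `inst/schema/`) and a flat CSV dialect (one row per
#' expert, conditional elicitation in `cond_*` columns, anchors repeated in
#' `anchor_open`/`anchor_evar`).  Every record is validated on the way in:
#' hard invariant violations reject the file with an error naming the
#' offending expert and field; soft flags are attached as the
#' `"validation"` attribute.
#'
#' @param source Path to the file.
#' @param format `"json"`, `"csv"`, or `"auto"` (extension-based).
#' @param policy A [validation_policy()].
#' @return A validated [elicitation_set()].
#' @export
read_responses <- function(source, format = c("auto", "json", "csv"),
                           policy = validation_policy()) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(source)
  if (!file.exists(source)) stopf("read_responses: no such file: %s", source)
  set <- if (format == "json") read_responses_json(source) else read_responses_csv(source)
  v <- validate_set(set, policy)
  bad <- v[v$severity == "error", , drop = FALSE]
  if (nrow(bad))
    stopf("read_responses: invalid record(s):\n%s",
          paste(sprintf("  expert '%s', field '%s': %s",
                        bad$expert_id, bad$field, bad$message), collapse = "\n"))
  attr(set, "validation") <- v
  set
}

read_responses_json <- function(source) {
  doc <- tryCatch(jsonlite::read_json(source),
                  error = function(e) stopf("read_responses: malformed JSON in '%s': %s",
                                            source, conditionMessage(e)))
  recs <- doc$responses %||% list()
  responses <- lapply(seq_along(recs), function(i)
    response_from_list(recs[[i]], sprintf("%s: response %d", basename(source), i)))
  anchors <- NULL
  if (!is.null(doc$anchors))
    anchors <- anchor_scores(num_field(doc, c("anchors", "open_observed"), source),
                             num_field(doc, c("anchors", "evar_observed"), source))
  elicitation_set(responses, anchors, doc$schema_version %||% "1.0")
}

read_responses_csv <- function(source) {
  df <- tryCatch(utils::read.csv(source, stringsAsFactors = FALSE,
                                 fileEncoding = "UTF-8"),
                 error = function(e) stopf("read_responses: malformed CSV in '%s': %s",
                                           source, conditionMessage(e)))
  need <- setdiff(.CSV_COLS[1:14], names(df))
  if (length(need))
    stopf("read_responses: CSV '%s' missing column(s): %s",
          source, paste(need, collapse = ", "))
  responses <- lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    where <- sprintf("%s: line %d", basename(source), i + 1L)
    for (col in c("open_mode", "open_sd", "evar_mode", "evar_sd",
                  "cond_value", "cond_mode", "cond_sd"))
      if (!is.numeric(row[[col]]) || is.na(row[[col]]))
        stopf("%s: field '%s' must be a number", where, col)
    expert_response(
      expert_id = row$expert_id, role = row$role, venue = row$venue,
      years_band = row$years_band, familiarity = row$familiarity,
      correlation_category = if (is.na(row$correlation_category) ||
                                 !nzchar(row$correlation_category))
        NA_character_ else row$correlation_category,
      complete = as.logical(row$complete),
      open_missing = elicited_normal(row$open_mode, row$open_sd),
      evar_missing = elicited_normal(row$evar_mode, row$evar_sd),
      evar_given_open = conditional_elicitation(
        row$cond_value, elicited_normal(row$cond_mode, row$cond_sd)))
  })
  anchors <- NULL
  if (all(c("anchor_open", "anchor_evar") %in% names(df)) && nrow(df) &&
      !any(is.na(df$anchor_open))) {
    if (length(unique(df$anchor_open)) > 1L || length(unique(df$anchor_evar)) > 1L)
      stopf("read_responses: '%s' carries inconsistent anchor columns", source)
    anchors <- anchor_scores(df$anchor_open[1], df$anchor_evar[1])
  }
  elicitation_set(responses, anchors)
}

#' Write an elicitation set to file
#'
#' Inverse of [read_responses()]: a written set reads back field-for-field
#' identically, in either format.
#'
#' @param set An [elicitation_set()].
#' @param sink Output path.
#' @param format `"json"`, `"csv"`, or `"auto"` (extension-based).
#' @return `sink`, invisibly.
#' @export
write_responses <- function(set, sink, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(sink)
  if (!inherits(set, "elicitation_set"))
    stopf("write_responses: 'set' must be an elicitation_set")
  if (format == "json") {
    doc <- list(schema_version = set$schema_version,
                anchors = if (is.null(set$anchors)) NULL else
                  list(open_observed = set$anchors$open_observed,
                       evar_observed = set$anchors$evar_observed),
                responses = lapply(set$responses, response_to_list))
    jsonlite::write_json(doc, sink, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    rows <- lapply(set$responses, function(r) data.frame(
      expert_id = r$expert_id, role = r$role, venue = r$venue,
      years_band = r$years_band, familiarity = r$familiarity,
      correlation_category = if (is.na(r$correlation_category)) "" else r$correlation_category,
      complete = r$complete,
      open_mode = r$open_missing$mode, open_sd = r$open_missing$sd,
      evar_mode = r$evar_missing$mode, evar_sd = r$evar_missing$sd,
      cond_value = r$evar_given_open$conditioning_value,
      cond_mode = r$evar_given_open$distribution$mode,
      cond_sd = r$evar_given_open$distribution$sd,
      anchor_open = if (is.null(set$anchors)) NA_real_ else set$anchors$open_observed,
      anchor_evar = if (is.null(set$anchors)) NA_real_ else set$anchors$evar_observed,
      stringsAsFactors = FALSE))
    df <- if (length(rows)) do.call(rbind, rows) else
      as.data.frame(stats::setNames(rep(list(character(0)), length(.CSV_COLS)), .CSV_COLS))
    utils::write.csv(df, sink, row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(sink)
}
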
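# From one expert's elicitation session to a bivariate normal prior on the
# pattern-mixture sensitivity parameters (delta_O, delta_E): the offsets,
# on the 0-1 utility scale, between the mean QoL of patients who did not
# and did return the questionnaire, one per randomised arm.

#' Normal specification (mean, sd)
#'
#' Lightweight holder for a univariate normal on the utility scale, used
#' for sensitivity-parameter marginals.  `sd = 0` denotes a point mass
#' (a fixed, "known" sensitivity parameter, as in a tipping-point scan).
#'
#' @param mean Mean.
#' @param sd Standard deviation, `>= 0`.
#' @return An object of class `normal_spec`.
#' @export
normal_spec <- function(mean, sd) {
  mean <- as.numeric(mean); sd <- as.numeric(sd)
  if (length(mean) != 1L || length(sd) != 1L || !is.finite(mean) || !is.finite(sd))
    stopf("normal_spec: 'mean' and 'sd' must be single finite numbers")
  if (sd < 0) stopf("normal_spec: 'sd' must be >= 0")
  structure(list(mean = mean, sd = sd), class = "normal_spec")
}

as_normal_spec <- function(x, what = "delta") {
  if (inherits(x, "normal_spec")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(normal_spec(x[1], x[2]))
  if (is.list(x) && all(c("mean", "sd") %in% names(x)))
    return(normal_spec(x$mean, x$sd))
  stopf("'%s' must be a normal_spec, a (mean, sd) pair, or list(mean=, sd=)", what)
}

#' Convert an elicited QoL distribution to a sensitivity-parameter marginal
#'
#' The elicited distribution lives on the QoL elicitation scale (utility
#' times `scale`); the sensitivity parameter delta is the offset of the
#' non-responder's score from the same-arm observed-responder anchor, on
#' the utility scale:
#' `mean = (mode - anchor) / scale`, `sd = sd / scale`.
#'
#' @param elicited An [elicited_normal()].
#' @param anchor Anchor score on the elicitation scale (the observed
#'   responder's marked value for the same arm).
#' @param scale Elicitation scale factor (default 100; set to 1 for inputs
#'   already on the utility scale).
#' @return A [normal_spec()] for delta on the utility scale.
#' @examples
#' to_delta(elicited_normal(61, 16), anchor = 65)  # mean -0.04, sd 0.16
#' @export
to_delta <- function(elicited, anchor, scale = .QOL_SCALE) {
  if (!inherits(elicited, "elicited_normal"))
    stopf("to_delta: 'elicited' must be an elicited_normal")
  anchor <- as.numeric(anchor)
  if (length(anchor) != 1L || !is.finite(anchor))
    stopf("to_delta: 'anchor' must be a single finite number")
  if (elicited$sd <= 0) stopf("to_delta: elicited sd must be > 0")
  normal_spec((elicited$mode - anchor) / scale, elicited$sd / scale)
}

#' Derive the correlation between the two sensitivity parameters
#'
#' The third elicitation question gives the expert's distribution for
#' delta_E conditional on a stated delta_O value.  If the expert's joint
#' belief is bivariate normal, the conditional mean is linear in the
#' conditioning value and the conditional SD is deflated by
#' `sqrt(1 - rho^2)`, so rho is recoverable two ways:
#'
#' * `"mean_shift"`: `rho = (cond_mean - mean_E) * sd_O /
#'   ((cond_value - mean_O) * sd_E)` — uses the location shift of the
#'   conditional, the quantity the question most directly elicits;
#' * `"sd_ratio"`: `|rho| = sqrt(1 - (cond_sd / sd_E)^2)` — uses the
#'   variance deflation; the sign comes from `sign_hint` (`"auto"` takes
#'   the sign of the mean-shift formula, 0 when that is undefined).
#'
#' Values outside `[-1, 1]` (inconsistent elicitations) are clamped with a
#' warning; a conditional SD above the marginal SD gives `rho = 0` with a
#' warning under `"sd_ratio"`.
#'
#' @param marg_O,marg_E Marginal [normal_spec()]s for delta_O and delta_E
#'   (utility scale).
#' @param cond The conditional elicitation on the utility scale:
#'   `list(value =, mean =, sd =)` where `value` is the conditioning
#'   delta_O.
#' @param method `"mean_shift"` (default) or `"sd_ratio"`.
#' @param sign_hint `"auto"`, `"+"`, or `"-"` (used by `"sd_ratio"`).
#' @return Correlation in `[-1, 1]`.
#' @export
derive_correlation <- function(marg_O, marg_E, cond,
                               method = c("mean_shift", "sd_ratio"),
                               sign_hint = c("auto", "+", "-")) {
  method <- match.arg(method)
  sign_hint <- match.arg(sign_hint)
  marg_O <- as_normal_spec(marg_O, "marg_O")
  marg_E <- as_normal_spec(marg_E, "marg_E")
  if (!is.list(cond) || !all(c("value", "mean", "sd") %in% names(cond)))
    stopf("derive_correlation: 'cond' must be list(value=, mean=, sd=)")
  if (marg_O$sd <= 0 || marg_E$sd <= 0)
    stopf("derive_correlation: marginal sds must be > 0")

  shift_rho <- function() {
    dx <- cond$value - marg_O$mean
    if (dx == 0) return(NA_real_)
    (cond$mean - marg_E$mean) * marg_O$sd / (dx * marg_E$sd)
  }

  if (method == "mean_shift") {
    rho <- shift_rho()
    if (is.na(rho))
      stopf("derive_correlation: uninformative conditioning point (conditioning value equals the delta_O marginal mean)")
  } else {
    ratio <- cond$sd / marg_E$sd
    if (ratio > 1) {
      warnf("derive_correlation: conditional sd exceeds marginal sd; returning rho = 0")
      return(0)
    }
    rho <- sqrt(max(0, 1 - ratio^2))
    s <- switch(sign_hint,
                "+" = 1, "-" = -1,
                auto = {
                  raw <- shift_rho()
                  if (is.na(raw) || raw == 0) 0 else sign(raw)
                })
    rho <- rho * if (s == 0) 0 else s
  }
  if (abs(rho) > 1) {
    warnf("derive_correlation: raw value %.3f outside [-1, 1]; clamped", rho)
    rho <- max(-1, min(1, rho))
  }
  rho
}

#' Bivariate normal prior on (delta_O, delta_E)
#'
#' One expert's prior over the two sensitivity parameters, on the 0-1
#' utility scale.  Elicitation-derived priors always have positive SDs;
#' zero SDs (point masses) are admitted so that fixed-delta analyses (MAR,
#' tipping points) share the same machinery, and force the corresponding
#' correlation contribution to vanish.
#'
#' @param expert_id Identifier string.
#' @param mean_O,sd_O Marginal mean and SD of delta_O.
#' @param mean_E,sd_E Marginal mean and SD of delta_E.
#' @param rho Correlation in `[-1, 1]`.
#' @return An object of class `sensitivity_prior`.
#' @export
sensitivity_prior <- function(expert_id, mean_O, sd_O, mean_E, sd_E, rho = 0) {
  vals <- c(mean_O = mean_O, sd_O = sd_O, mean_E = mean_E, sd_E = sd_E, rho = rho)
  if (!all(is.finite(vals))) stopf("sensitivity_prior: all parameters must be finite")
  if (sd_O < 0 || sd_E < 0) stopf("sensitivity_prior: sds must be >= 0")
  if (rho < -1 || rho > 1) stopf("sensitivity_prior: rho must lie in [-1, 1]")
  if ((sd_O == 0 || sd_E == 0) && rho != 0)
    stopf("sensitivity_prior: rho must be 0 when a marginal sd is 0")
  structure(list(expert_id = as.character(expert_id),
                 mean_O = as.numeric(mean_O), sd_O = as.numeric(sd_O),
                 mean_E = as.numeric(mean_E), sd_E = as.numeric(sd_E),
                 rho = as.numeric(rho)),
            class = "sensitivity_prior")
}

#' @export
print.sensitivity_prior <- function(x, ...) {
  cat(sprintf(
    "Sensitivity prior [%s]: delta_O ~ N(%.4g, %.4g^2), delta_E ~ N(%.4g, %.4g^2), rho = %.3f\n",
    x$expert_id, x$mean_O, x$sd_O, x$mean_E, x$sd_E, x$rho))
  invisible(x)
}

#' @export
mean.sensitivity_prior <- function(x, ...) c(delta_O = x$mean_O, delta_E = x$mean_E)

#' Covariance matrix of a sensitivity prior
#' @param object A [sensitivity_prior()].
#' @param ... Unused.
#' @return 2x2 covariance matrix (rows/cols `delta_O`, `delta_E`).
#' @export
vcov.sensitivity_prior <- function(object, ...) {
  v <- matrix(c(object$sd_O^2, rep(object$rho * object$sd_O * object$sd_E, 2),
                object$sd_E^2), 2, 2,
              dimnames = list(c("delta_O", "delta_E"), c("delta_O", "delta_E")))
  v
}

#' Build one expert's bivariate normal sensitivity prior
#'
#' Marginals come from [to_delta()] applied to the two unconditional
#' elicitations against their same-arm anchors; the correlation comes from
#' [derive_correlation()] on the conditional elicitation, mapped to the
#' utility scale.  When the expert also answered the categorical
#' correlation question, that answer overrides the derived value only if
#' `respect_categorical = TRUE` (a `"zero"` answer then forces `rho = 0`;
#' `"positive"`/`"negative"` force the sign).
#'
#' A warning is emitted when more than `mass_warn_frac` of either marginal's
#' mass falls outside `mass_bounds` on the utility scale (elicited normals
#' are used untruncated on the bounded scale).
#'
#' @param r A complete, valid [expert_response()].
#' @param anchors [anchor_scores()] for the two arms.
#' @param method Correlation derivation method, see [derive_correlation()].
#' @param sign_hint Passed to [derive_correlation()].
#' @param respect_categorical Whether the categorical correlation answer
#'   overrides the derived rho (default `FALSE`).
#' @param scale Elicitation scale factor.
#' @param mass_bounds,mass_warn_frac Soft plausibility bounds for the delta
#'   marginals on the utility scale.
#' @return A [sensitivity_prior()].
#' @export
build_expert_prior <- function(r, anchors,
                               method = c("mean_shift", "sd_ratio"),
                               sign_hint = "auto",
                               respect_categorical = FALSE,
                               scale = .QOL_SCALE,
                               mass_bounds = c(-1.2, 1),
                               mass_warn_frac = 0.05) {
  method <- match.arg(method)
  if (!inherits(r, "expert_response")) stopf("build_expert_prior: 'r' must be an expert_response")
  if (!r$complete) stopf("build_expert_prior: response '%s' is incomplete", r$expert_id)
  if (!inherits(anchors, "anchor_scores"))
    stopf("build_expert_prior: 'anchors' must be anchor_scores")

  marg_O <- to_delta(r$open_missing, anchors$open_observed, scale)
  marg_E <- to_delta(r$evar_missing, anchors$evar_observed, scale)
  cond <- list(
    value = (r$evar_given_open$conditioning_value - anchors$open_observed) / scale,
    mean = (r$evar_given_open$distribution$mode - anchors$evar_observed) / scale,
    sd = r$evar_given_open$distribution$sd / scale)

  rho <- derive_correlation(marg_O, marg_E, cond, method, sign_hint)
  if (respect_categorical && !is.na(r$correlation_category)) {
    rho <- switch(r$correlation_category,
                  zero = 0,
                  positive = abs(rho),
                  negative = -abs(rho))
  }

  for (arm in list(c("delta_O", "open"), c("delta_E", "evar"))) {
    m <- if (arm[2] == "open") marg_O else marg_E
    out <- stats::pnorm(mass_bounds[1], m$mean, m$sd) +
      stats::pnorm(mass_bounds[2], m$mean, m$sd, lower.tail = FALSE)
    if (out > mass_warn_frac)
      warnf("build_expert_prior ['%s']: %.1f%% of %s prior mass outside [%g, %g]",
            r$expert_id, 100 * out, arm[1], mass_bounds[1], mass_bounds[2])
  }

  prior <- sensitivity_prior(r$expert_id, marg_O$mean, marg_O$sd,
                             marg_E$mean, marg_E$sd, rho)
  attr(prior, "method") <- method
  prior
}

#' Build sensitivity priors for a whole panel
#'
#' Applies [build_expert_prior()] to every complete response in the set,
#' using the set's stored anchors unless `anchors` is supplied.
#'
#' @param set An [elicitation_set()].
#' @param anchors Optional [anchor_scores()] overriding the set's.
#' @param ... Passed to [build_expert_prior()].
#' @return A list of [sensitivity_prior()] objects, named by expert id.
#' @export
build_panel_priors <- function(set, anchors = NULL, ...) {
  if (!inherits(set, "elicitation_set"))
    stopf("build_panel_priors: 'set' must be an elicitation_set")
  anchors <- anchors %||% set$anchors
  if (is.null(anchors))
    stopf("build_panel_priors: anchors are required (none stored in the set)")
  complete <- Filter(function(r) r$complete, set$responses)
  priors <- lapply(complete, build_expert_prior, anchors = anchors, ...)
  names(priors) <- vapply(priors, `[[`, character(1), "expert_id")
  priors
}

#' Read / write sensitivity priors as JSON
#'
#' Priors are stored as a JSON array of records with fields `expert_id`,
#' `mean_O`, `sd_O`, `mean_E`, `sd_E`, `rho`.
#'
#' @param priors List of [sensitivity_prior()] objects.
#' @param path File path.
#' @return `write_priors`: `path` invisibly; `read_priors`: list of priors.
#' @export
write_priors <- function(priors, path) {
  recs <- lapply(priors, function(p)
    list(expert_id = p$expert_id, mean_O = p$mean_O, sd_O = p$sd_O,
         mean_E = p$mean_E, sd_E = p$sd_E, rho = p$rho))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_priors
#' @export
read_priors <- function(path) {
  recs <- jsonlite::read_json(path)
  priors <- lapply(recs, function(p)
    sensitivity_prior(p$expert_id, p$mean_O, p$sd_O, p$mean_E, p$sd_E, p$rho))
  names(priors) <- vapply(priors, `[[`, character(1), "expert_id")
  priors
}
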
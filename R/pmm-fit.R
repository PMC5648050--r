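# Front-end fitting function in the classic modelling idiom: formula +
# data in, a classed fit out, with the usual extractor methods.

#' Fit a pattern-mixture model for a trial with missing outcomes
#'
#' One entry point over the package's two estimators.  `method = "bayes"`
#' runs the fully Bayesian fit ([bayesian_fit()]) with the supplied prior
#' on the sensitivity parameters; `method = "moment"` runs the closed-form
#' moment estimator ([moment_estimate_pooled()]) on the arm summaries
#' derived from the data.  `missing = "mar"` fixes both deltas at zero;
#' `missing = "complete_case"` additionally ignores the missingness
#' weighting.
#'
#' The model: within each arm, observed outcomes are normal with mean
#' `mu_a`; the unobserved non-responder mean is `mu_a + delta_a`; the arm
#' mean is `mu_a + pi_a delta_a` with `pi_a` the missing proportion; and
#' the estimand is `Delta = (mu_E + pi_E delta_E) - (mu_O + pi_O delta_O)`,
#' with `(delta_O, delta_E)` given by the (typically elicitation-derived)
#' `prior`.
#'
#' @param formula Model formula `qol ~ arm` or `qol ~ arm + covariate...`.
#'   The treatment term must be a two-level factor; levels named
#'   `OPEN`/`EEVAR` (any case) are mapped to the open-repair and
#'   endovascular roles, otherwise the first level is treated as control
#'   (`O`) and the second as treatment (`E`).
#' @param data Data frame of patient records; outcomes are `NA` when
#'   missing (or flagged in an optional `missing` column).
#' @param prior A [pooled_prior()] or single [sensitivity_prior()]
#'   (ignored under `missing = "mar"`/`"complete_case"`).
#' @param method `"bayes"` (default) or `"moment"`.
#' @param missing `"mnar"` (default, uses `prior`), `"mar"`, or
#'   `"complete_case"`.
#' @param config An [mcmc_config()] for the Bayesian methods.
#' @param conf Confidence level for the moment method.
#' @return An object of class `pmm_fit` with components `estimate`, `ci`,
#'   `p_mcid` (Bayes only), and the underlying `fit`.
#' @examples
#' sim <- generate_trial(trial_gen_config(n_per_arm = 60, seed = 7))
#' prior <- linear_pool(list(sensitivity_prior("x", -0.05, 0.1, -0.01, 0.04, 0)))
#' fit <- pmm_fit(qol ~ arm, sim$data, prior,
#'                config = mcmc_config(iter = 500, seed = 7))
#' fit
#' @export
pmm_fit <- function(formula, data, prior = NULL,
                    method = c("bayes", "moment"),
                    missing = c("mnar", "mar", "complete_case"),
                    config = mcmc_config(), conf = 0.95) {
  method <- match.arg(method)
  missing <- match.arg(missing)
  cl <- match.call()

  tf <- stats::terms(formula)
  vars <- attr(tf, "term.labels")
  if (!length(vars)) stopf("pmm_fit: formula must contain a treatment-arm term")
  response <- as.character(attr(tf, "variables"))[2]
  arm_var <- vars[1]
  covariates <- vars[-1]
  for (v in c(response, arm_var, covariates))
    if (!v %in% names(data)) stopf("pmm_fit: no column '%s' in data", v)

  arm_raw <- as.factor(data[[arm_var]])
  levs <- levels(arm_raw)
  if (length(levs) != 2L) stopf("pmm_fit: arm term '%s' must have exactly 2 levels", arm_var)
  norm <- normalise_arm_label(levs)
  if (setequal(norm, c("OPEN", "EEVAR"))) {
    arm <- norm[as.integer(arm_raw)]
  } else {
    arm <- c("OPEN", "EEVAR")[as.integer(arm_raw)]  # first level = control
  }

  df <- data.frame(arm = arm, qol = data[[response]])
  if ("missing" %in% names(data)) df$missing <- data$missing
  for (v in covariates) df[[v]] <- data[[v]]

  if (missing == "mnar") {
    if (is.null(prior)) stopf("pmm_fit: an MNAR fit needs a prior on (delta_O, delta_E)")
    if (inherits(prior, "sensitivity_prior")) prior <- linear_pool(list(prior),
                                                                  label = prior$expert_id)
    if (!inherits(prior, "pooled_prior"))
      stopf("pmm_fit: 'prior' must be a pooled_prior or sensitivity_prior")
  }

  if (method == "bayes") {
    fit <- switch(missing,
      mnar = bayesian_fit(df, prior, config, covariates = covariates),
      mar = mar_fit(df, config, covariates = covariates),
      complete_case = mar_fit(df, config, covariates = covariates,
                              complete_case = TRUE))
    est <- fit$delta_hat; ci <- fit$ci; p_mcid <- fit$p_mcid
  } else {
    if (length(covariates))
      stopf("pmm_fit: the moment method does not support covariate adjustment")
    e <- summarise_arm(df, "EEVAR"); o <- summarise_arm(df, "OPEN")
    fit <- switch(missing,
      mnar = moment_estimate_pooled(e, o, prior, conf = conf),
      mar = moment_estimate(e, o, normal_spec(0, 0), normal_spec(0, 0), conf = conf),
      complete_case = {
        e0 <- arm_summary(e$mu, e$se_mu, 0, arm = "EEVAR")
        o0 <- arm_summary(o$mu, o$se_mu, 0, arm = "OPEN")
        moment_estimate(e0, o0, normal_spec(0, 0), normal_spec(0, 0), conf = conf)
      })
    est <- fit$delta_hat; ci <- c(fit$ci_low, fit$ci_high); p_mcid <- NA_real_
  }

  structure(list(call = cl, method = method, missing = missing,
                 estimate = est, ci = ci, p_mcid = p_mcid,
                 mcid = if (method == "bayes") config$mcid else NA_real_,
                 prior_label = if (missing == "mnar") prior$label else missing,
                 fit = fit, data = df, covariates = covariates),
            class = "pmm_fit")
}

delta_draws <- function(object) {
  if (object$method != "bayes")
    stopf("no posterior draws: fit used method = '%s'", object$method)
  object$fit$draws$Delta
}

#' @export
print.pmm_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Pattern-mixture fit (%s, %s; prior: %s)\n",
              x$method, x$missing, x$prior_label))
  cat(sprintf("  Treatment difference (eEVAR - OPEN): %.*f, 95%% %s (%.*f, %.*f)\n",
              digits, x$estimate,
              if (x$method == "bayes") "CrI" else "CI",
              digits, x$ci[1], digits, x$ci[2]))
  if (!is.na(x$p_mcid))
    cat(sprintf("  P(Delta >= %.3g) = %.3f\n", x$mcid, x$p_mcid))
  invisible(x)
}

#' @export
summary.pmm_fit <- function(object, ...) {
  if (object$method == "bayes") summary(object$fit) else object$fit
}

#' @export
coef.pmm_fit <- function(object, ...) {
  if (object$method == "bayes") coef(object$fit) else c(Delta = object$estimate)
}

#' @export
confint.pmm_fit <- function(object, parm, level = 0.95, ...) {
  if (object$method == "bayes") {
    a <- (1 - level) / 2
    ci <- stats::quantile(delta_draws(object), c(a, 1 - a), names = FALSE)
  } else {
    ci <- confint(object$fit, level = level)[1, ]
  }
  matrix(ci, 1, 2, dimnames = list("Delta", sprintf("%g %%", c((1 - level) / 2,
                                                               1 - (1 - level) / 2) * 100)))
}

#' Simulate treatment-difference draws from a fitted model
#'
#' For Bayesian fits, resamples the posterior draws of `Delta`; for moment
#' fits, draws from the normal approximation `N(estimate, variance)`.
#'
#' @param object A `pmm_fit`.
#' @param nsim Number of draws.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return Numeric vector of length `nsim`.
#' @export
simulate.pmm_fit <- function(object, nsim = 1000, seed = NULL, ...) {
  with_seed(seed, {
    if (object$method == "bayes") {
      d <- delta_draws(object)
      sample(d, nsim, replace = TRUE)
    } else {
      stats::rnorm(nsim, object$fit$delta_hat, object$fit$se)
    }
  })
}

#' @export
residuals.pmm_fit <- function(object, ...) {
  df <- object$data
  miss <- if ("missing" %in% names(df)) as.logical(df$missing) else is.na(df$qol)
  mu <- coef(object)
  fitted_arm <- ifelse(df$arm == "EEVAR",
                       if ("mu_E" %in% names(mu)) mu[["mu_E"]] else NA_real_,
                       if ("mu_O" %in% names(mu)) mu[["mu_O"]] else NA_real_)
  out <- df$qol - fitted_arm
  out[miss] <- NA_real_
  out
}

#' Density-strip plot of a fitted treatment difference
#'
#' Renders the posterior (or normal-approximation) distribution of `Delta`
#' as a density strip with the mean and 95% interval marked, the standard
#' one-fit view; see [community_report()] for the multi-prior comparison.
#'
#' @param x A `pmm_fit`.
#' @param grid Evaluation grid for the strip.
#' @param ... Passed to the underlying plot.
#' @return `x`, invisibly.
#' @export
plot.pmm_fit <- function(x, grid = seq(-0.3, 0.4, length.out = 701), ...) {
  draws <- if (x$method == "bayes") delta_draws(x) else
    simulate(x, nsim = 10000, seed = 1)
  strip <- make_density_strip(draws, grid = grid,
                              mcid = if (is.na(x$mcid)) 0.03 else x$mcid)
  plot(strip, main = sprintf("Treatment difference (%s)", x$prior_label), ...)
  invisible(x)
}
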
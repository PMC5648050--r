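# Closed-form pattern-mixture estimation of the treatment difference.
#
# Within each arm the mean QoL of patients with missing outcomes is taken
# to be the observed-responder mean plus an offset delta, so the arm mean
# is mu + pi * delta, weighting by the missing proportion pi.  The
# treatment difference is
#     (mu_E + pi_E delta_E) - (mu_O + pi_O delta_O),
# and, with all inputs independent, its variance is
#     V(mu_E) + pi_E^2 V(delta_E) + V(mu_O) + pi_O^2 V(delta_O).

#' Observed-data summary for one arm
#'
#' @param mu Mean QoL among responders (utility scale).
#' @param se_mu Standard error of `mu`, `> 0`.
#' @param pi Proportion of randomised patients with a missing outcome.
#' @param n_obs,n_miss Optional patient counts; when both are given they
#'   must be consistent with `pi`.
#' @param arm Optional arm label (`"OPEN"` / `"EEVAR"`).
#' @return An object of class `arm_summary`.
#' @examples
#' arm_summary(mu = 0.76, se_mu = 0.02, pi = 0.18, arm = "EEVAR")
#' @export
arm_summary <- function(mu, se_mu, pi, n_obs = NA_integer_, n_miss = NA_integer_,
                        arm = NA_character_) {
  if (!is.finite(mu) || !is.finite(se_mu) || !is.finite(pi))
    stopf("arm_summary: 'mu', 'se_mu' and 'pi' must be finite")
  if (se_mu <= 0) stopf("arm_summary: 'se_mu' must be > 0")
  if (pi < 0 || pi > 1) stopf("arm_summary: 'pi' must lie in [0, 1]")
  if (!is.na(n_obs) && !is.na(n_miss)) {
    if (abs(pi - n_miss / (n_obs + n_miss)) > 1e-8)
      stopf("arm_summary: 'pi' (%g) inconsistent with counts %d/%d",
            pi, n_miss, n_obs + n_miss)
  }
  structure(list(mu = as.numeric(mu), se_mu = as.numeric(se_mu),
                 pi = as.numeric(pi), n_obs = as.integer(n_obs),
                 n_miss = as.integer(n_miss), arm = as.character(arm)),
            class = "arm_summary")
}

#' @export
print.arm_summary <- function(x, ...) {
  cat(sprintf("Arm %s: observed mean %.4f (SE %.4f), missing proportion %.3f",
              x$arm, x$mu, x$se_mu, x$pi))
  if (!is.na(x$n_obs)) cat(sprintf(" [%d observed, %d missing]", x$n_obs, x$n_miss))
  cat("\n")
  invisible(x)
}

normalise_arm_label <- function(x) {
  up <- toupper(trimws(as.character(x)))
  up[up %in% c("EEVAR", "EVAR", "E")] <- "EEVAR"
  up[up %in% c("OPEN", "O")] <- "OPEN"
  up
}

#' Summarise one arm of a trial dataset
#'
#' @param data A trial data frame with columns `arm`, `qol` (NA when
#'   missing) and optionally `missing` (0/1; defaults to `is.na(qol)`).
#' @param arm Arm label (`"OPEN"` or `"EEVAR"`, case-insensitive).
#' @return An [arm_summary()].
#' @export
summarise_arm <- function(data, arm) {
  arm <- normalise_arm_label(arm)
  rows <- data[normalise_arm_label(data$arm) == arm, , drop = FALSE]
  if (!nrow(rows)) stopf("summarise_arm: arm '%s' absent from data", arm)
  miss <- if ("missing" %in% names(rows)) as.logical(rows$missing) else is.na(rows$qol)
  if (any(!miss & is.na(rows$qol)))
    stopf("summarise_arm: outcome absent for record(s) not flagged missing")
  y <- rows$qol[!miss]
  if (length(y) < 2L)
    stopf("summarise_arm: arm '%s' has fewer than 2 observed outcomes", arm)
  arm_summary(mu = mean(y), se_mu = stats::sd(y) / sqrt(length(y)),
              pi = mean(miss), n_obs = sum(!miss), n_miss = sum(miss), arm = arm)
}

new_moment_estimate <- function(delta_hat, variance, conf, inputs) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  se <- sqrt(variance)
  structure(list(delta_hat = delta_hat, variance = variance, se = se,
                 ci_low = delta_hat - z * se, ci_high = delta_hat + z * se,
                 conf = conf, inputs = inputs),
            class = "moment_estimate")
}

#' Pattern-mixture moment estimate of the treatment difference
#'
#' Point estimate `(mu_E + pi_E m_E) - (mu_O + pi_O m_O)` where `m_a` is
#' the mean of the delta specification for arm `a`; variance by the
#' independence formula `se_E^2 + pi_E^2 s_E^2 + se_O^2 + pi_O^2 s_O^2`;
#' equal-tailed normal confidence interval.  Point-mass delta
#' specifications (`sd = 0`) reproduce a fixed-delta analysis, and zero
#' means with zero SDs reproduce the observed-data-only analysis.
#'
#' @param e,o [arm_summary()] for the eEVAR and open-repair arms.
#' @param delta_e,delta_o [normal_spec()] (or `(mean, sd)` pairs) for
#'   delta_E and delta_O on the utility scale.
#' @param conf Confidence level (default 0.95).
#' @return An object of class `moment_estimate`.
#' @examples
#' e <- arm_summary(0.76, 0.02, 0.18, arm = "EEVAR")
#' o <- arm_summary(0.69, 0.03, 0.24, arm = "OPEN")
#' moment_estimate(e, o, delta_e = c(-0.01, 0.04), delta_o = c(-0.05, 0.1))
#' @export
moment_estimate <- function(e, o, delta_e, delta_o, conf = 0.95) {
  stopifnot(inherits(e, "arm_summary"), inherits(o, "arm_summary"))
  delta_e <- as_normal_spec(delta_e, "delta_e")
  delta_o <- as_normal_spec(delta_o, "delta_o")
  delta_hat <- (e$mu + e$pi * delta_e$mean) - (o$mu + o$pi * delta_o$mean)
  variance <- e$se_mu^2 + e$pi^2 * delta_e$sd^2 + o$se_mu^2 + o$pi^2 * delta_o$sd^2
  new_moment_estimate(delta_hat, variance, conf,
                      list(e = e, o = o, delta_e = delta_e, delta_o = delta_o))
}

#' Moment estimate under a pooled mixture prior
#'
#' Plugs the pooled prior's mixture moments into the pattern-mixture
#' formula and extends the variance with the covariance cross-term
#' `-2 pi_E pi_O cov(delta_E, delta_O)` (the independence formula is
#' recovered when the pooled covariance is zero).
#'
#' @param e,o [arm_summary()] for the eEVAR and open-repair arms.
#' @param pool A [pooled_prior()].
#' @param conf Confidence level.
#' @return An object of class `moment_estimate`.
#' @export
moment_estimate_pooled <- function(e, o, pool, conf = 0.95) {
  stopifnot(inherits(e, "arm_summary"), inherits(o, "arm_summary"))
  if (!inherits(pool, "pooled_prior"))
    stopf("moment_estimate_pooled: 'pool' must be a pooled_prior")
  mo <- pool_moments(pool)
  delta_hat <- (e$mu + e$pi * mo$mean["delta_E"]) - (o$mu + o$pi * mo$mean["delta_O"])
  variance <- e$se_mu^2 + e$pi^2 * mo$cov["delta_E", "delta_E"] +
    o$se_mu^2 + o$pi^2 * mo$cov["delta_O", "delta_O"] -
    2 * e$pi * o$pi * mo$cov["delta_E", "delta_O"]
  new_moment_estimate(unname(delta_hat), unname(variance), conf,
                      list(e = e, o = o, pool_label = pool$label,
                           pool_moments = mo))
}

#' @export
print.moment_estimate <- function(x, digits = 3, ...) {
  cat(sprintf("Pattern-mixture moment estimate (eEVAR - OPEN): %.*f\n",
              digits, x$delta_hat))
  cat(sprintf("  variance %.6f (SE %.*f); %g%% CI (%.*f, %.*f)\n",
              x$variance, digits, x$se, 100 * x$conf,
              digits, x$ci_low, digits, x$ci_high))
  invisible(x)
}

#' @export
coef.moment_estimate <- function(object, ...) c(delta = object$delta_hat)

#' @export
confint.moment_estimate <- function(object, parm, level = NULL, ...) {
  if (!is.null(level) && abs(level - object$conf) > 1e-12) {
    z <- stats::qnorm(1 - (1 - level) / 2)
    return(matrix(c(object$delta_hat - z * object$se,
                    object$delta_hat + z * object$se), 1, 2,
                  dimnames = list("delta", sprintf("%g %%", c((1 - level) / 2,
                                                              1 - (1 - level) / 2) * 100))))
  }
  matrix(c(object$ci_low, object$ci_high), 1, 2,
         dimnames = list("delta", sprintf("%g %%", c((1 - object$conf) / 2,
                                                     1 - (1 - object$conf) / 2) * 100)))
}

#' Tipping-point scan over fixed sensitivity parameters
#'
#' Evaluates the moment estimator over a grid of known (SD 0) delta values
#' and flags, per cell, whether the confidence interval excludes zero and
#' whether the point estimate reaches the minimum clinically important
#' difference.  The tipping points are the grid cells where those flags
#' change.
#'
#' @param e,o [arm_summary()] for the eEVAR and open-repair arms.
#' @param grid_O,grid_E Finite vectors of delta_O / delta_E values.
#' @param mcid Minimum clinically important difference (utility units).
#' @param conf Confidence level.
#' @return A `pmm_tipping` object: data frame with columns `delta_O`,
#'   `delta_E`, `estimate`, `ci_low`, `ci_high`, `ci_excludes_zero`,
#'   `reaches_mcid`.
#' @export
tipping_point_scan <- function(e, o, grid_O, grid_E, mcid = 0.03, conf = 0.95) {
  if (!all(is.finite(grid_O)) || !all(is.finite(grid_E)))
    stopf("tipping_point_scan: grids must be finite")
  cells <- expand.grid(delta_O = grid_O, delta_E = grid_E,
                       KEEP.OUT.ATTRS = FALSE)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  est <- (e$mu + e$pi * cells$delta_E) - (o$mu + o$pi * cells$delta_O)
  se <- sqrt(e$se_mu^2 + o$se_mu^2)  # deltas are fixed, only mu variance remains
  out <- cbind(cells,
               estimate = est,
               ci_low = est - z * se,
               ci_high = est + z * se)
  out$ci_excludes_zero <- out$ci_low > 0 | out$ci_high < 0
  out$reaches_mcid <- out$estimate >= mcid
  structure(list(grid = out, mcid = mcid, conf = conf, e = e, o = o),
            class = "pmm_tipping")
}

#' @export
print.pmm_tipping <- function(x, ...) {
  g <- x$grid
  cat(sprintf("Tipping-point scan: %d cells (%d x %d grid)\n", nrow(g),
              length(unique(g$delta_O)), length(unique(g$delta_E))))
  cat(sprintf("  CI excludes 0 in %d cells; estimate >= MCID (%.3g) in %d cells\n",
              sum(g$ci_excludes_zero), x$mcid, sum(g$reaches_mcid)))
  invisible(x)
}

#' @export
plot.pmm_tipping <- function(x, ...) {
  g <- x$grid
  dO <- sort(unique(g$delta_O)); dE <- sort(unique(g$delta_E))
  z <- matrix(g$estimate[order(g$delta_E, g$delta_O)], length(dO), length(dE))
  graphics::image(dO, dE, z, col = grDevices::hcl.colors(64, "viridis"),
                  xlab = expression(delta[O]), ylab = expression(delta[E]),
                  main = "Treatment difference over fixed sensitivity parameters", ...)
  graphics::contour(dO, dE, z, add = TRUE)
  sig <- matrix(g$ci_excludes_zero[order(g$delta_E, g$delta_O)],
                length(dO), length(dE))
  if (any(sig) && !all(sig))
    graphics::contour(dO, dE, sig + 0, levels = 0.5, add = TRUE,
                      lwd = 2, lty = 2, drawlabels = FALSE)
  invisible(x)
}
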
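# Fully Bayesian pattern-mixture model.
#
# Observed outcomes in arm a are normal with mean mu_a (optionally
# covariate-adjusted) and SD sigma_a under weak priors; the sensitivity
# parameters (delta_O, delta_E) are drawn from the pooled mixture prior
# via a latent component indicator.  Because delta never enters the
# likelihood (the defining non-identifiability of the pattern-mixture
# model), its posterior equals its prior, and the posterior factorises:
# mu_a given the data (conjugate normal, or normal/inverse-gamma Gibbs
# when sigma_a is unknown), delta from the pool, pi_a either plugged in or
# Beta-binomial.  The treatment difference is
#     Delta = (mu_E + pi_E delta_E) - (mu_O + pi_O delta_O).

#' MCMC configuration for the Bayesian pattern-mixture fit
#'
#' @param chains Number of chains, `>= 2` (used for split-Rhat).
#' @param iter Kept iterations per chain.
#' @param warmup Warm-up iterations per chain (discarded; relevant to the
#'   Gibbs sampler used with patient-level data and unknown arm SDs).
#' @param seed Integer seed; required for reproducibility.
#' @param mcid Minimum clinically important difference on the utility
#'   scale (default 0.03).
#' @param pi_mode `"plugin"` fixes the missingness proportions at their
#'   observed values (matching the closed-form variance formula, which
#'   carries no V(pi) term); `"beta_binomial"` gives them Beta(1,1)
#'   priors and propagates their uncertainty (requires counts).
#' @param rhat_max Largest acceptable split-Rhat; larger values abort
#'   reporting unless `force = TRUE`.
#' @param force Report even when convergence diagnostics fail.
#' @param mu_prior_sd SD of the weak normal prior on arm means (utility
#'   scale; default 10, effectively flat over the plausible range).
#' @param sigma_upper Upper bound of the uniform prior on arm outcome SDs.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 4, iter = 2000, warmup = 2000, seed = 1,
                        mcid = 0.03, pi_mode = c("plugin", "beta_binomial"),
                        rhat_max = 1.05, force = FALSE,
                        mu_prior_sd = 10, sigma_upper = 5) {
  pi_mode <- match.arg(pi_mode)
  chains <- as.integer(chains); iter <- as.integer(iter); warmup <- as.integer(warmup)
  if (chains < 2L) stopf("mcmc_config: 'chains' must be >= 2")
  if (iter < 1L || warmup < 0L) stopf("mcmc_config: bad iteration counts")
  if (is.null(seed) || is.na(seed)) stopf("mcmc_config: a seed is required")
  structure(list(chains = chains, iter = iter, warmup = warmup,
                 seed = as.integer(seed), mcid = mcid, pi_mode = pi_mode,
                 rhat_max = rhat_max, force = isTRUE(force),
                 mu_prior_sd = mu_prior_sd, sigma_upper = sigma_upper),
            class = "mcmc_config")
}

# ---- convergence diagnostics ----------------------------------------------

#' Split-Rhat of a draws matrix
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half, so within-chain trends register as apparent non-convergence.
#'
#' @param mat Numeric matrix, iterations x chains.
#' @return Split-Rhat (1 for constant draws).
#' @export
split_rhat <- function(mat) {
  mat <- as.matrix(mat)
  n2 <- floor(nrow(mat) / 2)
  if (n2 < 2L) return(NA_real_)
  halves <- cbind(mat[seq_len(n2), , drop = FALSE],
                  mat[seq_len(n2) + n2, , drop = FALSE])
  m <- ncol(halves); n <- nrow(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, stats::var)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size of a draws matrix
#'
#' Autocorrelation-based estimate using Geyer's initial positive sequence
#' on chain-averaged autocorrelations.
#'
#' @param mat Numeric matrix, iterations x chains.
#' @return Estimated effective number of draws.
#' @export
ess_draws <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat); m <- ncol(mat)
  if (n < 4L) return(NA_real_)
  if (stats::var(as.numeric(mat)) == 0) return(n * m)
  lag_max <- min(n - 1L, 200L)
  acfs <- vapply(seq_len(m), function(j)
    as.numeric(stats::acf(mat[, j], lag.max = lag_max, plot = FALSE,
                          demean = TRUE)$acf)[-1],
    numeric(lag_max))
  rho <- rowMeans(acfs)
  s <- 0; t <- 1
  while (t + 1 <= length(rho)) {
    pair <- rho[t] + rho[t + 1]
    if (!is.finite(pair) || pair < 0) break
    s <- s + pair
    t <- t + 2
  }
  max(1, n * m / (1 + 2 * s))
}

# ---- input normalisation ---------------------------------------------------

# Accepts a trial data frame (columns arm, qol, missing) or a list with
# arm_summary entries named e/o (or EEVAR/OPEN).
as_trial_input <- function(data) {
  if (is.data.frame(data)) {
    if (!all(c("arm", "qol") %in% names(data)))
      stopf("trial data must have columns 'arm' and 'qol'")
    arms <- normalise_arm_label(data$arm)
    if (!all(c("OPEN", "EEVAR") %in% arms))
      stopf("trial data must contain both OPEN and EEVAR arms")
    return(list(type = "data", df = data))
  }
  if (is.list(data)) {
    nm <- tolower(names(data))
    e <- data[[which(nm %in% c("e", "eevar", "evar"))[1]]]
    o <- data[[which(nm %in% c("o", "open"))[1]]]
    if (inherits(e, "arm_summary") && inherits(o, "arm_summary"))
      return(list(type = "summary", e = e, o = o))
  }
  stopf("data must be a trial data frame or list(e = arm_summary, o = arm_summary)")
}

# Conjugate draw of the arm mean for summary-level input:
# likelihood mu_hat ~ N(mu, se^2), prior mu ~ N(0, s0^2).
draw_mu_summary <- function(summ, n, s0) {
  prec <- 1 / summ$se_mu^2 + 1 / s0^2
  post_var <- 1 / prec
  post_mean <- post_var * summ$mu / summ$se_mu^2
  stats::rnorm(n, post_mean, sqrt(post_var))
}

# Gibbs sampler for one arm with patient-level outcomes:
#   y ~ N(X beta, sigma^2), beta ~ N(0, s0^2 I), sigma ~ U(0, upper).
# Returns kept draws of the adjusted arm mean (intercept) and sigma.
gibbs_arm <- function(y, X, cfg, n_keep) {
  n <- length(y); p <- ncol(X)
  XtX <- crossprod(X); Xty <- crossprod(X, y)
  prior_prec <- diag(1 / cfg$mu_prior_sd^2, p)
  beta <- stats::coef(stats::lm.fit(X, y))
  beta[is.na(beta)] <- 0
  sigma2 <- stats::var(y)
  total <- cfg$warmup + n_keep
  mu_out <- numeric(n_keep); sigma_out <- numeric(n_keep)
  for (it in seq_len(total)) {
    prec <- XtX / sigma2 + prior_prec
    ch <- chol(prec)
    b_mean <- backsolve(ch, forwardsolve(t(ch), Xty / sigma2))
    beta <- b_mean + backsolve(ch, stats::rnorm(p))
    ss <- sum((y - X %*% beta)^2)
    repeat {
      sigma2 <- 1 / stats::rgamma(1, shape = (n - 1) / 2, rate = ss / 2)
      if (sigma2 < cfg$sigma_upper^2) break
    }
    if (it > cfg$warmup) {
      mu_out[it - cfg$warmup] <- beta[1]
      sigma_out[it - cfg$warmup] <- sqrt(sigma2)
    }
  }
  list(mu = mu_out, sigma = sigma_out)
}

# ---- the fit ---------------------------------------------------------------

#' Bayesian pattern-mixture fit with a mixture prior on the deltas
#'
#' Fits the two-arm pattern-mixture model with the pooled expert prior on
#' the sensitivity parameters and returns posterior draws and summaries of
#' the treatment difference `Delta`, the arm means, and the deltas.  With
#' summary-level input the posterior is sampled directly (the model is
#' conjugate); with patient-level data and unknown arm SDs a per-arm Gibbs
#' sampler is used.  Covariate adjustment adds linear terms (weak normal
#' priors) to the arm means; covariates are centred on their overall mean
#' so that the intercept is the adjusted arm mean.
#'
#' Reporting is refused (with an error) when any monitored parameter's
#' split-Rhat exceeds `config$rhat_max`, unless `config$force` is set.
#'
#' @param data Trial data frame (columns `arm`, `qol`, optional `missing`
#'   and covariates) or `list(e = , o = )` of [arm_summary()] objects.
#' @param pool A [pooled_prior()] on (delta_O, delta_E).
#' @param config An [mcmc_config()].
#' @param covariates Character vector of covariate column names
#'   (patient-level data only).
#' @param complete_case If `TRUE`, analyse responders only with no
#'   missingness adjustment (`pi = 0`).
#' @return An object of class `pmm_bayes`: posterior draws, summaries,
#'   `p_mcid`, convergence diagnostics, and the config echo.
#' @export
bayesian_fit <- function(data, pool, config = mcmc_config(),
                         covariates = NULL, complete_case = FALSE) {
  if (!inherits(pool, "pooled_prior")) stopf("bayesian_fit: 'pool' must be a pooled_prior")
  if (!inherits(config, "mcmc_config")) stopf("bayesian_fit: 'config' must be an mcmc_config")
  input <- as_trial_input(data)
  n_keep <- config$iter
  n_tot <- n_keep * config$chains

  with_seed(config$seed, {
    if (input$type == "summary") {
      if (!is.null(covariates) && length(covariates))
        stopf("bayesian_fit: covariate adjustment needs patient-level data")
      e <- input$e; o <- input$o
      mu_E <- draw_mu_summary(e, n_tot, config$mu_prior_sd)
      mu_O <- draw_mu_summary(o, n_tot, config$mu_prior_sd)
      sigma_E <- sigma_O <- NULL
      counts <- list(E = c(e$n_obs, e$n_miss), O = c(o$n_obs, o$n_miss))
      pi_hat <- c(E = e$pi, O = o$pi)
    } else {
      df <- input$df
      arms <- normalise_arm_label(df$arm)
      miss <- if ("missing" %in% names(df)) as.logical(df$missing) else is.na(df$qol)
      draw_arm <- function(a) {
        rows <- which(arms == a & !miss)
        y <- df$qol[rows]
        if (length(y) < 2L) stopf("bayesian_fit: arm '%s' has < 2 observed outcomes", a)
        X <- matrix(1, length(y), 1)
        if (!is.null(covariates) && length(covariates)) {
          for (cv in covariates) {
            if (!cv %in% names(df)) stopf("bayesian_fit: no covariate column '%s'", cv)
            X <- cbind(X, df[[cv]][rows] - mean(df[[cv]], na.rm = TRUE))
          }
        }
        do.call(cbind, lapply(seq_len(config$chains), function(ch) {
          d <- gibbs_arm(y, X, config, n_keep)
          cbind(d$mu, d$sigma)
        }))
      }
      dE <- draw_arm("EEVAR"); dO <- draw_arm("OPEN")
      mu_E <- as.numeric(dE[, seq(1, ncol(dE), by = 2)])
      sigma_E <- as.numeric(dE[, seq(2, ncol(dE), by = 2)])
      mu_O <- as.numeric(dO[, seq(1, ncol(dO), by = 2)])
      sigma_O <- as.numeric(dO[, seq(2, ncol(dO), by = 2)])
      counts <- list(E = c(sum(arms == "EEVAR" & !miss), sum(arms == "EEVAR" & miss)),
                     O = c(sum(arms == "OPEN" & !miss), sum(arms == "OPEN" & miss)))
      pi_hat <- c(E = counts$E[2] / sum(counts$E), O = counts$O[2] / sum(counts$O))
    }

    if (complete_case) {
      pi_E <- rep(0, n_tot); pi_O <- rep(0, n_tot)
    } else if (config$pi_mode == "plugin") {
      pi_E <- rep(unname(pi_hat["E"]), n_tot); pi_O <- rep(unname(pi_hat["O"]), n_tot)
    } else {
      if (any(is.na(unlist(counts))))
        stopf("bayesian_fit: pi_mode = 'beta_binomial' needs observed/missing counts")
      pi_E <- stats::rbeta(n_tot, 1 + counts$E[2], 1 + counts$E[1])
      pi_O <- stats::rbeta(n_tot, 1 + counts$O[2], 1 + counts$O[1])
    }

    dd <- sample_pool(pool, n_tot)
    delta_O <- dd[, "delta_O"]; delta_E <- dd[, "delta_E"]
    component <- attr(dd, "component")
    Delta <- (mu_E + pi_E * delta_E) - (mu_O + pi_O * delta_O)

    draws <- data.frame(Delta = Delta, mu_O = mu_O, mu_E = mu_E,
                        delta_O = delta_O, delta_E = delta_E,
                        pi_O = pi_O, pi_E = pi_E, component = component)
    if (!is.null(sigma_O)) { draws$sigma_O <- sigma_O; draws$sigma_E <- sigma_E }

    monitored <- setdiff(names(draws), "component")
    diag_tab <- do.call(rbind, lapply(monitored, function(par) {
      m <- matrix(draws[[par]], nrow = n_keep, ncol = config$chains)
      data.frame(parameter = par, rhat = split_rhat(m), ess = ess_draws(m))
    }))
    bad <- diag_tab$parameter[is.finite(diag_tab$rhat) & diag_tab$rhat > config$rhat_max]
    if (length(bad)) {
      msg <- sprintf("bayesian_fit: split-Rhat above %.3g for: %s",
                     config$rhat_max, paste(bad, collapse = ", "))
      if (config$force) warnf("%s (reporting forced)", msg) else stop(msg, call. = FALSE)
    }

    qs <- t(vapply(monitored, function(par)
      stats::quantile(draws[[par]], c(0.025, 0.5, 0.975), names = FALSE),
      numeric(3)))
    summary_tab <- data.frame(parameter = monitored,
                              mean = vapply(monitored, function(p) mean(draws[[p]]), numeric(1)),
                              sd = vapply(monitored, function(p) stats::sd(draws[[p]]), numeric(1)),
                              q2.5 = qs[, 1], median = qs[, 2], q97.5 = qs[, 3],
                              row.names = NULL)

    structure(list(draws = draws,
                   summary = summary_tab,
                   delta_hat = mean(Delta),
                   ci = stats::quantile(Delta, c(0.025, 0.975), names = FALSE),
                   p_mcid = mean(Delta >= config$mcid),
                   diagnostics = diag_tab,
                   pool_label = pool$label,
                   config = config,
                   complete_case = complete_case,
                   input_type = input$type),
              class = "pmm_bayes")
  })
}

#' MAR and complete-case comparator fits
#'
#' The missing-at-random analysis is [bayesian_fit()] with both
#' sensitivity parameters fixed at zero (point-mass pool); the
#' complete-case variant additionally drops the missingness weighting
#' entirely.
#'
#' @inheritParams bayesian_fit
#' @return A `pmm_bayes` object.
#' @export
mar_fit <- function(data, config = mcmc_config(), covariates = NULL,
                    complete_case = FALSE) {
  zero_pool <- linear_pool(list(sensitivity_prior("mar", 0, 0, 0, 0, 0)),
                           label = if (complete_case) "complete_case" else "MAR")
  bayesian_fit(data, zero_pool, config, covariates = covariates,
               complete_case = complete_case)
}

#' Posterior probability that the treatment difference exceeds a threshold
#'
#' @param r A `pmm_bayes` fit (or numeric vector of Delta draws).
#' @param threshold Utility threshold; default 0.03, the minimum
#'   clinically important difference for EQ-5D utilities.
#' @return `P(Delta >= threshold)` as a fraction of posterior draws.
#' @export
prob_exceeds <- function(r, threshold = 0.03) {
  draws <- if (inherits(r, "pmm_bayes")) r$draws$Delta
           else if (inherits(r, "pmm_fit")) delta_draws(r)
           else as.numeric(r)
  if (length(draws) < 1000)
    warnf("prob_exceeds: only %d draws; estimate may be unstable", length(draws))
  mean(draws >= threshold)
}

#' @export
print.pmm_bayes <- function(x, digits = 3, ...) {
  cat(sprintf("Bayesian pattern-mixture fit (prior: %s%s)\n", x$pool_label,
              if (x$complete_case) ", complete case" else ""))
  cat(sprintf("  Delta (eEVAR - OPEN): posterior mean %.*f, 95%% CrI (%.*f, %.*f)\n",
              digits, x$delta_hat, digits, x$ci[1], digits, x$ci[2]))
  cat(sprintf("  P(Delta >= %.3g) = %.3f\n", x$config$mcid, x$p_mcid))
  cat(sprintf("  %d chains x %d kept draws; max split-Rhat %.4f, min ESS %.0f\n",
              x$config$chains, x$config$iter,
              max(x$diagnostics$rhat, na.rm = TRUE),
              min(x$diagnostics$ess, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.pmm_bayes <- function(object, ...) {
  out <- merge(object$summary, object$diagnostics, by = "parameter", sort = FALSE)
  class(out) <- c("summary.pmm_bayes", "data.frame")
  out
}

#' @export
coef.pmm_bayes <- function(object, ...) {
  stats::setNames(object$summary$mean, object$summary$parameter)
}
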
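# Seed-deterministic generators for synthetic trials and expert panels.
#
# The trial generator emulates a two-arm surgical trial with normal QoL
# outcomes on the utility scale and outcome-dependent (logistic-in-outcome)
# missingness, the canonical MNAR mechanism for "sicker patients return
# fewer questionnaires".  The panel generator draws each expert's true
# belief as an exact bivariate normal over (delta_O, delta_E) and emits
# the three elicited distributions implied by it, so prior construction
# can be tested by exact round-trip inversion.

#' Configuration for the synthetic trial generator
#'
#' Defaults emulate the motivating trial's observed 3-month QoL structure:
#' responder means near 0.69 (open repair) and 0.76 (eEVAR), outcome SD
#' 0.3, and logistic outcome-dependent missingness calibrated to missing
#' proportions of roughly 0.24 and 0.18 (about 21% overall).
#'
#' @param n_per_arm Patients per arm (scalar or named `c(OPEN=, EEVAR=)`).
#' @param true_mean_O,true_mean_E True arm mean outcomes (utility).
#' @param sd_O,sd_E True arm outcome SDs, `> 0`.
#' @param miss_intercept,miss_slope Logistic missingness coefficients per
#'   arm (scalar or named length-2): `P(missing) = plogis(a + b * driver)`.
#'   A negative slope makes low-QoL patients more likely to be missing.
#' @param mechanism `"mnar"` (driver = true outcome), `"mar"` (driver =
#'   observed covariate; requires `covariates`), or `"mcar"` (slope
#'   ignored).
#' @param covariates Optional named numeric vector of linear covariate
#'   effects; each named covariate is drawn standard normal per patient.
#' @param seed Integer seed.
#' @return An object of class `trial_gen_config`.
#' @export
trial_gen_config <- function(n_per_arm = 200,
                             true_mean_O = 0.69, true_mean_E = 0.76,
                             sd_O = 0.3, sd_E = 0.3,
                             miss_intercept = c(OPEN = 0.23, EEVAR = 0.00),
                             miss_slope = c(OPEN = -2, EEVAR = -2),
                             mechanism = c("mnar", "mar", "mcar"),
                             covariates = NULL, seed = 1) {
  mechanism <- match.arg(mechanism)
  as_pair <- function(x, what) {
    if (length(x) == 1L) x <- c(OPEN = unname(x), EEVAR = unname(x))
    if (!all(c("OPEN", "EEVAR") %in% names(x)))
      stopf("trial_gen_config: '%s' must be a scalar or named c(OPEN=, EEVAR=)", what)
    x[c("OPEN", "EEVAR")]
  }
  n_per_arm <- as_pair(n_per_arm, "n_per_arm")
  if (any(n_per_arm < 2)) stopf("trial_gen_config: n_per_arm must be >= 2")
  if (sd_O <= 0 || sd_E <= 0) stopf("trial_gen_config: outcome sds must be > 0")
  if (mechanism == "mar" && is.null(covariates))
    stopf("trial_gen_config: MAR missingness needs at least one covariate")
  structure(list(n_per_arm = n_per_arm,
                 true_mean_O = true_mean_O, true_mean_E = true_mean_E,
                 sd_O = sd_O, sd_E = sd_E,
                 miss_intercept = as_pair(miss_intercept, "miss_intercept"),
                 miss_slope = as_pair(miss_slope, "miss_slope"),
                 mechanism = mechanism, covariates = covariates,
                 seed = as.integer(seed)),
            class = "trial_gen_config")
}

arm_marginal <- function(cfg, arm) {
  mean <- if (arm == "OPEN") cfg$true_mean_O else cfg$true_mean_E
  sd <- if (arm == "OPEN") cfg$sd_O else cfg$sd_E
  if (!is.null(cfg$covariates)) sd <- sqrt(sd^2 + sum(cfg$covariates^2))
  list(mean = mean, sd = sd)
}

#' True sensitivity parameters implied by a trial configuration
#'
#' Under the generator, delta_a = E(Y | missing, arm a) - E(Y | observed,
#' arm a), computed by numerical integration of the logistic-normal
#' selection mechanism on the marginal outcome distribution.  Zero under
#' MCAR; under covariate-driven (MAR) missingness delta equals the
#' covariate-mediated gap `beta_1 (E(z | missing) - E(z | observed))`,
#' which a covariate-adjusted analysis removes.
#'
#' @param cfg A [trial_gen_config()].
#' @return Named vector `c(delta_O, delta_E)` on the utility scale.
#' @export
truth_delta <- function(cfg) {
  if (!inherits(cfg, "trial_gen_config")) stopf("truth_delta: 'cfg' must be a trial_gen_config")
  if (cfg$mechanism == "mcar") return(c(delta_O = 0, delta_E = 0))
  out <- vapply(c(OPEN = "OPEN", EEVAR = "EEVAR"), function(arm) {
    marg <- arm_marginal(cfg, arm)
    a <- cfg$miss_intercept[arm]; b <- cfg$miss_slope[arm]
    if (cfg$mechanism == "mar") {
      # missingness driven by the first covariate z ~ N(0,1); outcome and z
      # share only the linear effect beta1 * z
      beta1 <- cfg$covariates[[1]]
      pm <- stats::integrate(function(z) stats::plogis(a + b * z) * stats::dnorm(z),
                             -Inf, Inf)$value
      ez_m <- stats::integrate(function(z) z * stats::plogis(a + b * z) * stats::dnorm(z),
                               -Inf, Inf)$value / pm
      ez_o <- -pm * ez_m / (1 - pm)  # E(z) = 0 decomposition
      return(beta1 * (ez_m - ez_o))
    }
    pm <- stats::integrate(function(y) stats::plogis(a + b * y) * stats::dnorm(y, marg$mean, marg$sd),
                           -Inf, Inf)$value
    ey_m <- stats::integrate(function(y) y * stats::plogis(a + b * y) * stats::dnorm(y, marg$mean, marg$sd),
                             -Inf, Inf)$value / pm
    ey_o <- (marg$mean - pm * ey_m) / (1 - pm)
    ey_m - ey_o
  }, numeric(1))
  c(delta_O = unname(out["OPEN"]), delta_E = unname(out["EEVAR"]))
}

#' Generate a synthetic two-arm trial with controllable missingness
#'
#' @param cfg A [trial_gen_config()].
#' @return `list(data = , truth = )`: `data` is a patient-level data frame
#'   (`patient_id`, `arm`, `qol` (`NA` when missing), `missing`, covariate
#'   columns); `truth` records the generating configuration, the true
#'   treatment difference `delta_true = true_mean_E - true_mean_O`, and
#'   the quadrature-exact sensitivity parameters from [truth_delta()].
#' @examples
#' sim <- generate_trial(trial_gen_config(n_per_arm = 50, seed = 42))
#' head(sim$data)
#' sim$truth$delta_true
#' @export
generate_trial <- function(cfg) {
  if (!inherits(cfg, "trial_gen_config")) stopf("generate_trial: 'cfg' must be a trial_gen_config")
  with_seed(cfg$seed, {
    rows <- lapply(c("OPEN", "EEVAR"), function(arm) {
      n <- cfg$n_per_arm[arm]
      mu <- if (arm == "OPEN") cfg$true_mean_O else cfg$true_mean_E
      sd <- if (arm == "OPEN") cfg$sd_O else cfg$sd_E
      df <- data.frame(arm = rep(arm, n))
      lin <- rep(mu, n)
      if (!is.null(cfg$covariates)) {
        for (cv in names(cfg$covariates)) {
          z <- stats::rnorm(n)
          df[[cv]] <- z
          lin <- lin + cfg$covariates[[cv]] * z
        }
      }
      y <- stats::rnorm(n, lin, sd)
      driver <- switch(cfg$mechanism,
                       mnar = y,
                       mar = df[[names(cfg$covariates)[1]]],
                       mcar = rep(0, n))
      slope <- if (cfg$mechanism == "mcar") 0 else cfg$miss_slope[arm]
      p_miss <- stats::plogis(cfg$miss_intercept[arm] + slope * driver)
      miss <- stats::runif(n) < p_miss
      df$qol <- ifelse(miss, NA_real_, y)
      df$missing <- as.integer(miss)
      df
    })
    df <- do.call(rbind, rows)
    df <- cbind(patient_id = sprintf("p%04d", seq_len(nrow(df))), df)
    truth <- list(config = cfg,
                  delta_true = cfg$true_mean_E - cfg$true_mean_O,
                  delta = truth_delta(cfg))
    list(data = df, truth = truth)
  })
}

#' Configuration for the synthetic expert-panel generator
#'
#' Defaults emulate the observed panel structure: 26 experts (9 nurses, 17
#' doctors), central beliefs of about -0.04 (open) and -0.01 (eEVAR) for
#' the non-responder offsets, elicited uncertainty SDs around 0.16 utility
#' units, spread across experts of similar magnitude, and a moderately
#' positive shared correlation.
#'
#' @param n_experts Number of experts.
#' @param true_delta_O,true_delta_E Panel-level mean beliefs (utility).
#' @param within_expert_sd Central elicited uncertainty SD (utility).
#' @param between_expert_sd SD of belief means across experts (utility).
#' @param rho_true Correlation of each expert's bivariate belief, or a
#'   length-`n_experts` vector of per-expert correlations.
#' @param role_mix Named counts summing to `n_experts`, e.g.
#'   `c(nurse = 9, doctor = 17)`; `NULL` (default) assigns roughly 35%
#'   nurses and the rest doctors, the observed panel composition.
#' @param sd_jitter Lognormal SD (log scale) of per-expert variation in
#'   elicited uncertainty; 0 gives identical SDs.
#' @param seed Integer seed.
#' @return An object of class `panel_gen_config`.
#' @export
panel_gen_config <- function(n_experts = 26,
                             true_delta_O = -0.04, true_delta_E = -0.01,
                             within_expert_sd = 0.16, between_expert_sd = 0.16,
                             rho_true = 0.3,
                             role_mix = NULL,
                             sd_jitter = 0.3, seed = 1) {
  if (is.null(role_mix)) {
    n_nurse <- round(0.35 * n_experts)
    role_mix <- c(nurse = n_nurse, doctor = n_experts - n_nurse)
  }
  if (within_expert_sd <= 0 || between_expert_sd < 0)
    stopf("panel_gen_config: sds must be positive")
  if (any(rho_true < -1 | rho_true > 1))
    stopf("panel_gen_config: rho_true must lie in [-1, 1]")
  if (!length(rho_true) %in% c(1L, n_experts))
    stopf("panel_gen_config: rho_true must be scalar or length n_experts")
  if (sum(role_mix) != n_experts)
    stopf("panel_gen_config: role_mix must sum to n_experts")
  if (!all(names(role_mix) %in% c("doctor", "nurse", "other")))
    stopf("panel_gen_config: role_mix names must be doctor/nurse/other")
  structure(list(n_experts = as.integer(n_experts),
                 true_delta_O = true_delta_O, true_delta_E = true_delta_E,
                 within_expert_sd = within_expert_sd,
                 between_expert_sd = between_expert_sd,
                 rho_true = rho_true, role_mix = role_mix,
                 sd_jitter = sd_jitter, seed = as.integer(seed)),
            class = "panel_gen_config")
}

#' Generate a synthetic expert panel with known belief structure
#'
#' Each expert k holds an exact bivariate normal belief over
#' (delta_O, delta_E) with means drawn around the panel-level truth,
#' elicited-uncertainty SDs jittered around `within_expert_sd`, and
#' correlation `rho_true[k]`.  The emitted response contains the two
#' marginal elicitations plus the conditional elicitation evaluated one
#' marginal SD above the open-arm mode, all on the elicitation scale
#' anchored at `anchors`.  By construction [build_expert_prior()] applied
#' to the output recovers each generating prior exactly (to numerical
#' round-off); the generating priors are stored in the `"truth"` attribute.
#'
#' @param cfg A [panel_gen_config()].
#' @param anchors [anchor_scores()]; required, no default.
#' @return An [elicitation_set()] with per-expert generating priors in
#'   `attr(, "truth")`.
#' @export
generate_panel <- function(cfg, anchors) {
  if (!inherits(cfg, "panel_gen_config")) stopf("generate_panel: 'cfg' must be a panel_gen_config")
  if (!inherits(anchors, "anchor_scores")) stopf("generate_panel: 'anchors' must be anchor_scores")
  with_seed(cfg$seed, {
    n <- cfg$n_experts
    roles <- sample(rep(names(cfg$role_mix), cfg$role_mix))
    rho <- rep(cfg$rho_true, length.out = n)
    m_O <- stats::rnorm(n, cfg$true_delta_O, cfg$between_expert_sd)
    m_E <- stats::rnorm(n, cfg$true_delta_E, cfg$between_expert_sd)
    s_O <- cfg$within_expert_sd * exp(stats::rnorm(n, 0, cfg$sd_jitter))
    s_E <- cfg$within_expert_sd * exp(stats::rnorm(n, 0, cfg$sd_jitter))

    responses <- vector("list", n)
    truth <- vector("list", n)
    for (k in seq_len(n)) {
      id <- sprintf("expert%02d", k)
      open_mode <- anchors$open_observed + .QOL_SCALE * m_O[k]
      evar_mode <- anchors$evar_observed + .QOL_SCALE * m_E[k]
      # a bounded slider cannot record a mode off the scale: clamp and make
      # the clamped value the expert's generating belief
      if (open_mode < .QOL_MIN || open_mode > .QOL_MAX ||
          evar_mode < .QOL_MIN || evar_mode > .QOL_MAX) {
        warnf("generate_panel: expert %s mode clamped to the elicitation scale", id)
        open_mode <- min(max(open_mode, .QOL_MIN), .QOL_MAX)
        evar_mode <- min(max(evar_mode, .QOL_MIN), .QOL_MAX)
        m_O[k] <- (open_mode - anchors$open_observed) / .QOL_SCALE
        m_E[k] <- (evar_mode - anchors$evar_observed) / .QOL_SCALE
      }
      # conditional elicitation about one marginal SD away from the
      # open-arm mode (towards the interior of the scale), read off the
      # exact bivariate normal conditional; the step is shortened until
      # both the conditioning point and the conditional mode fit on scale
      step <- s_O[k]
      dirs <- if (.QOL_MAX - open_mode >= open_mode - .QOL_MIN) c(1, -1) else c(-1, 1)
      repeat {
        placed <- FALSE
        for (dir in dirs) {
          cv <- m_O[k] + dir * step
          cm <- m_E[k] + rho[k] * s_E[k] / s_O[k] * (cv - m_O[k])
          cv_scale <- anchors$open_observed + .QOL_SCALE * cv
          cm_scale <- anchors$evar_observed + .QOL_SCALE * cm
          if (cv_scale >= .QOL_MIN && cv_scale <= .QOL_MAX &&
              cm_scale >= .QOL_MIN && cm_scale <= .QOL_MAX) {
            placed <- TRUE; break
          }
        }
        if (placed) break
        step <- step / 2
      }
      cond_value_u <- cv
      cond_mean_u <- cm
      cond_sd_u <- s_E[k] * sqrt(1 - rho[k]^2)
      if (cond_sd_u <= 0) cond_sd_u <- 1e-9  # |rho| = 1: degenerate conditional
      responses[[k]] <- expert_response(
        expert_id = id, role = roles[k],
        venue = if (k %% 2) "conference" else "email",
        open_missing = elicited_normal(open_mode, .QOL_SCALE * s_O[k]),
        evar_missing = elicited_normal(evar_mode, .QOL_SCALE * s_E[k]),
        evar_given_open = conditional_elicitation(
          anchors$open_observed + .QOL_SCALE * cond_value_u,
          elicited_normal(anchors$evar_observed + .QOL_SCALE * cond_mean_u,
                          .QOL_SCALE * cond_sd_u)),
        correlation_category = if (rho[k] > 0) "positive" else if (rho[k] < 0)
          "negative" else "zero")
      truth[[k]] <- sensitivity_prior(id, m_O[k], s_O[k], m_E[k], s_E[k], rho[k])
    }
    set <- elicitation_set(responses, anchors)
    names(truth) <- vapply(truth, `[[`, character(1), "expert_id")
    attr(set, "truth") <- truth
    attr(set, "config") <- cfg
    set
  })
}
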
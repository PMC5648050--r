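# Shared fixtures, built in code.

# Worked-example arm summaries: observed responder means 0.76 (SE 0.02) and
# 0.69 (SE 0.03); missing proportions 0.18 and 0.24.
fig_arms <- function() {
  list(e = arm_summary(0.76, 0.02, 0.18, arm = "EEVAR"),
       o = arm_summary(0.69, 0.03, 0.24, arm = "OPEN"))
}

# The matching single-expert delta beliefs: N(-0.01, 0.04^2) for eEVAR,
# N(-0.05, 0.1^2) for open repair.
fig_deltas <- function() list(e = normal_spec(-0.01, 0.04),
                              o = normal_spec(-0.05, 0.1))

test_anchors <- function() anchor_scores(open_observed = 65, evar_observed = 73)

# A complete response whose conditional elicitation is exactly consistent
# with a bivariate normal belief (m_O, s_O, m_E, s_E, rho) on the utility
# scale, conditioning `at_sd` marginal SDs above the open-arm mode.
consistent_response <- function(id, m_O, s_O, m_E, s_E, rho,
                                anchors = test_anchors(), role = "doctor",
                                at_sd = 1) {
  # keep the modes on the bounded slider scale, then condition towards the
  # interior so the conditioning point and conditional mode stay on it too
  clamp <- function(m, anchor) (min(max(anchor + 100 * m, -20), 100) - anchor) / 100
  m_O <- clamp(m_O, anchors$open_observed)
  m_E <- clamp(m_E, anchors$evar_observed)
  on_scale <- function(v) v >= -20 && v <= 100
  repeat {
    placed <- FALSE
    for (dir in c(at_sd, -at_sd)) {
      cond_value <- m_O + dir * s_O
      cond_mean <- m_E + rho * s_E / s_O * (cond_value - m_O)
      if (on_scale(anchors$open_observed + 100 * cond_value) &&
          on_scale(anchors$evar_observed + 100 * cond_mean)) {
        placed <- TRUE; break
      }
    }
    if (placed) break
    at_sd <- at_sd / 2
  }
  cond_sd <- s_E * sqrt(1 - rho^2)
  expert_response(
    expert_id = id, role = role,
    open_missing = elicited_normal(anchors$open_observed + 100 * m_O, 100 * s_O),
    evar_missing = elicited_normal(anchors$evar_observed + 100 * m_E, 100 * s_E),
    evar_given_open = conditional_elicitation(
      anchors$open_observed + 100 * cond_value,
      elicited_normal(anchors$evar_observed + 100 * cond_mean, 100 * cond_sd)))
}

small_set <- function() {
  elicitation_set(list(
    consistent_response("alice", -0.05, 0.10, -0.01, 0.04, 0.5),
    consistent_response("bob", 0.02, 0.08, 0.03, 0.06, 0, role = "nurse")),
    anchors = test_anchors())
}

# Random valid sensitivity priors for property-style checks.
random_priors <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(k)
    sensitivity_prior(sprintf("r%02d", k),
                      mean_O = stats::rnorm(1, 0, 0.1),
                      sd_O = stats::runif(1, 0.02, 0.25),
                      mean_E = stats::rnorm(1, 0, 0.1),
                      sd_E = stats::runif(1, 0.02, 0.25),
                      rho = stats::runif(1, -0.95, 0.95)))
}

# Bivariate normal mixture density, written out from the closed form as an
# independent oracle for pooled-density checks.
dpool_bivariate <- function(pool, x, y) {
  out <- 0
  for (k in seq_along(pool$components)) {
    p <- pool$components[[k]]
    det <- p$sd_O^2 * p$sd_E^2 * (1 - p$rho^2)
    zx <- (x - p$mean_O) / p$sd_O
    zy <- (y - p$mean_E) / p$sd_E
    q <- (zx^2 - 2 * p$rho * zx * zy + zy^2) / (1 - p$rho^2)
    out <- out + pool$weights[k] * exp(-q / 2) / (2 * pi * sqrt(det))
  }
  out
}
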
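# Converting elicitations to sensitivity-parameter priors.

test_that("to_delta maps elicitation-scale answers to utility-scale offsets", {
  d <- to_delta(elicited_normal(61, 16), anchor = 65)
  expect_equal(d$mean, -0.04)
  expect_equal(d$sd, 0.16)

  # an expert matching the anchor is MAR-consistent
  expect_equal(to_delta(elicited_normal(65, 10), anchor = 65)$mean, 0)
})

test_that("to_delta is scale-equivariant", {
  en <- elicited_normal(61, 16)
  default <- to_delta(en, 65)           # /100 step active
  raw <- to_delta(en, 65, scale = 1)    # /100 step disabled
  expect_equal(raw$mean, 100 * default$mean)
  expect_equal(raw$sd, 100 * default$sd)
})

test_that("panel-mean delta recovers the generating delta within SE", {
  # Monte Carlo over generated panels: the mean of the constructed delta
  # means across experts estimates the panel-level truth.
  anch <- test_anchors()
  truth_O <- -0.06
  reps <- 40
  means <- vapply(seq_len(reps), function(r) {
    set <- generate_panel(panel_gen_config(n_experts = 20, true_delta_O = truth_O,
                                           between_expert_sd = 0.08, seed = 100 + r),
                          anch)
    pr <- build_panel_priors(set)
    mean(vapply(pr, `[[`, numeric(1), "mean_O"))
  }, numeric(1))
  se <- sd(means) / sqrt(reps)
  expect_lt(abs(mean(means) - truth_O), 3 * se + 1e-12)
})

test_that("derive_correlation recovers rho from exactly-consistent conditionals", {
  marg_O <- normal_spec(-0.04, 0.16)
  marg_E <- normal_spec(-0.01, 0.15)
  for (rho in c(-0.9, -0.5, 0, 0.5, 0.9)) {
    at <- marg_O$mean + 0.7 * marg_O$sd
    cond <- list(value = at,
                 mean = marg_E$mean + rho * marg_E$sd / marg_O$sd * (at - marg_O$mean),
                 sd = marg_E$sd * sqrt(1 - rho^2))
    expect_equal(derive_correlation(marg_O, marg_E, cond, "mean_shift"), rho,
                 tolerance = 1e-12)
    expect_equal(derive_correlation(marg_O, marg_E, cond, "sd_ratio"), rho,
                 tolerance = 1e-12)
  }
})

test_that("mean_shift and sd_ratio agree in absolute value on consistent inputs", {
  set.seed(21)
  for (i in 1:25) {
    rho <- runif(1, -0.99, 0.99)
    mo <- normal_spec(rnorm(1, 0, 0.1), runif(1, 0.05, 0.3))
    me <- normal_spec(rnorm(1, 0, 0.1), runif(1, 0.05, 0.3))
    at <- mo$mean + runif(1, 0.2, 2) * mo$sd * sample(c(-1, 1), 1)
    cond <- list(value = at,
                 mean = me$mean + rho * me$sd / mo$sd * (at - mo$mean),
                 sd = me$sd * sqrt(1 - rho^2))
    r1 <- derive_correlation(mo, me, cond, "mean_shift")
    r2 <- derive_correlation(mo, me, cond, "sd_ratio", sign_hint = "auto")
    expect_equal(abs(r1), abs(r2), tolerance = 1e-9)
    expect_equal(r1, r2, tolerance = 1e-9)  # auto sign follows the shift
  }
})

test_that("derive_correlation enforces its edge-case contracts", {
  mo <- normal_spec(0, 0.1); me <- normal_spec(0, 0.1)

  # no conditional shift -> rho 0
  expect_equal(derive_correlation(mo, me, list(value = 0.1, mean = 0, sd = 0.1)), 0)

  # conditioning at the marginal mean is uninformative for mean_shift
  expect_error(derive_correlation(mo, me, list(value = 0, mean = 0.05, sd = 0.1)),
               "uninformative conditioning point")

  # inconsistent elicitation: raw value 1.2 clamps to 1 with a warning
  cond <- list(value = 0.1, mean = 0.12, sd = 0.05)
  expect_warning(r <- derive_correlation(mo, me, cond, "mean_shift"), "clamped")
  expect_equal(r, 1)

  # conditional sd above marginal sd: sd_ratio falls back to 0 with warning
  expect_warning(r <- derive_correlation(mo, me, list(value = 0.1, mean = 0, sd = 0.2),
                                         "sd_ratio"), "rho = 0")
  expect_equal(r, 0)

  # explicit sign hints control the sd_ratio sign
  cond <- list(value = 0.1, mean = 0.05, sd = 0.08)
  expect_gt(derive_correlation(mo, me, cond, "sd_ratio", "+"), 0)
  expect_lt(derive_correlation(mo, me, cond, "sd_ratio", "-"), 0)
})

test_that("build_expert_prior composes marginals and correlation correctly", {
  anch <- test_anchors()

  # conditional identical to the marginal: independence prior
  r0 <- consistent_response("ind", -0.05, 0.1, -0.01, 0.04, 0, anchors = anch)
  p0 <- build_expert_prior(r0, anch)
  expect_equal(p0$rho, 0)
  expect_equal(p0$mean_O, -0.05, tolerance = 1e-12)
  expect_equal(p0$sd_E, 0.04, tolerance = 1e-12)

  # full generator inversion: all five parameters to <= 1e-9
  set.seed(31)
  for (i in 1:10) {
    truth <- c(m_O = rnorm(1, -0.04, 0.05), s_O = runif(1, 0.05, 0.2),
               m_E = rnorm(1, -0.01, 0.05), s_E = runif(1, 0.05, 0.2),
               rho = runif(1, -0.9, 0.9))
    r <- consistent_response("gen", truth["m_O"], truth["s_O"],
                             truth["m_E"], truth["s_E"], truth["rho"],
                             anchors = anch)
    p <- build_expert_prior(r, anch)
    got <- c(p$mean_O, p$sd_O, p$mean_E, p$sd_E, p$rho)
    expect_lt(max(abs(got - unname(truth))), 1e-9)
  }

  # determinism: same response + config -> bit-identical prior
  expect_identical(build_expert_prior(r0, anch), build_expert_prior(r0, anch))
})

test_that("a panel with a known positive-correlation split yields matching priors", {
  # 13 of 25 experts positively correlated, 11 zero, 1 negative
  rhos <- c(rep(0.5, 13), rep(0, 11), -0.4)
  anch <- test_anchors()
  set <- generate_panel(panel_gen_config(n_experts = 25, rho_true = rhos,
                                         between_expert_sd = 0.05,
                                         role_mix = c(nurse = 8, doctor = 17),
                                         seed = 5),
                        anch)
  priors <- build_panel_priors(set)
  rho_hat <- vapply(priors, `[[`, numeric(1), "rho")
  expect_equal(sum(rho_hat > 1e-9), 13L)
  expect_equal(sum(abs(rho_hat) <= 1e-9), 11L)
  expect_equal(sum(rho_hat < -1e-9), 1L)
})

test_that("the categorical correlation answer overrides only on request", {
  anch <- test_anchors()
  r <- consistent_response("c", -0.05, 0.1, -0.01, 0.08, 0.6, anchors = anch)
  r$correlation_category <- "zero"
  expect_equal(build_expert_prior(r, anch)$rho, 0.6, tolerance = 1e-9)
  expect_equal(build_expert_prior(r, anch, respect_categorical = TRUE)$rho, 0)
})

test_that("untruncated priors with heavy out-of-range mass warn", {
  anch <- test_anchors()
  r <- consistent_response("wide", 0, 0.9, 0, 0.1, 0, anchors = anch)
  expect_warning(build_expert_prior(r, anch), "mass outside")
})

test_that("sensitivity_prior enforces its invariants", {
  expect_error(sensitivity_prior("x", 0, -0.1, 0, 0.1, 0), "sds")
  expect_error(sensitivity_prior("x", 0, 0.1, 0, 0.1, 1.2), "rho")
  expect_error(sensitivity_prior("x", 0, 0, 0, 0.1, 0.5), "rho must be 0")
  p <- sensitivity_prior("x", -0.05, 0.1, -0.01, 0.04, 0.5)
  ev <- eigen(vcov(p), symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-12)
})

test_that("priors round-trip through their JSON file format", {
  priors <- random_priors(5, seed = 41)
  path <- tempfile(fileext = ".json")
  write_priors(priors, path)
  back <- read_priors(path)
  expect_equal(unname(back), unname(priors), tolerance = 1e-12)
})
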
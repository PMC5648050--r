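# The fully Bayesian pattern-mixture fit.

quick_cfg <- function(seed, iter = 1500, chains = 4, warmup = 200, ...)
  mcmc_config(chains = chains, iter = iter, warmup = warmup, seed = seed, ...)

test_that("degenerate delta priors reduce to the conjugate normal posterior", {
  a <- fig_arms()
  pool <- linear_pool(list(sensitivity_prior("pt", -0.05, 1e-6, -0.01, 1e-6, 0)))
  fit <- bayesian_fit(a, pool, quick_cfg(seed = 1, iter = 4000, chains = 4))
  n <- length(fit$draws$Delta)
  # closed form: Delta ~ N(0.08, 0.02^2 + 0.03^2) (weak prior shrinkage is
  # O(se^2/100), far below Monte Carlo resolution)
  sd_true <- sqrt(0.0004 + 0.0009)
  expect_lt(abs(fit$delta_hat - 0.08), 3 * sd_true / sqrt(n))
  expect_lt(abs(sd(fit$draws$Delta) - sd_true), 3 * sd_true / sqrt(2 * n))
})

test_that("delta is non-identifiable: its posterior equals the pooled prior", {
  pool <- linear_pool(random_priors(4, seed = 51))
  sim <- generate_trial(trial_gen_config(n_per_arm = 120, seed = 52))
  fit <- bayesian_fit(sim$data, pool, quick_cfg(seed = 53, iter = 2000))
  ref <- sample_pool(pool, 8000, seed = 54)
  n <- length(fit$draws$delta_O); m <- nrow(ref)
  crit <- 1.95 * sqrt((n + m) / (n * m))  # two-sample KS, alpha ~ 0.001
  for (par in c("delta_O", "delta_E")) {
    D <- suppressWarnings(ks.test(fit$draws[[par]], ref[, par])$statistic)
    expect_lt(unname(D), crit)
  }
})

test_that("moment estimator agrees with the Bayesian posterior in the conjugate case", {
  a <- fig_arms()
  p <- sensitivity_prior("x", -0.05, 0.1, -0.01, 0.04, 0)
  pool <- linear_pool(list(p))
  m <- moment_estimate_pooled(a$e, a$o, pool)
  fit <- bayesian_fit(a, pool, quick_cfg(seed = 2, iter = 4000))
  n <- length(fit$draws$Delta)
  expect_lt(abs(fit$delta_hat - m$delta_hat), 3 * m$se / sqrt(n))
  expect_lt(abs(sd(fit$draws$Delta) - m$se), 3 * m$se / sqrt(2 * n))
})

test_that("mar_fit is the zero-point-mass special case", {
  a <- fig_arms()
  cfg <- quick_cfg(seed = 3, iter = 3000)
  mar <- mar_fit(a, cfg)
  zero <- bayesian_fit(a, linear_pool(list(sensitivity_prior("z", 0, 0, 0, 0, 0))),
                       cfg)
  expect_equal(mar$draws$Delta, zero$draws$Delta)  # same seed, same model
  expect_lt(abs(mar$delta_hat - 0.07), 3 * sd(mar$draws$Delta) / sqrt(length(mar$draws$Delta)))
  expect_true(all(mar$draws$delta_O == 0) && all(mar$draws$delta_E == 0))
})

test_that("under MCAR the MAR and complete-case analyses coincide", {
  sim <- generate_trial(trial_gen_config(n_per_arm = 400, mechanism = "mcar",
                                         miss_intercept = -1.3, seed = 61))
  cfg <- quick_cfg(seed = 62, iter = 2000)
  mar <- mar_fit(sim$data, cfg)
  cc <- mar_fit(sim$data, cfg, complete_case = TRUE)
  # same observed records, both unadjusted: identical posteriors for Delta
  mc_se <- sd(mar$draws$Delta) / sqrt(length(mar$draws$Delta))
  expect_lt(abs(mar$delta_hat - cc$delta_hat), 3 * mc_se)
})

test_that("a non-degenerate MNAR prior never narrows the interval below MAR", {
  sim <- generate_trial(trial_gen_config(n_per_arm = 150, seed = 71))
  cfg <- quick_cfg(seed = 72, iter = 2500)
  mar <- mar_fit(sim$data, cfg)
  for (s in 1:3) {
    pool <- linear_pool(random_priors(sample(1:5, 1), seed = 80 + s))
    mnar <- bayesian_fit(sim$data, pool, cfg)
    expect_gte(diff(mnar$ci), diff(mar$ci) * 0.98)  # 2% MC slack
  }
})

test_that("prob_exceeds matches closed forms", {
  fake <- structure(list(draws = data.frame(Delta = rep(0.05, 2000))),
                    class = "pmm_bayes")
  expect_equal(prob_exceeds(fake, 0.03), 1)
  expect_equal(prob_exceeds(fake, -1e6), 1)

  set.seed(5)
  draws <- rnorm(2e5, 0.08, 0.044)
  target <- 1 - pnorm((0.03 - 0.08) / 0.044)
  expect_lt(abs(prob_exceeds(draws, 0.03) - target),
            3 * sqrt(target * (1 - target) / 2e5))

  expect_warning(prob_exceeds(rep(0.05, 100)), "only 100 draws")
})

test_that("patient-level Gibbs fit recovers the arm structure", {
  sim <- generate_trial(trial_gen_config(n_per_arm = 250, seed = 91))
  pool <- linear_pool(list(sensitivity_prior("p", -0.05, 0.05, -0.01, 0.05, 0.3)))
  fit <- bayesian_fit(sim$data, pool, quick_cfg(seed = 92, iter = 800, chains = 2,
                                                warmup = 300))
  s <- summarise_arm(sim$data, "OPEN")
  post <- fit$summary[fit$summary$parameter == "mu_O", ]
  expect_lt(abs(post$mean - s$mu), 4 * s$se_mu)
  expect_true(all(c("sigma_O", "sigma_E") %in% fit$summary$parameter))
  sig <- fit$summary[fit$summary$parameter == "sigma_O", ]
  expect_lt(abs(sig$mean - 0.3), 0.08)
  expect_true(all(fit$diagnostics$rhat < 1.05, na.rm = TRUE))
})

test_that("beta-binomial missingness widens uncertainty relative to plug-in", {
  sim <- generate_trial(trial_gen_config(n_per_arm = 80, seed = 101))
  pool <- linear_pool(list(sensitivity_prior("p", -0.1, 0.02, -0.1, 0.02, 0)))
  plug <- bayesian_fit(sim$data, pool, quick_cfg(seed = 102, iter = 3000))
  bb <- bayesian_fit(sim$data, pool, quick_cfg(seed = 102, iter = 3000,
                                               pi_mode = "beta_binomial"))
  expect_true(all(plug$draws$pi_E == plug$draws$pi_E[1]))
  expect_gt(var(bb$draws$pi_E), 0)
  expect_gte(sd(bb$draws$Delta), sd(plug$draws$Delta) * 0.98)
})

test_that("covariate adjustment runs and centres the adjusted means", {
  cfg <- trial_gen_config(n_per_arm = 200, covariates = c(age = 0.1),
                          mechanism = "mar", miss_slope = -1, seed = 111)
  sim <- generate_trial(cfg)
  pool <- linear_pool(list(sensitivity_prior("p", 0, 0.02, 0, 0.02, 0)))
  fit <- bayesian_fit(sim$data, pool, quick_cfg(seed = 112, iter = 600, chains = 2,
                                                warmup = 200),
                      covariates = "age")
  expect_lt(abs(fit$delta_hat - 0.07), 0.1)
  expect_error(bayesian_fit(fig_arms(), pool, quick_cfg(seed = 1),
                            covariates = "age"), "patient-level")
})

test_that("convergence diagnostics behave on iid and divergent chains", {
  set.seed(7)
  good <- matrix(rnorm(4000), 1000, 4)
  expect_lt(split_rhat(good), 1.01)
  expect_gt(ess_draws(good), 1000)

  bad <- good + rep(c(0, 5, 0, 5), each = 1000)
  expect_gt(split_rhat(bad), 1.05)

  const <- matrix(1, 1000, 4)
  expect_equal(split_rhat(const), 1)
  expect_equal(ess_draws(const), 4000)
})
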
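# Linear opinion pooling and the community of priors.

test_that("linear_pool defaults to equal weights and preserves order", {
  priors <- random_priors(26, seed = 1)
  pool <- linear_pool(priors)
  expect_length(pool$weights, 26)
  expect_equal(pool$weights, rep(1 / 26, 26))
  expect_identical(vapply(pool$components, `[[`, character(1), "expert_id"),
                   vapply(priors, `[[`, character(1), "expert_id"))

  expect_error(linear_pool(list()), "non-empty")
  expect_error(linear_pool(priors[1:2], weights = c(0.6, 0.5)), "sum")
  expect_error(linear_pool(priors[1:2], weights = c(1.5, -0.5)), "non-negative")
})

test_that("pooling identical components is idempotent in density", {
  p <- sensitivity_prior("a", -0.05, 0.1, -0.01, 0.04, 0.3)
  pool <- linear_pool(rep(list(p), 7))
  x <- seq(-0.5, 0.5, length.out = 101)
  expect_equal(dpool_marginal(pool, x, "O"), dnorm(x, -0.05, 0.1), tolerance = 1e-12)
  expect_equal(dpool_marginal(pool, x, "E"), dnorm(x, -0.01, 0.04), tolerance = 1e-12)
  expect_equal(dpool_bivariate(pool, 0.02, -0.03),
               dpool_bivariate(linear_pool(list(p)), 0.02, -0.03), tolerance = 1e-12)
})

test_that("pool_moments matches closed forms and stays PSD", {
  p <- sensitivity_prior("one", -0.05, 0.1, -0.01, 0.04, 0.5)
  mo <- pool_moments(linear_pool(list(p)))
  expect_equal(unname(mo$mean), c(-0.05, -0.01))
  expect_equal(unname(mo$cov), unname(vcov(p)), tolerance = 1e-15)

  # two equal-weight components, delta_O means 0 and 2 with unit variance:
  # mixture mean 1, mixture variance 1 + 1 = 2 in that coordinate
  q1 <- sensitivity_prior("m0", 0, 1, 0, 1e-6, 0)
  q2 <- sensitivity_prior("m2", 2, 1, 0, 1e-6, 0)
  mo2 <- pool_moments(linear_pool(list(q1, q2)))
  expect_equal(unname(mo2$mean["delta_O"]), 1)
  expect_equal(unname(mo2$cov["delta_O", "delta_O"]), 2)

  # PSD contract over random pools
  for (s in 1:10) {
    pool <- linear_pool(random_priors(sample(2:26, 1), seed = 100 + s))
    ev <- eigen(pool_moments(pool)$cov, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-12)
  }
})

test_that("pool_moments is permutation-invariant", {
  priors <- random_priors(8, seed = 3)
  set.seed(4)
  perm <- sample(8)
  expect_equal(pool_moments(linear_pool(priors)),
               pool_moments(linear_pool(priors[perm])), tolerance = 1e-12)
})

test_that("sample_pool is seed-reproducible and matches the mixture", {
  pool <- linear_pool(random_priors(3, seed = 7), weights = c(0.3, 0.5, 0.2))
  expect_identical(sample_pool(pool, 500, seed = 9), sample_pool(pool, 500, seed = 9))

  two <- linear_pool(random_priors(2, seed = 8), weights = c(0.3, 0.7))
  n <- 1e5
  d <- sample_pool(two, n, seed = 10)
  freq <- mean(attr(d, "component") == 1L)
  expect_lt(abs(freq - 0.3), 3 * sqrt(0.3 * 0.7 / n))

  mo <- pool_moments(two)
  for (j in 1:2) {
    se <- sd(d[, j]) / sqrt(n)
    expect_lt(abs(mean(d[, j]) - mo$mean[j]), 3 * se)
  }
})

test_that("the pooled bivariate density integrates to 1", {
  pool <- linear_pool(random_priors(5, seed = 12))
  mo <- pool_moments(pool)
  lim_x <- mo$mean[1] + c(-8, 8) * sqrt(mo$cov[1, 1])
  lim_y <- mo$mean[2] + c(-8, 8) * sqrt(mo$cov[2, 2])
  gx <- seq(lim_x[1], lim_x[2], length.out = 301)
  gy <- seq(lim_y[1], lim_y[2], length.out = 301)
  dens <- outer(gx, gy, function(x, y) dpool_bivariate(pool, x, y))
  total <- sum(dens) * diff(gx[1:2]) * diff(gy[1:2])
  expect_equal(total, 1, tolerance = 1e-3)
})

test_that("select_community resolves roles, extremes and ids", {
  anch <- test_anchors()
  # wide-belief experts clamp to the slider bounds; irrelevant here
  set <- suppressWarnings(
    generate_panel(panel_gen_config(n_experts = 26,
                                    role_mix = c(nurse = 9, doctor = 17),
                                    seed = 2),
                   anch))
  # emulate the analyst dropping one vague nurse before pooling
  nurse_ids <- vapply(Filter(function(r) r$role == "nurse", set$responses),
                      `[[`, character(1), "expert_id")
  priors <- build_panel_priors(set)
  priors <- priors[setdiff(names(priors), nurse_ids[1])]

  expect_length(select_community(set, priors, "all")$components, 25)
  expect_length(select_community(set, priors, "nurses")$components, 8)
  expect_length(select_community(set, priors, "doctors")$components, 17)

  one <- select_community(set, priors, names(priors)[3])
  expect_length(one$components, 1)
  expect_equal(one$components[[1]]$expert_id, names(priors)[3])

  expect_error(select_community(set, priors, "nobody"), "matches no priors")
  empty <- elicitation_set(list())
  expect_error(select_community(empty, list(), "all"), "non-empty|matches no priors")
})

test_that("sceptic and enthusiast are the extremes of the belief difference", {
  # one expert believes eEVAR non-responders score 0.2 lower (sceptic), one
  # believes they score 0.29 higher (enthusiast); the rest sit in between
  anch <- test_anchors()
  mk <- function(id, diff, role = "doctor")
    consistent_response(id, m_O = 0, s_O = 0.1, m_E = diff, s_E = 0.1, rho = 0,
                        anchors = anch, role = role)
  set <- elicitation_set(list(mk("sceptic1", -0.2), mk("mid1", 0.02),
                              mk("mid2", 0.05, "nurse"), mk("enthusiast1", 0.29)),
                         anchors = anch)
  priors <- build_panel_priors(set)
  expect_equal(find_extreme_expert(priors, "sceptical"), "sceptic1")
  expect_equal(find_extreme_expert(priors, "enthusiastic"), "enthusiast1")

  comm <- community_of_priors(set, priors)
  expect_named(comm, c("all", "doctors", "nurses", "sceptic", "enthusiast"))
  expect_equal(comm$sceptic$components[[1]]$expert_id, "sceptic1")
  expect_equal(comm$enthusiast$components[[1]]$expert_id, "enthusiast1")
})

test_that("pools round-trip through their JSON file format", {
  pool <- linear_pool(random_priors(4, seed = 20), weights = c(0.4, 0.3, 0.2, 0.1),
                      label = "doctors")
  path <- tempfile(fileext = ".json")
  write_pool(pool, path)
  back <- read_pool(path)
  expect_equal(back$label, "doctors")
  expect_equal(back$weights, pool$weights, tolerance = 1e-12)
  expect_equal(unname(lapply(back$components, unclass)),
               unname(lapply(pool$components, unclass)), tolerance = 1e-12)
})
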
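# Density strips, the community report, prior overlays, and the CLI.

test_that("density strips are max-normalised with the peak at the mode", {
  set.seed(181)
  draws <- rnorm(20000)
  grid <- seq(-4, 4, length.out = 401)
  strip <- make_density_strip(draws, grid = grid)
  expect_true(all(strip$intensity >= 0 & strip$intensity <= 1))
  expect_equal(max(strip$intensity), 1)
  peak <- grid[which.max(strip$intensity)]
  expect_lt(abs(peak - 0), 2 * diff(grid[1:2]) + 0.05)

  const <- suppressWarnings(make_density_strip(rep(0.12, 10), grid = grid))
  expect_equal(sum(const$intensity > 0), 1L)
  expect_equal(max(const$intensity), 1)
  expect_equal(grid[which.max(const$intensity)], 0.12, tolerance = 0.02)

  expect_warning(make_density_strip(rnorm(100)), "noisy")
})

test_that("strip annotations summarise the draws", {
  set.seed(182)
  draws <- rnorm(50000, 0.08, 0.044)
  strip <- make_density_strip(draws, mcid = 0.03)
  a <- strip$annotations
  expect_lt(abs(a$mean - 0.08), 0.002)
  expect_lt(abs(a$ci_low - (0.08 - 1.96 * 0.044)), 0.005)
  expect_lt(abs(a$p_mcid - (1 - pnorm((0.03 - 0.08) / 0.044))), 0.01)
})

test_that("community_report contrasts fixed-delta and observed-only analyses", {
  a <- fig_arms()
  cfg <- mcmc_config(chains = 2, iter = 3000, seed = 191)
  informed <- bayesian_fit(a, linear_pool(list(
    sensitivity_prior("pt", -0.05, 1e-6, -0.01, 1e-6, 0))), cfg)
  observed <- mar_fit(a, cfg)
  rep <- community_report(list(informed = informed, observed_only = observed))
  expect_equal(round(rep$table$mean, 2), c(0.08, 0.07))
  expect_equal(rep$table$label, c("informed", "observed_only"))
  expect_true(all(rep$table$p_mcid >= 0 & rep$table$p_mcid <= 1))

  expect_error(community_report(list(a = observed, a = informed)), "duplicate")
  expect_error(community_report(list(observed)), "named")

  single <- community_report(list(only = observed))
  expect_equal(nrow(single$table), 1L)
})

test_that("the report JSON twin round-trips", {
  a <- fig_arms()
  cfg <- mcmc_config(chains = 2, iter = 2000, seed = 192)
  rep <- community_report(list(MAR = mar_fit(a, cfg)))
  path <- tempfile(fileext = ".json")
  write_report_json(rep, path)
  back <- read_report_json(path)
  expect_equal(back$table$mean, rep$table$mean, tolerance = 1e-12)
  expect_equal(back$strips$MAR$intensity, rep$strips$MAR$intensity, tolerance = 1e-12)
  expect_equal(back$strips$MAR$annotations$p_mcid, rep$strips$MAR$annotations$p_mcid)
  expect_equal(back$grid, rep$grid)
})

test_that("prior overlays are exact weighted sums and smoother than components", {
  priors <- random_priors(25, seed = 201)
  pool <- linear_pool(priors)
  ov <- prior_overlay(priors, pool, arm = "O")
  expect_equal(ov$pooled, as.numeric(ov$components %*% pool$weights),
               tolerance = 1e-12)

  # identical components: pooled curve equals the component curve
  same <- linear_pool(rep(priors[1], 5))
  ov1 <- prior_overlay(rep(priors[1], 5), same, arm = "E")
  expect_equal(ov1$pooled, unname(ov1$components[, 1]), tolerance = 1e-12)

  # pooling smooths: total variation of the pooled curve is below the
  # roughest component's
  tv <- function(v) sum(abs(diff(v)))
  expect_lt(tv(ov$pooled), max(apply(ov$components, 2, tv)))
})

test_that("the CLI validates, simulates, builds priors, pools and analyses", {
  tmp <- tempfile(); dir.create(tmp)
  anch_file <- file.path(tmp, "anchors.yaml")
  writeLines(c("open_observed: 65", "evar_observed: 73"), anch_file)

  panel_file <- file.path(tmp, "panel.json")
  expect_equal(suppressMessages(pmm_cli(c(
    "simulate", "panel", "--config", "/dev/null", "--seed", "7",
    "--anchors", anch_file, "-o", panel_file))), 0L, ignore_attr = TRUE)
  expect_true(file.exists(panel_file))

  expect_equal(suppressMessages(pmm_cli(c("validate", panel_file))), 0L,
               ignore_attr = TRUE)

  priors_file <- file.path(tmp, "priors.json")
  suppressMessages(pmm_cli(c("build-priors", panel_file, "-o", priors_file)))
  expect_gt(length(read_priors(priors_file)), 0)

  pool_file <- file.path(tmp, "pool.json")
  suppressMessages(pmm_cli(c("pool", priors_file, "--group", "all",
                             "-o", pool_file)))
  expect_s3_class(read_pool(pool_file), "pooled_prior")

  trial_file <- file.path(tmp, "trial.csv")
  suppressMessages(pmm_cli(c("simulate", "trial", "--seed", "3",
                             "-o", trial_file)))
  result_file <- file.path(tmp, "result.json")
  suppressMessages(pmm_cli(c("analyse", "--data", trial_file,
                             "--pool", pool_file, "--seed", "5",
                             "--iter", "500", "--chains", "2",
                             "-o", result_file)))
  res <- jsonlite::read_json(result_file, simplifyVector = TRUE)
  expect_true(is.finite(res$delta_mean))
  expect_length(res$ci, 2)

  report_file <- file.path(tmp, "report.json")
  resdir <- file.path(tmp, "results"); dir.create(resdir)
  file.copy(result_file, file.path(resdir, "all.json"))
  suppressMessages(capture.output(pmm_cli(c("report", "--results", resdir,
                                            "-o", report_file))))
  expect_s3_class(read_report_json(report_file), "pmm_report")

  # a corrupt record exits non-zero
  bad_file <- file.path(tmp, "bad.json")
  set <- read_responses(panel_file)
  set$responses[[1]]$open_missing$sd <- 0
  write_responses(set, bad_file)
  expect_equal(suppressMessages(pmm_cli(c("validate", bad_file))), 1L,
               ignore_attr = TRUE)
})
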
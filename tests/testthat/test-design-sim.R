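# design-evaluation machinery; chain settings here are deliberately short —
# the cells only need variance summaries, not publication-grade posteriors

tiny_scenario <- function(brood_levels, host_levels, replicates,
                          seed = 1, design = small_design()) {
  scenario_spec(design = design,
                params = generative_params(),
                brood_levels = brood_levels, host_levels = host_levels,
                replicates = replicates,
                settings = mcmc_settings(2500, 1000, 3, seed = 1),
                seed = seed)
}

test_that("positive_call thresholds the HPD lower bound of the share", {
  eff <- list(host = matrix(0, 30, 2, dimnames = list(NULL, c("a", "b"))))
  # share draws ~ 0.5: variance equal to residual
  hi <- fake_perf_mcmc(rep(0, 30), eff,
                       variances = list(host = rep(1, 30) + rnorm(30, 0, 1e-4)),
                       residual = rep(1, 30))
  expect_true(positive_call(hi, "host", epsilon_share = 0.01))
  # share draws ~ 0.001
  lo <- fake_perf_mcmc(rep(0, 30), eff,
                       variances = list(host = 0.001 + abs(rnorm(30, 0, 1e-5))),
                       residual = rep(1, 30))
  expect_false(positive_call(lo, "host", epsilon_share = 0.01))
  expect_error(positive_call(hi, "nonexistent"), "unknown component")
})

test_that("a single-replicate scenario reports that replicate verbatim", {
  res <- run_scenario(tiny_scenario(0, 2.09, replicates = 1, seed = 5))
  expect_equal(res$failures, 0L)
  grid <- summarize_grid(res)
  expect_equal(unique(grid$n), 1L)
  # bias equals the single estimate minus truth; MC SEs are flagged NA
  host_row <- grid[grid$component == "host", ]
  est <- res$replicates$estimate[res$replicates$component == "host"]
  expect_equal(host_row$bias, est - 2.09)
  expect_equal(host_row$rmse, abs(est - 2.09))
  expect_true(is.na(host_row$bias_se))
  expect_true(is.na(host_row$positive_rate_se))
})

test_that("summarize_grid keeps one summary block per scenario cell", {
  res <- run_scenario(tiny_scenario(c(0, 1), c(0, 2.09), replicates = 2, seed = 6))
  grid <- summarize_grid(res)
  expect_equal(dplyr::n_distinct(grid$cell), 4L)
  # every cell summarises all four fitted components
  expect_equal(nrow(grid), 4L * 4L)
  expect_true(all(grid$rmse >= abs(grid$bias) - 1e-12))
  expect_true(all(grid$positive_rate >= 0 & grid$positive_rate <= 1))
  # call counts add up to the replicate count
  expect_equal(unique(grid$n_calls), 2L)
  expect_identical(nrow(res$calls), 8L)
})

test_that("uniform mixed-brood assignment turns brood variance into pure individual noise", {
  # under the protocol's per-individual uniform assignment, individuals are
  # exchangeable within a population, so brood variance adds no
  # among-culture structure: the excess among-culture variance of survival
  # proportions (beyond binomial sampling noise) stays at zero
  excess <- numeric(40)
  d <- assay_design(1, 1, 50, 10, broods_per_pop = 2)
  p <- generative_params(survival = list(intercept = 0, v_pop = 0, v_host = 0,
                                         v_pop_host = 0, v_culture = 0,
                                         v_brood = 4))
  for (r in seq_along(excess)) {
    sim <- simulate_assay(d, p, seed = 1300 + r)
    ph <- tapply(sim$survived, sim$culture, mean)
    excess[r] <- var(ph) - mean(ph) * (1 - mean(ph)) / 10
  }
  expect_lt(abs(mean(excess)) / (sd(excess) / sqrt(length(excess))), 3)
})

test_that("clustered broods push unmodelled brood variance into the culture estimate", {
  # batch-wise stocking (one brood per culture) makes brood effects
  # culture-level effects; the model without a brood term must absorb them
  # into its culture variance
  d <- assay_design(2, 3, 4, 15, broods_per_pop = c(12, 12))
  base <- tiny_scenario(c(0, 1), 0.5, replicates = 8, seed = 7, design = d)
  base$params$survival$intercept <- 0
  base$broods_per_culture <- 1L
  res <- run_scenario(base)
  cul <- res$replicates[res$replicates$component == "culture", ]
  m0 <- mean(cul$estimate[cul$brood_var == 0])
  m1 <- mean(cul$estimate[cul$brood_var == 1])
  expect_gt(m1, m0)
  expect_gt(m1, generative_params()$survival$v_culture)
})

test_that("power at the reference host effect exceeds the matched null call rate", {
  d <- assay_design(4, 9, 2, 10, broods_per_pop = c(15, 14, 126, 19))
  spec <- scenario_spec(design = d, params = generative_params(),
                        brood_levels = 0, host_levels = c(0, 2.09),
                        replicates = 6,
                        settings = mcmc_settings(4000, 1500, 3, seed = 1),
                        seed = 33)
  res <- run_scenario(spec)
  g <- summarize_grid(res)
  null_rate <- unique(g$positive_rate[g$host_var == 0])
  alt_rate <- unique(g$positive_rate[g$host_var == 2.09])
  expect_gt(alt_rate, null_rate)
})

test_that("epsilon calibration matches the requested null exceedance level", {
  set.seed(9)
  lb <- rbeta(400, 0.5, 20) # skewed, strictly positive, like share lower bounds
  eps <- calibrate_epsilon(lb, alpha = 0.05)
  expect_lt(abs(mean(lb > eps) - 0.05), 0.02)
  expect_error(calibrate_epsilon(lb[1:5]), "20")
})

test_that("replicate failures are flagged and excluded, not fatal", {
  # an impossible design cell: make all-identical survival highly likely by
  # pushing the intercept far out, so some replicates abort in the fit
  spec <- tiny_scenario(0, 0, replicates = 4, seed = 11)
  spec$params$survival$intercept <- -12
  res <- suppressWarnings(run_scenario(spec))
  expect_gt(res$failures, 0)
  expect_equal(nrow(res$calls), 4L)
  expect_true(all(!res$calls$ok[!is.na(res$calls$error)]))
})
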
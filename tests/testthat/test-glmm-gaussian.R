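# the Gibbs sampler against conjugate normal theory; the one-way fixture and
# its exact-posterior oracle live in helper-fixtures.R

test_that("conditioned chains match the closed-form multivariate-normal posterior", {
  dat <- one_way_data()
  sig2_u <- 2; sig2_e <- 1
  fit <- fit_gaussian_lmm(dat, model_spec("mass", random_terms = "culture"),
                          settings = mcmc_settings(22000, 2000, 20, seed = 5),
                          fixed_variances = list(culture = sig2_u, residual = sig2_e))
  exact <- exact_one_way_posterior(dat, sig2_u, sig2_e)

  draws <- cbind(fit$draws$intercept, fit$effects$culture)
  n_eff <- nrow(draws)
  for (j in c(1, 2, 8, 14, 21)) { # intercept + a spread of group effects
    expect_lt(abs(mean(draws[, j]) - exact$mean[j]), 5 * exact$sd[j] / sqrt(n_eff))
    expect_equal(sd(draws[, j]), unname(exact$sd[j]), tolerance = 0.1)
    ks <- suppressWarnings(
      ks.test(draws[, j], "pnorm", exact$mean[j], exact$sd[j]))
    expect_gt(ks$p.value, 0.001)
  }
})

test_that("a pure-intercept dataset recovers the intercept and shrinks the variances", {
  # all group variances zero in truth; residual 1, intercept 26.3
  set.seed(41)
  d <- small_design()
  dat <- hostassay:::design_layout(d)
  dat$sex <- sample(c("F", "M"), nrow(dat), replace = TRUE)
  dat$pupal_mass_mg <- rnorm(nrow(dat), 26.3, 1)

  fit <- fit_gaussian_lmm(dat, model_spec("mass"),
                          settings = mcmc_settings(8000, 2000, 5, seed = 6))
  s <- summarize_model(fit)
  ic <- s[s$term == "intercept", ]
  post_sd <- sd(fit$draws$intercept)
  expect_lt(abs(ic$mean - 26.3), 3 * max(post_sd, 1 / sqrt(nrow(dat))))
  # residual close to the generative 1, random variances collapsed well below it
  expect_equal(s$mean[s$term == "residual"], 1, tolerance = 0.3)
  vars <- s[s$type == "variance" & s$term != "residual", ]
  expect_true(all(apply(
    fit$draws[paste0("var_", vars$term)], 2, median) < 0.5))
})

test_that("with no information the variance posterior reproduces its prior", {
  # residual pinned far above the response scale: group effects then carry no
  # likelihood information and their variance should be sampled from the
  # prior (a moderately informative prior keeps the chain well mixed)
  set.seed(51)
  dat <- tibble::tibble(culture = rep(c("a", "b"), each = 10),
                        pupal_mass_mg = rnorm(20))
  fit <- fit_gaussian_lmm(dat, model_spec("mass", random_terms = "culture"),
                          priors = prior_spec(term_nu = 5, term_V = 2),
                          settings = mcmc_settings(42000, 2000, 20, seed = 7),
                          fixed_variances = list(residual = 1e8))
  draws <- fit$draws$var_culture
  # prior: sigma^2 ~ Inv-Gamma(shape nu/2 = 2.5, rate nu V / 2 = 5)
  p <- c(0.1, 0.25, 0.5, 0.75, 0.9)
  prior_q <- 1 / qgamma(1 - p, shape = 2.5, rate = 5)
  expect_equal(unname(quantile(draws, p)), prior_q, tolerance = 0.15)
})

test_that("gaussian fitting guards its preconditions", {
  dat <- one_way_data()
  dat$pupal_mass_mg <- 5
  expect_error(fit_gaussian_lmm(dat, model_spec("mass", random_terms = "culture")),
               "zero variance")
  dat2 <- one_way_data(); dat2$culture <- "only"
  expect_error(fit_gaussian_lmm(dat2, model_spec("mass", random_terms = "culture")),
               "single level")
  expect_error(model_spec("devtime", random_terms = c("host", "sex")), "sex")
})

test_that("thinning bookkeeping stores exactly the expected draws", {
  dat <- one_way_data(n_groups = 4, per_group = 5)
  fit <- fit_gaussian_lmm(dat, model_spec("mass", random_terms = "culture"),
                          settings = mcmc_settings(100, 0, 1, seed = 1))
  expect_equal(nrow(fit$draws), 100L)
  expect_equal(nrow(fit$effects$culture), 100L)
})

test_that("dropping rows with missing response is reported", {
  sim <- simulate_assay(small_design(), generative_params(), seed = 13)
  expect_message(
    fit_gaussian_lmm(sim, model_spec("devtime"),
                     settings = quick_settings(1500, 500, 2)),
    "dropping")
})
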
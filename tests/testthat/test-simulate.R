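zero_var_params <- function(surv_intercept = 0) {
  generative_params(
    survival = list(intercept = surv_intercept, v_pop = 0, v_host = 0,
                    v_pop_host = 0, v_culture = 0, v_brood = 0),
    mass = list(v_pop = 0, v_host = 0, v_pop_host = 0, v_culture = 0,
                v_brood = 0, v_resid = 1, sex_effect = 0),
    devtime = list(v_pop = 0, v_host = 0, v_pop_host = 0, v_culture = 0,
                   v_brood = 0, v_resid = 1))
}

test_that("with zero variances the survival proportion matches the inverse-logit intercept", {
  d <- assay_design(4, 9, 5, 20, broods_per_pop = c(126, 15, 14, 19))

  sim0 <- simulate_assay(d, zero_var_params(0), seed = 1)
  se <- sqrt(0.25 / nrow(sim0))
  expect_lt(abs(mean(sim0$survived) - 0.5), 3 * se)

  # plogis(-2.29) = 0.0920
  p <- plogis(-2.29)
  sim1 <- simulate_assay(d, zero_var_params(-2.29), seed = 2)
  se1 <- sqrt(p * (1 - p) / nrow(sim1))
  expect_lt(abs(mean(sim1$survived) - p), 3 * se1)

  # Gaussian responses concentrate on their intercepts
  expect_equal(mean(sim1$pupal_mass_mg, na.rm = TRUE), 26.3,
               tolerance = 3 * 1 / sqrt(sum(sim1$survived)) / 26.3)
  expect_equal(mean(sim1$dev_time_days, na.rm = TRUE), 33.9,
               tolerance = 3 * 1 / sqrt(sum(sim1$survived)) / 33.9)
})

test_that("records of non-survivors carry no mass, development time or sex", {
  sim <- simulate_assay(small_design(), generative_params(), seed = 5)
  dead <- sim[sim$survived == 0, ]
  expect_true(all(is.na(dead$pupal_mass_mg)))
  expect_true(all(is.na(dead$dev_time_days)))
  expect_true(all(is.na(dead$sex)))
  alive <- sim[sim$survived == 1, ]
  expect_true(all(alive$pupal_mass_mg > 0))
  expect_true(all(alive$dev_time_days > 0))
  expect_true(all(alive$sex %in% c("F", "M")))
})

test_that("simulation is byte-identical for identical design, params and seed", {
  d <- small_design(); p <- generative_params()
  expect_identical(simulate_assay(d, p, seed = 99), simulate_assay(d, p, seed = 99))
  expect_false(identical(simulate_assay(d, p, seed = 99),
                         simulate_assay(d, p, seed = 100)))
})

test_that("among-host variance of cell logits recovers the generative host variance", {
  # oracle: moment estimator on empirical cell logits across replicate
  # simulations; intercept 0 keeps survival near 1/2 so the binomial noise
  # correction (delta-method variance of the empirical logit) is small
  d <- assay_design(1, 9, 5, 40, broods_per_pop = 20)
  p <- generative_params(
    survival = list(intercept = 0, v_host = 2.09, v_pop = 0.001,
                    v_pop_host = 0.001, v_culture = 0.001, v_brood = 0),
    # keep the Gaussian responses quiet: a 1-population design draws a single
    # population effect, and the reference-scale variances could push the
    # whole dev-time mean negative
    mass = list(v_pop = 0, v_host = 0, v_pop_host = 0, v_culture = 0,
                v_resid = 1, sex_effect = 0),
    devtime = list(v_pop = 0, v_host = 0, v_pop_host = 0, v_culture = 0,
                   v_resid = 1))
  vars <- noise <- numeric(200)
  for (r in 1:200) {
    sim <- simulate_assay(d, p, seed = 5000 + r)
    agg <- tapply(sim$survived, sim$host, sum)
    n_h <- tapply(sim$survived, sim$host, length)
    el <- log((agg + 0.5) / (n_h - agg + 0.5))
    vars[r] <- var(el)
    noise[r] <- mean(1 / (agg + 0.5) + 1 / (n_h - agg + 0.5))
  }
  est <- mean(vars) - mean(noise)
  mc_se <- sd(vars) / sqrt(length(vars))
  expect_lt(abs(est - 2.09), 3 * mc_se)
})

test_that("among-group variance of simulated group effects converges to the component", {
  # 5000 cultures of 2 individuals, mass response driven almost purely by the
  # culture component
  d <- assay_design(1, 1, 5000, 2, broods_per_pop = 1)
  p <- generative_params(
    survival = list(intercept = 20, v_pop = 0, v_host = 0, v_pop_host = 0,
                    v_culture = 0, v_brood = 0),
    mass = list(v_pop = 0, v_host = 0, v_pop_host = 0, v_culture = 3,
                v_brood = 0, v_resid = 0.02, sex_effect = 0))
  sim <- simulate_assay(d, p, seed = 21)
  cul_means <- tapply(sim$pupal_mass_mg, sim$culture, mean)
  expect_lt(abs(var(cul_means) - 3) / 3, 0.10)
})

test_that("negative variances and malformed params are rejected", {
  expect_error(generative_params(survival = list(v_host = -1)), ">= 0")
  expect_error(generative_params(mass = list(prop_female = 1.5)), "prop_female")
  expect_error(generative_params(survival = list(nonsense = 1)), "unknown")
  expect_error(simulate_assay(small_design(), list(), seed = 1), "generative_params")
})
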
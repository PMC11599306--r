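test_that("variance shares reproduce hand arithmetic on a single draw", {
  one <- data.frame(host = 2.09, population = 0.046,
                    "population:host" = 0.87, culture = 0.0005,
                    residual = 1, check.names = FALSE)
  vs <- variance_shares(one)
  expect_equal(vs$share[vs$component == "host"], 2.09 / 4.0065,
               tolerance = 1e-12)
  expect_equal(sum(vs$share), 1, tolerance = 1e-12)
})

test_that("equal variances split the total evenly and shares always sum to one", {
  k <- 5
  eq <- as.data.frame(matrix(2.5, nrow = 40, ncol = k))
  names(eq) <- c("a", "b", "c", "d", "residual")
  vs <- variance_shares(eq)
  expect_equal(vs$share, rep(1 / k, k))

  fit <- cached_surv_fit()
  shares <- attr(variance_shares(fit), "share_draws")
  expect_equal(unname(rowSums(shares)), rep(1, nrow(shares)), tolerance = 1e-12)
  expect_true(all(shares >= 0 & shares <= 1))
})

test_that("summaries are invariant to the order of draws", {
  fit <- cached_surv_fit()
  perm <- fit
  set.seed(1)
  idx <- sample(nrow(fit$draws))
  perm$draws <- fit$draws[idx, ]
  perm$effects <- lapply(fit$effects, function(m) m[idx, , drop = FALSE])
  vs1 <- variance_shares(fit); vs2 <- variance_shares(perm)
  attr(vs1, "share_draws") <- attr(vs2, "share_draws") <- NULL
  expect_equal(vs1, vs2)
  s1 <- treatment_predictions(fit, "host")
  s2 <- treatment_predictions(perm, "host")
  expect_equal(s1, s2)
})

test_that("treatment predictions apply the inverse link and zero out unused terms", {
  # all effects zero, gaussian: every prediction equals the intercept (33.9)
  effects <- list(
    host = matrix(0, 5, 3, dimnames = list(NULL, c("h1", "h2", "h3"))),
    population = matrix(0, 5, 2, dimnames = list(NULL, c("p1", "p2"))),
    "population:host" = matrix(0, 5, 6, dimnames = list(
      NULL, as.vector(outer(c("p1", "p2"), c("h1", "h2", "h3"), paste, sep = ":")))),
    culture = matrix(0, 5, 4, dimnames = list(NULL, paste0("c", 1:4))))
  fit0 <- fake_perf_mcmc(rep(33.9, 5), effects,
                         variances = list(host = rep(1, 5)), residual = rep(1, 5))
  tp <- treatment_predictions(fit0, "host")
  expect_true(all(tp$mean == 33.9 & tp$lower == 33.9 & tp$upper == 33.9))
  tpc <- treatment_predictions(fit0, "cell")
  expect_true(all(tpc$mean == 33.9))
  expect_equal(nrow(tpc), 6L)

  # logit link: eta = 0 -> probability one half
  fitb <- fake_perf_mcmc(rep(0, 5), effects,
                         variances = list(host = rep(1, 5)),
                         residual = rep(1, 5), response = "surv",
                         family = "binary-logit")
  expect_true(all(treatment_predictions(fitb, "host")$mean == 0.5))

  # survival predictions always land in [0, 1]
  pd <- prediction_draws(cached_surv_fit(), "cell")
  expect_true(all(pd >= 0 & pd <= 1))
})

test_that("host-level predictions can marginalise over populations", {
  fit <- cached_surv_fit()
  zero <- prediction_draws(fit, "host", marginal = "zero")
  avg <- prediction_draws(fit, "host", marginal = "average")
  cell <- prediction_draws(fit, "cell")
  h <- colnames(zero)[1]
  pops <- unique(sub(":.*", "", colnames(cell)))
  expect_equal(avg[, h],
               rowMeans(cell[, paste(pops, h, sep = ":")]),
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(zero[, h], avg[, h])))
})

test_that("model summaries carry means, intervals and ESS per term", {
  fit <- cached_mass_fit()
  s <- summarize_model(fit)
  expect_setequal(s$term, c("intercept", "host", "population",
                            "population:host", "culture", "sex", "residual"))
  expect_true(all(s$lower <= s$mean & s$mean <= s$upper))
  expect_true(all(s$ess > 0))
  expect_identical(tidy(fit), s)
  g <- glance(fit)
  expect_equal(g$n_draws, nrow(fit$draws))

  # constant chains summarise to the constant with a degenerate interval
  eff <- list(host = matrix(0, 20, 2, dimnames = list(NULL, c("a", "b"))))
  cfit <- fake_perf_mcmc(rep(2.5, 20), eff,
                         variances = list(host = rep(4, 20)),
                         residual = rep(1, 20))
  cs <- summarize_model(cfit)
  expect_equal(cs[cs$term == "host", c("mean", "lower", "upper")],
               tibble::tibble(mean = 4, lower = 4, upper = 4),
               ignore_attr = TRUE)
})
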
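cell_matrix <- function(pops, hosts, n = 50, fill = function(p, h, n) rnorm(n)) {
  cells <- as.vector(outer(pops, hosts, paste, sep = ":"))
  m <- matrix(NA_real_, n, length(cells), dimnames = list(NULL, cells))
  for (p in pops) for (h in hosts) {
    m[, paste(p, h, sep = ":")] <- fill(p, h, n)
  }
  m
}

two_pop_flora <- list(A = "x", B = "y")

test_that("local-vs-foreign probabilities identify a uniformly best population", {
  set.seed(81)
  m <- cell_matrix(c("A", "B"), c("x", "y"),
                   fill = function(p, h, n) rnorm(n) + if (p == "A") 10 else 0)
  lvf <- local_vs_foreign(m, two_pop_flora)
  expect_equal(lvf$p_best[lvf$host == "x" & lvf$population == "A"], 1)
  expect_true(lvf$local_wins[lvf$host == "x"][1])   # A is local on x and best
  expect_false(lvf$local_wins[lvf$host == "y"][1])  # B is local on y but loses
})

test_that("exchangeable populations share the win probability evenly", {
  set.seed(82)
  pops <- c("p1", "p2", "p3", "p4")
  m <- cell_matrix(pops, c("x", "y"), n = 4000)
  lvf <- local_vs_foreign(m, setNames(as.list(rep("x", 4)), pops))
  probs <- lvf$p_best[lvf$host == "x"]
  expect_equal(probs, rep(0.25, 4), tolerance = 0.1)
  expect_equal(sum(probs), 1, tolerance = 1e-12)
})

test_that("home-vs-away compares home and away host means draw-wise", {
  set.seed(83)
  m <- cell_matrix(c("A", "B"), c("x", "y"),
                   fill = function(p, h, n) {
                     rnorm(n, mean = if (p == "A" && h == "x") 5 else 0)
                   })
  hva <- home_vs_away(m, two_pop_flora)
  expect_equal(hva$p_home_gt_away[hva$population == "A"], 1)
  expect_lt(abs(hva$p_home_gt_away[hva$population == "B"] - 0.5), 0.25)
  expect_match(hva$caveat[1], "definitive")

  # a population whose flora has no assayed host is an error
  expect_error(home_vs_away(m, list(A = "x", B = "unassayed")), "no home host")
})

test_that("criteria are invariant to monotone transformations of the metric", {
  set.seed(84)
  m <- cell_matrix(c("A", "B"), c("x", "y"), n = 200,
                   fill = function(p, h, n) runif(n, 1, 5))
  expect_equal(local_vs_foreign(m, two_pop_flora),
               local_vs_foreign(exp(m), two_pop_flora))
  expect_equal(home_vs_away(m, two_pop_flora)$p_home_gt_away,
               home_vs_away(2 * m + 1, two_pop_flora)$p_home_gt_away,
               tolerance = 1e-12)
})

test_that("a generated home-host boost is recovered by criterion 2", {
  # simulate survival with a deliberate interaction boost on the home cell,
  # fit, and check the posterior probability of home > away
  d <- assay_design(2, 3, 3, 20, broods_per_pop = c(8, 8),
                    populations = c("A", "B"), hosts = c("x", "y", "z"))
  set.seed(85)
  layout <- hostassay:::design_layout(d)
  boost <- ifelse(layout$population == "A" & layout$host == "x", 2.5, 0)
  eta <- -1 + boost + rnorm(d$n_cultures, 0, 0.1)[match(layout$culture, unique(layout$culture))]
  layout$survived <- rbinom(nrow(layout), 1, plogis(eta))
  fit <- fit_binary_glmm(layout, settings = quick_settings(6000, 2000, 4, seed = 85))
  pd <- prediction_draws(fit, "cell")
  hva <- home_vs_away(pd, list(A = "x", B = "y"), metric = "survival")
  expect_gt(hva$p_home_gt_away[hva$population == "A"], 0.95)
})

test_that("random flora maps win at about chance level", {
  set.seed(86)
  pops <- c("p1", "p2", "p3", "p4")
  hosts <- c("h1", "h2", "h3")
  wins <- 0; trials <- 200
  for (i in seq_len(trials)) {
    m <- cell_matrix(pops, hosts, n = 1)
    flora <- setNames(as.list(sample(hosts, 4, replace = TRUE)), pops)
    lvf <- local_vs_foreign(m, flora)
    w <- unique(lvf[, c("host", "local_wins")])
    wins <- wins + sum(w$local_wins, na.rm = TRUE)
  }
  # with one draw exactly one population wins each host; each population is
  # independently local to a host with probability 1/3, so the expected
  # local-win rate per host is E[# local pops]/4 = 1/3
  expect_lt(abs(wins / (trials * length(hosts)) - 1 / 3), 0.06)
})
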
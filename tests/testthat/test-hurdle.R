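test_that("psrf matches the direct between/within formula on hand-sized chains", {
  # two identical chains {1,2,3}: B = 0, W = 1, var+ = (n-1)/n W = 2/3
  expect_equal(psrf(list(c(1, 2, 3), c(1, 2, 3)), split = FALSE), sqrt(2 / 3))
  # direct evaluation for two unequal chains
  c1 <- c(1, 2, 3, 4); c2 <- c(2, 3, 4, 7)
  n <- 4
  W <- mean(c(var(c1), var(c2)))
  B <- n * var(c(mean(c1), mean(c2)))
  expected <- sqrt(((n - 1) / n * W + B / n) / W)
  expect_equal(psrf(list(c1, c2), split = FALSE), expected)
  expect_error(psrf(list(c(1, 2, 3))), "two chains")
  expect_error(psrf(list(1:4, 1:5)), "equal length")
})

test_that("psrf separates converged from non-converged chains", {
  set.seed(42)
  a <- rnorm(5000); b <- rnorm(5000)
  expect_lt(psrf(list(a, b)), 1.05)
  expect_gt(psrf(list(a, b + 10)), 5)
})

test_that("participation posterior agrees with the Beta conjugate oracle", {
  d <- hurdle_fixture(100, pi0 = 0.5, mu = 2, sigma = 0.5, seed = 10)
  k <- sum(d$episodes$oop_monthly > 0)
  fit <- fit_participation(d, "x", quick_spec(), seed = 1)
  p <- unlist(lapply(fit$draws, function(m) m[, "p"]))
  oracle <- (k + 0.5) / (100 + 1)  # Jeffreys-Beta posterior mean
  expect_lt(abs(mean(p) - oracle), 0.05)
  expect_lt(abs(mean(p) - 0.5), 0.1)

  # all-positive outcomes: separation warning, posterior near 1
  dall <- hurdle_fixture(100, pi0 = 0, mu = 2, sigma = 0.5, seed = 11)
  expect_warning(fitall <- fit_participation(dall, "x", quick_spec(), seed = 2),
                 "separated")
  pall <- unlist(lapply(fitall$draws, function(m) m[, "p"]))
  expect_gt(mean(pall), 0.95)
})

test_that("consumption posterior recovers log-normal parameters", {
  d <- hurdle_fixture(5000, pi0 = 0, mu = 2, sigma = 1, seed = 12)
  suppressWarnings(fit <- fit_consumption(d, "x", quick_spec(), seed = 3))
  mu <- unlist(lapply(fit$draws, function(m) m[, "mu"]))
  sg <- unlist(lapply(fit$draws, function(m) m[, "sigma"]))
  expect_lt(abs(mean(mu) - 2), 3 * sd(mu))
  expect_lt(abs(mean(sg) - 1), 3 * sd(sg))
})

test_that("degenerate spread concentrates mu at log(c) with small sigma", {
  hh <- tibble::tibble(household_id = paste0("h", 1:20), size = 1L, weight = 1,
                       food_exp = 50, nonfood_exp = 50, total_exp = 100,
                       residence = "rural")
  ind <- tibble::tibble(individual_id = paste0("p", 1:20),
                        household_id = hh$household_id, age = 40, sex = "male")
  ep <- tibble::tibble(individual_id = ind$individual_id, code = "flat",
                       category = "acute", oop_reported = 7, recall = "days30")
  d <- as_survey_dataset(hh, ind, ep)
  expect_warning(fit <- fit_consumption(d, "flat", quick_spec(), seed = 4),
                 "degenerate")
  mu <- unlist(lapply(fit$draws, function(m) m[, "mu"]))
  sg <- unlist(lapply(fit$draws, function(m) m[, "sigma"]))
  expect_lt(abs(mean(mu) - log(7)), 0.05)
  expect_lt(mean(sg), 0.2)
})

test_that("too few positive costs is an explicit error", {
  d <- hurdle_fixture(10, pi0 = 1, mu = 2, sigma = 1, seed = 13)
  expect_error(fit_consumption(d, "x", quick_spec(), seed = 1),
               "at least 2")
})

test_that("combine_mean applies the hurdle composition draw-wise", {
  expect_equal(combine_mean(1.0, log(7), 0), 7)
  expect_equal(combine_mean(0.0, 3.2, 1.4), 0)
  expect_equal(combine_mean(0.5, 0, sqrt(2 * log(2))), 1)
  p <- c(0.2, 0.9); mu <- c(1, 2); s <- c(0.5, 1)
  expect_equal(combine_mean(p, mu, s), p * exp(mu + s^2 / 2))
})

test_that("fit_hurdle recovers a known mean and respects invariants", {
  pi0 <- 0.2; mu <- 2; sigma <- 1
  truth <- (1 - pi0) * exp(mu + sigma^2 / 2)
  d <- hurdle_fixture(2000, pi0, mu, sigma, seed = 14)
  fit <- fit_hurdle(d, "x", quick_spec(), seed = 5)
  row <- fit$summary[fit$summary$term == "mean_cost", ]
  post_sd <- sd(fit$draws$m)
  expect_lt(abs(row$estimate - truth), 3 * post_sd)
  expect_true(row$cri_low < row$estimate, )
  expect_true(row$estimate < row$cri_high)
  # participation shrinkage, draw-wise
  expect_true(all(fit$draws$m <= exp(fit$draws$mu + fit$draws$sigma^2 / 2) + 1e-12))
  expect_true(all(fit$draws$m >= 0))
  expect_true(all(fit$psrf < 1.1))

  # determinism: same data, same seed, same summaries
  fit2 <- fit_hurdle(d, "x", quick_spec(), seed = 5)
  expect_identical(fit$summary, fit2$summary)

  # tidy/glance contracts
  td <- tidy(fit)
  expect_setequal(td$term, c("p", "mu", "sigma", "mean_cost"))
  expect_true(glance(fit)$converged)
})

test_that("an all-zero code collapses to participation near zero and mean zero", {
  d <- hurdle_fixture(200, pi0 = 1, mu = 2, sigma = 0.5, seed = 15)
  expect_warning(fit <- fit_hurdle(d, "x", quick_spec(), seed = 6), "separated")
  row <- fit$summary[fit$summary$term == "mean_cost", ]
  expect_equal(row$estimate, 0)
  p_row <- fit$summary[fit$summary$term == "p", ]
  expect_lt(p_row$estimate, 0.05)
  expect_equal(fit$n_positive, 0L)
})

test_that("posterior error in the mean shrinks as n grows", {
  pi0 <- 0.2; mu <- 2; sigma <- 1
  truth <- (1 - pi0) * exp(mu + sigma^2 / 2)
  err <- sapply(c(500, 2000, 8000), function(n) {
    e <- sapply(1:10, function(r) {
      d <- hurdle_fixture(n, pi0, mu, sigma, seed = 1000 * n + r)
      f <- fit_hurdle(d, "x", hurdle_spec(n_iter = 800, n_warmup = 300), seed = r)
      abs(f$summary$estimate[f$summary$term == "mean_cost"] - truth)
    })
    median(e)
  })
  expect_true(err[2] < err[1])
  expect_true(err[3] < err[2])
})

test_that("cost-model covariates with zero true effect are covered by the CrI", {
  # covariate effect 0 in the generator; its 95% CrI should usually cover 0
  covered <- sapply(1:12, function(r) {
    sim <- simulate_survey(
      sim_config(n_households = 150,
                 illness_table = illness_profile()[5, ] |>
                   dplyr::mutate(prevalence = 0.6, zero_prob = 0.1)),
      seed = 300 + r)
    f <- fit_consumption(sim$data, "nonspecific_fever",
                         hurdle_spec(covariates = "sex", n_iter = 800,
                                     n_warmup = 300),
                         seed = r)
    b <- unlist(lapply(f$draws, function(m) m[, "b"]))
    q <- quantile(b, c(0.025, 0.975))
    q[1] <= 0 && 0 <= q[2]
  })
  expect_gte(mean(covered), 0.9)
})

test_that("fit_costs returns one row per code and flags unfittable codes", {
  tab <- illness_profile()[c(1, 5), ]
  tab$prevalence <- c(0.2, 0.3)
  sim <- simulate_survey(sim_config(n_households = 120, illness_table = tab), seed = 16)
  res <- suppressMessages(fit_costs(sim$data, spec = quick_spec(), seed = 2))
  expect_setequal(res$code, tab$code)
  expect_true(all(res$mean_cost > 0, na.rm = TRUE))
})
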
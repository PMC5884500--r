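#' Sampler specification for the Bayesian models
#'
#' Controls the MCMC run shared by the hurdle cost model and the incidence
#' models: number of chains (at least two, so convergence can be diagnosed),
#' iterations, warm-up, thinning, and the diffuse-prior scales used when no
#' informative prior is supplied. `fit_hurdle()` doubles `n_iter` (up to
#' `max_doublings` times) until the split-chain PSRF of every monitored
#' parameter falls below `psrf_threshold`.
#'
#' @param covariates Character vector of covariate names drawn from
#'   `age`, `sex`, `quintile`, `residence` (empty = intercept-only).
#' @param prior_coef_sd SD of the Normal(0, sd) prior on regression
#'   coefficients in the cost model (diffuse default 100).
#' @param prior_sigma_sd Scale of the half-Normal prior on the log-scale
#'   residual SD (default 10).
#' @param n_chains,n_iter,n_warmup,thin MCMC controls; `n_iter` counts
#'   post-warm-up iterations per chain.
#' @param psrf_threshold Convergence cut-off for the split-chain PSRF.
#' @param max_doublings How many times `fit_hurdle()` may double `n_iter`.
#' @return A list of class `hurdle_spec`.
#' @export
hurdle_spec <- function(covariates = character(),
                        prior_coef_sd = 100,
                        prior_sigma_sd = 10,
                        n_chains = 2, n_iter = 2000, n_warmup = 500, thin = 1,
                        psrf_threshold = 1.1, max_doublings = 3) {
  if (n_chains < 2) abort("`n_chains` must be >= 2 (needed for PSRF).")
  if (n_iter <= 0 || n_warmup < 0) abort("`n_iter` must be positive and `n_warmup` non-negative.")
  bad <- setdiff(covariates, c("age", "sex", "quintile", "residence"))
  if (length(bad)) abort(sprintf("Unknown covariate(s): %s", paste(bad, collapse = ", ")))
  structure(
    list(covariates = covariates, prior_coef_sd = prior_coef_sd,
         prior_sigma_sd = prior_sigma_sd, n_chains = as.integer(n_chains),
         n_iter = as.integer(n_iter), n_warmup = as.integer(n_warmup),
         thin = as.integer(thin), psrf_threshold = psrf_threshold,
         max_doublings = as.integer(max_doublings)),
    class = "hurdle_spec"
  )
}

# Covariate design matrix (without intercept) for a set of episodes, joining
# individual- and household-level attributes. Age enters in decades centred
# at 40; sex/residence as 0/1 indicators; quintile as a numeric score.
episode_design <- function(dataset, episodes, covariates) {
  if (!length(covariates)) return(NULL)
  df <- episodes %>%
    left_join(select(dataset$individuals, "individual_id", "household_id", "age", "sex"),
              by = "individual_id") %>%
    left_join(select(dataset$households, "household_id", "residence", "quintile"),
              by = "household_id")
  cols <- list()
  if ("age" %in% covariates) cols$age10 <- (df$age - 40) / 10
  if ("sex" %in% covariates) cols$male <- as.numeric(df$sex == "male")
  if ("quintile" %in% covariates) {
    if (anyNA(df$quintile)) abort("Quintiles not assigned; run assign_quintiles() first.")
    cols$quintile <- df$quintile - 3
  }
  if ("residence" %in% covariates) cols$urban <- as.numeric(df$residence == "urban")
  do.call(cbind, cols)
}

# Run a JAGS model and return a list of per-chain draw matrices.
run_jags <- function(model_string, data, monitor, spec, seed, inits_extra = NULL) {
  inits <- lapply(seq_len(spec$n_chains), function(k) {
    c(list(.RNG.name = "base::Mersenne-Twister",
           .RNG.seed = as.integer(seed) + k), inits_extra)
  })
  model <- rjags::jags.model(textConnection(model_string), data = data,
                             inits = inits, n.chains = spec$n_chains, quiet = TRUE)
  if (spec$n_warmup > 0) update(model, spec$n_warmup, progress.bar = "none")
  samples <- rjags::coda.samples(model, monitor, n.iter = spec$n_iter,
                                 thin = spec$thin, progress.bar = "none")
  lapply(samples, function(ch) {
    m <- as.matrix(ch)
    colnames(m) <- colnames(ch)
    m
  })
}

jags_participation_model <- function(has_covariates, aggregated) {
  if (aggregated) {
    # intercept-only model collapses to a binomial count
    "model {
      y ~ dbin(p, n)
      logit(p) <- b0
      b0 ~ dnorm(0, prec_b)
    }"
  } else if (has_covariates) {
    "model {
      for (i in 1:n) {
        z[i] ~ dbern(p_i[i])
        logit(p_i[i]) <- b0 + inprod(X[i, ], b[])
      }
      b0 ~ dnorm(0, prec_b)
      for (j in 1:k) { b[j] ~ dnorm(0, prec_b) }
      p <- ilogit(b0)
    }"
  }
}

jags_consumption_model <- function(has_covariates) {
  if (has_covariates) {
    "model {
      for (i in 1:n) {
        ly[i] ~ dnorm(mu + inprod(X[i, ], b[]), tau)
      }
      mu ~ dnorm(0, prec_b)
      for (j in 1:k) { b[j] ~ dnorm(0, prec_b) }
      sigma ~ dnorm(0, prec_s) T(0, )
      tau <- 1 / (sigma * sigma)
    }"
  } else {
    # sufficient-statistic form of the iid normal likelihood:
    # ybar | mu, tau ~ N(mu, 1/(n tau)); ss = sum (ly - ybar)^2 with
    # ss tau ~ chi^2(n-1), i.e. ss ~ Gamma((n-1)/2, rate tau/2)
    "model {
      ybar ~ dnorm(mu, n * tau)
      ss ~ dgamma((n - 1) / 2, tau / 2)
      mu ~ dnorm(0, prec_b)
      sigma ~ dnorm(0, prec_s) T(0, )
      tau <- 1 / (sigma * sigma)
    }"
  }
}

#' Participation hurdle: probability of incurring any cost
#'
#' First stage of the hurdle model: a Bayesian logistic regression of the
#' indicator `oop_monthly > 0` with diffuse Normal priors. Without
#' covariates the fit collapses to a binomial intercept model and `p` is the
#' inverse-logit of the intercept.
#'
#' @param dataset A `survey_dataset`.
#' @param code Illness code to fit.
#' @param spec A [hurdle_spec()].
#' @param seed Integer seed.
#' @return A list with `draws` (per-chain matrices including column `p`),
#'   `psrf` (per parameter), `n`, `n_positive`.
#' @export
fit_participation <- function(dataset, code, spec = hurdle_spec(), seed = 1) {
  ep <- filter(dataset$episodes, .data$code == !!code)
  if (nrow(ep) == 0) abort(sprintf("No episodes with code '%s'.", code))
  z <- as.integer(ep$oop_monthly > 0)
  if (all(z == 1) || all(z == 0)) {
    warn(sprintf("Code '%s': outcome is separated (%s); the prior regularises the fit.",
                 code, if (all(z == 1)) "all positive" else "all zero"))
  }
  X <- episode_design(dataset, ep, spec$covariates)
  prec_b <- 1 / spec$prior_coef_sd^2
  if (is.null(X)) {
    draws <- run_jags(jags_participation_model(FALSE, TRUE),
                      data = list(y = sum(z), n = length(z), prec_b = prec_b),
                      monitor = c("p", "b0"), spec = spec, seed = seed)
  } else {
    draws <- run_jags(jags_participation_model(TRUE, FALSE),
                      data = list(z = z, X = X, n = length(z), k = ncol(X), prec_b = prec_b),
                      monitor = c("p", "b0", "b"), spec = spec, seed = seed)
  }
  list(draws = draws, psrf = psrf_all(draws), n = length(z), n_positive = sum(z))
}

#' Consumption hurdle: level of positive spending
#'
#' Second stage of the hurdle model: a Bayesian linear regression of
#' log-transformed positive monthly costs, with diffuse Normal priors on the
#' location and a half-Normal prior on the residual SD. Returns draws of the
#' log-scale location `mu` and residual SD `sigma`.
#'
#' @inheritParams fit_participation
#' @return A list with `draws`, `psrf`, `n_positive`.
#' @export
fit_consumption <- function(dataset, code, spec = hurdle_spec(), seed = 1) {
  ep <- filter(dataset$episodes, .data$code == !!code, .data$oop_monthly > 0)
  if (nrow(ep) < 2) {
    abort(sprintf("Code '%s': %d positive cost(s); at least 2 are needed to fit the consumption hurdle.",
                  code, nrow(ep)))
  }
  ly <- log(ep$oop_monthly)
  X <- episode_design(dataset, ep, spec$covariates)
  ss <- sum((ly - mean(ly))^2)
  monitor <- c("mu", "sigma")
  if (!is.null(X)) {
    data <- list(ly = ly, n = length(ly), X = X, k = ncol(X),
                 prec_b = 1 / spec$prior_coef_sd^2,
                 prec_s = 1 / spec$prior_sigma_sd^2)
    monitor <- c(monitor, "b")
    model <- jags_consumption_model(TRUE)
  } else if (ss < 1e-12) {
    # zero spread: the likelihood piles all mass at sigma -> 0, so the
    # posterior collapses to the point (mu = log cost, sigma = 0)
    warn(sprintf("Code '%s': all positive costs are identical; the consumption posterior is degenerate.",
                 code))
    draws <- lapply(seq_len(spec$n_chains), function(k) {
      cbind(mu = rep(mean(ly), spec$n_iter), sigma = rep(0, spec$n_iter))
    })
    return(list(draws = draws, psrf = psrf_all(draws), n_positive = length(ly)))
  } else {
    data <- list(ybar = mean(ly), ss = ss, n = length(ly),
                 prec_b = 1 / spec$prior_coef_sd^2,
                 prec_s = 1 / spec$prior_sigma_sd^2)
    model <- jags_consumption_model(FALSE)
  }
  draws <- run_jags(model, data = data, monitor = monitor, spec = spec, seed = seed)
  list(draws = draws, psrf = psrf_all(draws), n_positive = length(ly))
}

#' Combine the two hurdles into a mean cost
#'
#' Applied draw-wise: the expected monthly cost is the probability of
#' incurring any cost times the log-normal mean of the positive cost,
#' `m = p * exp(mu + sigma^2 / 2)`.
#'
#' @param p Participation probability draw(s).
#' @param mu Log-scale location draw(s).
#' @param sigma Log-scale residual SD draw(s).
#' @return Mean cost draw(s), same length.
#' @examples
#' combine_mean(0.5, 0, sqrt(2 * log(2))) # 1
#' @export
combine_mean <- function(p, mu, sigma) {
  stopifnot(all(p >= 0 & p <= 1), all(sigma >= 0))
  p * exp(mu + sigma^2 / 2)
}

#' Fit the Bayesian two-stage hurdle cost model for one illness
#'
#' Orchestrates both hurdles, combines their draws into the posterior of the
#' mean monthly OOP cost `m = p exp(mu + sigma^2/2)`, and checks convergence
#' with the split-chain PSRF; if any monitored parameter exceeds the
#' threshold the iteration count is doubled (up to `spec$max_doublings`
#' times) and the model re-run.
#'
#' @inheritParams fit_participation
#' @return A `hurdle_fit` object: draws of `p`, `mu`, `sigma`, `m`;
#'   posterior summaries; PSRF per parameter; sample sizes. Has [tidy()] and
#'   [glance()] methods.
#' @export
fit_hurdle <- function(dataset, code, spec = hurdle_spec(), seed = 1) {
  attempt <- 0
  current <- spec
  repeat {
    part <- fit_participation(dataset, code, current, seed = seed)
    if (part$n_positive == 0) {
      # no positive costs at all: participation ~ 0 and the combined mean is
      # exactly zero draw-wise; there is no consumption stage to fit
      p <- unlist(lapply(part$draws, function(m) m[, "p"]))
      q <- unname(quantile(p, c(0.025, 0.975)))
      summary <- tibble(
        term = c("p", "mu", "sigma", "mean_cost"),
        estimate = c(mean(p), NA, NA, 0),
        cri_low = c(q[1], NA, NA, 0),
        cri_high = c(q[2], NA, NA, 0))
      return(structure(
        list(code = code,
             draws = list(p = p, mu = rep(NA_real_, length(p)),
                          sigma = rep(NA_real_, length(p)),
                          m = rep(0, length(p))),
             summary = summary, psrf = part$psrf["p"],
             n = part$n, n_positive = 0L,
             n_iter = current$n_iter, spec = current),
        class = "hurdle_fit"))
    }
    cons <- fit_consumption(dataset, code, current, seed = seed + 1000L)
    psrfs <- c(part$psrf[c("p")], cons$psrf[c("mu", "sigma")])
    if (all(psrfs < current$psrf_threshold)) break
    if (attempt >= spec$max_doublings) {
      abort(sprintf(
        "Hurdle model for '%s' did not converge (PSRF %s after %d iterations).",
        code,
        paste(sprintf("%s=%.3f", names(psrfs), psrfs), collapse = ", "),
        current$n_iter))
    }
    attempt <- attempt + 1
    current$n_iter <- current$n_iter * 2L
    message(sprintf("Code '%s': PSRF above %.2f; doubling iterations to %d.",
                    code, current$psrf_threshold, current$n_iter))
  }

  p <- unlist(lapply(part$draws, function(m) m[, "p"]))
  mu <- unlist(lapply(cons$draws, function(m) m[, "mu"]))
  sigma <- unlist(lapply(cons$draws, function(m) m[, "sigma"]))
  k <- min(length(p), length(mu))
  m_draws <- combine_mean(p[seq_len(k)], mu[seq_len(k)], sigma[seq_len(k)])

  summarise_draws <- function(x) {
    q <- unname(quantile(x, c(0.025, 0.975)))
    tibble(estimate = mean(x), cri_low = q[1], cri_high = q[2])
  }
  summary <- bind_rows(
    mutate(summarise_draws(p), term = "p"),
    mutate(summarise_draws(mu), term = "mu"),
    mutate(summarise_draws(sigma), term = "sigma"),
    mutate(summarise_draws(m_draws), term = "mean_cost")
  ) %>% select("term", "estimate", "cri_low", "cri_high")

  structure(
    list(code = code,
         draws = list(p = p[seq_len(k)], mu = mu[seq_len(k)],
                      sigma = sigma[seq_len(k)], m = m_draws),
         summary = summary,
         psrf = psrfs,
         n = part$n, n_positive = part$n_positive,
         n_iter = current$n_iter, spec = current),
    class = "hurdle_fit"
  )
}

#' @export
print.hurdle_fit <- function(x, ...) {
  row <- filter(x$summary, .data$term == "mean_cost")
  cat(sprintf("<hurdle_fit> code=%s n=%d (positive %d)\n", x$code, x$n, x$n_positive))
  cat(sprintf("  mean monthly OOP: %.3f (95%% CrI %.3f-%.3f), max PSRF %.3f\n",
              row$estimate, row$cri_low, row$cri_high, max(x$psrf)))
  invisible(x)
}

#' @rdname fit_hurdle
#' @param x,object A `hurdle_fit`.
#' @param ... Unused.
#' @method tidy hurdle_fit
#' @export
tidy.hurdle_fit <- function(x, ...) {
  mutate(x$summary, code = x$code, .before = 1)
}

#' @rdname fit_hurdle
#' @method glance hurdle_fit
#' @export
glance.hurdle_fit <- function(x, ...) {
  tibble(code = x$code, n = x$n, n_positive = x$n_positive,
         n_iter = x$n_iter, max_psrf = max(x$psrf),
         converged = max(x$psrf) < x$spec$psrf_threshold)
}

#' @rdname fit_hurdle
#' @method autoplot hurdle_fit
#' @export
autoplot.hurdle_fit <- function(object, ...) {
  df <- tibble(m = object$draws$m)
  row <- filter(object$summary, .data$term == "mean_cost")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$m)) +
    ggplot2::geom_density(fill = "#2166ac", alpha = 0.4) +
    ggplot2::geom_vline(xintercept = row$estimate, colour = "#b2182b") +
    ggplot2::labs(x = "Mean monthly OOP cost", y = "Posterior density",
                  title = sprintf("Posterior mean cost, %s", object$code)) +
    ggplot2::theme_minimal()
}

#' Fit hurdle models for several illness codes
#'
#' @param dataset A `survey_dataset`.
#' @param codes Illness codes (default: all codes present).
#' @param spec A [hurdle_spec()].
#' @param seed Integer seed; per-code seeds are derived from it.
#' @return A tibble with one row per code: posterior mean cost, 95% CrI,
#'   PSRF, sample sizes. Codes with too few positive costs are reported with
#'   `NA` estimates and a message.
#' @export
fit_costs <- function(dataset, codes = NULL, spec = hurdle_spec(), seed = 1) {
  codes <- codes %||% sort(unique(dataset$episodes$code))
  purrr::imap_dfr(setNames(codes, codes), function(code, nm) {
    fit <- tryCatch(
      fit_hurdle(dataset, code, spec, seed = seed + match(code, codes)),
      error = function(e) {
        message(sprintf("Skipping '%s': %s", code, conditionMessage(e)))
        NULL
      })
    if (is.null(fit)) {
      return(tibble(code = code, mean_cost = NA_real_, cri_low = NA_real_,
                    cri_high = NA_real_, n = NA_integer_,
                    n_positive = NA_integer_, max_psrf = NA_real_))
    }
    row <- filter(fit$summary, .data$term == "mean_cost")
    tibble(code = code, mean_cost = row$estimate, cri_low = row$cri_low,
           cri_high = row$cri_high, n = fit$n, n_positive = fit$n_positive,
           max_psrf = max(fit$psrf))
  })
}
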
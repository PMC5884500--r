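#' Pool published incidence estimates into a prior
#'
#' Combines published estimates of an incidence (catastrophic payment or
#' impoverishment) by DerSimonian-Laird random-effects meta-analysis on the
#' logit scale. Each study contributes either a proportion with a 95%
#' confidence interval — its logit-scale standard error is taken as
#' `(logit(hi) - logit(lo)) / (2 * 1.96)` — or event counts
#' (`events`, `total`), in which case the delta-method binomial SE
#' `sqrt(1/events + 1/(total - events))` is used. Boundary proportions get
#' the continuity correction `0.5 / (n + 1)`.
#'
#' @param estimates Data frame with columns `label`, `incidence` (proportion
#'   in (0,1)) and either `ci_low`/`ci_high` or `events`/`total`.
#' @return A `pooled_prior` object: pooled incidence with 95% CI, the
#'   logit-scale mean and SD (for use as a prior), and the between-study
#'   variance `tau2`. Has [tidy()] and [glance()] methods.
#' @export
pool_estimates <- function(estimates) {
  est <- as_tibble(estimates)
  if (nrow(est) < 1) abort("At least one estimate is required.")
  if (!"incidence" %in% names(est) && all(c("events", "total") %in% names(est))) {
    est$incidence <- est$events / est$total
  }
  has_ci <- all(c("ci_low", "ci_high") %in% names(est)) &&
    !anyNA(est$ci_low) && !anyNA(est$ci_high)
  has_counts <- all(c("events", "total") %in% names(est))

  prop <- est$incidence
  if (has_counts) {
    boundary <- est$events == 0 | est$events == est$total
    if (any(boundary)) {
      est$events[boundary] <- est$events[boundary] + 0.5
      est$total[boundary] <- est$total[boundary] + 1
      prop <- est$events / est$total
    }
  }
  if (any(prop <= 0 | prop >= 1)) {
    prop <- pmin(pmax(prop, 0.5 / (length(prop) + 1)), 1 - 0.5 / (length(prop) + 1))
  }
  yi <- qlogis(prop)
  sei <- if (has_ci) {
    if (any(!(est$ci_low < est$incidence & est$incidence < est$ci_high))) {
      abort("Each interval must satisfy ci_low < incidence < ci_high.")
    }
    (qlogis(est$ci_high) - qlogis(est$ci_low)) / (2 * qnorm(0.975))
  } else if (has_counts) {
    sqrt(1 / est$events + 1 / (est$total - est$events))
  } else {
    abort("Each estimate needs either ci_low/ci_high or events/total.")
  }
  vi <- sei^2

  k <- length(yi)
  wi <- 1 / vi
  fixed <- sum(wi * yi) / sum(wi)
  Q <- sum(wi * (yi - fixed)^2)
  tau2 <- if (k > 1) max(0, (Q - (k - 1)) / (sum(wi) - sum(wi^2) / sum(wi))) else 0
  wstar <- 1 / (vi + tau2)
  mu <- sum(wstar * yi) / sum(wstar)
  se <- sqrt(1 / sum(wstar))

  structure(
    list(pooled_incidence = plogis(mu),
         ci_low = plogis(mu - qnorm(0.975) * se),
         ci_high = plogis(mu + qnorm(0.975) * se),
         logit_mean = mu, logit_sd = se, tau2 = tau2, Q = Q, k = k,
         studies = tibble(label = est$label %||% as.character(seq_len(k)),
                          incidence = est$incidence, logit = yi, se = sei)),
    class = "pooled_prior"
  )
}

#' @export
print.pooled_prior <- function(x, ...) {
  cat(sprintf("<pooled_prior> k=%d pooled=%.4f (95%% CI %.4f-%.4f) tau2=%.5f\n",
              x$k, x$pooled_incidence, x$ci_low, x$ci_high, x$tau2))
  invisible(x)
}

#' @rdname pool_estimates
#' @param x A `pooled_prior`.
#' @param ... Unused.
#' @method tidy pooled_prior
#' @export
tidy.pooled_prior <- function(x, ...) x$studies

#' @rdname pool_estimates
#' @method glance pooled_prior
#' @export
glance.pooled_prior <- function(x, ...) {
  tibble(k = x$k, pooled_incidence = x$pooled_incidence,
         ci_low = x$ci_low, ci_high = x$ci_high,
         logit_mean = x$logit_mean, logit_sd = x$logit_sd,
         tau2 = x$tau2, Q = x$Q)
}

#' Turn a pooled incidence into an intercept prior
#'
#' Maps a pooled incidence (point estimate with 95% interval, either a
#' `pooled_prior` or the published summary directly) onto a
#' Normal(logit mean, logit SD) prior for the intercept of a Bayesian
#' logistic incidence model. Degenerate SDs are widened to a floor.
#'
#' @param pooled A `pooled_prior`, or a proportion with `ci_low`/`ci_high`
#'   supplied as separate arguments.
#' @param ci_low,ci_high 95% interval when `pooled` is a plain proportion.
#' @param sd_floor Minimum allowed logit-scale SD (default 0.05).
#' @return A list of class `intercept_prior` with `mean` and `sd`
#'   (logit scale) and the implied incidence scale summary.
#' @export
prior_from_pooled <- function(pooled, ci_low = NULL, ci_high = NULL, sd_floor = 0.05) {
  if (inherits(pooled, "pooled_prior")) {
    mu <- pooled$logit_mean
    sd <- pooled$logit_sd
  } else {
    if (is.null(ci_low) || is.null(ci_high)) {
      abort("Supply `ci_low` and `ci_high` with a plain proportion.")
    }
    mu <- qlogis(pooled)
    sd <- (qlogis(ci_high) - qlogis(ci_low)) / (2 * qnorm(0.975))
  }
  if (!is.finite(sd) || sd < sd_floor) {
    warn(sprintf("Prior SD %.4g below floor; widened to %.2f.", sd, sd_floor))
    sd <- sd_floor
  }
  structure(list(mean = mu, sd = sd, incidence = plogis(mu)),
            class = "intercept_prior")
}

#' Published pooled incidence priors for South and South-East Asia
#'
#' Loads the shipped table of pooled incidences of household catastrophic
#' health payment (at 10% of total consumption, 40% of non-food expenditure
#' and 40% of capacity to pay) and impoverishment, compiled from published
#' estimates for Nepal, Bangladesh, India, Pakistan, Vietnam and Myanmar in
#' two eras (early 1990s and early 2010s). Use a row with
#' [prior_from_pooled()] to parameterise an informative intercept prior.
#'
#' @return A tibble with columns `indicator`, `era`, `years`, `incidence`,
#'   `ci_low`, `ci_high` (proportions).
#' @export
pooled_priors <- function() {
  path <- system.file("extdata", "pooled_priors.csv", package = "oopburden")
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
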
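#' Threshold rule for catastrophic health payment
#'
#' A payment is catastrophic when it exceeds (strictly) a fraction `z` of a
#' resource base: total household consumption, non-food consumption, or
#' capacity to pay. The four conventional rules are total\@10%, total\@15%,
#' non-food\@40% and capacity-to-pay\@40%.
#'
#' @param basis `"total_consumption"`, `"nonfood"` or `"capacity_to_pay"`.
#' @param fraction Threshold fraction `z` in (0, 1).
#' @return A list of class `threshold_rule`.
#' @export
threshold_rule <- function(basis = c("total_consumption", "nonfood", "capacity_to_pay"),
                           fraction = 0.10) {
  basis <- match.arg(basis)
  if (fraction <= 0 || fraction >= 1) abort("`fraction` must lie in (0, 1).")
  structure(list(basis = basis, fraction = fraction), class = "threshold_rule")
}

#' The four standard threshold rules
#'
#' @return Named list of [threshold_rule()]s: `total10`, `total15`,
#'   `nonfood40`, `ctp40`.
#' @export
standard_rules <- function() {
  list(total10 = threshold_rule("total_consumption", 0.10),
       total15 = threshold_rule("total_consumption", 0.15),
       nonfood40 = threshold_rule("nonfood", 0.40),
       ctp40 = threshold_rule("capacity_to_pay", 0.40))
}

#' Catastrophic-payment flag
#'
#' Flags a payment as catastrophic when it strictly exceeds
#' `fraction * denominator`.
#'
#' @param oop Out-of-pocket payment(s), >= 0.
#' @param denominator Resource base(s), > 0.
#' @param rule A [threshold_rule()] (only its `fraction` is used here; the
#'   caller chooses the matching denominator).
#' @return Integer 0/1 vector.
#' @export
catastrophic_flag <- function(oop, denominator, rule) {
  stopifnot(inherits(rule, "threshold_rule"))
  assert_nonnegative(oop, "oop")
  if (any(denominator <= 0)) abort("`denominator` must be positive.")
  as.integer(oop > rule$fraction * denominator)
}

#' Subsistence (food-needs) line
#'
#' The subsistence line underlying capacity to pay: the weighted mean food
#' expenditure per equivalent adult among households whose food share of
#' total consumption lies in a middle percentile window (default the 45th to
#' 55th weighted percentile, by weight midpoint). If the window captures no
#' household it is widened symmetrically.
#'
#' @param dataset A `survey_dataset`.
#' @param window Percentile window as a length-2 vector (default `c(0.45, 0.55)`).
#' @param beta Equivalence-scale exponent (defaults to the dataset's config).
#' @return The subsistence line, NPR per equivalent adult per month.
#' @export
subsistence_line <- function(dataset, window = c(0.45, 0.55), beta = NULL) {
  stopifnot(inherits(dataset, "survey_dataset"))
  beta <- beta %||% dataset$config$beta
  hh <- dataset$households
  if (nrow(hh) < 10) warn("Fewer than 10 households; the subsistence line is unstable.")
  fs <- hh$food_exp / hh$total_exp
  o <- order(fs)
  w <- hh$weight[o]
  mid <- (cumsum(w) - w / 2) / sum(w)
  lo <- window[1]; hi <- window[2]
  sel <- integer(0)
  while (!length(sel)) {
    sel <- o[mid >= lo & mid <= hi]
    if (!length(sel)) {
      lo <- max(0, lo - 0.05); hi <- min(1, hi + 0.05)
      warn(sprintf("Empty food-share window; widened to [%.2f, %.2f].", lo, hi))
    }
  }
  eqs <- equivalent_size(hh$size[sel], beta)
  weighted.mean(hh$food_exp[sel] / eqs, hh$weight[sel])
}

#' Capacity to pay
#'
#' A household's non-subsistence spending: total consumption minus its
#' subsistence allowance (`line * size^beta`) when reported food spending is
#' at least that allowance, otherwise total minus actual food spending
#' (the household spends less on food than the subsistence norm). Floored at
#' a small positive value.
#'
#' @param households Household tibble (needs `total_exp`, `food_exp`, `size`).
#' @param line Subsistence line from [subsistence_line()].
#' @param beta Equivalence-scale exponent.
#' @param floor Positive floor applied (with a warning) when the difference
#'   is non-positive.
#' @return Capacity to pay per household, NPR/month.
#' @export
capacity_to_pay <- function(households, line, beta = 0.56, floor = 1e-8) {
  assert_positive(line, "line")
  se <- line * equivalent_size(households$size, beta)
  ctp <- ifelse(households$food_exp >= se,
                households$total_exp - se,
                households$total_exp - households$food_exp)
  if (any(ctp <= 0)) {
    warn(sprintf("%d household(s) with non-positive capacity to pay; floored.", sum(ctp <= 0)))
    ctp <- pmax(ctp, floor)
  }
  ctp
}

# Resource base per household for a rule (vector aligned with households).
rule_denominator <- function(dataset, rule, line = NULL, beta = NULL) {
  hh <- dataset$households
  beta <- beta %||% dataset$config$beta
  switch(rule$basis,
         total_consumption = hh$total_exp,
         nonfood = hh$nonfood_exp,
         capacity_to_pay = {
           line <- line %||% subsistence_line(dataset, beta = beta)
           capacity_to_pay(hh, line, beta)
         })
}

#' Catastrophic-payment flags for a dataset
#'
#' Computes the 0/1 catastrophic flag for every unit under a threshold rule.
#' At `level = "household"` the payment is the household's total monthly OOP
#' and there is one row per household. At `level = "illness"` each illness
#' episode is flagged on its own monthly cost against its household's
#' resource base (one row per episode), which is how disease-specific burden
#' is measured.
#'
#' @param dataset A `survey_dataset`.
#' @param rule A [threshold_rule()].
#' @param level `"household"` or `"illness"`.
#' @param line Optional pre-computed subsistence line (capacity-to-pay rules).
#' @return A tibble of flags with ids, `flag`, and the household weight.
#' @export
catastrophic_flags <- function(dataset, rule = threshold_rule(),
                               level = c("household", "illness"), line = NULL) {
  level <- match.arg(level)
  denom <- rule_denominator(dataset, rule, line = line)
  hh <- dataset$households
  if (level == "household") {
    per_hh <- household_oop(dataset)
    oop_vec <- per_hh$oop_monthly[match(hh$household_id, per_hh$household_id)]
    tibble(household_id = hh$household_id,
           oop = oop_vec,
           denominator = denom,
           flag = catastrophic_flag(oop_vec, denom, rule),
           weight = hh$weight)
  } else {
    ep <- dataset$episodes %>%
      left_join(select(dataset$individuals, "individual_id", "household_id"),
                by = "individual_id")
    j <- match(ep$household_id, hh$household_id)
    tibble(individual_id = ep$individual_id, household_id = ep$household_id,
           code = ep$code, category = ep$category,
           oop = ep$oop_monthly, denominator = denom[j],
           flag = catastrophic_flag(ep$oop_monthly, denom[j], rule),
           weight = hh$weight[j])
  }
}

#' Impoverishment flags
#'
#' A household is impoverished by health payments when its per-capita
#' consumption is at or above the poverty line before subtracting OOP
#' payments and strictly below it after. Households already under the line
#' are not flagged (the differencing convention). OOP larger than total
#' consumption is floored at zero post-OOP consumption, with a warning.
#'
#' @param dataset A `survey_dataset`.
#' @param poverty_line Per-capita poverty line, NPR/month.
#' @return A tibble with `household_id`, per-capita consumption before and
#'   after OOP, `flag`, `size`, `weight`.
#' @export
impoverishment_flags <- function(dataset, poverty_line) {
  assert_positive(poverty_line, "poverty_line")
  hh <- dataset$households
  oop <- household_oop(dataset)
  oop <- oop$oop_monthly[match(hh$household_id, oop$household_id)]
  over <- oop > hh$total_exp
  if (any(over)) {
    warn(sprintf("%d household(s) report OOP above total consumption; post-OOP consumption floored at 0.",
                 sum(over)))
  }
  pre <- hh$total_exp / hh$size
  post <- pmax(hh$total_exp - oop, 0) / hh$size
  tibble(household_id = hh$household_id, pre_pc = pre, post_pc = post,
         flag = as.integer(pre >= poverty_line & post < poverty_line),
         size = hh$size, weight = hh$weight)
}

#' Poverty headcounts before and after health payments
#'
#' Weighted proportion of individuals living in households below the poverty
#' line, computed from per-capita consumption with and without OOP payments;
#' the difference is the impoverishing impact of health spending.
#'
#' @inheritParams impoverishment_flags
#' @return A one-row tibble: `pre_oop`, `post_oop`, `difference`.
#' @export
headcounts <- function(dataset, poverty_line) {
  fl <- impoverishment_flags(dataset, poverty_line)
  pw <- fl$weight * fl$size  # person weights
  pre <- weighted.mean(fl$pre_pc < poverty_line, pw)
  post <- weighted.mean(fl$post_pc < poverty_line, pw)
  tibble(pre_oop = pre, post_oop = post, difference = post - pre)
}

#' Bayesian incidence model for a binary burden indicator
#'
#' Fits a Bayesian logistic regression to 0/1 burden flags. Unadjusted
#' (no covariates), the posterior incidence is the inverse-logit of the
#' intercept. Adjusted, the linear predictor includes the confounders and
#' the posterior incidence is the sample-standardised mean of fitted
#' probabilities over the observed covariate distribution, draw by draw.
#'
#' Priors: by default every coefficient (including the intercept) gets the
#' weakly informative Cauchy(0, 2.5) prior on standardised inputs. An
#' informative [prior_from_pooled()] replaces only the intercept prior.
#'
#' @param flags A flags tibble from [catastrophic_flags()] or
#'   [impoverishment_flags()], or any data frame with a 0/1 `flag` column.
#' @param dataset The `survey_dataset` the flags came from (needed when
#'   `covariates` are requested, to look up age/sex/quintile/residence).
#' @param covariates Character vector among `age`, `sex`, `quintile`,
#'   `residence`; empty for the unadjusted model.
#' @param prior Optional `intercept_prior` from [prior_from_pooled()].
#' @param spec A [hurdle_spec()] (MCMC controls; its `covariates` field is
#'   ignored here).
#' @param seed Integer seed.
#' @param scope Label stored on the result.
#' @return An `incidence_fit`: posterior incidence with 95% CrI, PSRF,
#'   counts. Has [tidy()] and [glance()] methods.
#' @export
fit_incidence <- function(flags, dataset = NULL, covariates = character(),
                          prior = NULL, spec = hurdle_spec(), seed = 1,
                          scope = "household") {
  y <- if (is.data.frame(flags)) flags$flag else as.integer(flags)
  if (!all(y %in% c(0L, 1L))) abort("`flags` must be 0/1.")
  if (length(unique(y)) == 1L) {
    warn("No variation in the outcome; the posterior is prior-dominated.")
  }
  X <- NULL
  if (length(covariates)) {
    if (is.null(dataset)) abort("`dataset` is required when covariates are used.")
    unit <- if ("individual_id" %in% names(flags)) {
      select(flags, "individual_id")
    } else {
      # household-level flags: individual covariates proxied by the first
      # listed member (household head); rows aligned with `flags`
      heads <- dataset$individuals %>%
        group_by(.data$household_id) %>%
        dplyr::slice(1) %>% ungroup()
      tibble(individual_id = heads$individual_id[
        match(flags$household_id, heads$household_id)])
    }
    X <- episode_design(dataset, unit, covariates)
    # standardise per the weakly-informative-prior convention:
    # numeric inputs to SD 1/2, binary inputs centred
    X <- scale_for_cauchy(X)
  }

  prior_mean <- if (is.null(prior)) 0 else prior$mean
  intercept_prior <- if (is.null(prior)) {
    "b0 ~ dt(prior_mean, pow(2.5, -2), 1)"
  } else {
    "b0 ~ dnorm(prior_mean, prior_prec)"
  }
  if (is.null(X)) {
    model <- sprintf("model {
      y ~ dbin(p, n)
      logit(p) <- b0
      %s
    }", intercept_prior)
    data <- list(y = sum(y), n = length(y), prior_mean = prior_mean)
    if (!is.null(prior)) data$prior_prec <- 1 / prior$sd^2
    draws <- run_jags(model, data, monitor = c("p", "b0"), spec = spec, seed = seed)
    p_draws_chain <- lapply(draws, function(m) m[, "p", drop = FALSE])
  } else {
    model <- sprintf("model {
      for (i in 1:n) {
        z[i] ~ dbern(pi[i])
        logit(pi[i]) <- b0 + inprod(X[i, ], b[])
      }
      %s
      for (j in 1:k) { b[j] ~ dt(0, pow(2.5, -2), 1) }
    }", intercept_prior)
    data <- list(z = y, X = X, n = length(y), k = ncol(X), prior_mean = prior_mean)
    if (!is.null(prior)) data$prior_prec <- 1 / prior$sd^2
    draws <- run_jags(model, data, monitor = c("b0", "b"), spec = spec, seed = seed)
    # marginal (sample-standardised) incidence per draw
    p_draws_chain <- lapply(draws, function(m) {
      bcols <- grep("^b\\[", colnames(m))
      eta <- matrix(m[, "b0"], nrow(m), nrow(X)) + m[, bcols, drop = FALSE] %*% t(X)
      matrix(rowMeans(plogis(eta)), ncol = 1, dimnames = list(NULL, "p"))
    })
  }

  diag_draws <- lapply(seq_along(draws), function(i) {
    cbind(draws[[i]][, setdiff(colnames(draws[[i]]), "p"), drop = FALSE],
          p = p_draws_chain[[i]][, 1])
  })
  rhat <- psrf_all(diag_draws)
  p <- unlist(lapply(p_draws_chain, function(m) m[, 1]))
  q <- unname(quantile(p, c(0.025, 0.975)))

  structure(
    list(scope = scope, incidence = mean(p), cri_low = q[1], cri_high = q[2],
         draws = p, psrf = rhat, adjusted = length(covariates) > 0,
         covariates = covariates,
         prior = if (is.null(prior)) "cauchy(0, 2.5)" else
           sprintf("normal(%.3f, %.3f) on logit", prior$mean, prior$sd),
         n = length(y), events = sum(y)),
    class = "incidence_fit"
  )
}

# Standardisation used with the Cauchy(0, 2.5) default prior: binary columns
# centred, numeric columns centred and scaled to SD 0.5.
scale_for_cauchy <- function(X) {
  apply(X, 2, function(col) {
    u <- unique(col)
    if (length(u) <= 2) {
      col - mean(col)
    } else if (sd(col) > 0) {
      (col - mean(col)) / (2 * sd(col))
    } else {
      col - mean(col)
    }
  })
}

#' @export
print.incidence_fit <- function(x, ...) {
  cat(sprintf("<incidence_fit> scope=%s %s n=%d events=%d\n",
              x$scope, if (x$adjusted) "adjusted" else "unadjusted", x$n, x$events))
  cat(sprintf("  incidence %.4f (95%% CrI %.4f-%.4f), max PSRF %.3f, prior %s\n",
              x$incidence, x$cri_low, x$cri_high, max(x$psrf), x$prior))
  invisible(x)
}

#' @rdname fit_incidence
#' @param x,object An `incidence_fit`.
#' @param ... Unused.
#' @method tidy incidence_fit
#' @export
tidy.incidence_fit <- function(x, ...) {
  tibble(scope = x$scope, estimate = x$incidence,
         cri_low = x$cri_low, cri_high = x$cri_high)
}

#' @rdname fit_incidence
#' @method glance incidence_fit
#' @export
glance.incidence_fit <- function(x, ...) {
  tibble(scope = x$scope, incidence = x$incidence, cri_low = x$cri_low,
         cri_high = x$cri_high, adjusted = x$adjusted, prior = x$prior,
         n = x$n, events = x$events, max_psrf = max(x$psrf))
}
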
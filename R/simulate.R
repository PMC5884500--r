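#' Default illness profile for the synthetic survey generator
#'
#' Eight illness codes spanning the chronic / acute / injury categories, each
#' with a per-person prevalence, a probability of zero expenditure
#' (`zero_prob`), and log-normal parameters for the positive monthly cost in
#' NPR. Zero-expenditure fractions sit between 0.05 and 0.35, the range seen
#' in national household surveys; the values are generator fixtures, not
#' empirical claims.
#'
#' @return A tibble with columns `code`, `category`, `prevalence`,
#'   `zero_prob`, `cost_log_mu`, `cost_log_sigma`.
#' @export
illness_profile <- function() {
  tibble::tribble(
    ~code,               ~category, ~prevalence, ~zero_prob, ~cost_log_mu, ~cost_log_sigma,
    "asthma",            "chronic", 0.020,       0.10,       6.4,          1.0,
    "diabetes",          "chronic", 0.012,       0.05,       7.2,          0.9,
    "heart_condition",   "chronic", 0.012,       0.13,       7.7,          1.1,
    "gastrointestinal",  "chronic", 0.050,       0.15,       5.8,          1.0,
    "nonspecific_fever", "acute",   0.080,       0.14,       5.7,          0.9,
    "diarrhea",          "acute",   0.050,       0.27,       5.1,          0.9,
    "respiratory",       "acute",   0.015,       0.14,       6.3,          1.0,
    "injury",            "injury",  0.018,       0.24,       7.5,          1.2
  )
}

#' Generator configuration for synthetic household surveys
#'
#' Describes a national-household-survey-like population: household sizes,
#' right-skewed monthly consumption, food shares, urban/rural split, and an
#' illness table whose costs follow a Bernoulli-gated log-normal — a point
#' mass at zero with probability `zero_prob`, otherwise
#' `lognormal(cost_log_mu, cost_log_sigma)` — matching the generative
#' assumptions of the two-stage hurdle model.
#'
#' Optional covariate effects (named vectors with any of `age10`, `male`,
#' `urban`; `age10` is age in decades centred at 40 years) shift the
#' participation logit and the log cost location for every code; both default
#' to zero so analytic ground-truth means hold exactly.
#'
#' @param n_households Number of households.
#' @param mean_size,size_dispersion Household size is
#'   `1 + NegBinomial(mu = mean_size - 1, size = size_dispersion)`.
#' @param consumption_log_mu,consumption_log_sigma Log-scale parameters of
#'   total monthly household consumption (NPR).
#' @param food_share_mean,food_share_sd Beta-distributed food share of total
#'   consumption (parameterised by mean and SD).
#' @param residence_urban_prob Probability a household is urban.
#' @param illness_table As [illness_profile()].
#' @param participation_effects,cost_effects Named covariate-effect vectors
#'   (see Details); default all zero.
#' @param poverty_quantile Poverty line set at this quantile of per-capita
#'   consumption (used for the impoverishment ground truth).
#' @param beta Equivalence-scale exponent used for the ground-truth
#'   capacity-to-pay enumeration.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_households = 1000,
                       mean_size = 4.9,
                       size_dispersion = 3,
                       consumption_log_mu = log(9000),
                       consumption_log_sigma = 0.55,
                       food_share_mean = 0.47,
                       food_share_sd = 0.10,
                       residence_urban_prob = 0.25,
                       illness_table = illness_profile(),
                       participation_effects = c(age10 = 0, male = 0, urban = 0),
                       cost_effects = c(age10 = 0, male = 0, urban = 0),
                       poverty_quantile = 0.2,
                       beta = 0.56) {
  probs <- c(residence_urban_prob, illness_table$prevalence,
             illness_table$zero_prob, poverty_quantile)
  if (any(probs < 0 | probs > 1)) abort("Probabilities must lie in [0, 1].")
  assert_positive(illness_table$cost_log_sigma, "cost_log_sigma")
  assert_positive(c(n_households, mean_size - 1, size_dispersion,
                    consumption_log_sigma, food_share_sd), "generator parameters")
  if (food_share_mean <= 0 || food_share_mean >= 1) abort("`food_share_mean` must lie in (0, 1).")
  structure(
    list(n_households = as.integer(n_households), mean_size = mean_size,
         size_dispersion = size_dispersion,
         consumption_log_mu = consumption_log_mu,
         consumption_log_sigma = consumption_log_sigma,
         food_share_mean = food_share_mean, food_share_sd = food_share_sd,
         residence_urban_prob = residence_urban_prob,
         illness_table = as_tibble(illness_table),
         participation_effects = participation_effects,
         cost_effects = cost_effects,
         poverty_quantile = poverty_quantile, beta = beta),
    class = "sim_config"
  )
}

# Ages drawn from a four-band pyramid typical of a young national population;
# uniform within bands.
sample_ages <- function(n) {
  band <- sample.int(4, n, replace = TRUE, prob = c(0.10, 0.365, 0.447, 0.088))
  lo <- c(0, 5, 20, 60)[band]
  hi <- c(5, 20, 60, 85)[band]
  floor(runif(n, lo, hi))
}

#' Generate a synthetic household survey with known ground truth
#'
#' Draws a full three-table survey dataset (households, individuals, illness
#' episodes) from [sim_config()] and returns it together with the ground
#' truth every downstream stage can be checked against: the analytic mean
#' monthly OOP cost per code, `(1 - zero_prob) * exp(mu + sigma^2 / 2)`, and
#' the catastrophic / impoverishment incidences obtained by brute-force
#' enumeration over the realised dataset.
#'
#' The same `config` and `seed` always reproduce the identical dataset.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (required; generation is always reproducible).
#' @return A list of class `survey_simulation` with elements `data` (a
#'   `survey_dataset`) and `truth` (see [enumerate_truth()]).
#' @export
simulate_survey <- function(config = sim_config(), seed) {
  stopifnot(inherits(config, "sim_config"))
  if (missing(seed)) abort("`seed` is required for reproducible generation.")
  set.seed(as.integer(seed))

  n <- config$n_households
  size <- 1L + rnbinom(n, mu = config$mean_size - 1, size = config$size_dispersion)
  total <- rlnorm(n, config$consumption_log_mu, config$consumption_log_sigma)
  fs <- rbeta_ms(n, config$food_share_mean, config$food_share_sd)
  households <- tibble(
    household_id = sprintf("H%05d", seq_len(n)),
    size = size,
    weight = 1,
    food_exp = total * fs,
    nonfood_exp = total * (1 - fs),
    total_exp = total,
    residence = ifelse(runif(n) < config$residence_urban_prob, "urban", "rural")
  )

  m <- sum(size)
  individuals <- tibble(
    individual_id = sprintf("P%06d", seq_len(m)),
    household_id = rep(households$household_id, size),
    age = sample_ages(m),
    sex = ifelse(runif(m) < 0.5, "female", "male")
  )

  urban <- rep(households$residence == "urban", size)
  x_age10 <- (individuals$age - 40) / 10
  x_male <- as.numeric(individuals$sex == "male")
  x_urban <- as.numeric(urban)
  eff <- function(coefs) {
    coefs <- coefs[c("age10", "male", "urban")]
    coefs[is.na(coefs)] <- 0
    coefs[["age10"]] * x_age10 + coefs[["male"]] * x_male + coefs[["urban"]] * x_urban
  }
  eta_part <- eff(config$participation_effects)
  eta_cost <- eff(config$cost_effects)

  tab <- config$illness_table
  episodes <- purrr::pmap_dfr(tab, function(code, category, prevalence, zero_prob,
                                            cost_log_mu, cost_log_sigma) {
    has <- which(runif(m) < prevalence)
    if (!length(has)) return(NULL)
    k <- length(has)
    p_pos <- plogis(qlogis(1 - zero_prob) + eta_part[has])
    positive <- runif(k) < p_pos
    monthly <- ifelse(positive,
                      rlnorm(k, cost_log_mu + eta_cost[has], cost_log_sigma), 0)
    recall <- if (category == "chronic") "months12" else "days30"
    tibble(
      individual_id = individuals$individual_id[has],
      code = code, category = category,
      oop_reported = if (recall == "months12") monthly * 12 else monthly,
      recall = recall
    )
  })
  if (is.null(episodes) || nrow(episodes) == 0) {
    episodes <- tibble(individual_id = character(), code = character(),
                       category = character(), oop_reported = numeric(),
                       recall = character())
  }

  data <- as_survey_dataset(
    households, individuals, episodes,
    config = survey_config(beta = config$beta),
    metadata = list(seed = as.integer(seed), generator = "oopburden")
  )
  pc <- households$total_exp / households$size
  poverty_line <- unname(quantile(rep(pc, households$size), config$poverty_quantile))
  truth <- enumerate_truth(data, poverty_line = poverty_line, beta = config$beta,
                           illness_table = tab)
  structure(list(data = data, truth = truth), class = "survey_simulation")
}

# Beta draw parameterised by mean and SD (clamped to a proper Beta).
rbeta_ms <- function(n, mean, sd) {
  v <- min(sd^2, mean * (1 - mean) * 0.99)
  k <- mean * (1 - mean) / v - 1
  stats::rbeta(n, mean * k, (1 - mean) * k)
}

#' @export
print.survey_simulation <- function(x, ...) {
  cat("<survey_simulation>\n")
  print(x$data)
  cat(sprintf("  poverty line (truth): %.2f\n", x$truth$poverty_line))
  invisible(x)
}

#' Brute-force ground-truth enumeration
#'
#' Walks the generated dataset with plain loops — deliberately independent of
#' the vectorised pipeline in [catastrophic_flags()], [headcounts()] and
#' friends — and counts, for each illness code and at the household level, the
#' incidence of catastrophic payment under all four threshold rules, plus the
#' impoverishment headcount. Used as the oracle the pipeline is tested
#' against.
#'
#' @param dataset A `survey_dataset`.
#' @param poverty_line Per-capita poverty line (NPR/month).
#' @param beta Equivalence-scale exponent for capacity to pay.
#' @param illness_table Optional generator illness table; when given, analytic
#'   true mean costs `(1 - zero_prob) exp(mu + sigma^2/2)` are attached.
#' @return A list with `illness_incidence` (tibble: code x rule), `household_incidence`
#'   (tibble: rule, incidence), `impoverished_count`, `poverty_line`,
#'   `subsistence_line` and (optionally) `true_mean` per code.
#' @export
enumerate_truth <- function(dataset, poverty_line, beta = 0.56, illness_table = NULL) {
  hh <- as.data.frame(dataset$households)
  ind <- as.data.frame(dataset$individuals)
  ep <- as.data.frame(dataset$episodes)

  # subsistence line: weighted mean food spending per equivalent adult among
  # households in the 45th-55th weighted percentile window of food share
  fs <- hh$food_exp / hh$total_exp
  o <- order(fs)
  cw <- cumsum(hh$weight[o]) / sum(hh$weight)
  mid <- cw - hh$weight[o] / (2 * sum(hh$weight))
  win <- o[mid >= 0.45 & mid <= 0.55]
  if (!length(win)) win <- o[which.min(abs(mid - 0.5))]
  eqs <- hh$size^beta
  subsistence <- sum(hh$food_exp[win] / eqs[win] * hh$weight[win]) / sum(hh$weight[win])

  # per-household denominators and OOP by loop
  hh_oop <- setNames(rep(0, nrow(hh)), hh$household_id)
  hh_of_ind <- setNames(ind$household_id, ind$individual_id)
  for (i in seq_len(nrow(ep))) {
    h <- hh_of_ind[[ep$individual_id[i]]]
    hh_oop[[h]] <- hh_oop[[h]] + ep$oop_monthly[i]
  }
  ctp <- numeric(nrow(hh))
  for (j in seq_len(nrow(hh))) {
    se <- subsistence * eqs[j]
    ctp[j] <- if (hh$food_exp[j] >= se) hh$total_exp[j] - se else hh$total_exp[j] - hh$food_exp[j]
    if (ctp[j] <= 0) ctp[j] <- 1e-8
  }
  denom <- function(rule, j) {
    switch(rule,
           total10 = 0.10 * hh$total_exp[j],
           total15 = 0.15 * hh$total_exp[j],
           nonfood40 = 0.40 * hh$nonfood_exp[j],
           ctp40 = 0.40 * ctp[j])
  }
  rules <- c("total10", "total15", "nonfood40", "ctp40")

  # illness-level: each episode's own monthly cost against its household's base
  codes <- unique(ep$code)
  ill <- list()
  for (code in codes) {
    rows <- which(ep$code == code)
    for (rule in rules) {
      hits <- 0
      for (i in rows) {
        j <- match(hh_of_ind[[ep$individual_id[i]]], hh$household_id)
        if (ep$oop_monthly[i] > denom(rule, j)) hits <- hits + 1
      }
      ill[[length(ill) + 1]] <- data.frame(code = code, rule = rule,
                                           incidence = hits / length(rows),
                                           n = length(rows))
    }
  }
  illness_incidence <- as_tibble(do.call(rbind, ill))

  # household level: total household OOP against each base
  house <- list()
  for (rule in rules) {
    hits <- 0
    for (j in seq_len(nrow(hh))) {
      if (hh_oop[[j]] > denom(rule, j)) hits <- hits + 1
    }
    house[[length(house) + 1]] <- data.frame(rule = rule, incidence = hits / nrow(hh))
  }
  household_incidence <- as_tibble(do.call(rbind, house))

  impoverished <- 0L
  for (j in seq_len(nrow(hh))) {
    pre <- hh$total_exp[j] / hh$size[j]
    post <- max(hh$total_exp[j] - hh_oop[[j]], 0) / hh$size[j]
    if (pre >= poverty_line && post < poverty_line) impoverished <- impoverished + 1L
  }

  out <- list(illness_incidence = illness_incidence,
              household_incidence = household_incidence,
              impoverished_count = impoverished,
              poverty_line = poverty_line,
              subsistence_line = subsistence)
  if (!is.null(illness_table)) {
    out$true_mean <- illness_table %>%
      mutate(true_mean = (1 - .data$zero_prob) *
               exp(.data$cost_log_mu + .data$cost_log_sigma^2 / 2)) %>%
      select("code", "true_mean")
  }
  out
}

#' Observed zero-expenditure fraction for one illness code
#'
#' @param dataset A `survey_dataset`.
#' @param code Illness code present in the episode table.
#' @return Fraction of that code's episodes with zero monthly cost.
#' @export
zero_cost_fraction <- function(dataset, code) {
  stopifnot(inherits(dataset, "survey_dataset"))
  ep <- filter(dataset$episodes, .data$code == !!code)
  if (nrow(ep) == 0) abort(sprintf("No episodes with code '%s'.", code))
  mean(ep$oop_monthly == 0)
}
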
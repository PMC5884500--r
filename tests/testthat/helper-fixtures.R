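# Fixtures built in code; no files on disk.

# Minimal hand-written survey: 3 households, 5 persons, 4 episodes.
tiny_tables <- function() {
  list(
    households = tibble::tibble(
      household_id = c("h1", "h2", "h3"),
      size = c(2L, 2L, 1L),
      weight = c(1, 1, 2),
      food_exp = c(40, 20, 50),
      nonfood_exp = c(60, 80, 50),
      total_exp = c(100, 100, 100),
      residence = c("urban", "rural", "rural")
    ),
    individuals = tibble::tibble(
      individual_id = c("p1", "p2", "p3", "p4", "p5"),
      household_id = c("h1", "h1", "h2", "h2", "h3"),
      age = c(34, 6, 61, 28, 45),
      sex = c("female", "male", "male", "female", "female")
    ),
    episodes = tibble::tibble(
      individual_id = c("p1", "p3", "p4", "p5"),
      code = c("asthma", "fever", "fever", "injury"),
      category = c("chronic", "acute", "acute", "injury"),
      oop_reported = c(120, 5, 0, 30),
      recall = c("months12", "days30", "days30", "days30")
    )
  )
}

tiny_survey <- function() {
  t <- tiny_tables()
  as_survey_dataset(t$households, t$individuals, t$episodes)
}

# Survey with exactly n single-person households, each reporting one episode
# of `code` with Bernoulli-gated log-normal monthly cost: the hurdle model's
# own generative process with known truth.
hurdle_fixture <- function(n, pi0, mu, sigma, code = "x", seed = 1) {
  set.seed(seed)
  positive <- stats::runif(n) >= pi0
  cost <- ifelse(positive, stats::rlnorm(n, mu, sigma), 0)
  hh <- tibble::tibble(
    household_id = sprintf("h%d", seq_len(n)), size = 1L, weight = 1,
    food_exp = 500, nonfood_exp = 500, total_exp = 1000, residence = "rural"
  )
  ind <- tibble::tibble(
    individual_id = sprintf("p%d", seq_len(n)),
    household_id = hh$household_id, age = 40, sex = "female"
  )
  ep <- tibble::tibble(
    individual_id = ind$individual_id, code = code, category = "acute",
    oop_reported = cost, recall = "days30"
  )
  as_survey_dataset(hh, ind, ep)
}

# Fast MCMC settings for tests.
quick_spec <- function(...) hurdle_spec(n_iter = 1500, n_warmup = 400, ...)
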
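#' Survey configuration
#'
#' Bundles the handful of conventions the data model depends on: the
#' equivalence-scale exponent used to convert household size into equivalent
#' adults, the tolerance used when checking that food and non-food consumption
#' add up to total consumption, and whether survey weights are used when
#' constructing expenditure quintiles.
#'
#' @param beta Equivalence-scale exponent: a household of `size` members counts
#'   as `size^beta` equivalent adults. Default 0.56, the WHO convention for
#'   capacity-to-pay analyses of household health spending.
#' @param tolerance Maximum allowed relative discrepancy
#'   `|food + nonfood - total| / total` when validating household records.
#' @param weighted_quintiles Use survey weights when ranking households into
#'   expenditure quintiles (default `TRUE`).
#' @return A list of class `survey_config`.
#' @export
survey_config <- function(beta = 0.56, tolerance = 0.01, weighted_quintiles = TRUE) {
  if (beta <= 0 || beta > 1) abort("`beta` must lie in (0, 1].")
  assert_nonnegative(tolerance, "tolerance")
  structure(
    list(beta = beta, tolerance = tolerance,
         weighted_quintiles = isTRUE(weighted_quintiles)),
    class = "survey_config"
  )
}

#' Convert a reported illness cost to a monthly basis
#'
#' Acute illnesses and injuries are reported over a 30-day recall window and
#' are already monthly; chronic illnesses are reported over 12 months and are
#' divided by 12, under the assumption that chronic care spending is spread
#' evenly over the year.
#'
#' @param oop_reported Non-negative reported out-of-pocket amount(s).
#' @param recall `"days30"` or `"months12"` (recycled against `oop_reported`).
#' @return Monthly cost, same length as `oop_reported`.
#' @examples
#' monthlyize(120, "months12") # 10
#' monthlyize(30, "days30")    # 30
#' @export
monthlyize <- function(oop_reported, recall) {
  assert_nonnegative(oop_reported, "oop_reported")
  recall <- match_recall(recall, length(oop_reported))
  ifelse(recall == "months12", oop_reported / 12, oop_reported)
}

match_recall <- function(recall, n) {
  recall <- as.character(recall)
  if (length(recall) == 1L) recall <- rep(recall, n)
  bad <- !recall %in% c("days30", "months12")
  if (any(bad)) {
    abort(sprintf("Unknown recall window: %s", paste(unique(recall[bad]), collapse = ", ")))
  }
  recall
}

#' Equivalent household size
#'
#' Converts household size into equivalent adults via the power scale
#' `size^beta`, so that larger households are credited with economies of
#' scale in consumption. `beta = 1` recovers the per-capita limit.
#'
#' @param size Household size(s), integer >= 1.
#' @param beta Exponent in (0, 1]; see [survey_config()].
#' @return `size^beta`.
#' @export
equivalent_size <- function(size, beta = 0.56) {
  if (any(size < 1)) abort("`size` must be >= 1.")
  if (beta <= 0 || beta > 1) abort("`beta` must lie in (0, 1].")
  size^beta
}

household_columns <- c("household_id", "size", "weight", "food_exp",
                       "nonfood_exp", "total_exp", "residence")
individual_columns <- c("individual_id", "household_id", "age", "sex")
episode_columns <- c("individual_id", "code", "category", "oop_reported", "recall")

#' Assemble and validate a survey dataset
#'
#' Binds the three survey tables (households, individuals, illness episodes)
#' into one validated object, derives the monthly cost `oop_monthly` for every
#' episode, and enforces referential integrity and the consumption identity
#' `food + nonfood = total` (within `config$tolerance`).
#'
#' Expected columns:
#' * households: `household_id, size, weight, food_exp, nonfood_exp, total_exp,
#'   residence` (`"urban"`/`"rural"`); optional `quintile`.
#' * individuals: `individual_id, household_id, age, sex` (`"female"`/`"male"`).
#' * episodes: `individual_id, code, category`
#'   (`"chronic"`/`"acute"`/`"injury"`/`"other"`), `oop_reported, recall`.
#'
#' @param households,individuals,episodes Data frames as above.
#' @param config A [survey_config()].
#' @param metadata Optional named list (e.g. survey year, currency year).
#' @return A `survey_dataset`: list with tibbles `households`, `individuals`,
#'   `episodes` plus `metadata` and `config`.
#' @export
as_survey_dataset <- function(households, individuals, episodes,
                              config = survey_config(), metadata = list()) {
  hh <- as_tibble(households)
  ind <- as_tibble(individuals)
  ep <- as_tibble(episodes)

  check_columns(hh, household_columns, "households")
  check_columns(ind, individual_columns, "individuals")
  check_columns(ep, episode_columns, "episodes")

  validate_households(hh, config$tolerance)
  validate_individuals(ind, hh)
  ep <- validate_episodes(ep, ind)

  hh$quintile <- if ("quintile" %in% names(hh)) as.integer(hh$quintile) else NA_integer_

  structure(
    list(households = hh, individuals = ind, episodes = ep,
         metadata = metadata, config = config),
    class = "survey_dataset"
  )
}

check_columns <- function(df, cols, table) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("Table `%s` is missing column(s): %s",
                  table, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

validate_households <- function(hh, tolerance) {
  if (anyDuplicated(hh$household_id)) abort("Duplicate household_id in households table.")
  fail_row <- function(cond, field, msg) {
    i <- which(cond)
    if (length(i)) {
      abort(sprintf("households row %d, field `%s`: %s", i[1], field, msg))
    }
  }
  fail_row(hh$size < 1 | hh$size != round(hh$size), "size", "must be a positive integer")
  fail_row(!(hh$weight > 0), "weight", "must be > 0")
  fail_row(hh$food_exp < 0, "food_exp", "must be >= 0")
  fail_row(hh$nonfood_exp < 0, "nonfood_exp", "must be >= 0")
  fail_row(!(hh$total_exp > 0), "total_exp", "must be > 0")
  fail_row(hh$total_exp < hh$food_exp, "total_exp", "total below food expenditure")
  fail_row(hh$total_exp < hh$nonfood_exp, "total_exp", "total below non-food expenditure")
  gap <- abs(hh$food_exp + hh$nonfood_exp - hh$total_exp) / hh$total_exp
  fail_row(gap > tolerance, "total_exp",
           "food + nonfood does not match total within tolerance")
  fail_row(!hh$residence %in% c("urban", "rural"), "residence",
           "must be 'urban' or 'rural'")
  invisible(hh)
}

validate_individuals <- function(ind, hh) {
  if (anyDuplicated(ind$individual_id)) abort("Duplicate individual_id in individuals table.")
  orphan <- !ind$household_id %in% hh$household_id
  if (any(orphan)) {
    abort(sprintf("individuals row %d, field `household_id`: no such household (%s)",
                  which(orphan)[1], ind$household_id[which(orphan)[1]]))
  }
  if (any(ind$age < 0)) abort("individuals: `age` must be >= 0.")
  if (any(!ind$sex %in% c("female", "male"))) {
    abort("individuals: `sex` must be 'female' or 'male'.")
  }
  invisible(ind)
}

validate_episodes <- function(ep, ind) {
  orphan <- !ep$individual_id %in% ind$individual_id
  if (any(orphan)) {
    abort(sprintf("episodes row %d, field `individual_id`: no such individual (%s)",
                  which(orphan)[1], ep$individual_id[which(orphan)[1]]))
  }
  neg <- ep$oop_reported < 0
  if (any(neg)) {
    abort(sprintf("episodes row %d, field `oop_reported`: negative cost", which(neg)[1]))
  }
  if (any(!ep$category %in% c("chronic", "acute", "injury", "other"))) {
    abort("episodes: `category` must be chronic, acute, injury or other.")
  }
  ep$recall <- match_recall(ep$recall, nrow(ep))
  # recall windows are tied to category by questionnaire design
  bad <- (ep$category == "chronic" & ep$recall != "months12") |
    (ep$category %in% c("acute", "injury") & ep$recall != "days30")
  if (any(bad)) {
    abort(sprintf("episodes row %d, field `recall`: recall window inconsistent with category `%s`",
                  which(bad)[1], ep$category[which(bad)[1]]))
  }
  ep$oop_monthly <- monthlyize(ep$oop_reported, ep$recall)
  ep
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat("<survey_dataset>\n")
  cat(sprintf("  households:  %d\n", nrow(x$households)))
  cat(sprintf("  individuals: %d\n", nrow(x$individuals)))
  cat(sprintf("  episodes:    %d (%d illness codes)\n",
              nrow(x$episodes), dplyr::n_distinct(x$episodes$code)))
  if (length(x$metadata)) {
    cat(sprintf("  metadata:    %s\n",
                paste(names(x$metadata), unlist(x$metadata), sep = "=", collapse = ", ")))
  }
  invisible(x)
}

#' Read a survey dataset from three CSV tables
#'
#' Reads the household, individual and illness-episode tables (UTF-8, comma
#' separated, header row, period decimal separator) and validates them with
#' [as_survey_dataset()].
#'
#' @param household_path,individual_path,episode_path CSV file paths.
#' @inheritParams as_survey_dataset
#' @return A `survey_dataset`.
#' @export
read_survey <- function(household_path, individual_path, episode_path,
                        config = survey_config(), metadata = list()) {
  for (p in c(household_path, individual_path, episode_path)) {
    if (!file.exists(p)) abort(sprintf("File not found: %s", p))
  }
  hh <- readr::read_csv(household_path, show_col_types = FALSE, progress = FALSE)
  ind <- readr::read_csv(individual_path, show_col_types = FALSE, progress = FALSE)
  ep <- readr::read_csv(episode_path, show_col_types = FALSE, progress = FALSE)
  as_survey_dataset(hh, ind, ep, config = config, metadata = metadata)
}

#' Write a survey dataset as three CSV tables
#'
#' Inverse of [read_survey()]; writes `households.csv`, `individuals.csv` and
#' `episodes.csv` into `dir` using the same CSV dialect.
#'
#' @param dataset A `survey_dataset`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the three file paths.
#' @export
write_survey <- function(dataset, dir) {
  stopifnot(inherits(dataset, "survey_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("households.csv", "individuals.csv", "episodes.csv"))
  readr::write_csv(dataset$households, paths[1], progress = FALSE)
  readr::write_csv(dataset$individuals, paths[2], progress = FALSE)
  readr::write_csv(dataset$episodes %>% select(-"oop_monthly"), paths[3], progress = FALSE)
  invisible(paths)
}

#' Assign equivalence-scaled expenditure quintiles
#'
#' Ranks households by total consumption per equivalent adult
#' (`total_exp / size^beta`) and splits the (weighted) population into five
#' groups of as nearly as possible equal cumulative weight; quintile 1 is the
#' poorest. A household whose weight midpoint falls at fraction `f` of total
#' weight receives quintile `ceiling(5 f)`. Ties are broken by stable input
#' order.
#'
#' @param dataset A `survey_dataset`.
#' @param beta Equivalence-scale exponent (defaults to the dataset's config).
#' @param weighted Use survey weights (defaults to the dataset's config).
#' @return The dataset with `households$quintile` filled in.
#' @export
assign_quintiles <- function(dataset, beta = NULL, weighted = NULL) {
  stopifnot(inherits(dataset, "survey_dataset"))
  beta <- beta %||% dataset$config$beta
  weighted <- weighted %||% dataset$config$weighted_quintiles
  hh <- dataset$households
  pea <- hh$total_exp / equivalent_size(hh$size, beta)
  if (length(unique(pea)) == 1L && nrow(hh) > 1L) {
    warn("All households have equal per-equivalent-adult expenditure; quintiles assigned by input order.")
  }
  w <- if (weighted) hh$weight else rep(1, nrow(hh))
  r <- fractional_rank(pea, w)
  q <- pmin(5L, pmax(1L, as.integer(ceiling(5 * r))))
  dataset$households$quintile <- q
  dataset
}

#' Monthly out-of-pocket spending per household
#'
#' Sums the monthly OOP cost of every illness episode reported by a
#' household's members. Households with no episodes get 0.
#'
#' @param dataset A `survey_dataset`.
#' @param household_id Optional id(s) to restrict to.
#' @return A tibble with `household_id` and `oop_monthly`, one row per
#'   household (all of them, or the requested subset in request order).
#' @export
household_oop <- function(dataset, household_id = NULL) {
  stopifnot(inherits(dataset, "survey_dataset"))
  per_hh <- dataset$episodes %>%
    left_join(select(dataset$individuals, "individual_id", "household_id"),
              by = "individual_id") %>%
    group_by(.data$household_id) %>%
    summarise(oop_monthly = sum(.data$oop_monthly), .groups = "drop")
  out <- tibble(household_id = dataset$households$household_id) %>%
    left_join(per_hh, by = "household_id") %>%
    mutate(oop_monthly = dplyr::coalesce(.data$oop_monthly, 0))
  if (!is.null(household_id)) {
    missing <- setdiff(household_id, out$household_id)
    if (length(missing)) abort(sprintf("Unknown household_id: %s", missing[1]))
    out <- out[match(household_id, out$household_id), ]
  }
  out
}
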
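#' Weighted fractional rank
#'
#' Ranks units from poorest to richest on a living-standards measure and
#' returns each unit's weighted fractional rank
#' `r_i = (cumulative weight before i + w_i / 2) / total weight`, in (0, 1).
#' Tied values share the midpoint rank of the tied block, so the rank is a
#' function of the value alone.
#'
#' @param x Living-standards measure (e.g. consumption per equivalent adult).
#' @param w Positive weights (default: equal).
#' @return Fractional ranks, aligned with `x`.
#' @examples
#' fractional_rank(c(10, 20, 30, 40, 50)) # 0.1 0.3 0.5 0.7 0.9
#' @export
fractional_rank <- function(x, w = rep(1, length(x))) {
  stopifnot(length(x) == length(w))
  assert_positive(w, "w")
  o <- order(x)
  cw <- cumsum(w[o])
  total <- cw[length(cw)]
  mid <- (cw - w[o] / 2) / total
  r <- numeric(length(x))
  r[o] <- mid
  # ties: every member of a tied block takes the block's midpoint rank
  if (anyDuplicated(x)) {
    start <- (cw - w[o]) / total
    end <- cw / total
    xs <- x[o]
    block_mid <- (ave(start, xs, FUN = min) + ave(end, xs, FUN = max)) / 2
    r[o] <- block_mid
  }
  r
}

#' Concentration index
#'
#' Measures socioeconomic inequality in a health variable as twice the
#' weighted covariance between the variable and the fractional wealth rank,
#' divided by the variable's weighted mean (the "convenient covariance"
#' formula). Negative values mean the burden is concentrated among the poor;
#' positive values among the rich. For a binary indicator the index is bounded
#' by (-1, 1).
#'
#' @param y Health/burden variable (e.g. a catastrophic-payment flag).
#' @param ranks Fractional ranks from [fractional_rank()].
#' @param w Positive weights (default: equal).
#' @return The concentration index, a scalar.
#' @export
concentration_index <- function(y, ranks, w = rep(1, length(y))) {
  stopifnot(length(y) == length(ranks), length(y) == length(w))
  mu <- weighted.mean(y, w)
  if (mu == 0) abort("Concentration index undefined: mean of `y` is zero.")
  2 * weighted_cov(y, ranks, w) / mu
}

#' Concentration curve
#'
#' Orders units from poorest to richest and accumulates population share
#' against burden share; the curve runs from (0, 0) to (1, 1). A curve above
#' the diagonal indicates the burden is concentrated among the poor
#' (negative concentration index).
#'
#' @inheritParams concentration_index
#' @return A tibble with columns `pop_share` and `burden_share`, starting at
#'   (0, 0).
#' @export
concentration_curve <- function(y, ranks, w = rep(1, length(y))) {
  stopifnot(length(y) == length(ranks), length(y) == length(w))
  if (weighted.mean(y, w) == 0) abort("Concentration curve undefined: mean of `y` is zero.")
  o <- order(ranks)
  tibble(
    pop_share = c(0, cumsum(w[o]) / sum(w)),
    burden_share = c(0, cumsum(y[o] * w[o]) / sum(y * w))
  )
}

#' Concentration analysis of a burden indicator
#'
#' Convenience wrapper producing both the concentration index and the curve
#' for a burden indicator over a wealth ranking.
#'
#' @param df A data frame with one row per unit.
#' @param burden Column with the burden indicator (unquoted).
#' @param wealth Column with the living-standards measure used for ranking
#'   (unquoted).
#' @param weight Optional weight column (unquoted).
#' @param scope Label for the result (e.g. an illness code or "household").
#' @return A `concentration` object: list with `index`, `curve`, `scope`, `n`.
#'   Has [tidy()], [glance()] and [autoplot()] methods.
#' @export
concentration <- function(df, burden, wealth, weight = NULL, scope = "household") {
  y <- dplyr::pull(df, {{ burden }})
  x <- dplyr::pull(df, {{ wealth }})
  w <- if (rlang::quo_is_null(rlang::enquo(weight))) rep(1, nrow(df)) else dplyr::pull(df, {{ weight }})
  r <- fractional_rank(x, w)
  structure(
    list(index = concentration_index(y, r, w),
         curve = concentration_curve(y, r, w),
         scope = scope, n = length(y)),
    class = "concentration"
  )
}

#' @export
print.concentration <- function(x, ...) {
  cat(sprintf("<concentration> scope=%s n=%d index=%.4f\n", x$scope, x$n, x$index))
  invisible(x)
}

#' @rdname concentration
#' @param x A `concentration` object.
#' @param ... Unused.
#' @method tidy concentration
#' @export
tidy.concentration <- function(x, ...) {
  mutate(x$curve, scope = x$scope)
}

#' @rdname concentration
#' @method glance concentration
#' @export
glance.concentration <- function(x, ...) {
  tibble(scope = x$scope, index = x$index, n = x$n)
}

#' @rdname concentration
#' @param object A `concentration` object.
#' @method autoplot concentration
#' @export
autoplot.concentration <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$pop_share, y = .data$burden_share)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "Cumulative population share (poorest first)",
      y = "Cumulative burden share",
      title = sprintf("Concentration curve (%s), index = %.3f", object$scope, object$index)
    ) +
    ggplot2::theme_minimal()
}
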
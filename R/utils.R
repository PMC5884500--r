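# Internal helpers shared across modules.

# Round half away from zero (report display convention; base round() is
# half-to-even, which disagrees with how published tables are rounded).
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Weighted quantile of type "inverse CDF on cumulative weight"; x need not be
# sorted. Returns the smallest x whose cumulative weight share >= p.
weighted_quantile <- function(x, w, p) {
  stopifnot(length(x) == length(w), all(w > 0))
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  vapply(p, function(pi) x[o][which(cw >= pi - 1e-12)[1]], numeric(1))
}

# Weighted covariance with frequency-style weights: E_w[xy] - E_w[x]E_w[y].
weighted_cov <- function(x, y, w) {
  w <- w / sum(w)
  mx <- sum(w * x)
  my <- sum(w * y)
  sum(w * (x - mx) * (y - my))
}

assert_positive <- function(x, what) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort(sprintf("`%s` must be positive and finite.", what))
  }
  invisible(x)
}

assert_nonnegative <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0)) {
    abort(sprintf("`%s` must be non-negative and finite.", what))
  }
  invisible(x)
}
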
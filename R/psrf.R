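#' Potential scale reduction factor (Gelman-Rubin)
#'
#' Compares between- and within-chain variance for one scalar parameter.
#' With `split = TRUE` (the default) each chain is first split in half, so
#' slow trends within a chain also inflate the statistic. Values near 1
#' indicate the chains are sampling the same distribution; the conventional
#' convergence cut-off is 1.1.
#'
#' Given m sequences of length n with within-sequence variances s_j^2 and
#' means xbar_j: W = mean(s_j^2), B = n * var(xbar_j),
#' var+ = (n-1)/n W + B/n, and PSRF = sqrt(var+ / W).
#'
#' @param chains A list of numeric vectors (one per chain, equal lengths) or
#'   a matrix with one column per chain.
#' @param split Split each chain in half first (requires length >= 4).
#' @return The PSRF, a scalar >= 0.
#' @export
psrf <- function(chains, split = TRUE) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)), function(j) chains[, j])
  if (!is.list(chains) || length(chains) < 2) {
    abort("`chains` must contain at least two chains.")
  }
  len <- lengths(chains)
  if (length(unique(len)) != 1) abort("All chains must have equal length.")
  n <- len[1]
  if (split) {
    if (n < 4) abort("Splitting requires chains of length >= 4; use split = FALSE for shorter chains.")
    half <- floor(n / 2)
    chains <- unlist(lapply(chains, function(ch) {
      list(ch[seq_len(half)], ch[seq.int(n - half + 1, n)])
    }), recursive = FALSE)
    n <- half
  }
  if (n < 2) abort("Chains must have length >= 2.")
  means <- vapply(chains, mean, numeric(1))
  vars <- vapply(chains, var, numeric(1))
  W <- mean(vars)
  B <- n * var(means)
  if (W == 0) return(if (B == 0) 1 else Inf)
  var_plus <- (n - 1) / n * W + B / n
  sqrt(var_plus / W)
}

# PSRF for every column of per-chain draw matrices.
psrf_all <- function(draws_by_chain, split = TRUE) {
  params <- colnames(draws_by_chain[[1]])
  vapply(params, function(p) {
    psrf(lapply(draws_by_chain, function(m) m[, p]), split = split)
  }, numeric(1))
}
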
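#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Draw Laplace-distributed random deviates
#'
#' Samples from the double-exponential (Laplace) distribution with location
#' `mu` and scale `b`, via inverse-CDF transform of uniform deviates.
#'
#' @param n number of deviates.
#' @param mu location parameter.
#' @param b scale parameter (> 0); the mean absolute deviation from `mu`.
#' @return numeric vector of length `n`.
#' @export
rlaplace <- function(n, mu = 0, b = 1) {
  stopifnot(b > 0)
  u <- stats::runif(n) - 0.5
  mu - b * sign(u) * log1p(-2 * abs(u))
}

## Pearson correlation of every row of a matrix against one fixed vector.
## Rows with zero variance yield NA.
row_pcc <- function(P, a) {
  a_c <- a - mean(a)
  sa <- sqrt(sum(a_c^2))
  P_c <- P - rowMeans(P)
  sp <- sqrt(rowSums(P_c^2))
  num <- as.numeric(P_c %*% a_c)
  out <- num / (sp * sa)
  out[sp == 0 | sa == 0] <- NA_real_
  out
}

vnorm <- function(v) sqrt(sum(v^2))

## Derive a child seed from a base seed; kept below 2^31 - 1.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483630L) + 1L
}

stop_hddr <- function(msg, class) {
  stop(structure(class = c(class, "hddr_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
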
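#' Largest-remainder rounding of proportions to integer counts
#'
#' Apportions `n` units among groups so that counts sum exactly to `n`:
#' each group gets `floor(n * p)` and the remaining units go to the groups
#' with the largest fractional remainders (ties broken by group order).
#'
#' @param n Total number of units (positive integer).
#' @param proportions Named or unnamed numeric vector of nonnegative
#'   fractions summing to 1 (within 1e-12).
#' @return Integer vector of counts, same names/length as `proportions`,
#'   summing to `n`.
#' @examples
#' largest_remainder(189, c(ND = 141, WD = 27, MD = 9, SD = 12) / 189)
#' @export
largest_remainder <- function(n, proportions) {
  stopifnot(length(n) == 1L, n >= 0, is.numeric(proportions))
  if (any(proportions < 0)) stop("proportions must be nonnegative")
  if (abs(sum(proportions) - 1) > 1e-12)
    stop("proportions must sum to 1 (got ", format(sum(proportions)), ")")
  raw <- n * proportions
  base <- floor(raw)
  left <- as.integer(round(n - sum(base)))
  if (left > 0) {
    rem <- raw - base
    take <- order(rem, decreasing = TRUE)[seq_len(left)]
    base[take] <- base[take] + 1
  }
  counts <- as.integer(base)
  names(counts) <- names(proportions)
  counts
}

# Deterministic per-unit substream seed derived from a master seed by a
# counter offset, kept inside 32-bit integer range so panels can be
# extended without reshuffling earlier units.
substream_seed <- function(seed, index) {
  as.integer((as.numeric(seed) %% 2147483647 + 104729 * as.numeric(index)) %%
    2147483647)
}

# Truncated-normal draws via inverse-CDF (exact, vectorized).
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

# Log-uniform draws on [lo, hi].
rloguniform <- function(n, lo, hi) {
  exp(runif(n, log(lo), log(hi)))
}

#' Ramanujan's approximation to the perimeter of an ellipse
#'
#' First Ramanujan approximation, accurate to well under 0.02\% for the
#' aspect ratios of quinoa seeds; used as analytic ground truth for
#' rendered seed images.
#'
#' @param a,b Semi-axis lengths (any consistent unit).
#' @return Approximate perimeter in the same unit.
#' @examples
#' ramanujan_perimeter(1, 1) / (2 * pi) # 1
#' @export
ramanujan_perimeter <- function(a, b) {
  pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
}
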
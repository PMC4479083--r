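#' Percentage rounded to the nearest integer
#'
#' Concordance and response rates are conventionally reported as whole
#' percentages. Rounding is half-away-from-zero (so 61.5 -> 62), not the
#' round-half-even rule of [base::round()]; at small pair counts the two
#' conventions disagree.
#'
#' @param k Numerator count.
#' @param n Denominator count (> 0).
#' @return Integer percentage `100 * k / n`, rounded half away from zero.
#' @examples
#' rate_percent(27, 36) # 75
#' rate_percent(24, 39) # 62
#' @export
rate_percent <- function(k, n) {
  if (!is.numeric(k) || !is.numeric(n) || any(n <= 0)) {
    abort("`k` and `n` must be numeric with n > 0.")
  }
  x <- 100 * k / n
  sign(x) * floor(abs(x) + 0.5)
}

# Derive a stage-specific seed from a user seed. Keeps every stream keyed to
# the single user-visible seed while decoupling stages from evaluation order.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) + 10007 * h) %% .Machine$integer.max)
}

# shared validator for user-supplied id vectors
check_no_duplicates <- function(x, what) {
  dup <- unique(x[duplicated(x)])
  if (length(dup) > 0) {
    abort(sprintf(
      "Duplicate %s: %s", what,
      paste(head(dup, 5), collapse = ", ")
    ))
  }
  invisible(x)
}
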
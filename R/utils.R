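#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.5 -> 1), the convention used when
#' comparing computed risk characterisation ratios with values printed at a
#' fixed number of decimals. Base R's `round()` rounds ties to even, which
#' disagrees with printed tables exactly at the ties.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half-up.
#' @examples
#' round_half_up(0.0235, 2) # 0.02
#' round_half_up(0.125, 2)  # 0.13 (round() would give 0.12)
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# half-up rounding to a number of significant figures
signif_half_up <- function(x, sig = 2) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi == 0) return(xi)
    e <- floor(log10(abs(xi))) - (sig - 1)
    round_half_up(xi / 10^e) * 10^e
  }, numeric(1))
}

# stop unless every element of x is a finite, strictly positive number
assert_positive <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    abort(sprintf("`%s` must be finite and strictly positive.", what),
          class = "hbmtier_domain_error")
  }
  invisible(x)
}

# seed handling: all stochastic entry points funnel through here so a given
# seed yields bit-identical draws across repeated calls
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}
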
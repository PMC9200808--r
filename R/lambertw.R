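#' Lambert W of an exponential, W(exp(z))
#'
#' Evaluates the principal branch of the Lambert W function at `exp(z)`,
#' working throughout in the log domain so that arguments whose exponential
#' overflows (or underflows) double precision are still handled exactly. This
#' is the primitive needed by the closed-form solution of Rogers' random
#' predator equation, where the W argument is
#' `a * h * N0 * exp(-a * (T - h * N0))` and the exponent grows linearly in
#' `a * h * N0`.
#'
#' For `z >= -30` the value is found by Newton iteration on
#' `g(w) = w + log(w) - z`, which is monotone for `w > 0` and converges
#' quadratically from the starting point `z - log(z)` (for `z > 1`) or
#' `exp(z)` (otherwise). For `z < -30` the two-term series
#' `W(x) = x (1 - x) + O(x^3)` at `x = exp(z)` is already accurate to well
#' below double-precision relative error.
#'
#' @param z Numeric vector; the natural logarithm of the W argument.
#' @return Numeric vector, `W(exp(z))`, same length as `z`.
#' @examples
#' lambert_w_exp(0)            # W(1) = 0.567143...
#' lambert_w_exp(log(1 * exp(1)))  # W(e) = 1
#' @export
lambert_w_exp <- function(z) {
  if (!is.numeric(z)) abort("`z` must be numeric.")
  w <- numeric(length(z))
  w[is.na(z)] <- NA_real_
  small <- !is.na(z) & z < -30
  ez <- exp(z[small])
  w[small] <- ez * (1 - ez)
  main <- !is.na(z) & !small
  if (any(main)) {
    zi <- z[main]
    wi <- ifelse(zi > 1, zi - log(pmax(zi, 1.000001)), exp(zi))
    for (i in seq_len(100L)) {
      wn <- wi - (wi + log(wi) - zi) / (1 + 1 / wi)
      bad <- wn <= 0            # Newton overshoot; bisect towards 0
      wn[bad] <- wi[bad] / 2
      if (max(abs(wn - wi) / pmax(abs(wn), 1e-300)) < 1e-15) {
        wi <- wn
        break
      }
      wi <- wn
    }
    w[main] <- wi
  }
  w
}
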
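#' Negative branch of the Lambert W function
#'
#' Solves `w * exp(w) = z` for the branch `w <= -1`, defined for
#' `z` in `(-1/e, 0)`. This branch inverts the Lindley cdf and therefore
#' yields the ELG quantile function in closed form.
#'
#' Evaluation uses Halley's method. The starting point is the asymptotic
#' `log(-z) - log(-log(-z))` away from the branch point and the series
#' `-1 - s - s^2/3` with `s = sqrt(2 (1 + e z))` near `z = -1/e`, where the
#' asymptotic start loses digits. Iteration stops when
#' `|w e^w - z| < 1e-12 * max(|z|, 1e-300)` (and always below 1e-12 absolute).
#'
#' @param z numeric vector with entries in the open interval `(-1/e, 0)`.
#' @return numeric vector `w` with `w <= -1` and `w * exp(w) == z`.
#' @examples
#' lambert_wm1(-2 * exp(-2))   # exactly -2
#' lambert_wm1(-1 / exp(1))    # branch point, -1
#' @export
lambert_wm1 <- function(z) {
  if (!is.numeric(z)) stop("z must be numeric", call. = FALSE)
  out <- vapply(z, lambert_wm1_scalar, numeric(1L))
  out
}

lambert_wm1_scalar <- function(z) {
  if (!is.finite(z) || z >= 0 || z < -exp(-1) - 1e-15)
    stop("z must lie in (-1/e, 0)", call. = FALSE)
  one_over_e <- exp(-1)
  if (abs(z + one_over_e) < 1e-16) return(-1)
  # initial guess
  if (z < -0.25) {
    s <- sqrt(2 * (1 + exp(1) * z))
    w <- -1 - s - s^2 / 3 - 11 * s^3 / 72
  } else {
    lz <- log(-z)
    w <- lz - log(-lz)
  }
  tol <- 1e-12 * max(abs(z), 1e-300)
  for (it in seq_len(80L)) {
    ew <- exp(w)
    f <- w * ew - z
    if (abs(f) < tol || abs(f) < 1e-15) break
    # Halley step
    wp1 <- w + 1
    denom <- ew * wp1 - (w + 2) * f / (2 * wp1)
    w_new <- w - f / denom
    if (!is.finite(w_new) || w_new > -1) {
      # fall back to a damped Newton step, projected into the branch
      w_new <- w - f / (ew * wp1)
      if (!is.finite(w_new) || w_new > -1) w_new <- -1 - abs(w + 1) / 2
    }
    if (abs(w_new - w) < 1e-15 * abs(w)) { w <- w_new; break }
    w <- w_new
  }
  w
}
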
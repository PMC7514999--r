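#' Truncation control for the auxiliary moment series
#'
#' The moment machinery of the ELG family rests on two auxiliary integrals,
#' `K(a, b, c, delta)` and its lower-truncated analogue `L(a, b, c, t)`,
#' whose series expansions are infinite sums. `series_control()` bundles the
#' truncation policy: the outer index is summed until `consecutive_small`
#' successive terms fall below `abs_tol` in absolute value, capped at
#' `max_outer_terms`.
#'
#' @param max_outer_terms cap on the outer summation index (default 500).
#' @param abs_tol absolute smallness threshold for terms (default 1e-12).
#' @param consecutive_small number of successive small terms required to
#'   declare convergence (default 3).
#' @return a list of class `"series_control"`.
#' @export
series_control <- function(max_outer_terms = 500L, abs_tol = 1e-12,
                           consecutive_small = 3L) {
  stopifnot(max_outer_terms >= 1, abs_tol > 0, consecutive_small >= 1)
  structure(list(max_outer_terms = as.integer(max_outer_terms),
                 abs_tol = abs_tol,
                 consecutive_small = as.integer(consecutive_small)),
            class = "series_control")
}

# Shared outer-loop driver: term_fun(i) returns the i-th outer term (i >= 0).
# Returns list(value, terms, converged, last_term).
sum_outer <- function(term_fun, ctrl) {
  total <- 0
  small_run <- 0L
  i <- 0L
  last <- NA_real_
  while (i < ctrl$max_outer_terms) {
    t_i <- term_fun(i)
    if (!is.finite(t_i))
      return(list(value = total, terms = i, converged = FALSE, last_term = t_i))
    total <- total + t_i
    last <- t_i
    small_run <- if (abs(t_i) < ctrl$abs_tol) small_run + 1L else 0L
    i <- i + 1L
    if (small_run >= ctrl$consecutive_small) {
      return(list(value = total, terms = i, converged = TRUE, last_term = last))
    }
  }
  list(value = total, terms = i, converged = FALSE, last_term = last)
}

#' Auxiliary integrals K and L of the exponentiated Lindley family
#'
#' `k_series()` evaluates
#' \deqn{K(a,b,c,\delta) = \int_0^\infty x^c (1+x)
#'   \left[1 - \frac{1+b+bx}{1+b} e^{-bx}\right]^{a-1} e^{-\delta x}\,dx}
#' by its series expansion in generalized binomial coefficients and gamma
#' functions; `l_series()` evaluates the lower-truncated analogue
#' \deqn{L(a,b,c,t) = \int_t^\infty x^c (1+x) \,[\,\cdot\,]^{a-1} e^{-bx}\,dx}
#' via upper incomplete gamma functions. These sums carry the raw moments,
#' mgf, residual-life moments, mean deviations and Lorenz curve of the ELG
#' distribution. `L(a,b,c,0) = K(a,b,c,b)`.
#'
#' For integer `a - 1` the outer sum terminates exactly after `a` terms. For
#' non-integer `a` the outer terms decay only polynomially
#' (roughly `i^{-a-c-1}`), so slow convergence is possible; in that case the
#' functions either raise an error (`on_fail = "error"`, with partial-sum
#' diagnostics) or return the partial sum with `converged = FALSE` in the
#' `"diagnostics"` attribute (`on_fail = "partial"`). Callers that need a
#' guaranteed value (the public moment functions) fall back to adaptive
#' quadrature of the defining integral.
#'
#' @param a positive real exponent parameter.
#' @param b positive real (the Lindley rate inside the bracket).
#' @param c nonnegative integer power of `x`.
#' @param delta positive real exponential tilt (`k_series` only).
#' @param t nonnegative lower limit (`l_series` only).
#' @param ctrl a [series_control()].
#' @param on_fail `"error"` (default) or `"partial"`.
#' @return the value of the integral, with a `"diagnostics"` attribute
#'   (list: `terms`, `converged`, `last_term`).
#' @examples
#' k_series(1, 2, 1, 2)        # closed form: 1/4 + 2/8 = 0.5
#' l_series(1, 1, 0, 1)        # closed form: 3 * exp(-1)
#' @export
k_series <- function(a, b, c, delta, ctrl = series_control(),
                     on_fail = c("error", "partial")) {
  on_fail <- match.arg(on_fail)
  stopifnot(a > 0, b > 0, delta > 0, c >= 0, c == round(c))
  lb_ratio <- base::log(b) - log1p(b)   # log(b/(1+b))
  term_fun <- function(i) {
    w <- choose(a - 1, i) * (-1)^i      # sign-carrying outer weight
    if (w == 0) return(0)
    s <- b * i + delta
    m <- 0:i
    lt <- lchoose(i, m) + m * lb_ratio + lgamma(c + m + 1) -
      (c + m + 1) * base::log(s) + log1p((c + m + 1) / s)
    w * sum(exp(lt))
  }
  res <- sum_outer(term_fun, ctrl)
  finish_series(res, "K", on_fail)
}

#' @rdname k_series
#' @export
l_series <- function(a, b, c, t, ctrl = series_control(),
                     on_fail = c("error", "partial")) {
  on_fail <- match.arg(on_fail)
  stopifnot(a > 0, b > 0, t >= 0, c >= 0, c == round(c))
  lb_ratio <- base::log(b) - log1p(b)
  # log of upper incomplete gamma Gamma(shape, s*t)
  lgamma_upper <- function(shape, x) {
    lgamma(shape) + stats::pgamma(x, shape, lower.tail = FALSE, log.p = TRUE)
  }
  term_fun <- function(i) {
    w <- choose(a - 1, i) * (-1)^i
    if (w == 0) return(0)
    s <- b * (i + 1)
    m <- 0:i
    l1 <- lchoose(i, m) + m * lb_ratio +
      lgamma_upper(c + m + 1, s * t) - (c + m + 1) * base::log(s)
    l2 <- lchoose(i, m) + m * lb_ratio +
      lgamma_upper(c + m + 2, s * t) - (c + m + 2) * base::log(s)
    w * (sum(exp(l1)) + sum(exp(l2)))
  }
  res <- sum_outer(term_fun, ctrl)
  finish_series(res, "L", on_fail)
}

finish_series <- function(res, label, on_fail) {
  if (!res$converged && on_fail == "error") {
    stop(sprintf(
      "%s-series did not converge: %d terms summed, partial sum %.10g, last term %.3g",
      label, res$terms, res$value, res$last_term), call. = FALSE)
  }
  structure(res$value,
            diagnostics = list(terms = res$terms, converged = res$converged,
                               last_term = res$last_term))
}

series_converged <- function(x) isTRUE(attr(x, "diagnostics")$converged)
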
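#' Raw moments of the ELG distribution
#'
#' Computes `E(X^n)` for an ELG random variable. Two evaluation routes are
#' available. The series route expands the compounding denominator into a
#' signed mixture of exponentiated Lindley laws, whose moments are carried by
#' the auxiliary sum [k_series()]:
#' \deqn{E(X^n) = \frac{\alpha\theta^2}{(1+\theta)(1-p)} \sum_{k\ge 0}
#'   (k+1)\left(\frac{-p}{1-p}\right)^{k} K(\alpha(k+1), \theta, n, \theta),}
#' valid when `|p/(1-p)| < 1` (all `p < 1/2`); for `p` in `[1/2, 1)` the
#' alternative expansion in powers of `p(1 - G^alpha)` is used. The
#' quadrature route integrates `x^n f(x)` adaptively and is the fallback
#' whenever the series is divergent or slowly convergent (large `|p|`, large
#' required exponents `alpha (k+1)`, non-integer `alpha` tails); the method
#' actually used is recorded in the `"method"` attribute.
#'
#' @param n positive integer moment order.
#' @param alpha,theta,p ELG parameters (see [elg_params()]), or pass an
#'   `elg_params` object as `alpha`.
#' @param ctrl a [series_control()].
#' @param method `"auto"` (default), `"series"` or `"quadrature"`.
#' @return the moment, with attribute `"method"` one of `"series"`,
#'   `"quadrature"`.
#' @examples
#' elg_moment(1, 1, 2, 0)        # Lindley(2) mean: 4/6
#' elg_moment(2, 2, 1, 0.3)
#' @export
elg_moment <- function(n, alpha, theta, p, ctrl = series_control(),
                       method = c("auto", "series", "quadrature")) {
  pr <- resolve_params(alpha, theta, p)
  method <- match.arg(method)
  stopifnot(n >= 1, n == round(n))
  if (method != "quadrature") {
    val <- try(elg_moment_series(n, pr, ctrl), silent = TRUE)
    if (!inherits(val, "try-error")) {
      return(structure(as.numeric(val), method = "series"))
    }
    if (method == "series") stop(attr(val, "condition")$message, call. = FALSE)
  }
  q <- stats::integrate(function(x) x^n * delg(x, pr[1], pr[2], pr[3]),
                        0, Inf, rel.tol = 1e-10)$value
  structure(q, method = "quadrature")
}

# allow elg_moment(1, elg_params(...)) or elg_moment(1, a, t, p)
resolve_params <- function(alpha, theta, p) {
  if (inherits(alpha, "elg_params") || (length(alpha) == 3L && missing(theta)))
    return(as.numeric(as_elg_params(alpha)))
  as.numeric(elg_params(alpha, theta, p))
}

# Series evaluation; errors if outside the trusted regime or non-convergent.
elg_moment_series <- function(n, pr, ctrl, c_pow = n, delta = pr[2]) {
  alpha <- pr[1]; theta <- pr[2]; p <- pr[3]
  const <- alpha * theta^2 / (1 + theta)
  a_max <- 60                      # beyond this K() cancellation loses digits
  if (abs(p / (1 - p)) <= 0.9) {
    r <- p / (p - 1)               # signed ratio, |r| <= 0.9
    term_fun <- function(k) {
      a_k <- alpha * (k + 1)
      if (a_k > a_max) stop("series needs exponent beyond trusted range", call. = FALSE)
      (k + 1) * r^k * as.numeric(k_series(a_k, theta, c_pow, delta, ctrl))
    }
    res <- sum_outer(term_fun, ctrl)
    if (!res$converged) stop("moment series did not converge", call. = FALSE)
    return(const / (1 - p) * res$value)
  }
  if (p > 0 && p <= 0.6) {
    # expansion in powers of p(1 - G^alpha); inner alternating binomial sum
    Kcache <- new.env(parent = emptyenv())
    Kval <- function(j) {
      key <- as.character(j)
      if (is.null(Kcache[[key]])) {
        a_j <- alpha * (j + 1)
        if (a_j > a_max) stop("series needs exponent beyond trusted range", call. = FALSE)
        Kcache[[key]] <- as.numeric(k_series(a_j, theta, c_pow, delta, ctrl))
      }
      Kcache[[key]]
    }
    term_fun <- function(k) {
      j <- 0:k
      p^k * sum(choose(k, j) * (-1)^j * (j + 1) * vapply(j, Kval, numeric(1)))
    }
    res <- sum_outer(term_fun, ctrl)
    if (!res$converged) stop("moment series did not converge", call. = FALSE)
    return(const * res$value)
  }
  stop("series expansion untrusted for |p| this close to 1", call. = FALSE)
}

#' Moment generating function of the ELG distribution
#'
#' `M(t) = E(exp(tX))`, finite for `t < theta`. Series route as in
#' [elg_moment()] with the exponential tilt `delta = theta - t`; quadrature
#' fallback otherwise.
#'
#' @inheritParams elg_moment
#' @param t evaluation point, `t < theta`.
#' @return `M(t)` with a `"method"` attribute.
#' @export
elg_mgf <- function(t, alpha, theta, p, ctrl = series_control(),
                    method = c("auto", "series", "quadrature")) {
  pr <- resolve_params(alpha, theta, p)
  method <- match.arg(method)
  if (!is.finite(t) || t >= pr[2]) stop("mgf requires t < theta", call. = FALSE)
  if (method != "quadrature") {
    val <- try(elg_moment_series(0, pr, ctrl, c_pow = 0, delta = pr[2] - t),
               silent = TRUE)
    if (!inherits(val, "try-error"))
      return(structure(as.numeric(val), method = "series"))
    if (method == "series") stop(attr(val, "condition")$message, call. = FALSE)
  }
  q <- stats::integrate(function(x)
    exp(t * x + delg(x, pr[1], pr[2], pr[3], log = TRUE)),
    0, Inf, rel.tol = 1e-10)$value
  structure(q, method = "quadrature")
}

#' Skewness and kurtosis of the ELG distribution
#'
#' Moment-based shape measures computed from the first four raw moments:
#' skewness `gamma = (mu3 - 3 mu2 mu1 + 2 mu1^3) / (mu2 - mu1^2)^(3/2)` and
#' (non-excess) kurtosis
#' `kappa = (mu4 - 4 mu1 mu3 + 6 mu1^2 mu2 - 3 mu1^4) / (mu2 - mu1^2)^2`.
#'
#' @inheritParams elg_moment
#' @return named vector `c(skewness =, kurtosis =)`.
#' @export
elg_shape_measures <- function(alpha, theta, p, ctrl = series_control()) {
  pr <- resolve_params(alpha, theta, p)
  mu <- vapply(1:4, function(k)
    as.numeric(elg_moment(k, pr[1], pr[2], pr[3], ctrl)), numeric(1))
  v <- mu[2] - mu[1]^2
  g <- (mu[3] - 3 * mu[2] * mu[1] + 2 * mu[1]^3) / v^1.5
  k <- (mu[4] - 4 * mu[1] * mu[3] + 6 * mu[1]^2 * mu[2] - 3 * mu[1]^4) / v^2
  c(skewness = g, kurtosis = k)
}

# Partial upper moment I_q(t) = int_t^Inf x^q f(x) dx, series or quadrature.
elg_upper_partial <- function(q_pow, t, pr, ctrl = series_control()) {
  alpha <- pr[1]; theta <- pr[2]; p <- pr[3]
  if (abs(p / (1 - p)) <= 0.9) {
    val <- try({
      r <- p / (p - 1)
      a_max <- 60
      term_fun <- function(l) {
        a_l <- alpha * (l + 1)
        if (a_l > a_max) stop("exponent beyond trusted range", call. = FALSE)
        (l + 1) * r^l * as.numeric(l_series(a_l, theta, q_pow, t, ctrl))
      }
      res <- sum_outer(term_fun, ctrl)
      if (!res$converged) stop("partial-moment series did not converge", call. = FALSE)
      alpha * theta^2 / ((1 + theta) * (1 - p)) * res$value
    }, silent = TRUE)
    if (!inherits(val, "try-error")) return(structure(val, method = "series"))
  }
  q <- stats::integrate(function(x) x^q_pow * delg(x, alpha, theta, p),
                        t, Inf, rel.tol = 1e-10)$value
  structure(q, method = "quadrature")
}

#' Residual-life moments of the ELG distribution
#'
#' `m_r(t) = E[(X - t)^r | X > t]`, the r-th moment of the remaining
#' lifetime of a unit that has survived to `t`. Expanded binomially into
#' partial upper moments carried by [l_series()] (quadrature fallback).
#' `m_1` is the mean residual life; `m_r(0)` equals the r-th raw moment.
#'
#' @param r positive integer moment order.
#' @param t nonnegative age.
#' @inheritParams elg_moment
#' @return the residual-life moment.
#' @export
elg_residual_moment <- function(r, t, alpha, theta, p, ctrl = series_control()) {
  pr <- resolve_params(alpha, theta, p)
  stopifnot(r >= 1, r == round(r), t >= 0)
  S <- pelg(t, pr[1], pr[2], pr[3], lower.tail = FALSE)
  if (S <= 0) stop("survival at t is numerically zero", call. = FALSE)
  k <- 0:r
  parts <- vapply(k, function(kk)
    as.numeric(elg_upper_partial(r - kk, t, pr, ctrl)), numeric(1))
  sum(choose(r, k) * (-t)^k * parts) / S
}

#' Mean deviations about the mean and the median
#'
#' `delta1 = E|X - mu|` and `delta2 = E|X - M|` with `mu = E(X)` and `M` the
#' median `qelg(0.5)`. Uses the identities
#' `delta1 = 2 mu F(mu) - 2 mu + 2 I1(mu)` and `delta2 = -mu + 2 I1(M)`,
#' where `I1(t)` is the partial upper mean.
#'
#' @inheritParams elg_moment
#' @return named vector `c(delta1 =, delta2 =)`.
#' @export
elg_mean_deviations <- function(alpha, theta, p, ctrl = series_control()) {
  pr <- resolve_params(alpha, theta, p)
  mu <- as.numeric(elg_moment(1, pr[1], pr[2], pr[3], ctrl))
  M <- qelg(0.5, pr[1], pr[2], pr[3])
  I1mu <- as.numeric(elg_upper_partial(1, mu, pr, ctrl))
  I1M <- as.numeric(elg_upper_partial(1, M, pr, ctrl))
  c(delta1 = 2 * mu * pelg(mu, pr[1], pr[2], pr[3]) - 2 * mu + 2 * I1mu,
    delta2 = -mu + 2 * I1M)
}

#' Bonferroni and Lorenz curves of the ELG distribution
#'
#' For a probability level `u`, with `q = qelg(u)`:
#' Lorenz `L(u) = (1/mu) * int_0^q x f(x) dx` and Bonferroni
#' `B(u) = L(u) / u`. Always `0 <= L(u) <= u` and `L(1-) = 1`.
#'
#' @param u probability level in (0, 1).
#' @inheritParams elg_moment
#' @return named vector `c(B =, L =)`.
#' @export
elg_bonferroni_lorenz <- function(u, alpha, theta, p, ctrl = series_control()) {
  pr <- resolve_params(alpha, theta, p)
  stopifnot(u > 0, u < 1)
  mu <- as.numeric(elg_moment(1, pr[1], pr[2], pr[3], ctrl))
  q <- qelg(u, pr[1], pr[2], pr[3])
  L <- (mu - as.numeric(elg_upper_partial(1, q, pr, ctrl))) / mu
  c(B = L / u, L = L)
}

#' Order statistics of an ELG random sample
#'
#' Density and distribution function of the r-th order statistic of an iid
#' sample of size `n`, evaluated directly from the parent cdf/pdf:
#' `f_(r)(y) = n!/((r-1)!(n-r)!) F^(r-1) (1-F)^(n-r) f` and
#' `F_(r)(y) = P(at least r of n below y)` (binomial upper tail).
#'
#' @param y evaluation points.
#' @param r rank, `1 <= r <= n`.
#' @param n sample size.
#' @inheritParams elg_moment
#' @return numeric vector.
#' @export
delg_order <- function(y, r, n, alpha, theta, p) {
  pr <- resolve_params(alpha, theta, p)
  stopifnot(r >= 1, r <= n, r == round(r), n == round(n))
  lF <- pelg(y, pr[1], pr[2], pr[3], log.p = TRUE)
  lS <- pelg(y, pr[1], pr[2], pr[3], lower.tail = FALSE, log.p = TRUE)
  lf <- delg(y, pr[1], pr[2], pr[3], log = TRUE)
  out <- exp(lgamma(n + 1) - lgamma(r) - lgamma(n - r + 1) +
               (r - 1) * lF + (n - r) * lS + lf)
  out[y <= 0] <- 0
  out
}

#' @rdname delg_order
#' @export
pelg_order <- function(y, r, n, alpha, theta, p) {
  pr <- resolve_params(alpha, theta, p)
  stopifnot(r >= 1, r <= n, r == round(r), n == round(n))
  F <- pelg(y, pr[1], pr[2], pr[3])
  stats::pbinom(r - 1, n, F, lower.tail = FALSE)
}

#' Entropies of the ELG distribution
#'
#' `elg_shannon_entropy()` evaluates `H(X) = E[-log f(X)]` by adaptive
#' quadrature of `-f log f` (a one-dimensional integral). The Rényi entropy
#' `I_R(gamma) = log(int f^gamma) / (1 - gamma)` is likewise evaluated by
#' quadrature of `f^gamma` (primary path); the double-series expansion of
#' the same integral is available as an internal cross-check. As
#' `gamma -> 1`, `I_R -> H`.
#'
#' @param gamma_ord positive Rényi order, not equal to 1.
#' @inheritParams elg_moment
#' @return entropy in nats.
#' @export
elg_shannon_entropy <- function(alpha, theta, p) {
  pr <- resolve_params(alpha, theta, p)
  f <- function(x) {
    lf <- delg(x, pr[1], pr[2], pr[3], log = TRUE)
    out <- -exp(lf) * lf
    out[!is.finite(out)] <- 0
    out
  }
  stats::integrate(f, 0, Inf, rel.tol = 1e-9)$value
}

#' @rdname elg_shannon_entropy
#' @export
elg_renyi_entropy <- function(gamma_ord, alpha, theta, p) {
  pr <- resolve_params(alpha, theta, p)
  stopifnot(gamma_ord > 0, gamma_ord != 1)
  int <- stats::integrate(function(x)
    exp(gamma_ord * delg(x, pr[1], pr[2], pr[3], log = TRUE)),
    0, Inf, rel.tol = 1e-9)$value
  base::log(int) / (1 - gamma_ord)
}

# Series cross-check of int f^gamma (double sum over the compounding and
# bracket expansions; each (k, j) cell is a 1-D quadrature). Internal.
elg_renyi_integral_series <- function(gamma_ord, pr, kmax = 60L, jtol = 1e-10) {
  alpha <- pr[1]; theta <- pr[2]; p <- pr[3]
  const <- (alpha * theta^2 * (1 - p) / (1 + theta))^gamma_ord
  total <- 0
  for (k in 0:kmax) {
    wk <- choose(-2 * gamma_ord, k) * (-p)^k
    if (abs(wk) < jtol && k > 2) break
    inner <- 0
    for (j in 0:k) {
      expo <- alpha * gamma_ord - gamma_ord + alpha * j
      Jkj <- stats::integrate(function(x)
        (1 + x)^gamma_ord * exp(-theta * gamma_ord * x +
                                  expo * lindley_logcdf(x, theta)),
        0, Inf, rel.tol = 1e-10)$value
      inner <- inner + choose(k, j) * (-1)^j * Jkj
    }
    total <- total + wk * inner
  }
  const * total
}
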
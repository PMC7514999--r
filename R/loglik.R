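#' Log-likelihood, score and observed information of the ELG model
#'
#' `elg_loglik()` evaluates the ELG log-likelihood
#' \deqn{l = n\log\alpha + 2n\log\theta - n\log(\theta+1) + n\log(1-p)
#'   + \sum \log(1+x_i) - \theta \sum x_i
#'   + (\alpha-1)\sum\log\tau_i - 2\sum\log(1-p+p\tau_i^\alpha),}
#' with \eqn{\tau_i = G(x_i;\theta)} the Lindley cdf at the observations,
#' as the sum of the stable log-density ([delg()]).
#' Invalid parameter values return `-Inf` (a documented sentinel, so
#' optimizers can probe freely) rather than raising an error.
#'
#' `elg_score()` returns the analytic gradient in `(alpha, theta, p)`;
#' `elg_observed_info()` the observed Fisher information (negated Hessian),
#' computed as the symmetrized central-difference Jacobian of the analytic
#' score. The printed closed forms for two mixed partials in the source
#' derivation are inconsistent with finite differences of the
#' log-likelihood, so the numerically-validated score is treated as the
#' authority for second derivatives.
#'
#' @param x positive observation times.
#' @param alpha,theta,p ELG parameters (or an `elg_params` object as
#'   `alpha`).
#' @return `elg_loglik()`: scalar; `elg_score()`: length-3 vector
#'   (alpha, theta, p); `elg_observed_info()`: symmetric 3x3 matrix.
#' @examples
#' x <- elg_dataset("bladder_cancer_128")
#' elg_loglik(x, 1.0792, 0.0699, 0.9204)  # about -409.31
#' @export
elg_loglik <- function(x, alpha, theta, p) {
  pr <- try(resolve_params(alpha, theta, p), silent = TRUE)
  if (inherits(pr, "try-error")) return(-Inf)
  if (any(!is.finite(x) | x <= 0)) stop("observations must be positive", call. = FALSE)
  ll <- sum(delg(x, pr[1], pr[2], pr[3], log = TRUE))
  if (!is.finite(ll)) -Inf else ll
}

#' @rdname elg_loglik
#' @export
elg_score <- function(x, alpha, theta, p) {
  pr <- resolve_params(alpha, theta, p)
  alpha <- pr[1]; theta <- pr[2]; p <- pr[3]
  if (any(!is.finite(x) | x <= 0)) stop("observations must be positive", call. = FALSE)
  n <- length(x)
  logtau <- lindley_logcdf(x, theta)
  tau <- exp(logtau)
  ta <- exp(alpha * logtau)
  D <- 1 + p * expm1(alpha * logtau)          # 1 - p + p tau^alpha
  # d tau / d theta = theta x (2 + theta + theta x + x) e^{-theta x} / (theta+1)^2
  dtau <- theta * x * (2 + theta + theta * x + x) * exp(-theta * x) / (theta + 1)^2
  d_alpha <- n / alpha + sum(logtau) - 2 * p * sum(ta * logtau / D)
  d_theta <- 2 * n / theta - n / (theta + 1) - sum(x) +
    (alpha - 1) * sum(dtau / tau) -
    2 * alpha * p * sum(ta / tau * dtau / D)
  d_p <- -n / (1 - p) + 2 * sum((1 - ta) / D)
  c(alpha = d_alpha, theta = d_theta, p = d_p)
}

#' @rdname elg_loglik
#' @export
elg_observed_info <- function(x, alpha, theta, p) {
  pr <- resolve_params(alpha, theta, p)
  H <- matrix(0, 3, 3)
  for (j in 1:3) {
    h <- max(abs(pr[j]), 1e-2) * 1e-6
    up <- dn <- pr
    up[j] <- up[j] + h; dn[j] <- dn[j] - h
    H[, j] <- (elg_score(x, up[1], up[2], up[3]) -
                 elg_score(x, dn[1], dn[2], dn[3])) / (2 * h)
  }
  H <- (H + t(H)) / 2
  I <- -H
  dimnames(I) <- list(c("alpha", "theta", "p"), c("alpha", "theta", "p"))
  I
}
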
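# Independent numerical oracles used across test files.

# adaptive quadrature of x^n * f(x) over the positive half-line
moment_quad <- function(n, alpha, theta, p, lower = 0, upper = Inf) {
  stats::integrate(function(x) x^n * delg(x, alpha, theta, p),
                   lower, upper, rel.tol = 1e-10)$value
}

# central finite differences of the log-likelihood
loglik_fd_grad <- function(x, pr, h = 1e-6) {
  vapply(1:3, function(j) {
    hp <- max(abs(pr[j]), 1e-2) * h
    up <- dn <- pr
    up[j] <- up[j] + hp
    dn[j] <- dn[j] - hp
    (elg_loglik(x, up[1], up[2], up[3]) - elg_loglik(x, dn[1], dn[2], dn[3])) /
      (2 * hp)
  }, numeric(1))
}

loglik_fd_hessian <- function(x, pr, h = 1e-4) {
  H <- matrix(0, 3, 3)
  for (j in 1:3) {
    hp <- max(abs(pr[j]), 1e-2) * h
    up <- dn <- pr
    up[j] <- up[j] + hp
    dn[j] <- dn[j] - hp
    H[, j] <- (loglik_fd_grad(x, up) - loglik_fd_grad(x, dn)) / (2 * hp)
  }
  (H + t(H)) / 2
}

# naive direct evaluation of the ELG log-density (textbook formula, no
# log-space identities) -- deliberately independent of delg()
naive_elg_logpdf <- function(x, alpha, theta, p) {
  G <- 1 - (theta + 1 + theta * x) / (theta + 1) * exp(-theta * x)
  log(alpha * theta^2 * (1 - p) * (1 + x) * exp(-theta * x) * G^(alpha - 1) /
        ((theta + 1) * (1 - p + p * G^alpha)^2))
}

# bisection solve of w * exp(w) = z on the W_{-1} branch
bisect_wm1 <- function(z, lo = -700, hi = -1) {
  f <- function(w) w * exp(w) - z
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) * f(hi) <= 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# total probability mass, split at the median to tame the alpha < 1 spike
pdf_total <- function(alpha, theta, p) {
  m <- qelg(0.5, alpha, theta, p)
  stats::integrate(function(x) delg(x, alpha, theta, p), 0, m,
                   rel.tol = 1e-9)$value +
    stats::integrate(function(x) delg(x, alpha, theta, p), m, Inf,
                     rel.tol = 1e-9)$value
}

# parameter grid used by the core invariants (as stated for the family)
core_param_grid <- expand.grid(alpha = c(0.3, 1, 3), theta = c(0.3, 1, 3),
                               p = c(-1, -0.2, 0, 0.5, 0.95))
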
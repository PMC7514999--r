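# Likelihood, score, information, direct MLE, EM, Wald, LR, censoring.

data1 <- elg_dataset("bladder_cancer_128")
data2 <- elg_dataset("bank_waiting_100")

test_that("log-likelihood: frozen values and naive-formula oracle", {
  # maximized value implied by the published AIC (2k - 2l with k = 3)
  expect_equal(elg_loglik(data1, 1.0792, 0.0699, 0.9204),
               (6 - 824.6214) / 2, tolerance = 1e-4)
  # single Lindley point: log[ theta^2 (1+x) e^{-theta x} / (theta+1) ] at 1
  expect_equal(elg_loglik(1, 1, 1, 0), -1, tolerance = 1e-12)
  set.seed(5)
  for (i in 1:5) {
    pars <- c(stats::runif(1, 0.3, 3), stats::runif(1, 0.1, 2),
              stats::runif(1, -1, 0.95))
    x <- stats::rexp(20, 0.5) + 0.01
    expect_equal(elg_loglik(x, pars[1], pars[2], pars[3]),
                 sum(naive_elg_logpdf(x, pars[1], pars[2], pars[3])),
                 tolerance = 1e-9)
  }
  # invalid parameters: -Inf sentinel, not an error
  expect_identical(elg_loglik(data1, -1, 1, 0.5), -Inf)
  expect_identical(elg_loglik(data1, 1, 1, 1.2), -Inf)
})

test_that("score matches finite differences and the p = 0 closed form", {
  pr <- c(2, 1, 0.5)
  expect_equal(unname(elg_score(data2, pr[1], pr[2], pr[3])),
               loglik_fd_grad(data2, pr), tolerance = 1e-5)
  pr2 <- c(0.6, 0.2, -0.8)
  expect_equal(unname(elg_score(data1, pr2[1], pr2[2], pr2[3])),
               loglik_fd_grad(data1, pr2), tolerance = 1e-5)
  # p-component at p = 0 equals -n + 2 sum(1 - tau^alpha)
  a <- 1.3; th <- 0.4
  tau <- plindley(data2, th)
  expect_equal(elg_score(data2, a, th, 0)[["p"]],
               -length(data2) + 2 * sum(1 - tau^a), tolerance = 1e-10)
  # near-zero score at the MLE
  fit <- elg_fit(data1)
  expect_lt(max(abs(elg_score(data1, fit$par[1], fit$par[2], fit$par[3]))),
            1e-3)
})

test_that("observed information: symmetry, FD Hessian, cross-entry formula", {
  fit <- elg_fit(data1)
  I <- elg_observed_info(data1, fit$par[1], fit$par[2], fit$par[3])
  expect_identical(I, t(I))
  Ifd <- -loglik_fd_hessian(data1, unname(fit$par))
  expect_equal(unname(I), Ifd, tolerance = 1e-3)
  # hand-derived mixed partial at (alpha = 1, p = 0) on three points:
  # d2l/dp dalpha = -2 sum tau^a log tau (denominator 1 at p = 0)
  x3 <- c(0.5, 2, 7)
  I3 <- elg_observed_info(x3, 1, 1, 0)
  tau <- plindley(x3, 1)
  expect_equal(I3["alpha", "p"], -(-2 * sum(tau * log(tau))), tolerance = 1e-5)
})

test_that("direct MLE reproduces both case studies", {
  fit1 <- elg_fit(data1)
  expect_true(fit1$converged)
  expect_equal(unname(fit1$par), c(1.0792, 0.0699, 0.9204), tolerance = 3e-3)
  fit2 <- elg_fit(data2)
  expect_equal(unname(fit2$par), c(1.4602, 0.1725, 0.5385), tolerance = 4e-3)
  # loglik at optimum beats every multi-start seed by construction
  expect_gte(fit1$loglik, elg_loglik(data1, 1, 2 / mean(data1), 0.5))
})

test_that("parameter recovery within 3 Wald SE at n = 5000", {
  x <- elg_simulate(5000, 2, 1, 0.5, seed = 7)
  fit <- elg_fit(x)
  for (nm in c("alpha", "theta", "p")) {
    truth <- c(alpha = 2, theta = 1, p = 0.5)[[nm]]
    expect_lt(abs(fit$par[[nm]] - truth), 3 * fit$se[[nm]],
              label = paste("recovery of", nm))
  }
})

test_that("EM: case-study agreement, ascent, p = 0 fixed point, domain guard", {
  em1 <- elg_fit_em(data1)
  expect_equal(unname(em1$par), c(1.0792, 0.0699, 0.9204), tolerance = 3e-3)
  direct1 <- elg_fit(data1)
  expect_equal(unname(em1$par), unname(direct1$par), tolerance = 1e-3)
  # monotone observed-data log-likelihood from the stated start
  em2 <- elg_fit_em(data2, init = c(alpha = 1, theta = 0.1, p = 0.3))
  expect_true(all(diff(em2$loglik_trace) > -1e-8))
  expect_equal(unname(em2$par), unname(elg_fit(data2)$par), tolerance = 1e-3)
  # z_i = 1 at p = 0, so one EM sweep keeps p at 0 (submodel fixed point)
  x <- elg_simulate(200, 1, 1, 0, seed = 2)
  em0 <- elg_fit_em(x, init = c(alpha = 1, theta = 1, p = 0),
                    control = list(max_iter = 1L))
  expect_equal(em0$par[["p"]], 0, tolerance = 1e-12)
  expect_error(elg_fit_em(data1, init = c(alpha = 1, theta = 1, p = -0.5)),
               "p in \\[0, 1\\)")
})

test_that("EM and direct MLE agree on simulated data", {
  set.seed(31)
  for (i in 1:5) {
    x <- relg(300, 2, 1, 0.5)
    fd <- elg_fit(x, init = c(alpha = 2, theta = 1, p = 0.5))
    fe <- elg_fit_em(x, init = c(alpha = 2, theta = 1, p = 0.5))
    if (fd$par[["p"]] > 0.02) {
      # interior optimum: the two maximizers must coincide
      expect_equal(unname(fd$par), unname(fe$par), tolerance = 1e-3)
    } else {
      # unrestricted MLE outside the EM domain p in (0,1): EM must stop at
      # the p = 0 boundary (documented restriction of the latent-geometric
      # construction)
      expect_lt(fe$par[["p"]], 0.02)
    }
  }
})

test_that("Wald intervals: multiplier, shrinkage, degenerate SE", {
  fit <- elg_fit(data1)
  ci <- confint(fit, level = 0.95)
  z <- stats::qnorm(0.975)
  expect_equal(z, 1.959964, tolerance = 1e-6)
  expect_equal(unname(ci[, 2] - ci[, 1]), unname(2 * z * fit$se),
               tolerance = 1e-10)
  # width shrinks roughly as 1/sqrt(n) on nested samples
  x_big <- elg_simulate(4000, 2, 1, 0.5, seed = 9)
  w <- function(x) {
    f <- elg_fit(x, init = c(alpha = 2, theta = 1, p = 0.5))
    diff(confint(f)["theta", ])
  }
  w1 <- w(x_big[1:500]); w2 <- w(x_big)
  expect_lt(w2, w1)
  expect_equal(unname(w1 / w2), sqrt(8), tolerance = 0.5)
  # zero SE gives a zero-width interval
  fit0 <- fit
  fit0$se[] <- 0
  ci0 <- confint(fit0)
  expect_equal(ci0[, 1], ci0[, 2])
})

test_that("LR test: published statistic, null-equals-full, nested fits", {
  lr <- elg_lr_test(data1, null = "lg")
  expect_equal(lr$omega, 0.5645, tolerance = 0.02)
  expect_equal(lr$p_value, 0.4525, tolerance = 0.01)
  expect_identical(lr$df, 1L)
  # restriction fixing all parameters at the unrestricted MLE: omega ~ 0
  fit <- elg_fit(data1)
  lr0 <- elg_lr_test(data1, null = as.list(fit$par))
  expect_lt(lr0$omega, 1e-4)
  expect_gt(lr0$p_value, 0.999)
  # Lindley submodel has 2 restricted df
  lr2 <- elg_lr_test(data2, null = "lindley")
  expect_identical(lr2$df, 2L)
  expect_gte(lr2$omega, 0)
})

test_that("LR type-I error near nominal under the LG null", {
  set.seed(17)
  reps <- 200L
  rej <- 0L
  for (i in seq_len(reps)) {
    x <- relg(150, 1, 0.5, 0.4)
    f1 <- elg_fit(x, init = c(alpha = 1, theta = 0.5, p = 0.4))
    f0 <- elg_fit(x, fixed = list(alpha = 1),
                  init = c(alpha = 1, theta = 0.5, p = 0.4))
    omega <- max(2 * (f1$loglik - f0$loglik), 0)
    if (stats::pchisq(omega, 1, lower.tail = FALSE) < 0.05) rej <- rej + 1L
  }
  # binomial 3.5-sigma band around 5% with 200 replicates
  expect_gt(rej / reps, 0.05 - 3.5 * sqrt(0.05 * 0.95 / reps))
  expect_lt(rej / reps, 0.05 + 3.5 * sqrt(0.05 * 0.95 / reps))
})

test_that("censored likelihood: reductions and interval consistency", {
  cs <- elg_censored_sample(data2)
  expect_equal(elg_censored_loglik(cs, 1.5, 0.17, 0.5),
               elg_loglik(data2, 1.5, 0.17, 0.5), tolerance = 1e-12)
  # one interval record evaluated two ways
  iv <- elg_censored_sample(time = 1, status = 1L,
                            intervals = cbind(0.5, 2))
  ll <- elg_censored_loglik(iv, 2, 1, 0.5)
  dF_quad <- stats::integrate(function(x) delg(x, 2, 1, 0.5), 0.5, 2,
                              rel.tol = 1e-10)$value
  expect_equal(ll, delg(1, 2, 1, 0.5, log = TRUE) + log(dF_quad),
               tolerance = 1e-8)
  # right-censored term equals log survival
  rc <- elg_censored_sample(time = c(1, 2), status = c(1L, 0L))
  expect_equal(elg_censored_loglik(rc, 2, 1, 0.5),
               delg(1, 2, 1, 0.5, log = TRUE) +
                 pelg(2, 2, 1, 0.5, lower.tail = FALSE, log.p = TRUE),
               tolerance = 1e-12)
  expect_error(elg_censored_sample(numeric(0)), "empty")
  expect_error(elg_censored_sample(time = 1, intervals = cbind(2, 1)),
               "left < right")
})

test_that("censored MLE recovers truth under heavy right censoring", {
  x <- elg_simulate(2000, 2, 1, 0.5, seed = 21)
  cutoff <- stats::quantile(as.numeric(x), 0.7)
  cs <- elg_censored_sample(time = pmin(as.numeric(x), cutoff),
                            status = as.integer(as.numeric(x) <= cutoff))
  fit <- elg_fit_censored(cs, init = c(alpha = 2, theta = 1, p = 0.5))
  # uncensored information at truth bounds the censored SE from below;
  # allow 3x the uncensored SE as the recovery band
  ref <- elg_fit(elg_simulate(2000, 2, 1, 0.5, seed = 22),
                 init = c(alpha = 2, theta = 1, p = 0.5))
  for (nm in c("alpha", "theta", "p")) {
    truth <- c(alpha = 2, theta = 1, p = 0.5)[[nm]]
    expect_lt(abs(fit$par[[nm]] - truth), 9 * ref$se[[nm]],
              label = paste("censored recovery of", nm))
  }
})

test_that("bias shrinks as n grows at fixed truth (2, 1, 0.5)", {
  sizes <- c(200, 1000, 5000)
  max_abs_bias <- numeric(3)
  set.seed(23)
  for (s in seq_along(sizes)) {
    est <- replicate(8, {
      x <- relg(sizes[s], 2, 1, 0.5)
      unname(elg_fit(x, init = c(alpha = 2, theta = 1, p = 0.5))$par)
    })
    max_abs_bias[s] <- max(abs(rowMeans(est) - c(2, 1, 0.5)))
  }
  expect_lt(max_abs_bias[3], max_abs_bias[1])
  expect_lt(max_abs_bias[3], 0.08)
})
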
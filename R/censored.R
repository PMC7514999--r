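#' Multicensored samples
#'
#' Container for lifetime data under general multicensoring: `n0` exact
#' failure times, `n1` interval-bracketed failures `(s_{i-1}, s_i]`, and
#' `n2` right-censored survival times. Type-I and type-II censoring are
#' particular cases.
#'
#' Construct either from `(time, status)` records (`status` 1 = exact
#' failure, 0 = right-censored) plus an optional two-column `intervals`
#' matrix, or by passing the three components directly.
#'
#' @param time positive observation times.
#' @param status integer vector, same length as `time`: 1 exact, 0
#'   right-censored. Defaults to all exact.
#' @param intervals optional 2-column matrix/data.frame of interval records
#'   `(left, right)` with `0 <= left < right`.
#' @return object of class `"elg_censored_sample"`: list with components
#'   `exact`, `intervals` (2-column matrix), `rcens`.
#' @examples
#' elg_censored_sample(c(1, 2, 3), status = c(1, 1, 0))
#' @export
elg_censored_sample <- function(time = numeric(), status = NULL,
                                intervals = NULL) {
  if (is.null(status)) status <- rep(1L, length(time))
  stopifnot(length(status) == length(time), all(status %in% c(0L, 1L)))
  if (any(time <= 0 | !is.finite(time)))
    stop("all times must be positive and finite", call. = FALSE)
  if (is.null(intervals)) {
    intervals <- matrix(numeric(), ncol = 2)
  } else {
    intervals <- as.matrix(intervals)
    if (ncol(intervals) != 2) stop("intervals must have two columns", call. = FALSE)
    if (any(intervals[, 1] < 0) || any(intervals[, 1] >= intervals[, 2]))
      stop("intervals must satisfy 0 <= left < right", call. = FALSE)
  }
  out <- structure(list(exact = as.numeric(time[status == 1L]),
                        intervals = unname(intervals),
                        rcens = as.numeric(time[status == 0L])),
                   class = "elg_censored_sample")
  if (length(out$exact) + nrow(out$intervals) + length(out$rcens) < 1L)
    stop("empty censored sample", call. = FALSE)
  out
}

#' @export
print.elg_censored_sample <- function(x, ...) {
  cat(sprintf("Multicensored sample: %d exact, %d interval, %d right-censored\n",
              length(x$exact), nrow(x$intervals), length(x$rcens)))
  invisible(x)
}

#' Log-likelihood and MLE under multicensoring
#'
#' The multicensored ELG log-likelihood is the sum of
#' `log f(t_i)` over exact failures, `log [F(s_i) - F(s_{i-1})]` over
#' interval records and `log S(r_i)` over right-censored records. With no
#' censoring it coincides exactly with [elg_loglik()].
#'
#' `elg_fit_censored()` maximizes it with the same transformed-scale
#' multi-start quasi-Newton strategy as [elg_fit()]. Only point estimates
#' are produced: no information matrix is attempted for the censored model.
#'
#' @param data an [elg_censored_sample()].
#' @param alpha,theta,p ELG parameters (or an `elg_params` as `alpha`).
#' @return `elg_censored_loglik()`: scalar (`-Inf` for invalid parameters);
#'   `elg_fit_censored()`: an `"elg_fit"` object (without `vcov`/`se`).
#' @export
elg_censored_loglik <- function(data, alpha, theta, p) {
  stopifnot(inherits(data, "elg_censored_sample"))
  pr <- try(resolve_params(alpha, theta, p), silent = TRUE)
  if (inherits(pr, "try-error")) return(-Inf)
  ll <- 0
  if (length(data$exact))
    ll <- ll + sum(delg(data$exact, pr[1], pr[2], pr[3], log = TRUE))
  if (nrow(data$intervals)) {
    dF <- pelg(data$intervals[, 2], pr[1], pr[2], pr[3]) -
      pelg(data$intervals[, 1], pr[1], pr[2], pr[3])
    ll <- ll + sum(base::log(pmax(dF, 0)))
  }
  if (length(data$rcens))
    ll <- ll + sum(pelg(data$rcens, pr[1], pr[2], pr[3],
                        lower.tail = FALSE, log.p = TRUE))
  if (!is.finite(ll)) -Inf else ll
}

#' @rdname elg_censored_loglik
#' @param init,control as in [elg_fit()].
#' @export
elg_fit_censored <- function(data, init = NULL, control = list()) {
  stopifnot(inherits(data, "elg_censored_sample"))
  ctl <- utils::modifyList(list(maxit = 1000L, grad_tol = 1e-5), control)
  nll <- function(psi) -elg_censored_loglik(data, psi_to_par(psi)[1],
                                            psi_to_par(psi)[2],
                                            psi_to_par(psi)[3])
  all_t <- c(data$exact, data$rcens, as.vector(data$intervals))
  th0 <- 2 / mean(all_t)
  starts <- if (!is.null(init)) {
    list(unlist(init)[c("alpha", "theta", "p")])
  } else {
    grid <- expand.grid(alpha = c(0.5, 1, 2), p = c(-0.5, 0, 0.5, 0.9))
    lapply(seq_len(nrow(grid)), function(i)
      c(alpha = grid$alpha[i], theta = th0, p = grid$p[i]))
  }
  best <- NULL
  for (st in starts) {
    res <- try(stats::optim(par_to_psi(st), nll, method = "BFGS",
                            control = list(maxit = ctl$maxit, reltol = 1e-14)),
               silent = TRUE)
    if (inherits(res, "try-error") || !is.finite(res$value)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop("all optimizer starts failed", call. = FALSE)
  par <- psi_to_par(best$par)
  n <- length(data$exact) + nrow(data$intervals) + length(data$rcens)
  new_elg_fit(par = par, loglik = -best$value, vcov = NULL, se = NULL,
              n_iter = sum(best$counts, na.rm = TRUE),
              converged = best$convergence == 0, method = "direct-censored",
              fixed = NULL, free = c("alpha", "theta", "p"), n = n,
              data = data, boundary = par[["p"]] > 1 - 1e-6)
}
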
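#' Bundled case-study data sets
#'
#' Returns one of the two classical lifetime samples shipped with the
#' package as plain-text fixtures:
#'
#' * `"bladder_cancer_128"` — remission times (months) of 128 bladder-cancer
#'   patients (min 0.08, max 79.05), a standard benchmark for flexible
#'   lifetime distributions.
#' * `"bank_waiting_100"` — waiting times (minutes) before service of 100
#'   bank customers (min 0.8, max 38.5), classically used to argue for the
#'   Lindley model over the exponential.
#'
#' Each load is verified against frozen transcription checksums (count,
#' extremes, sum).
#'
#' @param id dataset identifier.
#' @return numeric vector of observation times with attribute `"id"`.
#' @examples
#' length(elg_dataset("bladder_cancer_128"))
#' @export
elg_dataset <- function(id = c("bladder_cancer_128", "bank_waiting_100")) {
  id <- match.arg(id)
  path <- system.file("extdata", paste0(id, ".txt"), package = "elgfit")
  if (path == "") {  # during development without installation
    path <- file.path("inst", "extdata", paste0(id, ".txt"))
  }
  x <- scan(path, what = numeric(), quiet = TRUE)
  chk <- list(
    bladder_cancer_128 = c(n = 128, min = 0.08, max = 79.05, sum = 1198.80),
    bank_waiting_100 = c(n = 100, min = 0.8, max = 38.5, sum = 987.70))[[id]]
  stopifnot(length(x) == chk[["n"]],
            isTRUE(all.equal(min(x), chk[["min"]])),
            isTRUE(all.equal(max(x), chk[["max"]])),
            isTRUE(all.equal(sum(x), chk[["sum"]], tolerance = 1e-10)))
  structure(x, id = id)
}

#' Simulate ELG samples, optionally censored
#'
#' Draws `n` iid ELG variates by exact inverse-transform sampling (see
#' [relg()]) and optionally applies right censoring: either administrative
#' censoring at a fixed time `censor_time`, or random censoring by an
#' independent exponential time with rate `censor_rate`. Truth metadata is
#' attached for parameter-recovery experiments.
#'
#' @param n sample size.
#' @param alpha,theta,p ELG parameters.
#' @param seed optional integer seed (full reproducibility).
#' @param censor_time optional fixed right-censoring time.
#' @param censor_rate optional exponential censoring rate.
#' @return if uncensored, a numeric vector; otherwise an
#'   [elg_censored_sample()] with exact and right-censored records. Either
#'   way the true parameters are stored in attribute `"truth"`.
#' @examples
#' x <- elg_simulate(100, 2, 1, 0.5, seed = 1)
#' cs <- elg_simulate(100, 2, 1, 0.5, seed = 1, censor_time = 2)
#' @export
elg_simulate <- function(n, alpha, theta, p, seed = NULL,
                         censor_time = NULL, censor_rate = NULL) {
  pr <- resolve_params(alpha, theta, p)
  if (!is.null(censor_time) && !is.null(censor_rate))
    stop("specify at most one censoring scheme", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  t <- qelg(stats::runif(n), pr[1], pr[2], pr[3])
  truth <- c(alpha = pr[1], theta = pr[2], p = pr[3])
  if (is.null(censor_time) && is.null(censor_rate))
    return(structure(t, truth = truth))
  cens <- if (!is.null(censor_time)) {
    if (censor_time <= 0) stop("censor_time must be positive", call. = FALSE)
    rep(censor_time, n)
  } else {
    if (censor_rate <= 0) stop("censor_rate must be positive", call. = FALSE)
    stats::rexp(n, censor_rate)
  }
  obs <- pmin(t, cens)
  status <- as.integer(t <= cens)
  out <- elg_censored_sample(time = obs, status = status)
  attr(out, "truth") <- truth
  out
}
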
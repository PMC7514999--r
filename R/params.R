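#' Parameter triple of the exponentiated Lindley-geometric distribution
#'
#' Constructs and validates the parameter vector of the ELG family:
#' `alpha` (exponent, the number of parallel components per system),
#' `theta` (Lindley rate of each component lifetime) and `p` (geometric
#' compounding parameter of the latent system count).
#'
#' The density remains a well-defined probability density for any `p < 1`,
#' including `p <= 0`, so the admissible domain is the open half-line
#' `p < 1` rather than the unit interval. `alpha = 1` reduces the family to
#' the Lindley-geometric (LG) distribution; `alpha = 1, p = 0` reduces it to
#' the one-parameter Lindley distribution.
#'
#' @param alpha positive shape exponent.
#' @param theta positive Lindley rate.
#' @param p compounding parameter, any real number strictly below 1.
#' @return A named numeric vector of class `"elg_params"`.
#' @examples
#' elg_params(1.0792, 0.0699, 0.9204)
#' elg_params(1, 0.5, -0.3)   # negative p is admissible
#' @export
elg_params <- function(alpha, theta, p) {
  check_elg_params(alpha, theta, p)
  structure(c(alpha = as.numeric(alpha), theta = as.numeric(theta),
              p = as.numeric(p)),
            class = "elg_params")
}

check_elg_params <- function(alpha, theta, p) {
  if (length(alpha) != 1L || length(theta) != 1L || length(p) != 1L)
    stop("alpha, theta and p must be scalars", call. = FALSE)
  if (!is.finite(alpha) || alpha <= 0)
    stop("alpha must be a positive real number", call. = FALSE)
  if (!is.finite(theta) || theta <= 0)
    stop("theta must be a positive real number", call. = FALSE)
  if (!is.finite(p) || p >= 1)
    stop("p must be a real number strictly below 1", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.elg_params <- function(x, ...) {
  cat(sprintf("ELG parameters: alpha = %.6g, theta = %.6g, p = %.6g\n",
              x[["alpha"]], x[["theta"]], x[["p"]]))
  invisible(x)
}

# Accept either an elg_params object or a plain length-3 vector/list.
as_elg_params <- function(params) {
  if (inherits(params, "elg_params")) return(params)
  if (is.list(params)) params <- unlist(params)
  if (length(params) != 3L)
    stop("params must contain exactly (alpha, theta, p)", call. = FALSE)
  nm <- names(params)
  if (!is.null(nm) && all(c("alpha", "theta", "p") %in% nm))
    params <- params[c("alpha", "theta", "p")]
  elg_params(params[[1L]], params[[2L]], params[[3L]])
}
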
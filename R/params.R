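#' Validated epidemic parameters
#'
#' Bundles the six rates of the bidirectional-immunization model together with
#' the population scale `N`. Susceptibles are infected per contact at rate
#' `beta`, reduced by vaccination to `beta * (1 - delta)`; infecteds recover at
#' rate `gamma`, raised by treatment to `gamma * (1 + lambda)`. Susceptibles
#' flow in at rate `b * N` per unit time and every compartment is subject to
#' the natural (not disease-induced) death rate `d`.
#'
#' @param b Birth rate per unit time (inflow of susceptibles as a fraction of
#'   `N` per unit time). Non-negative.
#' @param d Natural death rate per unit time. Non-negative.
#' @param beta Per-contact infection rate per unit time. Non-negative.
#' @param gamma Baseline recovery rate per unit time. Non-negative.
#' @param delta Vaccination-derived reduction of the infection rate, in
#'   \[0, 1\]. `delta = 1` shuts transmission off entirely.
#' @param lambda Treatment-derived enhancement of the recovery rate,
#'   non-negative and dimensionless.
#' @param N Population scale: 1 for density formulations, an integer >= 2 for
#'   count formulations (CTMC, network simulation).
#'
#' @return An object of class `"epi_params"`: a named list with the validated
#'   fields, values unchanged.
#' @examples
#' epi_params(b = 0.08, d = 0.05, beta = 0.175, gamma = 0.05,
#'            delta = 0.2, lambda = 0.3)
#' @export
epi_params <- function(b, d, beta, gamma, delta, lambda, N = 1) {
  chk_scalar <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
  }
  for (nm in c("b", "d", "beta", "gamma", "delta", "lambda", "N"))
    chk_scalar(get(nm), nm)
  if (b < 0) stop("'b' must be >= 0", call. = FALSE)
  if (d < 0) stop("'d' must be >= 0", call. = FALSE)
  if (beta < 0) stop("'beta' must be >= 0", call. = FALSE)
  if (gamma < 0) stop("'gamma' must be >= 0", call. = FALSE)
  if (delta < 0 || delta > 1) stop("'delta' must lie in [0, 1]", call. = FALSE)
  if (lambda < 0) stop("'lambda' must be >= 0", call. = FALSE)
  if (N <= 0) stop("'N' must be > 0", call. = FALSE)
  structure(
    list(b = b, d = d, beta = beta, gamma = gamma,
         delta = delta, lambda = lambda, N = N),
    class = "epi_params"
  )
}

#' @export
print.epi_params <- function(x, ...) {
  cat("Epidemic parameters (bidirectional immunization)\n")
  cat(sprintf("  birth b = %g, death d = %g, N = %g\n", x$b, x$d, x$N))
  cat(sprintf("  infection beta = %g (effective %g with delta = %g)\n",
              x$beta, x$beta * (1 - x$delta), x$delta))
  cat(sprintf("  recovery gamma = %g (effective %g with lambda = %g)\n",
              x$gamma, x$gamma * (1 + x$lambda), x$lambda))
  invisible(x)
}

as_epi_params <- function(x) {
  if (inherits(x, "epi_params")) return(x)
  if (is.list(x))
    return(do.call(epi_params, x[c("b", "d", "beta", "gamma",
                                   "delta", "lambda", "N")]))
  stop("cannot interpret 'params' as epidemic parameters", call. = FALSE)
}

# effective transmission and recovery rates used throughout
beta_eff <- function(params) params$beta * (1 - params$delta)
gamma_eff <- function(params) params$gamma * (1 + params$lambda)
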
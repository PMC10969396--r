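#' Simulation configuration
#'
#' Shared run configuration for the integrators and simulators: time horizon,
#' reporting step, replicate count, seed, how newborn susceptibles are
#' handled, and which contagion variant to run.
#'
#' `newborn_mode` distinguishes whether newly born susceptibles participate in
#' epidemic spreading (`"SPES"`) or accumulate in a passive pool that is
#' counted in S(t) but cannot be infected (`"SNES"`). Under SPES the model
#' admits an endemic equilibrium when R0 > 1; under SNES only the disease-free
#' outcome exists.
#'
#' @param t_max Positive horizon (time units, or steps for the discrete-time
#'   network simulator).
#' @param dt Positive reporting interval.
#' @param replicates Positive integer number of stochastic replicates.
#' @param seed Integer base seed.
#' @param newborn_mode `"SPES"` or `"SNES"`.
#' @param model_variant One of `"SIR"`, `"SIR_star"`, `"SIS"`, `"SIS_star"`.
#'   The starred variants apply the bidirectional immunization rates
#'   (`delta`, `lambda`); the plain variants force `delta = 0`, `lambda = 0`.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(t_max, dt = 1, replicates = 1L, seed = 1L,
                       newborn_mode = c("SPES", "SNES"),
                       model_variant = c("SIR", "SIR_star",
                                         "SIS", "SIS_star")) {
  if (t_max <= 0) stop("'t_max' must be > 0", call. = FALSE)
  if (dt <= 0) stop("'dt' must be > 0", call. = FALSE)
  if (replicates < 1) stop("'replicates' must be >= 1", call. = FALSE)
  structure(list(t_max = t_max, dt = dt,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed),
                 newborn_mode = match.arg(newborn_mode),
                 model_variant = match.arg(model_variant)),
            class = "sim_config")
}

#' Fraction of infected edges
#'
#' The quantity \eqn{\Theta = \frac{1}{\langle k\rangle}\sum_k k\,p(k)\,I_k}:
#' the probability that an edge emanating from a susceptible node points at an
#' infected node, the coupling through which degree classes interact in the
#' heterogeneous mean-field equations.
#'
#' @param Ik Per-degree-class infected densities, aligned with
#'   `dist$degrees`.
#' @param dist A [degree_distribution()].
#' @return A scalar in `[0, max(Ik)]`.
#' @export
infected_edge_fraction <- function(Ik, dist) {
  stopifnot(inherits(dist, "degree_distribution"))
  if (length(Ik) != length(dist$degrees))
    stop("'Ik' must align with the degree support (length mismatch)",
         call. = FALSE)
  if (any(Ik < 0)) stop("'Ik' must be non-negative", call. = FALSE)
  if (dist$mean_degree == 0)
    stop("mean degree is zero; infected edge fraction undefined",
         call. = FALSE)
  sum(dist$degrees * dist$probs * Ik) / dist$mean_degree
}

#' Homogeneous mean-field right-hand side
#'
#' Instantaneous rates of change of the (S, I, R) densities on a homogeneous
#' network with mean degree `k_mean`:
#' \deqn{dS/dt = bN - dS - \beta(1-\delta)\langle k\rangle S I}
#' \deqn{dI/dt = \beta(1-\delta)\langle k\rangle S I - \gamma(1+\lambda)I - dI}
#' \deqn{dR/dt = \gamma(1+\lambda)I - dR}
#' Under `newborn_mode = "SNES"` the state carries a fourth component, the
#' passive newborn pool P, which receives the birth inflow (`dP/dt = bN - dP`)
#' instead of the active susceptible class and takes no part in transmission.
#'
#' @param state Numeric `c(S, I, R)` (SPES) or `c(S, I, R, P)` (SNES),
#'   non-negative densities.
#' @param params An [epi_params()].
#' @param k_mean Positive mean degree.
#' @param newborn_mode `"SPES"` or `"SNES"`.
#' @return Numeric derivative vector of the same length as `state`.
#' @export
homogeneous_rhs <- function(state, params, k_mean,
                            newborn_mode = c("SPES", "SNES")) {
  newborn_mode <- match.arg(newborn_mode)
  params <- as_epi_params(params)
  if (k_mean <= 0) stop("'k_mean' must be > 0", call. = FALSE)
  nst <- if (newborn_mode == "SPES") 3L else 4L
  if (length(state) != nst)
    stop(sprintf("'state' must have %d components in %s mode", nst,
                 newborn_mode), call. = FALSE)
  if (any(state < 0)) stop("'state' must be non-negative", call. = FALSE)
  S <- state[1]; I <- state[2]; R <- state[3]
  infect <- beta_eff(params) * k_mean * S * I
  recover <- gamma_eff(params) * I
  inflow <- params$b * params$N
  dI <- infect - recover - params$d * I
  dR <- recover - params$d * R
  if (newborn_mode == "SPES") {
    c(inflow - params$d * S - infect, dI, dR)
  } else {
    P <- state[4]
    c(-params$d * S - infect, dI, dR, inflow - params$d * P)
  }
}

#' Heterogeneous (degree-structured) mean-field right-hand side
#'
#' Per-degree-class rates of change with coupling through the infected-edge
#' fraction \eqn{\Theta}:
#' \deqn{dS_k/dt = bN - dS_k - \beta(1-\delta)k S_k \Theta}
#' \deqn{dI_k/dt = \beta(1-\delta)k S_k \Theta - \gamma(1+\lambda)I_k - dI_k}
#' \deqn{dR_k/dt = \gamma(1+\lambda)I_k - dR_k}
#' SNES newborn handling is as in [homogeneous_rhs()]: a single scalar passive
#' pool receives the birth inflow.
#'
#' @param state List with components `Sk`, `Ik`, `Rk` (vectors aligned with
#'   `dist$degrees`) and, in SNES mode, scalar `P`.
#' @param params An [epi_params()].
#' @param dist A [degree_distribution()].
#' @param newborn_mode `"SPES"` or `"SNES"`.
#' @return List with `dSk`, `dIk`, `dRk` and, in SNES mode, `dP`.
#' @export
heterogeneous_rhs <- function(state, params, dist,
                              newborn_mode = c("SPES", "SNES")) {
  newborn_mode <- match.arg(newborn_mode)
  params <- as_epi_params(params)
  stopifnot(inherits(dist, "degree_distribution"))
  k <- dist$degrees
  for (nm in c("Sk", "Ik", "Rk")) {
    v <- state[[nm]]
    if (is.null(v) || length(v) != length(k))
      stop("state component '", nm, "' must align with the degree support",
           call. = FALSE)
    if (any(v < 0)) stop("state component '", nm, "' must be non-negative",
                         call. = FALSE)
  }
  theta <- infected_edge_fraction(state$Ik, dist)
  infect <- beta_eff(params) * k * state$Sk * theta
  recover <- gamma_eff(params) * state$Ik
  inflow <- params$b * params$N
  out <- list(
    dSk = -params$d * state$Sk - infect,
    dIk = infect - recover - params$d * state$Ik,
    dRk = recover - params$d * state$Rk
  )
  if (newborn_mode == "SPES") {
    out$dSk <- out$dSk + inflow
  } else {
    P <- state$P
    if (is.null(P) || P < 0)
      stop("SNES mode requires a non-negative passive pool 'P'",
           call. = FALSE)
    out$dP <- inflow - params$d * P
  }
  out
}

#' Closed-form total population
#'
#' With identical death rates across compartments, the total density
#' `T = S + I + R (+ P)` obeys `dT/dt = bN - dT`, hence
#' `T(t) = bN/d + (T0 - bN/d) exp(-d t)` (or `T0 + bN t` when `d = 0`). Used
#' as an independent oracle for the integrators.
#'
#' @param params An [epi_params()].
#' @param T0 Initial total density.
#' @param t Time (vectorized).
#' @return Total density at `t`.
#' @export
total_population_closed_form <- function(params, T0, t) {
  params <- as_epi_params(params)
  bN <- params$b * params$N
  if (params$d == 0) return(T0 + bN * t)
  eq <- bN / params$d
  eq + (T0 - eq) * exp(-params$d * t)
}

#' Integrate the mean-field equations
#'
#' Numerically integrates the homogeneous (scalar) or heterogeneous
#' (degree-structured) mean-field system on a uniform reporting grid with
#' spacing `config$dt`, using an adaptive stiff-capable integrator
#' (`deSolve::ode`, `lsoda`, relative tolerance `1e-8`). In SNES mode the
#' reported `S` column includes the passive newborn pool, so `S(t)` matches
#' the plotted susceptible proportion.
#'
#' @param params An [epi_params()].
#' @param dist A [degree_distribution()] for the heterogeneous system, or
#'   `NULL` to use the homogeneous system with mean degree `k_mean`.
#' @param k_mean Mean degree for the homogeneous system (ignored when `dist`
#'   is supplied).
#' @param init Optional initial state. Homogeneous: `c(S, I, R)`.
#'   Heterogeneous: list with `Sk`, `Ik`, `Rk`. Defaults to
#'   `I(0) = 1/N` (as a density, in every degree class), `R(0) = 0`,
#'   `S(0) = 1 - I(0)`.
#' @param config A [sim_config()].
#' @return An `epi_trajectory` data frame with columns `time`, `S`, `I`, `R`
#'   (global densities; heterogeneous results are aggregated over degree
#'   classes with weights `p(k)`).
#' @export
integrate_meanfield <- function(params, dist = NULL, k_mean = NULL,
                                init = NULL, config) {
  params <- as_epi_params(params)
  stopifnot(inherits(config, "sim_config"))
  snes <- config$newborn_mode == "SNES"
  times <- seq(0, config$t_max, by = config$dt)
  i0 <- 1 / params$N

  if (is.null(dist)) {
    if (is.null(k_mean) || k_mean <= 0)
      stop("homogeneous integration needs 'k_mean' > 0", call. = FALSE)
    y0 <- if (is.null(init)) c(1 - i0, i0, 0) else init
    if (length(y0) == 3L && snes) y0 <- c(y0, 0)
    if (any(y0 < 0)) stop("initial state must be non-negative", call. = FALSE)
    rhs <- function(t, y, p)
      list(homogeneous_rhs(pmax(y, 0), params, k_mean, config$newborn_mode))
    sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                        method = "lsoda", rtol = 1e-8, atol = 1e-10)
    if (attr(sol, "istate")[1] < 0)
      stop(sprintf("integrator failed; last good time %g",
                   max(sol[, 1], na.rm = TRUE)), call. = FALSE)
    S <- sol[, 2]; I <- sol[, 3]; R <- sol[, 4]
    if (snes) S <- S + sol[, 5]
  } else {
    stopifnot(inherits(dist, "degree_distribution"))
    nk <- length(dist$degrees)
    st0 <- if (is.null(init))
      list(Sk = rep(1 - i0, nk), Ik = rep(i0, nk), Rk = rep(0, nk))
    else init
    y0 <- c(st0$Sk, st0$Ik, st0$Rk, if (snes) 0)
    if (any(y0 < 0)) stop("initial state must be non-negative", call. = FALSE)
    rhs <- function(t, y, p) {
      y <- pmax(y, 0)
      st <- list(Sk = y[seq_len(nk)], Ik = y[nk + seq_len(nk)],
                 Rk = y[2 * nk + seq_len(nk)])
      if (snes) st$P <- y[3 * nk + 1]
      d <- heterogeneous_rhs(st, params, dist, config$newborn_mode)
      list(c(d$dSk, d$dIk, d$dRk, if (snes) d$dP))
    }
    sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                        method = "lsoda", rtol = 1e-8, atol = 1e-10)
    if (attr(sol, "istate")[1] < 0)
      stop(sprintf("integrator failed; last good time %g",
                   max(sol[, 1], na.rm = TRUE)), call. = FALSE)
    w <- dist$probs
    Sk <- sol[, 1 + seq_len(nk), drop = FALSE]
    Ik <- sol[, 1 + nk + seq_len(nk), drop = FALSE]
    Rk <- sol[, 1 + 2 * nk + seq_len(nk), drop = FALSE]
    S <- as.vector(Sk %*% w); I <- as.vector(Ik %*% w)
    R <- as.vector(Rk %*% w)
    if (snes) S <- S + sol[, 1 + 3 * nk + 1]
  }
  epi_trajectory(times, S, I, R, mode = "density")
}

#' Epidemic trajectory container
#'
#' Time grid with S/I/R values: densities for mean-field output, averaged
#' densities for ensemble output, integer counts for single stochastic runs.
#'
#' @param times Increasing time points.
#' @param S,I,R Equal-length non-negative series.
#' @param mode `"density"` or `"count"`.
#' @return A data frame of class `"epi_trajectory"` with attribute `mode`.
#' @export
epi_trajectory <- function(times, S, I, R, mode = c("density", "count")) {
  mode <- match.arg(mode)
  n <- length(times)
  if (length(S) != n || length(I) != n || length(R) != n)
    stop("'times', 'S', 'I', 'R' must have equal length", call. = FALSE)
  if (n && is.unsorted(times))
    stop("'times' must be increasing", call. = FALSE)
  if (any(c(S, I, R) < -1e-9))
    stop("trajectory values must be non-negative", call. = FALSE)
  if (mode == "count" && any(c(S, I, R) != round(c(S, I, R))))
    stop("count-mode trajectories must hold integers", call. = FALSE)
  structure(data.frame(time = times, S = S, I = I, R = R),
            mode = mode,
            class = c("epi_trajectory", "data.frame"))
}

#' @export
print.epi_trajectory <- function(x, ...) {
  cat(sprintf("Epidemic trajectory (%s mode): %d points on [%g, %g]\n",
              attr(x, "mode"), nrow(x),
              if (nrow(x)) min(x$time) else NA, if (nrow(x)) max(x$time) else NA))
  if (nrow(x)) {
    cat(sprintf("  peak I = %g at t = %g; final (S, I, R) = (%g, %g, %g)\n",
                max(x$I), x$time[which.max(x$I)],
                x$S[nrow(x)], x$I[nrow(x)], x$R[nrow(x)]))
  }
  invisible(x)
}

#' @export
plot.epi_trajectory <- function(x, ...) {
  ylim <- c(0, max(x$S, x$I, x$R))
  plot(x$time, x$S, type = "l", col = "steelblue", ylim = ylim,
       xlab = "time", ylab = if (attr(x, "mode") == "density")
         "density" else "count", ...)
  lines(x$time, x$I, col = "firebrick")
  lines(x$time, x$R, col = "darkgreen")
  legend("right", legend = c("S", "I", "R"), lty = 1,
         col = c("steelblue", "firebrick", "darkgreen"), bty = "n")
  invisible(x)
}
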
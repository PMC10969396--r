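#' Birth-death chain specification
#'
#' Finite continuous-time Markov chain over the infected count
#' `i = 1, ..., N` with only two event types: infection `(s, i) -> (s-1,
#' i+1)` at rate \eqn{\rho(s, i) = (s/N)\,\beta\,i\,(1-\delta)\,C} and
#' recovery `(s, i) -> (s, i-1)` at rate \eqn{\mu(s, i) = \gamma i
#' (1+\lambda)}, where `C` is the connectivity factor (\eqn{\langle k\rangle}
#' homogeneous, \eqn{\langle k^2\rangle/\langle k\rangle} heterogeneous).
#' Births and deaths do not enter the chain: it is a pure two-event process.
#'
#' Two boundary conventions coexist. The matrix artifacts (transition
#' probability matrix, generator, stationary distribution, embedded chain)
#' use the *reflected* chain on `i in 1..N`, in which state `i = 1` has no
#' recovery exit; the Gillespie simulator uses the *absorbing* chain, in
#' which `i = 0` terminates the epidemic. In the matrix layer the first rate
#' argument is the fixed initial susceptible count `s0` shifted by the number
#' of infections, `rho(s0 - i + 1, i)`, not a live state variable.
#'
#' @param N Integer population size (>= 2).
#' @param params An [epi_params()].
#' @param connectivity Positive connectivity factor `C`.
#' @param s0 Initial susceptible count, `1 <= s0 <= N - 1` (default `N - 1`).
#' @param boundary `"reflected"` or `"absorbing"`.
#' @return A list of class `"chain_spec"`.
#' @export
chain_spec <- function(N, params, connectivity, s0 = N - 1,
                       boundary = c("reflected", "absorbing")) {
  boundary <- match.arg(boundary)
  params <- as_epi_params(params)
  if (N < 2 || N != round(N))
    stop("'N' must be an integer >= 2", call. = FALSE)
  if (connectivity <= 0) stop("'connectivity' must be > 0", call. = FALSE)
  if (s0 < 1 || s0 > N - 1 || s0 != round(s0))
    stop("'s0' must be an integer in [1, N-1]", call. = FALSE)
  structure(list(N = as.integer(N), params = params,
                 connectivity = connectivity, s0 = as.integer(s0),
                 boundary = boundary),
            class = "chain_spec")
}

#' @export
print.chain_spec <- function(x, ...) {
  cat(sprintf(
    "Birth-death chain: N = %d, s0 = %d, connectivity = %g, %s boundary\n",
    x$N, x$s0, x$connectivity, x$boundary))
  invisible(x)
}

#' Infection (birth) rate of the chain
#'
#' \eqn{\rho(s, i) = (s/N)\,\beta\,i\,(1-\delta)\,C}; zero whenever `s = 0`
#' or `i = 0`.
#'
#' @param spec A [chain_spec()].
#' @param s,i Susceptible and infected counts, `s + i <= N`.
#' @return The transition rate to `(s-1, i+1)`.
#' @export
infection_rate <- function(spec, s, i) {
  stopifnot(inherits(spec, "chain_spec"))
  if (any(s < 0) || any(i < 0) || any(s + i > spec$N))
    stop("need 0 <= s, 0 <= i, s + i <= N", call. = FALSE)
  p <- spec$params
  (s / spec$N) * p$beta * i * (1 - p$delta) * spec$connectivity
}

#' Recovery (death) rate of the chain
#'
#' \eqn{\mu(s, i) = \gamma\,i\,(1+\lambda)}, independent of `s`.
#'
#' @param spec A [chain_spec()].
#' @param i Infected count (>= 0).
#' @return The transition rate to `(s, i-1)`.
#' @export
recovery_rate <- function(spec, i) {
  stopifnot(inherits(spec, "chain_spec"))
  if (any(i < 0)) stop("'i' must be >= 0", call. = FALSE)
  p <- spec$params
  p$gamma * i * (1 + p$lambda)
}

# superdiagonal rates rho(s0 - i + 1, i) for i = 1..N-1 (0 once susceptibles
# are exhausted) and subdiagonal rates mu(s0, i) for i = 2..N
chain_rates <- function(spec) {
  i_up <- seq_len(spec$N - 1)
  s_arg <- pmax(spec$s0 - i_up + 1, 0)
  list(rho = infection_rate(spec, s_arg, i_up),
       mu = recovery_rate(spec, 2:spec$N))
}

#' First-order transition probability matrix
#'
#' The `N x N` matrix over infected counts `i = 1..N` whose row `i` carries
#' `rho(s0 - i + 1, i) * dt` on the superdiagonal, `mu(s0, i) * dt` on the
#' subdiagonal, and the completion to 1 on the diagonal (reflected
#' convention: row 1 has no recovery exit). Valid only for `dt` small enough
#' that `dt * max(rho + mu) <= 1`.
#'
#' @param spec A [chain_spec()].
#' @param dt Positive first-order step.
#' @return A row-stochastic matrix.
#' @export
transition_probability_matrix <- function(spec, dt) {
  stopifnot(inherits(spec, "chain_spec"))
  if (dt <= 0) stop("'dt' must be > 0", call. = FALSE)
  r <- chain_rates(spec)
  exit <- c(r$rho, 0) + c(0, r$mu)   # total exit rate of rows 1..N
  dt_max <- 1 / max(exit)
  if (dt * max(exit) > 1)
    stop(sprintf("dt = %g too large for first-order probabilities; need dt <= %g",
                 dt, dt_max), call. = FALSE)
  N <- spec$N
  P <- diag(1 - exit * dt)
  P[cbind(seq_len(N - 1), 2:N)] <- r$rho * dt
  P[cbind(2:N, seq_len(N - 1))] <- r$mu * dt
  P
}

#' Generator (transition rate) matrix
#'
#' The infinitesimal generator `Q` of the reflected chain: superdiagonal
#' `rho`, subdiagonal `mu`, diagonal the negated off-diagonal row sum, so
#' every row sums to zero and `(P(dt) - I)/dt = Q` for any admissible `dt`.
#'
#' @param spec A [chain_spec()].
#' @return The `N x N` generator matrix.
#' @export
generator_matrix <- function(spec) {
  stopifnot(inherits(spec, "chain_spec"))
  r <- chain_rates(spec)
  N <- spec$N
  Q <- diag(-(c(r$rho, 0) + c(0, r$mu)))
  Q[cbind(seq_len(N - 1), 2:N)] <- r$rho
  Q[cbind(2:N, seq_len(N - 1))] <- r$mu
  Q
}

#' Stationary distribution of the reflected chain
#'
#' The steady-state probability \eqn{\pi_i} of observing `i` infected nodes,
#' computed by one of three equivalent routes: the local-balance recursion
#' \eqn{\pi_{i+1}/\pi_i = \rho(s_0-i+1, i)/\mu(s_0, i+1)} (default), the
#' closed-form product expression
#' \eqn{\pi_i \propto \frac{s_0!}{i\,(s_0-i+1)!}
#'   \left[\frac{\beta(1-\delta)C}{N\gamma(1+\lambda)}\right]^{i-1}}, or a
#' null-space solve of the generator. All three agree to high precision; the
#' alternatives exist as independent cross-checks. Probability beyond
#' `i = s0 + 1` is exactly zero (no susceptibles left to infect).
#'
#' @param spec A [chain_spec()] with `boundary = "reflected"` and
#'   `gamma * (1 + lambda) > 0`.
#' @param method `"recursion"`, `"closed_form"` or `"nullspace"`.
#' @return A probability vector over `i = 1..N` summing to 1.
#' @export
stationary_distribution <- function(spec,
                                    method = c("recursion", "closed_form",
                                               "nullspace")) {
  method <- match.arg(method)
  stopifnot(inherits(spec, "chain_spec"))
  if (spec$boundary != "reflected")
    stop("stationary distribution requires the reflected chain", call. = FALSE)
  if (gamma_eff(spec$params) <= 0)
    stop("gamma * (1 + lambda) must be > 0 (recursion divides by mu)",
         call. = FALSE)
  N <- spec$N
  r <- chain_rates(spec)
  if (method == "nullspace") {
    Q <- generator_matrix(spec)
    A <- rbind(t(Q), rep(1, N))          # pi Q = 0, sum(pi) = 1
    pi_ <- qr.solve(A, c(rep(0, N), 1))
    pi_[pi_ < 0] <- 0
    return(pi_ / sum(pi_))
  }
  logw <- if (method == "recursion") {
    cumsum(c(0, log(r$rho) - log(r$mu)))   # log pi_i up to a constant
  } else {
    p <- spec$params
    lc <- log(p$beta * (1 - p$delta) * spec$connectivity) -
      log(N * p$gamma * (1 + p$lambda))
    i <- seq_len(N)
    lw <- lgamma(spec$s0 + 1) - lgamma(pmax(spec$s0 - i + 2, 1)) -
      log(i) + (i - 1) * lc
    lw[i > spec$s0 + 1] <- -Inf
    lw
  }
  w <- exp(logw - max(logw[is.finite(logw)]))
  w[!is.finite(w)] <- 0
  w / sum(w)
}

#' Embedded (jump) chain transition matrix
#'
#' Discrete-time matrix of jump destinations of the reflected chain: zero
#' diagonal; interior row `i` holds `mu/(rho + mu)` on the subdiagonal and
#' `rho/(rho + mu)` on the superdiagonal; the boundary rows jump
#' deterministically (row 1 up, row N down). Every row sums to 1.
#'
#' @param spec A [chain_spec()].
#' @return A row-stochastic `N x N` matrix.
#' @export
embedded_chain_matrix <- function(spec) {
  stopifnot(inherits(spec, "chain_spec"))
  r <- chain_rates(spec)
  N <- spec$N
  R <- matrix(0, N, N)
  R[1, 2] <- 1
  R[N, N - 1] <- 1
  if (N > 2) {
    i <- 2:(N - 1)
    tot <- r$rho[i] + r$mu[i - 1]
    if (any(tot == 0))
      stop(sprintf("state i = %d has no exit (rho + mu = 0)",
                   i[which(tot == 0)[1]]), call. = FALSE)
    R[cbind(i, i - 1)] <- r$mu[i - 1] / tot
    R[cbind(i, i + 1)] <- r$rho[i] / tot
  }
  R
}

#' Exact stochastic (Gillespie) simulation of the absorbing chain
#'
#' Samples the continuous-time chain exactly: in state `(s, i)` the waiting
#' time is exponential with rate `rho(s, i) + mu(s, i)` and the jump is an
#' infection with probability `rho/(rho + mu)`, else a recovery. Here `s` is
#' the live susceptible count (it decrements with each infection) and `i = 0`
#' is absorbing: the epidemic halts. Exponential draws use the inverse
#' transform on R's seeded generator, so runs are reproducible given `seed`.
#'
#' @param spec A [chain_spec()] with `boundary = "absorbing"`.
#' @param i0 Initial infected count (>= 1, `i0 + s0 <= N`).
#' @param t_max Time horizon.
#' @param seed Integer seed.
#' @return A list of class `"jump_trajectory"`: `jump_times`, `s`, `i`
#'   (aligned vectors, starting at time 0) and flag `absorbed`.
#' @export
gillespie_run <- function(spec, i0, t_max, seed = 1L) {
  stopifnot(inherits(spec, "chain_spec"))
  if (spec$boundary != "absorbing")
    stop("gillespie_run requires the absorbing chain", call. = FALSE)
  if (i0 < 1 || i0 != round(i0)) stop("'i0' must be >= 1", call. = FALSE)
  if (i0 + spec$s0 > spec$N)
    stop("'i0' + 's0' must not exceed N", call. = FALSE)
  p <- spec$params
  cap <- 2L * spec$N + 2L
  tms <- numeric(cap); ss <- integer(cap); ii <- integer(cap)
  with_seed(seed, {
    t <- 0; s <- spec$s0; i <- as.integer(i0); n <- 1L
    tms[1] <- 0; ss[1] <- s; ii[1] <- i
    repeat {
      rho <- infection_rate(spec, s, i)
      mu <- recovery_rate(spec, i)
      tot <- rho + mu
      if (i == 0L || tot == 0) break
      t <- t - log(stats::runif(1)) / tot   # inverse-transform exponential
      if (t > t_max) break
      if (stats::runif(1) < rho / tot) {
        s <- s - 1L; i <- i + 1L
      } else {
        i <- i - 1L
      }
      n <- n + 1L
      tms[n] <- t; ss[n] <- s; ii[n] <- i
    }
    structure(list(jump_times = tms[seq_len(n)], s = ss[seq_len(n)],
                   i = ii[seq_len(n)], absorbed = i == 0L),
              class = "jump_trajectory")
  })
}

#' @export
print.jump_trajectory <- function(x, ...) {
  n <- length(x$jump_times)
  cat(sprintf(
    "Jump trajectory: %d jumps over [0, %g]; final (s, i) = (%d, %d)%s\n",
    n - 1L, x$jump_times[n], x$s[n], x$i[n],
    if (x$absorbed) " [absorbed]" else ""))
  invisible(x)
}

#' Ensemble of Gillespie runs
#'
#' Runs `replicates` independent trajectories with one named seed stream per
#' replicate (`seed + replicate index`), for ensemble averaging.
#'
#' @param spec A [chain_spec()] with `boundary = "absorbing"`.
#' @param i0,t_max As in [gillespie_run()].
#' @param replicates Number of runs.
#' @param seed Base seed.
#' @return A list of `"jump_trajectory"` objects.
#' @export
gillespie_ensemble <- function(spec, i0, t_max, replicates, seed = 1L) {
  lapply(seq_len(replicates), function(r)
    gillespie_run(spec, i0, t_max, seed = seed + r))
}

#' Average jump trajectories onto a time grid
#'
#' Samples each run at the grid points with last-state-carried-forward
#' interpolation and averages `s/N`, `i/N` and the implied recovered count
#' `r/N = (s0 + i0 - s - i)/N` across runs. The chain has no births or
#' deaths, so `s + i + r` is conserved at every grid point.
#'
#' @param runs Non-empty list of `"jump_trajectory"` objects.
#' @param grid Increasing time points.
#' @param N Population size used for density normalization.
#' @return An `epi_trajectory` in density mode.
#' @export
ensemble_average <- function(runs, grid, N) {
  if (length(runs) == 0L) stop("'runs' must be non-empty", call. = FALSE)
  if (is.unsorted(grid)) stop("'grid' must be increasing", call. = FALSE)
  acc_s <- numeric(length(grid)); acc_i <- numeric(length(grid))
  for (run in runs) {
    idx <- findInterval(grid, run$jump_times)
    idx[idx < 1L] <- 1L             # grid points before time 0: initial state
    acc_s <- acc_s + run$s[idx]
    acc_i <- acc_i + run$i[idx]
  }
  ns <- acc_s / length(runs) / N
  ni <- acc_i / length(runs) / N
  tot0 <- (runs[[1]]$s[1] + runs[[1]]$i[1]) / N
  epi_trajectory(grid, S = ns, I = ni, R = tot0 - ns - ni, mode = "density")
}
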
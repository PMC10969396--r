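#' Discrete-time Monte-Carlo simulation on a contact network
#'
#' Synchronous per-step contagion on an explicit graph. From the step-start
#' configuration, each susceptible node with `m` infected living neighbours
#' becomes infected with probability \eqn{1 - (1 - \beta(1-\delta))^m}; each
#' infected node recovers with probability `min(1, gamma * (1 + lambda))`
#' (SIR variants move to R, SIS variants back to S); each living node then
#' dies with probability `min(1, d)` (its edges die with it). Newborn
#' susceptibles, `round(b * n)` per step, accumulate in a passive pool that
#' is counted in the reported S density but never joins the graph and cannot
#' be infected. Densities are normalized by the initial node count `n`.
#'
#' The plain `"SIR"` / `"SIS"` variants force `delta = 0, lambda = 0`; the
#' starred variants `"SIR_star"` / `"SIS_star"` apply the bidirectional
#' immunization rates from `params`.
#'
#' @param network A [contact_network()] (or igraph graph).
#' @param params An [epi_params()].
#' @param config A [sim_config()]; `t_max` is the number of steps and
#'   `model_variant` selects the contagion variant.
#' @param initial_infected Either a count (that many nodes drawn uniformly)
#'   or a vector of 0-based node ids to start infected.
#' @param seed Integer seed; identical inputs reproduce the result exactly.
#' @param record_states Keep the full per-step status matrix (statuses
#'   0 = S, 1 = I, 2 = R, 3 = dead); memory-heavy, intended for diagnostics.
#' @return An object of class `"mcs_result"`: `trajectory` (density-mode
#'   [epi_trajectory()], S including the passive pool), `peak_I`, `passive`
#'   (per-step pool size), `counts` (raw count matrix) and optionally
#'   `states`.
#' @export
mcs_run <- function(network, params, config, initial_infected = 1,
                    seed = 1L, record_states = FALSE) {
  params <- as_epi_params(params)
  stopifnot(inherits(config, "sim_config"))
  g <- as_contact_network(network)
  csr <- adjacency_csr(g)
  n <- csr$n
  if (n < 1L) stop("network has no nodes", call. = FALSE)
  variant <- config$model_variant
  sis <- variant %in% c("SIS", "SIS_star")
  starred <- variant %in% c("SIR_star", "SIS_star")
  be <- if (starred) beta_eff(params) else params$beta
  ge <- if (starred) gamma_eff(params) else params$gamma
  steps <- as.integer(ceiling(config$t_max))

  status0 <- integer(n)
  res <- with_seed(seed, {
    # scalar -> that many uniformly drawn seed nodes; vector -> 0-based ids
    seeds <- if (length(initial_infected) == 1L)
      sample.int(n, initial_infected) - 1L
    else as.integer(initial_infected)
    if (any(seeds < 0 | seeds >= n))
      stop("initial infected ids must lie in [0, n)", call. = FALSE)
    status0[seeds + 1L] <- 1L
    .mcs_core(csr$neighbors - 1L, csr$ptr, n, steps, be, ge,
              params$b, params$d, sis, status0, record_states)
  })
  counts <- res$counts
  times <- 0:steps
  S <- (counts[, 1] + counts[, 4]) / n
  I <- counts[, 2] / n
  R <- counts[, 3] / n
  out <- list(trajectory = epi_trajectory(times, S, I, R, mode = "density"),
              peak_I = max(I), passive = counts[, 4], counts = counts,
              n = n, variant = variant)
  if (record_states) out$states <- res$states
  structure(out, class = "mcs_result")
}

#' @export
print.mcs_result <- function(x, ...) {
  cat(sprintf("MCS result (%s, n = %d): peak I = %.4g\n",
              x$variant, x$n, x$peak_I))
  print(x$trajectory)
  invisible(x)
}

#' Replicate-averaged Monte-Carlo simulation
#'
#' Runs `n_reps` independent replicates (seed `base_seed + r` for replicate
#' `r`) and averages the density trajectories. Per-replicate peak and final
#' densities are returned alongside; the final density of a replicate is the
#' mean over the last 10% of steps.
#'
#' @param network A fixed [contact_network()], or `NULL` when
#'   `network_factory` is given.
#' @param params,config,initial_infected As in [mcs_run()].
#' @param n_reps Number of replicates (>= 1).
#' @param base_seed Integer base seed.
#' @param network_factory Optional `function(seed)` returning a fresh network
#'   per replicate.
#' @return An `"mcs_result"` whose `trajectory` is the replicate mean, with
#'   extra fields `rep_peak_I`, `rep_I_inf`, `rep_R_inf`, `rep_S_inf`.
#' @export
replicate_average <- function(network = NULL, params, config, n_reps,
                              base_seed = 1L, initial_infected = 1,
                              network_factory = NULL) {
  if (n_reps < 1) stop("'n_reps' must be >= 1", call. = FALSE)
  if (is.null(network) && is.null(network_factory))
    stop("supply 'network' or 'network_factory'", call. = FALSE)
  acc <- NULL
  peak <- I_inf <- R_inf <- S_inf <- numeric(n_reps)
  passive <- NULL
  for (r in seq_len(n_reps)) {
    g <- if (is.null(network_factory)) network
    else network_factory(base_seed + r)
    res <- mcs_run(g, params, config, initial_infected,
                   seed = base_seed + r)
    tr <- res$trajectory
    if (is.null(acc)) {
      acc <- tr[, c("S", "I", "R")]
      passive <- res$passive
    } else {
      acc <- acc + tr[, c("S", "I", "R")]
      passive <- passive + res$passive
    }
    m <- epidemic_metrics(res)
    peak[r] <- m[["peak_I"]]; I_inf[r] <- m[["I_inf"]]
    R_inf[r] <- m[["R_inf"]]; S_inf[r] <- m[["S_inf"]]
  }
  acc <- acc / n_reps
  tr <- epi_trajectory(res$trajectory$time, acc$S, acc$I, acc$R,
                       mode = "density")
  structure(list(trajectory = tr, peak_I = max(acc$I),
                 passive = passive / n_reps, counts = NULL,
                 n = res$n, variant = res$variant, n_reps = n_reps,
                 rep_peak_I = peak, rep_I_inf = I_inf,
                 rep_R_inf = R_inf, rep_S_inf = S_inf),
            class = "mcs_result")
}

#' Epidemic summary metrics of a simulation result
#'
#' Peak infection density and its time, plus steady-state densities taken as
#' the mean over the final 10% of recorded steps.
#'
#' @param result An `"mcs_result"` (single replicate or replicate average).
#' @return Named numeric vector `peak_I`, `t_peak`, `I_inf`, `R_inf`,
#'   `S_inf`.
#' @export
epidemic_metrics <- function(result) {
  tr <- if (inherits(result, "mcs_result")) result$trajectory else result
  if (!nrow(tr)) stop("empty trajectory", call. = FALSE)
  tail_idx <- seq.int(min(nrow(tr), floor(nrow(tr) * 0.9) + 1L), nrow(tr))
  c(peak_I = max(tr$I), t_peak = tr$time[which.max(tr$I)],
    I_inf = mean(tr$I[tail_idx]), R_inf = mean(tr$R[tail_idx]),
    S_inf = mean(tr$S[tail_idx]))
}

#' Immunization sweep over (delta, beta) grids
#'
#' Replicate-averaged steady-state metrics for every combination of
#' vaccination rate `delta` and infection rate `beta`, holding the remaining
#' parameters fixed. Maps how the vaccination rate suppresses the epidemic
#' size `R(Inf)` and protects the never-infected fraction `S(Inf)`.
#'
#' @param network Fixed network, or `NULL` with a `network_factory`.
#' @param params Baseline [epi_params()].
#' @param delta_grid,beta_grid Values within the valid parameter domains.
#' @param config A [sim_config()] (its `model_variant` should be a starred
#'   variant so that `delta` takes effect).
#' @param n_reps Replicates per grid point.
#' @param base_seed Integer base seed.
#' @param network_factory Optional `function(seed)` for fresh networks.
#' @param initial_infected As in [mcs_run()].
#' @return A data frame with one row per `(delta, beta)` pair and columns
#'   `delta`, `beta`, `peak_I`, `I_inf`, `R_inf`, `S_inf`.
#' @export
immunization_sweep <- function(network = NULL, params, delta_grid, beta_grid,
                               config, n_reps, base_seed = 1L,
                               network_factory = NULL,
                               initial_infected = 1) {
  params <- as_epi_params(params)
  rows <- expand.grid(delta = delta_grid, beta = beta_grid,
                      KEEP.OUT.ATTRS = FALSE)
  out <- cbind(rows, peak_I = NA_real_, I_inf = NA_real_,
               R_inf = NA_real_, S_inf = NA_real_)
  for (idx in seq_len(nrow(rows))) {
    pl <- unclass(params)
    pl$delta <- rows$delta[idx]
    pl$beta <- rows$beta[idx]
    p2 <- do.call(epi_params, pl)
    res <- replicate_average(network, p2, config, n_reps,
                             base_seed = base_seed,
                             initial_infected = initial_infected,
                             network_factory = network_factory)
    tr <- res$trajectory
    tail_idx <- seq.int(min(nrow(tr), floor(nrow(tr) * 0.9) + 1L), nrow(tr))
    out$peak_I[idx] <- max(tr$I)
    out$I_inf[idx] <- mean(tr$I[tail_idx])
    out$R_inf[idx] <- mean(tr$R[tail_idx])
    out$S_inf[idx] <- mean(tr$S[tail_idx])
  }
  out
}
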
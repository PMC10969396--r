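#' Bidirectional-immunization epidemic model
#'
#' Central model constructor: binds a validated parameter set to a contact
#' structure (a degree distribution or an explicit network) and returns a
#' classed object on which the usual verbs operate — `print`, `coef`,
#' `summary` (reproduction numbers, thresholds, equilibria) and `simulate`
#' (mean-field integration, Gillespie sampling of the CTMC, or network
#' Monte-Carlo).
#'
#' @param params An [epi_params()] (or a plain list of its fields).
#' @param dist A [degree_distribution()] describing connectivity, or `NULL`
#'   when only `network` is given (its empirical distribution is used).
#' @param network Optional [contact_network()] for Monte-Carlo simulation.
#' @param network_class `"homogeneous"` or `"heterogeneous"`; decides which
#'   connectivity factor enters the analytic layer and the CTMC.
#' @return An object of class `"bisir_model"`.
#' @examples
#' m <- bisir_model(epi_params(0.08, 0.05, 0.175, 0.05, 0.2, 0.3),
#'                  dist = degenerate_distribution(4),
#'                  network_class = "homogeneous")
#' summary(m)
#' @export
bisir_model <- function(params, dist = NULL, network = NULL,
                        network_class = c("heterogeneous", "homogeneous")) {
  network_class <- match.arg(network_class)
  params <- as_epi_params(params)
  if (!is.null(network)) network <- as_contact_network(network)
  if (is.null(dist)) {
    if (is.null(network))
      stop("supply 'dist' and/or 'network'", call. = FALSE)
    dist <- empirical_degree_distribution(network)
  }
  structure(list(params = params, dist = dist, network = network,
                 network_class = network_class),
            class = "bisir_model")
}

#' @export
print.bisir_model <- function(x, ...) {
  cat("Bidirectional-immunization epidemic model\n")
  print(x$params)
  print(x$dist)
  if (!is.null(x$network))
    cat(sprintf("  contact network: %d nodes, %d edges\n",
                igraph::vcount(x$network), igraph::ecount(x$network)))
  cat(sprintf("  analytic network class: %s\n", x$network_class))
  invisible(x)
}

#' @export
coef.bisir_model <- function(object, ...) {
  unlist(unclass(object$params))
}

#' @export
summary.bisir_model <- function(object, ...) {
  out <- outbreak_summary(object$params, object$dist, object$network_class)
  eq0 <- disease_free_equilibrium(object$params, object$dist)
  eqs <- if (object$network_class == "heterogeneous")
    endemic_equilibrium(object$params, object$dist) else NULL
  structure(list(model = object, outbreak = out,
                 disease_free = eq0, endemic = eqs),
            class = "summary.bisir_model")
}

#' @export
print.summary.bisir_model <- function(x, ...) {
  print(x$model)
  print(x$outbreak)
  print(x$disease_free)
  if (!is.null(x$endemic)) print(x$endemic)
  invisible(x)
}

#' Simulate an epidemic model
#'
#' Dispatches to the three simulation engines. `method = "meanfield"`
#' integrates the deterministic equations ([integrate_meanfield()]);
#' `"gillespie"` samples the continuous-time chain exactly
#' ([gillespie_run()]) and averages `nsim` replicates on the reporting grid;
#' `"network"` runs the discrete-time Monte-Carlo simulation on the model's
#' contact network ([mcs_run()] / [replicate_average()]).
#'
#' @param object A [bisir_model()].
#' @param nsim Number of stochastic replicates (ignored for `"meanfield"`).
#' @param seed Integer seed (overrides `config$seed` when given).
#' @param method `"meanfield"`, `"gillespie"` or `"network"`.
#' @param config A [sim_config()].
#' @param N Population size for the Gillespie chain (default 1000).
#' @param i0 Initial infected count for the Gillespie chain (default 1).
#' @param ... Passed through to the underlying engine.
#' @return An [epi_trajectory()] (meanfield, gillespie) or an
#'   `"mcs_result"` (network).
#' @export
simulate.bisir_model <- function(object, nsim = 1, seed = NULL,
                                 method = c("meanfield", "gillespie",
                                            "network"),
                                 config, N = 1000L, i0 = 1L, ...) {
  method <- match.arg(method)
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) seed <- config$seed
  conn <- if (object$network_class == "heterogeneous")
    connectivity_ratio(object$dist) else object$dist$mean_degree
  switch(method,
    meanfield = {
      if (object$network_class == "heterogeneous")
        integrate_meanfield(object$params, dist = object$dist,
                            config = config, ...)
      else
        integrate_meanfield(object$params,
                            k_mean = object$dist$mean_degree,
                            config = config, ...)
    },
    gillespie = {
      spec <- chain_spec(N, object$params, conn, s0 = N - i0,
                         boundary = "absorbing")
      runs <- gillespie_ensemble(spec, i0 = i0, t_max = config$t_max,
                                 replicates = nsim, seed = seed)
      ensemble_average(runs, seq(0, config$t_max, by = config$dt), N)
    },
    network = {
      if (is.null(object$network))
        stop("model has no contact network; supply one to bisir_model()",
             call. = FALSE)
      if (nsim == 1L)
        mcs_run(object$network, object$params, config, seed = seed, ...)
      else
        replicate_average(object$network, object$params, config,
                          n_reps = nsim, base_seed = seed, ...)
    })
}
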
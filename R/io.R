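#' Read an undirected edge list
#'
#' Parses whitespace-separated integer pairs, one edge per line; `#` starts a
#' comment. Node ids are remapped to `0..n-1` preserving first-appearance
#' order of the original ids; self-loops and duplicate edges are dropped with
#' a message reporting the counts.
#'
#' @param path Path to the edge-list file.
#' @return A [contact_network()].
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  keep <- nzchar(trimws(lines))
  if (!any(keep)) stop("empty edge list: ", path, call. = FALSE)
  idx <- which(keep)
  parts <- strsplit(trimws(lines[keep]), "[[:space:]]+")
  bad <- which(lengths(parts) != 2L |
                 vapply(parts, function(p) anyNA(suppressWarnings(
                   as.numeric(p))), logical(1)))
  if (length(bad))
    stop(sprintf("malformed edge at line %d of %s", idx[bad[1]], path),
         call. = FALSE)
  m <- matrix(as.numeric(unlist(parts)), ncol = 2, byrow = TRUE)
  if (any(m != round(m)))
    stop("edge list node ids must be integers: ", path, call. = FALSE)
  ids <- unique(as.vector(t(m)))
  from <- match(m[, 1], ids) - 1L
  to <- match(m[, 2], ids) - 1L
  loops <- from == to
  key <- paste(pmin(from, to), pmax(from, to))
  dups <- duplicated(key) & !loops
  if (any(loops))
    message(sum(loops), " self-loop(s) dropped")
  if (any(dups))
    message(sum(dups), " duplicate edge(s) dropped")
  keep_e <- !loops & !dups
  contact_network(cbind(from, to)[keep_e, , drop = FALSE],
                  n = length(ids))
}

#' Write a trajectory as a delimited table
#'
#' Comma-separated table with header `time,S,I,R`, one row per grid point at
#' full double precision, so that reading it back reproduces the values
#' exactly. Count-mode trajectories are written with integer formatting.
#'
#' @param trajectory An [epi_trajectory()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_trajectory_table <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "epi_trajectory"))
  df <- as.data.frame(trajectory)
  if (attr(trajectory, "mode") == "count")
    for (cl in c("S", "I", "R")) df[[cl]] <- as.integer(df[[cl]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("time,S,I,R", con)
  if (nrow(df))
    writeLines(paste(format(df$time, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     vapply(df$S, format_full, character(1)),
                     vapply(df$I, format_full, character(1)),
                     vapply(df$R, format_full, character(1)),
                     sep = ","), con)
  invisible(path)
}

format_full <- function(x) {
  if (is.integer(x) || x == round(x)) format(x, scientific = FALSE)
  else sprintf("%.17g", x)
}

#' Read a trajectory table written by [write_trajectory_table()]
#'
#' @param path Input path.
#' @param mode `"density"` or `"count"`.
#' @return An [epi_trajectory()].
#' @export
read_trajectory_table <- function(path, mode = c("density", "count")) {
  mode <- match.arg(mode)
  df <- utils::read.csv(path)
  epi_trajectory(df$time, df$S, df$I, df$R, mode = mode)
}

#' Run a command from a structured configuration
#'
#' Single entry point behind the command-line tool. The configuration is a
#' flat named list (typically parsed from a YAML file; command-line flags
#' override file values) with a `command` field naming one of: `r0`,
#' `threshold`, `meanfield`, `ctmc-steady`, `gillespie`, `netsim`, `sweep`,
#' `sensitivity`. Parameter fields are `b, d, beta, gamma, delta, lambda, N`;
#' the contact structure is given by `network` (`er`, `ba`, `edgelist`,
#' `degenerate`, `poisson`) with its options (`n`, `k`, `xi`, `k_max`, `m`,
#' `path`), and run options by `t_max`, `dt`, `replicates`, `seed`,
#' `newborn_mode`, `model_variant`, `i0`, `s0`.
#'
#' Outputs are written under `out` (a path prefix): the primary result table
#' and a reproducibility manifest (JSON: every resolved parameter, the seed
#' and the package version) sufficient to re-run the command.
#'
#' @param config Named list as described, or a path to a YAML file.
#' @param quiet Suppress progress messages.
#' @return The computed object, invisibly.
#' @export
run_from_config <- function(config, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (is.null(config$command))
    stop("config must name a 'command'", call. = FALSE)
  commands <- c("r0", "threshold", "meanfield", "ctmc-steady", "gillespie",
                "netsim", "sweep", "sensitivity")
  if (!config$command %in% commands)
    stop("unknown command '", config$command, "'; available: ",
         paste(commands, collapse = ", "), call. = FALSE)
  say <- function(...) if (!quiet) message(...)

  grab <- function(nm, default = NULL) {
    if (!is.null(config[[nm]])) config[[nm]] else default
  }
  params <- epi_params(b = grab("b", 0.08), d = grab("d", 0.05),
                       beta = grab("beta", 0.175),
                       gamma = grab("gamma", 0.05),
                       delta = grab("delta", 0.2),
                       lambda = grab("lambda", 0.3),
                       N = grab("N", 1))
  seed <- as.integer(grab("seed", 1L))
  net_type <- grab("network", "degenerate")
  say(sprintf("command=%s seed=%d network=%s", config$command, seed,
              net_type))

  network <- NULL
  dist <- switch(net_type,
    degenerate = degenerate_distribution(grab("k", 4)),
    poisson = poisson_degree_distribution(grab("xi", 4),
                                          grab("k_max", 20 * grab("xi", 4))),
    er = {
      network <- generate_er(grab("n", 1000), grab("k", 4), seed = seed)
      empirical_degree_distribution(network)
    },
    ba = {
      network <- generate_ba(grab("n", 1000),
                             max(1L, round(grab("k", 4) / 2)), seed = seed)
      empirical_degree_distribution(network)
    },
    edgelist = {
      network <- read_edge_list(grab("path"))
      empirical_degree_distribution(network)
    },
    stop("unknown network type '", net_type, "'", call. = FALSE))
  if (!is.null(network)) say(sprintf("network built: %d nodes, %d edges",
                                     igraph::vcount(network),
                                     igraph::ecount(network)))
  net_class <- grab("network_class",
                    if (net_type %in% c("ba", "edgelist"))
                      "heterogeneous" else "homogeneous")
  cfg <- sim_config(t_max = grab("t_max", 100), dt = grab("dt", 1),
                    replicates = grab("replicates", 1L), seed = seed,
                    newborn_mode = grab("newborn_mode", "SPES"),
                    model_variant = grab("model_variant", "SIR_star"))

  result <- switch(config$command,
    "r0" = basic_reproduction_number(params, dist, net_class),
    "threshold" = outbreak_threshold(params, dist, net_class),
    "meanfield" = {
      tr <- if (net_class == "heterogeneous")
        integrate_meanfield(params, dist = dist, config = cfg)
      else integrate_meanfield(params, k_mean = dist$mean_degree,
                               config = cfg)
      say("integration done")
      tr
    },
    "ctmc-steady" = {
      conn <- if (net_class == "heterogeneous") connectivity_ratio(dist)
      else dist$mean_degree
      Ncount <- as.integer(grab("N_chain", 100))
      spec <- chain_spec(Ncount, params, conn,
                         s0 = grab("s0", Ncount - 1L))
      stationary_distribution(spec)
    },
    "gillespie" = {
      conn <- if (net_class == "heterogeneous") connectivity_ratio(dist)
      else dist$mean_degree
      Ncount <- as.integer(grab("N_chain", 1000))
      i0 <- as.integer(grab("i0", 1L))
      spec <- chain_spec(Ncount, params, conn, s0 = Ncount - i0,
                         boundary = "absorbing")
      gillespie_run(spec, i0 = i0, t_max = cfg$t_max, seed = seed)
    },
    "netsim" = {
      if (is.null(network))
        stop("command 'netsim' needs an explicit network (er/ba/edgelist)",
             call. = FALSE)
      res <- replicate_average(network, params, cfg, cfg$replicates,
                               base_seed = seed)
      say(sprintf("%d replicate(s) completed", cfg$replicates))
      res
    },
    "sweep" = {
      if (is.null(network))
        stop("command 'sweep' needs an explicit network", call. = FALSE)
      res <- immunization_sweep(
        network, params,
        delta_grid = grab("delta_grid", seq(0, 1, 0.25)),
        beta_grid = grab("beta_grid", params$beta),
        config = cfg, n_reps = cfg$replicates, base_seed = seed)
      say("sweep completed")
      res
    },
    "sensitivity" = {
      pair <- grab("pair", "beta_gamma")
      sensitivity_grid(params, pair,
                       range1 = unlist(grab("range1", c(0.05, 0.5))),
                       range2 = unlist(grab("range2", c(0.01, 0.2))),
                       resolution = grab("resolution", 25L),
                       dist = dist, network_class = net_class)
    })

  out <- grab("out")
  if (!is.null(out)) {
    write_outputs(result, out, config$command)
    manifest <- list(command = config$command,
                     params = unclass(params), seed = seed,
                     network = net_type, network_class = net_class,
                     config = unclass(cfg),
                     options = config[setdiff(names(config),
                                              c("command", "out"))],
                     package_version =
                       as.character(utils::packageVersion("bisir")))
    jsonlite::write_json(manifest, paste0(out, "_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    say("outputs written to ", out)
  }
  invisible(result)
}

write_outputs <- function(result, out, command) {
  if (inherits(result, "epi_trajectory")) {
    write_trajectory_table(result, paste0(out, "_trajectory.csv"))
  } else if (inherits(result, "mcs_result")) {
    write_trajectory_table(result$trajectory, paste0(out, "_trajectory.csv"))
  } else if (inherits(result, "jump_trajectory")) {
    df <- data.frame(time = result$jump_times, s = result$s, i = result$i)
    utils::write.csv(df, paste0(out, "_jumps.csv"), row.names = FALSE)
  } else if (is.matrix(result)) {
    utils::write.csv(as.data.frame(result), paste0(out, "_grid.csv"))
  } else if (is.data.frame(result)) {
    utils::write.csv(result, paste0(out, "_table.csv"), row.names = FALSE)
  } else if (is.numeric(result) && length(result) > 1) {
    utils::write.csv(data.frame(i = seq_along(result), pi = result),
                     paste0(out, "_pi.csv"), row.names = FALSE)
  } else {
    writeLines(format(result, digits = 12), paste0(out, "_value.txt"))
  }
}
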
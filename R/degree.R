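#' Degree distributions and their moments
#'
#' A `degree_distribution` stores a finite degree support `degrees`, matching
#' probabilities `probs`, and the first two moments \eqn{\langle k\rangle} and
#' \eqn{\langle k^2\rangle}. The ratio \eqn{\langle k^2\rangle/\langle
#' k\rangle} is the connectivity factor through which network heterogeneity
#' enters every analytic expression of the model.
#'
#' @param degrees Strictly increasing non-negative integer degrees.
#' @param probs Probabilities matching `degrees`; must be non-negative and sum
#'   to 1 within `1e-12`.
#' @return An object of class `"degree_distribution"` with fields `degrees`,
#'   `probs`, `mean_degree`, `second_moment`.
#' @seealso [poisson_degree_distribution()], [degenerate_distribution()],
#'   [empirical_degree_distribution()]
#' @export
degree_distribution <- function(degrees, probs) {
  if (length(degrees) != length(probs) || length(degrees) == 0L)
    stop("'degrees' and 'probs' must be non-empty and of equal length",
         call. = FALSE)
  if (any(degrees < 0) || any(degrees != round(degrees)))
    stop("'degrees' must be non-negative integers", call. = FALSE)
  if (is.unsorted(degrees, strictly = TRUE))
    stop("'degrees' must be strictly increasing", call. = FALSE)
  if (any(probs < 0))
    stop("'probs' must be non-negative", call. = FALSE)
  if (abs(sum(probs) - 1) > 1e-12)
    stop("'probs' must sum to 1 (within 1e-12)", call. = FALSE)
  structure(
    list(degrees = as.numeric(degrees), probs = as.numeric(probs),
         mean_degree = sum(degrees * probs),
         second_moment = sum(degrees^2 * probs)),
    class = "degree_distribution"
  )
}

#' @export
print.degree_distribution <- function(x, ...) {
  cat(sprintf(
    "Degree distribution on %d degree classes [%g..%g]\n",
    length(x$degrees), min(x$degrees), max(x$degrees)))
  cat(sprintf("  <k> = %.6g   <k^2> = %.6g   <k^2>/<k> = %.6g\n",
              x$mean_degree, x$second_moment, connectivity_ratio(x)))
  invisible(x)
}

#' Connectivity factor of a degree distribution
#'
#' Returns \eqn{\langle k^2\rangle/\langle k\rangle}, the effective contact
#' multiplier on heterogeneous networks. For a degenerate (regular) support
#' this equals the degree itself, recovering the homogeneous description.
#'
#' @param dist A [degree_distribution()].
#' @return A positive scalar.
#' @export
connectivity_ratio <- function(dist) {
  stopifnot(inherits(dist, "degree_distribution"))
  if (dist$mean_degree == 0)
    stop("mean degree is zero; connectivity ratio undefined", call. = FALSE)
  dist$second_moment / dist$mean_degree
}

#' Truncated Poisson degree distribution
#'
#' Builds the Poisson degree law \eqn{p(k) \sim \xi^k e^{-\xi}/k!}
#' characteristic of Erdos-Renyi (homogeneous) networks, truncated to
#' `0..k_max` and renormalized. The truncation must leave out at most `1e-9`
#' of the probability mass.
#'
#' @param xi Positive Poisson parameter (the mean degree).
#' @param k_max Truncation degree; must cover mass >= 1 - 1e-9.
#' @return A [degree_distribution()] with `mean_degree` approximately `xi`.
#' @examples
#' d <- poisson_degree_distribution(4, 40)
#' d$mean_degree           # ~4
#' connectivity_ratio(d)   # ~5  (xi + 1 for a Poisson law)
#' @export
poisson_degree_distribution <- function(xi, k_max) {
  if (!is.numeric(xi) || length(xi) != 1L || xi <= 0)
    stop("'xi' must be a positive scalar", call. = FALSE)
  if (k_max < 0 || k_max != round(k_max))
    stop("'k_max' must be a non-negative integer", call. = FALSE)
  mass <- stats::ppois(k_max, xi)
  if (mass < 1 - 1e-9)
    stop(sprintf(
      "k_max = %d covers only %.12f of the Poisson(%g) mass (need >= 1 - 1e-9)",
      k_max, mass, xi), call. = FALSE)
  p <- stats::dpois(0:k_max, xi)
  degree_distribution(0:k_max, p / sum(p))
}

#' Degenerate (regular-network) degree distribution
#'
#' Point mass at a single degree `k`: every node has exactly `k` contacts, the
#' homogeneous limit in which \eqn{\langle k^2\rangle/\langle k\rangle = k}.
#'
#' @param k Positive integer degree.
#' @return A [degree_distribution()].
#' @export
degenerate_distribution <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k))
    stop("'k' must be a positive integer", call. = FALSE)
  degree_distribution(k, 1)
}

#' Empirical degree distribution of a contact network
#'
#' Observed degree frequencies of an undirected graph, used e.g. to measure
#' the connectivity factor of generated scale-free networks.
#'
#' @param network A [contact_network()] (or igraph object).
#' @return A [degree_distribution()] whose mean equals `2 * |E| / |V|`.
#' @export
empirical_degree_distribution <- function(network) {
  g <- as_contact_network(network)
  n <- igraph::vcount(g)
  if (n == 0L) stop("network has no nodes", call. = FALSE)
  deg <- igraph::degree(g)
  tab <- table(deg)
  ks <- as.integer(names(tab))
  o <- order(ks)
  degree_distribution(ks[o], as.numeric(tab)[o] / n)
}

#' Average degree from printed node and edge counts
#'
#' Handshake-lemma bookkeeping: the average degree of an undirected graph with
#' `n_nodes` nodes and `n_edges` edges is `2 * n_edges / n_nodes`. Useful for
#' checking the reported average degree of published network datasets without
#' access to the graphs themselves.
#'
#' @param n_nodes,n_edges Positive counts.
#' @return The average degree.
#' @examples
#' average_degree_from_counts(4039, 88234)   # ~43.69
#' @export
average_degree_from_counts <- function(n_nodes, n_edges) {
  if (n_nodes <= 0) stop("'n_nodes' must be positive", call. = FALSE)
  if (n_edges < 0) stop("'n_edges' must be non-negative", call. = FALSE)
  2 * n_edges / n_nodes
}
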
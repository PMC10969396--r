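#' Contact networks
#'
#' Contact structure for the Monte-Carlo simulator is an undirected simple
#' graph (no self-loops, no multi-edges), stored as an igraph object with
#' nodes implicitly labelled `0..n-1`. Any igraph graph is accepted where a
#' contact network is expected; it is simplified and stripped of direction on
#' the way in.
#'
#' @param edges Two-column matrix (or data.frame) of 0-based node ids, one
#'   undirected edge per row.
#' @param n Number of nodes; defaults to `max(edges) + 1`. Isolated nodes
#'   beyond the largest endpoint are kept when `n` is larger.
#' @return An igraph object of class `c("contact_network", "igraph")`.
#' @export
contact_network <- function(edges, n = NULL) {
  edges <- as.matrix(edges)
  if (length(edges) && (ncol(edges) != 2L || any(edges != round(edges)) ||
                        any(edges < 0)))
    stop("'edges' must be a two-column matrix of non-negative integer ids",
         call. = FALSE)
  if (is.null(n)) n <- if (length(edges)) max(edges) + 1 else 0
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, as.vector(t(edges)) + 1L)
  as_contact_network(g)
}

as_contact_network <- function(g) {
  if (!igraph::is_igraph(g))
    stop("expected an igraph object or contact_network", call. = FALSE)
  if (igraph::is_directed(g)) g <- igraph::as_undirected(g, mode = "collapse")
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  class(g) <- unique(c("contact_network", class(g)))
  g
}

#' Erdos-Renyi random contact network
#'
#' `G(n, p)` graph with `p = mean_degree / (n - 1)`, the standard homogeneous
#' benchmark whose degree distribution is asymptotically Poisson with mean
#' `mean_degree`. Reproducible given `seed`.
#'
#' @param n Number of nodes (>= 2).
#' @param mean_degree Target mean degree, in `(0, n - 1)`. Zero is allowed and
#'   yields an edgeless graph.
#' @param seed Integer seed.
#' @return A [contact_network()].
#' @export
generate_er <- function(n, mean_degree, seed = 1L) {
  if (n < 2) stop("'n' must be >= 2", call. = FALSE)
  p <- mean_degree / (n - 1)
  if (p < 0 || p > 1)
    stop(sprintf("mean_degree = %g gives invalid edge probability %g",
                 mean_degree, p), call. = FALSE)
  g <- with_seed(seed, igraph::sample_gnp(n, p, directed = FALSE))
  as_contact_network(g)
}

#' Barabasi-Albert scale-free contact network
#'
#' Preferential-attachment graph in which each new node attaches `m` edges to
#' existing nodes, producing a power-law degree tail; the heterogeneous
#' benchmark. The mean degree approaches `2 m` for large `n` (exactly
#' `2 m (n - m) / n` under this construction).
#'
#' @param n Number of nodes.
#' @param m Edges added per new node, `1 <= m < n`.
#' @param seed Integer seed.
#' @return A [contact_network()].
#' @export
generate_ba <- function(n, m, seed = 1L) {
  if (m < 1 || m >= n) stop("need 1 <= m < n", call. = FALSE)
  g <- with_seed(seed,
    igraph::sample_pa(n, m = m, directed = FALSE))
  as_contact_network(g)
}

# run expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# compressed adjacency (1-based CSR) for the C++ simulator
adjacency_csr <- function(g) {
  g <- as_contact_network(g)
  n <- igraph::vcount(g)
  adj <- igraph::as_adj_list(g, mode = "all")
  lens <- lengths(adj)
  list(neighbors = as.integer(unlist(adj, use.names = FALSE)),
       ptr = c(0L, cumsum(lens)), n = n)
}
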
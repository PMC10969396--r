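#' Disease-free equilibrium
#'
#' The equilibrium with no infection, which always exists: every degree class
#' settles at `S* = bN/d`, `I* = 0`, `R* = 0` (the susceptible density
#' balances birth inflow against natural death).
#'
#' @param params An [epi_params()] with `d > 0`.
#' @param dist Optional [degree_distribution()]; when supplied the equilibrium
#'   is laid out per degree class.
#' @return A list of class `"equilibrium_point"` with fields `kind`
#'   (`"disease_free"`), `Sk`, `Ik`, `Rk`, `theta`.
#' @export
disease_free_equilibrium <- function(params, dist = NULL) {
  params <- as_epi_params(params)
  if (params$d <= 0)
    stop("'d' must be > 0: no finite equilibrium without mortality",
         call. = FALSE)
  nk <- if (is.null(dist)) 1L else length(dist$degrees)
  sstar <- params$b * params$N / params$d
  structure(list(kind = "disease_free",
                 Sk = rep(sstar, nk), Ik = rep(0, nk), Rk = rep(0, nk),
                 theta = 0),
            class = "equilibrium_point")
}

#' @export
print.equilibrium_point <- function(x, ...) {
  cat(sprintf("%s equilibrium (theta = %g)\n",
              if (x$kind == "disease_free") "Disease-free" else "Endemic",
              x$theta))
  if (length(x$Sk) == 1L) {
    cat(sprintf("  S* = %g, I* = %g, R* = %g\n", x$Sk, x$Ik, x$Rk))
  } else {
    cat(sprintf("  %d degree classes; global (S*, I*, R*) not aggregated\n",
                length(x$Sk)))
  }
  invisible(x)
}

#' Self-consistency auxiliary function for the infected-edge fraction
#'
#' The endemic equilibrium requires the infected-edge fraction
#' \eqn{\Theta} to solve a self-consistency equation; the auxiliary function
#' \deqn{F(\Theta) = \Theta - \frac{1}{\langle k\rangle}\sum_k
#'   \frac{bN\beta(1-\delta)k^2 p(k)\,\Theta}
#'        {[d + \beta k(1-\delta)\Theta]\,[\gamma(1+\lambda)+d]}}
#' vanishes at the trivial root \eqn{\Theta = 0} and, precisely when R0 > 1,
#' at a unique nontrivial root in (0, 1). F is convex on \[0, 1\] (its second
#' derivative is positive), which guarantees uniqueness.
#'
#' @param theta Value(s) in `[0, 1]`.
#' @param params An [epi_params()] with `d > 0`.
#' @param dist A [degree_distribution()].
#' @return `F(theta)`, vectorized over `theta`.
#' @export
auxiliary_F <- function(theta, params, dist) {
  params <- as_epi_params(params)
  stopifnot(inherits(dist, "degree_distribution"))
  if (params$d <= 0) stop("'d' must be > 0", call. = FALSE)
  if (any(theta < 0 | theta > 1))
    stop("'theta' must lie in [0, 1]", call. = FALSE)
  k <- dist$degrees; p <- dist$probs
  be <- beta_eff(params)
  denom_rec <- gamma_eff(params) + params$d
  vapply(theta, function(th) {
    th - sum(params$b * params$N * be * k^2 * p * th /
               ((params$d + be * k * th) * denom_rec)) / dist$mean_degree
  }, numeric(1))
}

#' Solve for the endemic infected-edge fraction
#'
#' Finds the nontrivial root \eqn{\Theta^* \in (0, 1]} of [auxiliary_F()] by
#' bracketed bisection (no derivatives), or reports that none exists. A root
#' exists if and only if `F'(0) < 0`, which is equivalent to R0 > 1; since
#' `F(0) = 0`, `F(1) > 0` and F is convex, the root is unique and bisection on
#' `[eps, 1]` with `eps = 1e-12` is guaranteed to converge.
#'
#' @param params An [epi_params()] with `d > 0`.
#' @param dist A [degree_distribution()].
#' @param tol Bisection tolerance on `|F|` (default `1e-12`).
#' @return The root, or `NULL` when the system is sub- or exactly critical.
#' @export
solve_endemic_theta <- function(params, dist, tol = 1e-12) {
  params <- as_epi_params(params)
  stopifnot(inherits(dist, "degree_distribution"))
  if (params$d <= 0) stop("'d' must be > 0", call. = FALSE)
  # F'(0) = 1 - R0, so the sub/supercritical decision is exact
  r0 <- basic_reproduction_number(params, dist, "heterogeneous")
  if (r0 <= 1) return(NULL)
  lo <- 1e-12; hi <- 1
  flo <- auxiliary_F(lo, params, dist)
  fhi <- auxiliary_F(hi, params, dist)
  if (flo > 0) return(NULL)       # supercriticality too weak to register
  if (fhi <= 0) return(1)         # only reachable when bN >= gamma(1+lambda)+d
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    fm <- auxiliary_F(mid, params, dist)
    if (abs(fm) < tol) return(mid)
    if (fm < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Endemic equilibrium
#'
#' Per-degree-class equilibrium densities at the nontrivial infected-edge
#' fraction \eqn{\Theta^*}:
#' \deqn{S_k^* = \frac{bN}{d + \beta k(1-\delta)\Theta^*}, \quad
#'   I_k^* = \frac{bN\beta k\Theta^*(1-\delta)}
#'     {[d + \beta k\Theta^*(1-\delta)][\gamma(1+\lambda)+d]}, \quad
#'   R_k^* = \frac{\gamma(1+\lambda)}{d} I_k^*}
#' Returns `NULL` when no endemic state exists (R0 <= 1).
#'
#' @param params An [epi_params()] with `d > 0`.
#' @param dist A [degree_distribution()].
#' @return An `"equilibrium_point"` with `kind = "endemic"`, or `NULL`.
#' @export
endemic_equilibrium <- function(params, dist) {
  params <- as_epi_params(params)
  theta <- solve_endemic_theta(params, dist)
  if (is.null(theta)) return(NULL)
  k <- dist$degrees
  be <- beta_eff(params)
  bN <- params$b * params$N
  denom_k <- params$d + be * k * theta
  Sk <- bN / denom_k
  Ik <- bN * be * k * theta / (denom_k * (gamma_eff(params) + params$d))
  Rk <- gamma_eff(params) * Ik / params$d
  structure(list(kind = "endemic", Sk = Sk, Ik = Ik, Rk = Rk, theta = theta),
            class = "equilibrium_point")
}

# closed-form endemic infected-edge fraction for the scalar (homogeneous /
# degenerate-support) self-consistency equation; NULL when subcritical
homogeneous_endemic_theta <- function(params, k) {
  be <- beta_eff(params)
  if (be <= 0 || k <= 0) return(NULL)
  amp <- params$b * params$N * be * k / (gamma_eff(params) + params$d)
  theta <- (amp - params$d) / (be * k)
  if (theta <= 0) NULL else min(theta, 1)
}

#' Basic reproduction number
#'
#' Expected number of secondary infections caused by one infected individual
#' in a fully susceptible population at the demographic equilibrium:
#' \deqn{R_0 = \frac{bN\beta(1-\delta)}{d^2 + \gamma d(1+\lambda)} \times C}
#' with connectivity factor \eqn{C = \langle k^2\rangle/\langle k\rangle} on
#' heterogeneous networks and \eqn{C = \langle k\rangle} on homogeneous ones.
#' An epidemic can invade precisely when R0 > 1.
#'
#' @param params An [epi_params()] with `d > 0`.
#' @param dist A [degree_distribution()].
#' @param network_class `"homogeneous"` or `"heterogeneous"`.
#' @return R0 (non-negative scalar).
#' @export
basic_reproduction_number <- function(params, dist,
                                      network_class = c("heterogeneous",
                                                        "homogeneous")) {
  network_class <- match.arg(network_class)
  params <- as_epi_params(params)
  stopifnot(inherits(dist, "degree_distribution"))
  if (params$d <= 0)
    stop("'d' must be > 0: R0 diverges without mortality", call. = FALSE)
  conn <- if (network_class == "heterogeneous")
    connectivity_ratio(dist) else dist$mean_degree
  params$b * params$N * beta_eff(params) * conn /
    (params$d^2 + params$gamma * params$d * (1 + params$lambda))
}

#' Outbreak threshold on the infection rate
#'
#' The critical per-contact infection rate \eqn{\beta_c} at which R0 = 1:
#' \deqn{\beta_c = \frac{d^2 + \gamma d(1+\lambda)}{bN(1-\delta)}
#'   \times \frac{\langle k\rangle}{\langle k^2\rangle}}
#' (homogeneous analogue with \eqn{1/\langle k\rangle}). Infection rates above
#' the threshold produce an outbreak. Since
#' \eqn{\langle k^2\rangle/\langle k\rangle \ge \langle k\rangle},
#' heterogeneity always lowers the threshold.
#'
#' @inheritParams basic_reproduction_number
#' @return `beta_c > 0`.
#' @export
outbreak_threshold <- function(params, dist,
                               network_class = c("heterogeneous",
                                                 "homogeneous")) {
  network_class <- match.arg(network_class)
  params <- as_epi_params(params)
  stopifnot(inherits(dist, "degree_distribution"))
  if (params$d <= 0) stop("'d' must be > 0", call. = FALSE)
  if (params$delta >= 1)
    stop("'delta' = 1 shuts off transmission: threshold infinite",
         call. = FALSE)
  if (params$b <= 0)
    stop("'b' = 0 empties the population: threshold infinite", call. = FALSE)
  conn <- if (network_class == "heterogeneous")
    connectivity_ratio(dist) else dist$mean_degree
  (params$d^2 + params$gamma * params$d * (1 + params$lambda)) /
    (params$b * params$N * (1 - params$delta) * conn)
}

#' Outbreak summary
#'
#' Bundles R0, the outbreak threshold, the endemic infected-edge fraction (if
#' any) and the resulting regime classification. The regime is reported as
#' `"critical"` when `|R0 - 1| <= 1e-9`.
#'
#' @inheritParams basic_reproduction_number
#' @return A list of class `"outbreak_summary"` with fields `R0`, `beta_c`
#'   (`Inf` when `delta = 1` or `b = 0`), `endemic_theta` (`NULL` if absent)
#'   and `regime`.
#' @export
outbreak_summary <- function(params, dist,
                             network_class = c("heterogeneous",
                                               "homogeneous")) {
  network_class <- match.arg(network_class)
  params <- as_epi_params(params)
  r0 <- basic_reproduction_number(params, dist, network_class)
  bc <- if (params$delta >= 1 || params$b <= 0) Inf
  else outbreak_threshold(params, dist, network_class)
  theta <- if (network_class == "heterogeneous")
    solve_endemic_theta(params, dist)
  else homogeneous_endemic_theta(params, dist$mean_degree)
  regime <- if (abs(r0 - 1) <= 1e-9) "critical"
  else if (r0 > 1) "supercritical" else "subcritical"
  structure(list(R0 = r0, beta_c = bc, endemic_theta = theta,
                 regime = regime, network_class = network_class),
            class = "outbreak_summary")
}

#' @export
print.outbreak_summary <- function(x, ...) {
  cat(sprintf("Outbreak summary (%s network)\n", x$network_class))
  cat(sprintf("  R0 = %.6g  (%s)\n", x$R0, x$regime))
  cat(sprintf("  outbreak threshold beta_c = %.6g\n", x$beta_c))
  if (!is.null(x$endemic_theta))
    cat(sprintf("  endemic infected-edge fraction theta* = %.6g\n",
                x$endemic_theta))
  else cat("  no endemic equilibrium (disease-free only)\n")
  invisible(x)
}

#' R0 sensitivity grid over a parameter pair
#'
#' Evaluates the basic reproduction number on a rectangular grid over one of
#' the parameter pairs `(beta, gamma)`, `(delta, lambda)` or `(b, d)`, holding
#' the remaining parameters fixed. Useful for mapping which interventions move
#' the system across the R0 = 1 outbreak boundary.
#'
#' @param params Baseline [epi_params()].
#' @param pair One of `"beta_gamma"`, `"delta_lambda"`, `"b_d"`.
#' @param range1,range2 Length-2 ranges for the first/second parameter of the
#'   pair; must stay inside each parameter's valid domain.
#' @param resolution Grid points per axis (default 25).
#' @param dist A [degree_distribution()].
#' @param network_class `"homogeneous"` or `"heterogeneous"`.
#' @return A `resolution x resolution` matrix of R0 values; rows index the
#'   first parameter (dimnames carry the grid values).
#' @export
sensitivity_grid <- function(params,
                             pair = c("beta_gamma", "delta_lambda", "b_d"),
                             range1, range2, resolution = 25L, dist,
                             network_class = c("heterogeneous",
                                               "homogeneous")) {
  pair <- match.arg(pair)
  network_class <- match.arg(network_class)
  params <- as_epi_params(params)
  fields <- switch(pair,
                   beta_gamma = c("beta", "gamma"),
                   delta_lambda = c("delta", "lambda"),
                   b_d = c("b", "d"))
  v1 <- seq(range1[1], range1[2], length.out = resolution)
  v2 <- seq(range2[1], range2[2], length.out = resolution)
  out <- matrix(NA_real_, resolution, resolution,
                dimnames = list(signif(v1, 8), signif(v2, 8)))
  for (i in seq_along(v1)) for (j in seq_along(v2)) {
    pl <- unclass(params)
    pl[[fields[1]]] <- v1[i]
    pl[[fields[2]]] <- v2[j]
    p2 <- do.call(epi_params, pl)   # revalidates: out-of-domain range errors
    out[i, j] <- basic_reproduction_number(p2, dist, network_class)
  }
  out
}
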
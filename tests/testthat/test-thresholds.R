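test_that("disease-free equilibrium is bN/d in every degree class", {
  p <- ref_params()
  eq <- disease_free_equilibrium(p)
  expect_equal(eq$Sk, 1.6)
  expect_equal(eq$Ik, 0)
  expect_equal(eq$theta, 0)
  p0 <- epi_params(0, 0.05, 0.1, 0.1, 0, 0)
  expect_equal(disease_free_equilibrium(p0)$Sk, 0)
  p2 <- epi_params(0.16, 0.05, 0.175, 0.05, 0.2, 0.3)
  expect_equal(disease_free_equilibrium(p2)$Sk, 3.2)  # linear in b
  expect_error(disease_free_equilibrium(epi_params(0.1, 0, 0.1, 0.1, 0, 0)),
               "d")
})

test_that("auxiliary function has the predicted endpoint behaviour", {
  p <- ref_params()
  d4 <- degenerate_distribution(4)
  expect_equal(auxiliary_F(0, p, d4), 0)
  expect_gt(auxiliary_F(1, p, d4), 0)
  # F(1) > 0 rests on the premise bN < gamma (1 + lambda) + d
  for (pp in draw_params(30, seed = 3)) {
    expect_equal(auxiliary_F(0, pp, d4), 0)
    if (pp$b * pp$N < pp$gamma * (1 + pp$lambda) + pp$d)
      expect_gt(auxiliary_F(1, pp, d4), 0)
  }
  expect_lt(abs(auxiliary_F(theta_star_degenerate(p, 4), p, d4)), 1e-3)
})

test_that("auxiliary function is convex on [0, 1]", {
  d <- degree_distribution(c(1, 3, 4, 8), c(0.2, 0.3, 0.3, 0.2))
  set.seed(7)
  for (pp in draw_params(10, seed = 7)) {
    a <- runif(1, 0, 0.5); b <- runif(1, 0.5, 1)
    expect_lte(auxiliary_F((a + b) / 2, pp, d),
               mean(auxiliary_F(c(a, b), pp, d)) + 1e-12)
  }
})

test_that("endemic theta matches the closed form and exists iff R0 > 1", {
  p <- ref_params()
  d4 <- degenerate_distribution(4)
  expect_equal(solve_endemic_theta(p, d4), theta_star_degenerate(p, 4),
               tolerance = 1e-9)
  expect_null(solve_endemic_theta(epi_params(0.08, 0.05, 0, 0.05, 0.2, 0.3),
                                  d4))
  dists <- list(d4, poisson_degree_distribution(4, 60),
                degree_distribution(c(1, 2, 5, 9), c(0.4, 0.3, 0.2, 0.1)))
  for (pp in draw_params(100, seed = 5)) {
    dist <- dists[[sample.int(3, 1)]]
    r0 <- basic_reproduction_number(pp, dist, "heterogeneous")
    if (abs(r0 - 1) <= 1e-6) next
    th <- solve_endemic_theta(pp, dist)
    if (r0 > 1) {
      expect_false(is.null(th))
      expect_gt(th, 0)
      expect_lte(th, 1)
    } else {
      expect_null(th)
    }
  }
})

test_that("endemic equilibrium is self-consistent and annihilates the RHS", {
  p <- ref_params()
  d4 <- degenerate_distribution(4)
  eq <- endemic_equilibrium(p, d4)
  expect_equal(infected_edge_fraction(eq$Ik, d4), eq$theta,
               tolerance = 1e-9)
  expect_equal(eq$Ik, theta_star_degenerate(p, 4), tolerance = 1e-6)
  expect_null(endemic_equilibrium(epi_params(0.08, 0.05, 0, 0.05, 0.2, 0.3),
                                  d4))
  dist <- poisson_degree_distribution(6, 80)
  eqh <- endemic_equilibrium(p, dist)
  rhs <- heterogeneous_rhs(list(Sk = eqh$Sk, Ik = eqh$Ik, Rk = eqh$Rk),
                           p, dist)
  expect_lt(max(abs(unlist(rhs))), 1e-8)
})

test_that("reproduction numbers match hand evaluations", {
  p <- ref_params()
  d4 <- degenerate_distribution(4)
  expect_equal(basic_reproduction_number(p, d4, "homogeneous"),
               0.0448 / 0.00575)
  expect_equal(basic_reproduction_number(
    epi_params(0.08, 0.05, 0.175, 0.05, 1, 0.3), d4, "homogeneous"), 0)
  # connectivity ratio 10: two-point law with <k> = 6.4, <k^2> = 64
  d10 <- degree_distribution(c(4, 16), c(0.8, 0.2))
  expect_equal(connectivity_ratio(d10), 10)
  expect_equal(basic_reproduction_number(p, d10, "heterogeneous"),
               0.0448 / 0.00575 / 4 * 10)
  # homogeneous and heterogeneous coincide exactly on a point mass
  expect_identical(basic_reproduction_number(p, d4, "homogeneous"),
                   basic_reproduction_number(p, d4, "heterogeneous"))
})

test_that("outbreak threshold inverts the reproduction number", {
  p <- ref_params()
  d4 <- degenerate_distribution(4)
  expect_equal(outbreak_threshold(p, d4, "homogeneous"), 0.00575 / 0.256)
  expect_error(outbreak_threshold(
    epi_params(0.08, 0.05, 0.175, 0.05, 1, 0.3), d4), "delta")
  expect_error(outbreak_threshold(
    epi_params(0, 0.05, 0.175, 0.05, 0.2, 0.3), d4), "'b'")
  het <- poisson_degree_distribution(4, 60)
  expect_lte(outbreak_threshold(p, het, "heterogeneous"),
             outbreak_threshold(p, het, "homogeneous"))
  for (pp in draw_params(50, seed = 9)) {
    bc <- outbreak_threshold(pp, het, "heterogeneous")
    pc <- epi_params(pp$b, pp$d, bc, pp$gamma, pp$delta, pp$lambda)
    expect_equal(basic_reproduction_number(pc, het, "heterogeneous"), 1,
                 tolerance = 1e-12)
  }
})

test_that("sensitivity grids have the analytic monotonicity structure", {
  p <- ref_params()
  d4 <- degenerate_distribution(4)
  g_dl <- sensitivity_grid(p, "delta_lambda", c(0, 0.9), c(0, 1),
                           resolution = 10, dist = d4,
                           network_class = "homogeneous")
  expect_true(all(apply(g_dl, 2, diff) < 0))   # R0 strictly decreasing in delta
  g_bg <- sensitivity_grid(p, "beta_gamma", c(0.05, 0.5), c(0.01, 0.2),
                           resolution = 8, dist = d4,
                           network_class = "homogeneous")
  ratios <- g_bg[-1, ] / g_bg[-nrow(g_bg), ]    # R0 linear in beta
  expect_lt(max(abs(sweep(ratios, 1, ratios[, 1], `-`))), 1e-12)
  het <- poisson_degree_distribution(4, 60)
  g_hom <- sensitivity_grid(p, "b_d", c(0.02, 0.2), c(0.02, 0.2),
                            resolution = 6, dist = het,
                            network_class = "homogeneous")
  g_het <- sensitivity_grid(p, "b_d", c(0.02, 0.2), c(0.02, 0.2),
                            resolution = 6, dist = het,
                            network_class = "heterogeneous")
  expect_true(all(g_het >= g_hom))
  expect_error(sensitivity_grid(p, "delta_lambda", c(0, 1.5), c(0, 1),
                                resolution = 4, dist = d4), "delta")
})

test_that("outbreak summary classifies regimes consistently", {
  p <- ref_params()
  d4 <- degenerate_distribution(4)
  s <- outbreak_summary(p, d4, "homogeneous")
  expect_equal(s$regime, "supercritical")
  expect_false(is.null(s$endemic_theta))
  sub <- outbreak_summary(epi_params(0.08, 0.05, 0.002, 0.05, 0.2, 0.3), d4,
                          "homogeneous")
  expect_equal(sub$regime, "subcritical")
  expect_null(sub$endemic_theta)
  off <- outbreak_summary(epi_params(0.08, 0.05, 0.175, 0.05, 1, 0.3), d4)
  expect_identical(off$beta_c, Inf)
})
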
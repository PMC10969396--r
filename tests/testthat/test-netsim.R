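test_that("graph generators hit their target degrees and are reproducible", {
  g <- generate_er(1000, 4, seed = 3)
  p <- 4 / 999
  se <- 3 * sqrt(4 / 1000 * (1 - p))
  expect_lt(abs(mean(igraph::degree(g)) - 4), se)
  expect_identical(igraph::as_edgelist(generate_er(200, 3, seed = 7)),
                   igraph::as_edgelist(generate_er(200, 3, seed = 7)))
  expect_equal(igraph::ecount(generate_er(100, 0, seed = 1)), 0)
  expect_error(generate_er(100, 150, seed = 1), "probability")

  b <- generate_ba(1000, 2, seed = 5)
  expect_equal(mean(igraph::degree(b)), 2 * 2 * (1000 - 2) / 1000,
               tolerance = 0.01)
  db <- empirical_degree_distribution(b)
  expect_gt(connectivity_ratio(db), db$mean_degree)  # heavy tail
  expect_identical(igraph::as_edgelist(generate_ba(300, 2, seed = 9)),
                   igraph::as_edgelist(generate_ba(300, 2, seed = 9)))
  expect_error(generate_ba(5, 5, seed = 1), "m < n")
})

test_that("full vaccination and edgeless graphs stop transmission", {
  g <- generate_er(300, 4, seed = 2)
  p1 <- epi_params(0, 0, 0.3, 0.1, 1, 0, N = 1)
  cfg <- sim_config(t_max = 60, dt = 1, model_variant = "SIR_star")
  r <- mcs_run(g, p1, cfg, initial_infected = 5, seed = 6)
  expect_equal(max(r$counts[, 2] + r$counts[, 3]), 5)   # only the seeds
  expect_equal(r$counts[nrow(r$counts), 3], 5)          # all recovered
  empty <- contact_network(matrix(0, 0, 2), n = 300)
  p0 <- epi_params(0, 0, 0.3, 0.1, 0, 0, N = 1)
  r2 <- mcs_run(empty, p0, cfg, initial_infected = 5, seed = 6)
  expect_equal(max(r2$counts[, 2] + r2$counts[, 3]), 5)
})

test_that("counts are conserved exactly without births and deaths", {
  g <- generate_er(400, 4, seed = 8)
  p <- epi_params(0, 0, 0.2, 0.05, 0.1, 0.2, N = 1)
  for (variant in c("SIR_star", "SIS_star")) {
    cfg <- sim_config(t_max = 50, dt = 1, model_variant = variant)
    r <- mcs_run(g, p, cfg, seed = 4)
    expect_true(all(rowSums(r$counts[, 1:3]) == 400))
  }
})

test_that("immunization couples monotonically under shared random draws", {
  g <- generate_er(400, 4, seed = 5)
  cfg_p <- sim_config(t_max = 60, dt = 1, model_variant = "SIR")
  cfg_s <- sim_config(t_max = 60, dt = 1, model_variant = "SIR_star")
  # recovery off: per-step infected-set nesting is exact
  a <- mcs_run(g, epi_params(0, 0, 0.175, 0, 0, 0), cfg_p, seed = 9,
               record_states = TRUE)
  b <- mcs_run(g, epi_params(0, 0, 0.175, 0, 0.4, 0), cfg_s, seed = 9,
               record_states = TRUE)
  for (row in seq_len(nrow(a$states)))
    expect_true(all(b$states[row, ] != 1L | a$states[row, ] == 1L))
  # with recovery: cumulative ever-infected count dominance, several seeds
  for (s in 1:5) {
    a <- mcs_run(g, epi_params(0, 0, 0.175, 0.05, 0, 0), cfg_p, seed = s)
    b <- mcs_run(g, epi_params(0, 0, 0.175, 0.05, 0.4, 0), cfg_s, seed = s)
    expect_true(all(b$counts[, 2] + b$counts[, 3] <=
                      a$counts[, 2] + a$counts[, 3]))
  }
})

test_that("replicate averaging is deterministic and reduces variance", {
  g <- generate_er(300, 4, seed = 1)
  p <- ref_params()
  cfg <- sim_config(t_max = 40, dt = 1, model_variant = "SIR_star")
  one <- replicate_average(g, p, cfg, n_reps = 1, base_seed = 20)
  direct <- mcs_run(g, p, cfg, seed = 21)
  expect_identical(one$trajectory$I, direct$trajectory$I)
  again <- replicate_average(g, p, cfg, n_reps = 10, base_seed = 20)
  twice <- replicate_average(g, p, cfg, n_reps = 10, base_seed = 20)
  expect_identical(again$trajectory, twice$trajectory)
  # averaging k replicates shrinks the sd of the step-15 infected density
  step_I <- function(n_reps, base) {
    replicate_average(g, p, cfg, n_reps = n_reps,
                      base_seed = base)$trajectory$I[16]
  }
  set.seed(1)
  v1 <- stats::var(vapply(1:30, function(b) step_I(1, 1000 + b), 1))
  v8 <- stats::var(vapply(1:30, function(b) step_I(8, 2000 + 10 * b), 1))
  expect_lt(v8, v1)
})

test_that("epidemic metrics summarize peaks and tails", {
  tr <- epi_trajectory(0:9, S = rep(0.5, 10), I = seq(0.5, 0.05, -0.05),
                       R = rep(0, 10))
  m <- epidemic_metrics(tr)
  expect_equal(m[["peak_I"]], 0.5)
  expect_equal(m[["t_peak"]], 0)
  expect_equal(m[["I_inf"]], 0.05)
  g <- generate_er(500, 6, seed = 3)
  # supercritical SIS without demography reaches a stable endemic plateau
  p <- epi_params(0, 0, 0.2, 0.1, 0.2, 0.3, N = 1)
  cfg <- sim_config(t_max = 150, dt = 1, model_variant = "SIS_star")
  res <- replicate_average(g, p, cfg, n_reps = 20, base_seed = 40,
                           initial_infected = 25)
  tail_I <- res$trajectory$I[136:151]
  expect_gt(mean(tail_I), 0.2)
  expect_lt(stats::sd(tail_I) / mean(tail_I), 0.1)
  # SIR infections die out over a long horizon
  cfg_sir <- sim_config(t_max = 300, dt = 1, model_variant = "SIR_star")
  res_sir <- mcs_run(g, p, cfg_sir, initial_infected = 25, seed = 2)
  expect_lt(epidemic_metrics(res_sir)[["I_inf"]], 1e-6)
})

test_that("immunization sweeps respond monotonically to vaccination", {
  p <- ref_params()
  cfg <- sim_config(t_max = 60, dt = 1, model_variant = "SIR_star")
  tab <- immunization_sweep(network_factory = function(s)
    generate_er(400, 4, s),
    params = p, delta_grid = c(0, 0.5, 1), beta_grid = 0.3,
    config = cfg, n_reps = 30, base_seed = 3, initial_infected = 4)
  expect_equal(nrow(tab), 3)
  # delta = 1: epidemic size is exactly the seeds, S(inf) untouched by disease
  expect_true(all(diff(tab$R_inf) < 0))
  expect_true(all(diff(tab$S_inf) > 0))
})
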
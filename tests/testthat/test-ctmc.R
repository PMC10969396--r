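# small reference chain: N = 2, s0 = 1, beta = 0.2, gamma = 0.1, conn = 1
ref_chain <- function(boundary = "reflected") {
  chain_spec(2, epi_params(0, 0, 0.2, 0.1, 0, 0, N = 2), 1,
             s0 = 1, boundary = boundary)
}

rand_chain <- function(N, seed, s0 = N - 1) {
  set.seed(seed)
  p <- epi_params(0, 0, runif(1, 0.05, 0.5), runif(1, 0.02, 0.3),
                  runif(1, 0, 0.9), runif(1, 0, 1), N = N)
  chain_spec(N, p, runif(1, 1, 12), s0 = s0)
}

test_that("transition rates match their defining formulas", {
  sp <- ref_chain()
  expect_equal(infection_rate(sp, 1, 1), 0.1)
  expect_equal(infection_rate(sp, 1, 0), 0)
  expect_equal(infection_rate(sp, 0, 1), 0)
  expect_error(infection_rate(sp, 2, 1), "<= N")
  p <- epi_params(0, 0, 0.1, 0.1, 0, 0, N = 10)
  expect_equal(recovery_rate(chain_spec(10, p, 4), 1), 0.1)
  p2 <- epi_params(0, 0, 0.1, 0.05, 0, 0.3, N = 20)
  expect_equal(recovery_rate(chain_spec(20, p2, 4), 10), 0.65)
  # heterogeneous connectivity rescales the infection rate linearly
  sp4 <- chain_spec(50, p, 4)
  sp10 <- chain_spec(50, p, 10)
  expect_equal(infection_rate(sp10, 20, 5) / infection_rate(sp4, 20, 5),
               10 / 4)
})

test_that("transition probability matrix is the printed first-order form", {
  sp <- ref_chain()
  P <- transition_probability_matrix(sp, 1)
  expect_equal(P, rbind(c(0.9, 0.1), c(0.2, 0.8)))
  expect_equal(rowSums(P), c(1, 1))
  Ph <- transition_probability_matrix(sp, 0.5)
  expect_equal(Ph[1, 2], P[1, 2] / 2)
  expect_equal(Ph[2, 1], P[2, 1] / 2)
  expect_error(transition_probability_matrix(sp, 10), "dt")
  for (s in 1:5) {
    spc <- rand_chain(30, s)
    dt <- 0.1 / max(abs(diag(generator_matrix(spc))))
    Pr <- transition_probability_matrix(spc, dt)
    expect_equal(rowSums(Pr), rep(1, 30))
    expect_true(all(Pr >= 0 & Pr <= 1))
  }
})

test_that("generator rows sum to zero and match (P - I)/dt", {
  for (s in 1:5) {
    sp <- rand_chain(25, s + 10)
    Q <- generator_matrix(sp)
    expect_lt(max(abs(rowSums(Q))), 1e-12)
    expect_true(all(diag(Q) <= 0))
    off <- Q; diag(off) <- 0
    expect_true(all(off >= 0))
    dt <- 0.5 / max(abs(diag(Q)))
    P <- transition_probability_matrix(sp, dt)
    expect_lt(max(abs((P - diag(25)) / dt - Q)), 1e-12)
  }
})

test_that("stationary distribution: recursion, closed form, null space agree", {
  sp <- ref_chain()
  expect_equal(stationary_distribution(sp), c(2, 1) / 3)
  set.seed(99)
  for (rep in 1:12) {
    N <- sample(3:100, 1)
    s0 <- if (rep %% 3 == 0) sample(seq_len(N - 1), 1) else N - 1
    sp <- rand_chain(N, rep + 500, s0 = s0)
    pi_r <- stationary_distribution(sp, "recursion")
    pi_c <- stationary_distribution(sp, "closed_form")
    pi_n <- stationary_distribution(sp, "nullspace")
    expect_equal(sum(pi_r), 1, tolerance = 1e-12)
    expect_lt(max(abs(pi_r - pi_c)), 1e-10)
    expect_lt(max(abs(pi_r - pi_n)), 1e-10)
    # detailed balance pi_i rho = pi_{i+1} mu across the whole chain
    i <- seq_len(N - 1)
    rho <- infection_rate(sp, pmax(sp$s0 - i + 1, 0), i)
    mu <- recovery_rate(sp, i + 1)
    expect_equal(pi_r[i + 1] * mu, pi_r[i] * rho, tolerance = 1e-12)
  }
  p0 <- epi_params(0, 0, 0.2, 0, 0, 0, N = 5)
  expect_error(stationary_distribution(chain_spec(5, p0, 2)), "mu")
})

test_that("embedded chain matrix has the printed boundary and interior rows", {
  sp <- ref_chain()
  R <- embedded_chain_matrix(sp)
  expect_equal(R, rbind(c(0, 1), c(1, 0)))
  p <- epi_params(0, 0, 0.3, 0.1, 0, 0, N = 6)
  sp6 <- chain_spec(6, p, 4)
  R6 <- embedded_chain_matrix(sp6)
  expect_equal(rowSums(R6), rep(1, 6))
  expect_true(all(diag(R6) == 0))
  # equals jump-probability normalization of the generator off-diagonals
  Q <- generator_matrix(sp6)
  off <- Q; diag(off) <- 0
  expect_equal(R6[2:5, ], off[2:5, ] / rowSums(off[2:5, ]))
  # rho = mu at a state -> both exits 0.5: at i = 3 with s0 = 5, N = 6,
  # conn = 2 the rates are rho = (3/6)*0.1*3*2 = 0.3 = mu = 0.1*3
  sym <- chain_spec(6, epi_params(0, 0, 0.1, 0.1, 0, 0, N = 6), 2)
  Rs <- embedded_chain_matrix(sym)
  expect_equal(Rs[3, 2], 0.5)
  expect_equal(Rs[3, 4], 0.5)
  # a dead interior state is reported
  pz <- epi_params(0, 0, 0, 0, 0, 0, N = 4)
  expect_error(embedded_chain_matrix(chain_spec(4, pz, 2)), "no exit")
})

test_that("recovery-only Gillespie runs are pure death chains", {
  p <- epi_params(0, 0, 0.2, 0.1, 1, 0.5, N = 30)
  sp <- chain_spec(30, p, 4, s0 = 25, boundary = "absorbing")
  r <- gillespie_run(sp, i0 = 5, t_max = Inf, seed = 4)
  expect_equal(length(r$jump_times) - 1L, 5L)
  expect_true(r$absorbed)
  expect_true(all(diff(r$i) == -1))
  expect_true(all(diff(r$jump_times) > 0))
  # absorption time for i0 = 1 is exponential(gamma (1 + lambda))
  rate <- 0.1 * 1.5
  times <- vapply(1:2000, function(s) {
    run <- gillespie_run(sp, i0 = 1, t_max = Inf, seed = s)
    run$jump_times[2]
  }, numeric(1))
  expect_lt(abs(mean(times) - 1 / rate), 3 / rate / sqrt(2000))
  ks <- suppressWarnings(stats::ks.test(times, stats::pexp, rate))
  expect_gt(ks$p.value, 0.01)
})

test_that("transmission-dominant Gillespie runs exhaust the susceptibles", {
  p <- epi_params(0, 0, 5, 0, 0, 0, N = 40)
  sp <- chain_spec(40, p, 4, s0 = 30, boundary = "absorbing")
  r <- gillespie_run(sp, i0 = 5, t_max = Inf, seed = 8)
  expect_equal(r$i[length(r$i)], 35L)
  expect_equal(r$s[length(r$s)], 0L)
  expect_false(r$absorbed)
  expect_error(gillespie_run(sp, i0 = 0, t_max = 10), "i0")
  expect_identical(gillespie_run(sp, 5, 10, seed = 3),
                   gillespie_run(sp, 5, 10, seed = 3))
})

test_that("ensemble averaging conserves mass and recovers single runs", {
  p <- epi_params(0, 0, 0.3, 0.08, 0.1, 0.2, N = 50)
  sp <- chain_spec(50, p, 4, s0 = 45, boundary = "absorbing")
  run <- gillespie_run(sp, i0 = 5, t_max = 20, seed = 12)
  ens <- ensemble_average(list(run), run$jump_times, 50)
  expect_equal(ens$S * 50, run$s)
  expect_equal(ens$I * 50, run$i)
  runs <- gillespie_ensemble(sp, 5, 20, replicates = 20, seed = 31)
  grid <- seq(0, 20, 0.5)
  ens2 <- ensemble_average(runs, grid, 50)
  expect_lt(max(abs(ens2$S + ens2$I + ens2$R - 1)), 1e-12)
  expect_error(ensemble_average(list(), grid, 50), "non-empty")
})
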
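# Reference parameter set used throughout (the supercritical study setting)
ref_params <- function(N = 1) {
  epi_params(b = 0.08, d = 0.05, beta = 0.175, gamma = 0.05,
             delta = 0.2, lambda = 0.3, N = N)
}

# closed-form endemic infected-edge fraction for a degenerate distribution
# at degree k: solves the scalar self-consistency equation by hand
theta_star_degenerate <- function(p, k) {
  be <- p$beta * (1 - p$delta)
  amp <- p$b * p$N * be * k / (p$gamma * (1 + p$lambda) + p$d)
  (amp - p$d) / (be * k)
}

# random valid parameter draws for property-style loops
draw_params <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    epi_params(b = runif(1, 0.01, 0.2), d = runif(1, 0.01, 0.2),
               beta = runif(1, 0.01, 0.5), gamma = runif(1, 0.01, 0.3),
               delta = runif(1, 0, 0.95), lambda = runif(1, 0, 1)))
}

star_graph <- function() {
  contact_network(cbind(0, 1:4))
}

cycle_graph <- function(n = 4) {
  contact_network(cbind(0:(n - 1), c(1:(n - 1), 0)))
}
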
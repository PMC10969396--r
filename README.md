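# bisir

Epidemic modelling with **bidirectional immunization** on contact networks:
an SIR (and SIS) model in which vaccination lowers the infection rate of
susceptibles by a factor $(1-\delta)$ while clinical treatment raises the
recovery rate of infecteds by a factor $(1+\lambda)$, with demographic
turnover through a birth rate $b$ and a natural death rate $d$. The package
is aimed at infectious-disease modellers who want the analytic, Markov-chain
and network Monte-Carlo views of one model in a single, seeded, reproducible
toolbox.

On a network with degree distribution $p(k)$ the mean-field equations per
degree class $k$ are

$$
\frac{dS_k}{dt} = bN - dS_k - \beta(1-\delta)k S_k\Theta,\quad
\frac{dI_k}{dt} = \beta(1-\delta)k S_k\Theta - \gamma(1+\lambda)I_k - dI_k,\quad
\frac{dR_k}{dt} = \gamma(1+\lambda)I_k - dR_k,
$$

with $\Theta = \frac{1}{\langle k\rangle}\sum_k k\,p(k)\,I_k$ the
infected-edge fraction. The basic reproduction number is

$$
R_0 = \frac{bN\beta(1-\delta)}{d^2+\gamma d(1+\lambda)}\cdot C,
$$

where the connectivity factor $C$ is $\langle k\rangle$ on homogeneous and
$\langle k^2\rangle/\langle k\rangle$ on heterogeneous networks; the
outbreak threshold $\beta_c$ solves $R_0 = 1$.

Three layers expose the same model:

* **Analytic** — equilibria, the self-consistency equation for the endemic
  $\Theta^*$, $R_0$, $\beta_c$, and $R_0$ sensitivity grids.
* **Continuous-time Markov chain** — a finite birth–death chain over the
  infected count with infection rate $(s/N)\beta i(1-\delta)C$ and recovery
  rate $\gamma i(1+\lambda)$: transition probability and generator matrices,
  stationary distribution (three independent routes), embedded jump chain,
  exact Gillespie sampling.
* **Network Monte-Carlo** — synchronous discrete-time contagion on explicit
  graphs (Erdős–Rényi, Barabási–Albert, or user edge lists) with a compiled
  inner loop, replicate averaging, epidemic metrics and immunization sweeps.

## Worked example

```r
library(bisir)

p <- epi_params(b = 0.08, d = 0.05, beta = 0.175, gamma = 0.05,
                delta = 0.2, lambda = 0.3)
m <- bisir_model(p, dist = degenerate_distribution(4),
                 network_class = "homogeneous")
summary(m)
#> Outbreak summary (homogeneous network)
#>   R0 = 7.7913  (supercritical)
#>   outbreak threshold beta_c = 0.0224609
#>   endemic infected-edge fraction theta* = 0.606366
#> Disease-free equilibrium (theta = 0)
#>   S* = 1.6, I* = 0, R* = 0
```

$R_0 \approx 7.79 \gg 1$: at these rates the epidemic invades, the critical
infection rate is $\beta_c \approx 0.022$ (an order of magnitude below
$\beta = 0.175$), and the endemic infected density settles near 0.606. The
disease-free susceptible level $b/d = 1.6$ reflects raw (unrenormalized)
densities. Integrating the mean-field system confirms the analytic endemic
level:

```r
tr <- simulate(m, method = "meanfield", config = sim_config(t_max = 500, dt = 5))
tail(tr, 1)
#>     time         S         I         R
#> 101  500 0.2053571 0.6063665 0.7882764
```

A stochastic counterpart on an explicit graph:

```r
g <- generate_er(2000, 4, seed = 42)
net <- bisir_model(p, network = g, network_class = "homogeneous")
res <- simulate(net, nsim = 100, method = "network", seed = 100,
                config = sim_config(t_max = 100, dt = 1,
                                    model_variant = "SIR_star"))
res$peak_I
#> [1] 0.006735
```

With one initial infected, a per-step death probability of 0.05 and
non-participating newborns, network epidemics are marginal — the
replicate-mean peak is a fraction of a percent — yet comparing variants at
equal seeds shows the immunization effect cleanly (the plain-SIR peak is
roughly three times higher).

The command-line wrapper mirrors the package functions:

```sh
./exec/bisir r0 --k 4 --network degenerate --network_class homogeneous
#> 7.791304348
```

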
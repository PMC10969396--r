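---
title: "Modelling epidemics with bidirectional immunization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling epidemics with bidirectional immunization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bisir)
```

## The model

`bisir` implements an SIR (and SIS) compartmental model on contact networks
in which two interventions act simultaneously and in opposite directions:

* **vaccination** of susceptibles multiplies the per-contact infection rate
  $\beta$ by $(1-\delta)$, with $\delta \in [0, 1]$ the effective vaccination
  rate;
* **clinical treatment** of infecteds multiplies the recovery rate $\gamma$
  by $(1+\lambda)$, with $\lambda \ge 0$ the treatment-derived enhancement.

Demography enters through a birth rate $b$ (inflow of susceptibles, a
fraction of the population scale $N$ per unit time) and a natural — not
disease-induced — death rate $d$ applied to every compartment. On a
homogeneous network with mean degree $\langle k\rangle$ the mean-field
equations are

$$
\frac{dS}{dt} = bN - dS - \beta(1-\delta)\langle k\rangle SI,\qquad
\frac{dI}{dt} = \beta(1-\delta)\langle k\rangle SI - \gamma(1+\lambda)I - dI,
$$
$$
\frac{dR}{dt} = \gamma(1+\lambda)I - dR.
$$

On heterogeneous networks the population is stratified by degree: each class
$k$ carries densities $(S_k, I_k, R_k)$, coupled through the infected-edge
fraction $\Theta = \frac{1}{\langle k\rangle}\sum_k k\,p(k)\,I_k$ — the
probability that an edge leaving a susceptible points at an infected node.
Network structure enters every analytic expression through a single scalar,
the **connectivity factor**: $\langle k\rangle$ for homogeneous networks,
$\langle k^2\rangle/\langle k\rangle$ for heterogeneous ones. Since
$\langle k^2\rangle/\langle k\rangle \ge \langle k\rangle$ (with equality
only for regular graphs), heterogeneity always amplifies spread.

Setting the degree-class derivatives to zero gives the disease-free
equilibrium $(bN/d, 0, 0)$, which always exists, and a self-consistency
equation for $\Theta$ whose auxiliary function $F(\Theta)$
(`auxiliary_F()`) satisfies $F(0) = 0$ and is convex on $[0,1]$. A
nontrivial root — an endemic state — exists precisely when $F'(0) < 0$,
i.e. when the basic reproduction number

$$
R_0 = \frac{bN\beta(1-\delta)}{d^2 + \gamma d(1+\lambda)}\cdot C,
\qquad C \in \{\langle k\rangle,\ \langle k^2\rangle/\langle k\rangle\}
$$

exceeds one. Inverting $R_0 = 1$ for $\beta$ gives the outbreak threshold
$\beta_c$ (`outbreak_threshold()`). Note $R_0$ diverges as $d \to 0$; the
package refuses $d = 0$ in the analytic layer rather than extrapolating.

At the reference rate set used throughout the documentation
($b = 0.08$, $d = 0.05$, $\beta = 0.175$, $\gamma = 0.05$, $\delta = 0.2$,
$\lambda = 0.3$) and $\langle k\rangle = 4$:

```{r analytic}
p <- epi_params(0.08, 0.05, 0.175, 0.05, 0.2, 0.3)
m <- bisir_model(p, dist = degenerate_distribution(4),
                 network_class = "homogeneous")
summary(m)
```

## Numerical choices in the analytic layer

The endemic root is found by bracketed bisection on $[10^{-12}, 1]$ to
$|F| < 10^{-12}$; convexity guarantees uniqueness and makes
derivative-based methods unnecessary. Two boundary subtleties are handled
explicitly:

* the textbook argument for $F(1) > 0$ assumes
  $bN < \gamma(1+\lambda) + d$; for parameter sets violating it the root may
  formally lie beyond 1 and is clamped at $\Theta^* = 1$ (per-degree
  densities are not normalized quantities when $b/d \ne 1$, so this regime
  is reachable);
* the regime is reported as "critical" when $|R_0 - 1| \le 10^{-9}$, since
  exact criticality is measure-zero in floating point.

Degree distributions are finite truncated supports. The Poisson constructor
(`poisson_degree_distribution()`) truncates at `k_max` and renormalizes,
requiring coverage of all but $10^{-9}$ of the mass, which keeps the moment
identities $\langle k\rangle \approx \xi$,
$\langle k^2\rangle/\langle k\rangle \approx \xi + 1$ accurate to well below
any tolerance used in the tests.

## Newborns: SPES versus SNES

Whether newly born susceptibles take part in transmission changes the
long-run outcome qualitatively. With participating newborns (**SPES**) the
inflow refuels the susceptible pool and a supercritical system settles at
the endemic equilibrium. With non-participating newborns (**SNES**) births
accumulate in a passive pool $P$ with $dP/dt = bN - dP$ that is *counted*
in the reported $S(t)$ but contributes nothing to the infection term; only
the disease-free outcome then exists. This bookkeeping keeps the total
population law $T(t) = bN/d + (T_0 - bN/d)e^{-dt}$ identical in the two
modes — the integrators are tested against that closed form at $10^{-6}$.

Reported densities are *raw* (not renormalized by the current population),
which is why $S(t)$ may exceed 1 early in a SPES run: the population total
relaxes towards $b/d = 1.6$ at the reference rates. Renormalizing by $T(t)$
would be the alternative convention; the package does not do it.

Mean-field integration uses `deSolve::ode` (`lsoda`, rtol $10^{-8}$, atol
$10^{-10}$) with an adaptive internal step and a uniform reporting grid of
spacing `dt`, so mean-field, chain and network outputs are directly
comparable. Default initial condition: $I(0) = 1/N$ (applied as a density in
every degree class, so the global infected density is $1/N$), $R(0) = 0$,
$S(0) = 1 - I(0)$.

## The continuous-time Markov chain layer

The count-level model is a birth–death chain over the infected count with
exactly two events: infection at rate
$\rho(s, i) = (s/N)\beta i(1-\delta)C$ and recovery at rate
$\mu(s, i) = \gamma i(1+\lambda)$. Births and deaths do not appear — the
chain is a pure two-event process, which is also why its simulator pairs
with the SNES (no replenishment) reading of the mean-field model.

Two boundary conventions coexist deliberately:

* the **matrix artifacts** — first-order transition probability matrix,
  generator, stationary distribution, embedded chain — live on the
  *reflected* chain over $i \in \{1..N\}$, in which state $i = 1$ has no
  recovery exit and the rate arguments follow the literal indexing
  $\rho(s_0 - i + 1, i)$, $\mu(s_0, i)$ with $s_0$ a fixed parameter
  (default $N-1$). When $s_0 < N - 1$ the factor $s_0 - i + 1$ reaches zero
  at $i = s_0 + 1$; the rate is taken as 0 there (no susceptibles left), so
  the stationary distribution is exactly zero beyond $i = s_0 + 1$.
* the **Gillespie simulator** uses the *absorbing* chain with a live
  susceptible count: $i = 0$ terminates the epidemic.

The stationary distribution is computed three independent ways — the
local-balance recursion $\pi_{i+1}/\pi_i = \rho(s_0-i+1,i)/\mu(s_0,i+1)$
(in log space, so long chains cannot overflow), the closed-form product
expression through $s_0!/(i\,(s_0-i+1)!)$, and a null-space solve of the
generator — and the test suite requires three-way agreement to $10^{-10}$
for random chains up to $N = 100$. Detailed balance
$\pi_i\rho = \pi_{i+1}\mu$ and the row-sum identities (generator rows sum
to 0, probability and embedded-chain rows to 1) are asserted as exact
structural properties.

Waiting times in the simulator are drawn by the inverse transform
$-\log(U)/(\rho+\mu)$ on R's seeded generator; ensembles assign one seed
per replicate (`seed + r`), making every ensemble bit-reproducible.

### Validating the simulator

Two checks anchor the stochastic layer. First, for a recovery-only chain
($\delta = 1$) the absorption time from one infected is exponential with
rate $\gamma(1+\lambda)$; the empirical mean over $10^4$ runs must sit
within three standard errors of $1/\gamma(1+\lambda)$, and a
Kolmogorov–Smirnov comparison against the exponential law is part of the
unit suite. Second, a 500-replicate ensemble at $N = 2000$ is compared with
the reduced ($b = d = 0$) mean-field solution in sup-norm at 0.03. That
comparison is meaningful only from a matched macroscopic initial state:
with a single initial infected the random takeoff delay smears the ensemble
mean by an order of magnitude more than the binomial sampling error, so
both sides are started from a 1% infected fraction ($i_0 = 20$,
$I(0) = 0.01$), under which the measured sup-norm is about $3\times10^{-3}$.

## The network Monte-Carlo layer

`mcs_run()` simulates the contagion on an explicit graph in synchronous
discrete steps computed from the step-start configuration:

* a susceptible with $m$ infected living neighbours is infected with
  probability $1 - (1-\beta(1-\delta))^m$ — the standard per-neighbour
  independent-transmission convention, which degenerates to
  $\beta(1-\delta)$ for a single infected neighbour;
* an infected recovers with probability $\min(1, \gamma(1+\lambda))$
  (the rate is used directly as a per-step probability; the alternative
  $1 - e^{-\gamma(1+\lambda)}$ differs by under 0.3% at the reference
  rates);
* every living node dies with probability $\min(1, d)$; a dead node's edges
  die with it (it no longer transmits or counts);
* newborns, `round(b n)` per step, join the passive pool
  $P \leftarrow P(1-d) + \mathrm{round}(bn)$ — deterministic decay rather
  than binomial thinning, mirroring the mean-field SNES pool and keeping
  the random stream independent of pool bookkeeping. Densities are
  normalized by the initial node count.

Vaccination is a *transmissibility* reduction applied to all susceptibles,
not a removal of a $\delta$-fraction of nodes — matching how $\delta$
enters every analytic expression. The plain `SIR`/`SIS` variants force
$\delta = \lambda = 0$; the starred variants apply both rates. Two uniforms
are consumed per node per step in fixed order regardless of status, so runs
with equal seeds are coupled draw-for-draw across parameterizations: with
recovery switched off this makes the vaccinated epidemic's infected set
provably nested inside the unvaccinated one step by step. Once recovery
desynchronizes the two runs, strict per-step nesting can fail, and the
suite instead asserts dominance of the cumulative ever-infected count. The
inner loop is compiled (Rcpp) and uses R's RNG, so seeding semantics are
those of base R.

Graphs come from igraph: `generate_er()` draws $G(n, p)$ with
$p = \langle k\rangle/(n-1)$; `generate_ba()` grows a preferential
attachment graph with $m = \mathrm{round}(\langle k\rangle/2)$ edges per
node, whose slight mean-degree deficit $2m(n-m)/n$ is reported, not
corrected. User graphs load from plain edge lists (`read_edge_list()`),
with self-loops and duplicates dropped.

## What the simulated comparisons show — and what they do not

The headline stochastic quantities reproduced by `scripts/acceptance.R`
compare plain and immunized variants on an ER graph with $n = 5000$,
$\langle k\rangle = 4$, the reference rates, one initial infected node and
200 replicates:

* the **peak infected density** of SIR versus SIR\* (relative reduction, %),
  over a 100-step horizon;
* the **steady-state infected density** of SIS versus SIS\*, taken as the
  mean over the final 10% of an 80-step horizon.

Two features of the study conditions matter for interpreting these. First,
a per-step death probability of 0.05 gives nodes a mean lifetime of 20
steps, so the living graph thins rapidly and epidemics are marginal rather
than massive; relative reductions from immunization are correspondingly
large (observed ≈ 65–75% for the peak and ≈ 75–80% for the steady
density). Second, with non-participating newborns both SIS variants decay
towards zero infected in absolute terms; it is the *ratio* of their
quasi-steady levels, not the levels themselves, that is stable, which fixes
the 80-step horizon: late enough for the transient to pass, early enough
that the mean infected count retains signal over 200 replicates.

The synthetic generators emulate the degree structure of homogeneous (ER /
Poisson) and heterogeneous (BA / power-law) contact patterns, but not
degree–degree correlations, clustering, communities or temporal contacts of
real networks. Passing tests therefore demonstrate internal consistency of
the three layers (analytic, chain, network) and the qualitative claims —
heterogeneity amplifies spread, immunization suppresses it — under those
idealized structures; they do not calibrate the model to any real epidemic.

## Problem sizes used by the test suite

The suite exercises the analytic layer at full precision (500-draw
property loops), the chain layer at $N \le 100$ for matrix identities and
$N = 2000$ with 500 replicates for the ensemble comparison, and the network
layer at $n$ between 300 and 2000 with up to 200 replicates; the
acceptance script runs the network comparisons at the full $n = 5000$ with
200 replicates. These sizes were chosen so that stochastic checks sit well
inside their tolerance bands at a few minutes of total compute.

## Known limitations

* Stability (Lyapunov) classification of the equilibria is out of scope;
  only existence and location are computed.
* No disease-induced mortality parameter exists: $d$ is identical across
  compartments by model construction.
* Degree correlations, weighted or directed contacts, and transient
  (matrix-exponential) chain distributions are not modelled.
* The discrete-time recovery convention ($\min(1, \gamma(1+\lambda))$)
  saturates for $\gamma(1+\lambda) > 1$; rates that large are outside the
  intended regime.
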
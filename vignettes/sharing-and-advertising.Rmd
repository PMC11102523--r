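---
title: "Sharing, advertising, and the spread of viral videos: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sharing, advertising, and the spread of viral videos: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viralsir)
```

## The model

`viralsir` treats the audience of an online video like the population of
an epidemic. *Susceptible* individuals have not seen the video;
*infected* individuals have watched it and actively share it; *recovered*
individuals have watched it and stopped sharing for good. Writing
$S(t), I(t), R(t)$ for the compartment sizes and $N$ for a fixed
reference population size, the dynamics are

$$
\begin{aligned}
S' &= -\frac{\beta I S}{N} - \frac{\gamma N^2}{N + I} + bN,\\
I' &= \frac{\beta_1 I S}{N} + \frac{\gamma N^2}{N + I} - \alpha I,\\
R' &= \frac{(\beta - \beta_1) I S}{N} + \alpha I.
\end{aligned}
$$

Two features distinguish this from a textbook SIR model. First, a
contact between a sharer and a susceptible has two possible outcomes: the
susceptible starts sharing (rate $\beta_1$) or watches and immediately
loses interest (rate $\beta - \beta_1$, with $\beta > \beta_1$). The
ratio $\beta_1/\beta$ is therefore the probability that a new viewer
becomes a sharer, and it is the single most interpretable quantity a fit
produces. Second, the *advertising function* $\gamma N^2/(N + I)$ models
a marketing budget that is spent hardest when the video has no organic
momentum: it equals $\gamma N$ when $I = 0$ and decays to zero as
sharers proliferate. New users join the susceptible pool at rate $bN$,
so the head count obeys the linear first integral
$S + I + R = N_0 + bNt$.

### Parameters

| Parameter  | Meaning                                   | Units   | Benchmark value |
|------------|-------------------------------------------|---------|-----------------|
| `beta`     | contact rate sharer–susceptible           | per day | 0.4             |
| `beta1`    | conversion-to-sharer part of `beta`       | per day | 0.1             |
| `alpha`    | rate of losing interest in sharing        | per day | 0.03            |
| `b`        | new-user inflow per head of `N`           | per day | 0.02            |
| `gamma`    | advertising rate                          | per day | 0.002           |

The "benchmark" column is the configuration used throughout the
package's examples and tests, with $N = 10^4$, $S_0 = 9900$,
$I_0 = 100$: an audience of ten thousand, one percent of whom share the
video spontaneously at launch. All theory operates in the regime
$\alpha > b > \gamma$ (flagged as `theory_regime` on the parameter
object): interest is lost faster than users arrive, and advertising on
its own cannot saturate the inflow of new users.

## Equilibrium and stability

With $N$ constant, $R$ is slaved to $S + I$ and the dynamics close on
the $(S, I)$ plane. Eliminating $S$ from the steady-state equations
leaves the quadratic $f(I) = \alpha I^2 + (\alpha - \tfrac{\beta_1}{\beta} b)NI
- (1 - \tfrac{\beta_1}{\beta})\gamma N^2 - \tfrac{\beta_1}{\beta} bN^2$,
whose constant term is negative whenever $\beta_1 < \beta$ — so a unique
positive root $I^*$ always exists and no root-bracketing logic is
needed. The implementation takes the explicit root
$I^* = (-B + \sqrt{B^2 - 4AC})/2A$ (the discriminant is provably
positive, and is asserted rather than branched on) and recovers $S^*$
from the susceptible nullcline. In the theory regime the root satisfies
$0 < I^* < N$ and $(b - \gamma/2)N/\beta < S^* < (\alpha -
\gamma/2)N/\beta_1$, and the Jacobian's characteristic polynomial
$\lambda^2 + \bar B \lambda + \bar C$ has $\bar B, \bar C > 0$, making
$(S^*, I^*)$ stable — in fact globally attracting on the open positive
quadrant. The package exposes all of these as computed certificates
(`interior_equilibrium()`, `stability_report()`) and the test suite
verifies them two independent ways: bisection of $f$ against the closed
form, and long-horizon integration from random interior starts.

Outside the regime ($\alpha \le b$ or $b \le \gamma$) the equilibrium
functions refuse to answer rather than extrapolate: nothing is proven
there, and a silently returned root of the quadratic may not be an
attractor of anything.

```{r equilibrium}
p <- model_params(beta = 0.4, beta1 = 0.1, alpha = 0.03, b = 0.02, gamma = 0.002)
interior_equilibrium(p, N = 1e4)
```

A sweep of `gamma` (`equilibrium_vs_gamma()`) shows the managerial
trade-off: more advertising always lowers $S^*$ and raises $I^*$, but
the eventual viewership rate responds non-monotonically, so there is an
interior optimum in advertising spend.

## Attribution: what did advertising buy?

Two complementary answers are provided, and they are deliberately not
interchangeable.

**Direct conversions.** Along a trajectory, the cumulative outflows of
susceptibles through sharing and through advertising are
$n_S(T) = \int_0^T \beta I S / N \, dt$ and
$n_A(T) = \int_0^T \gamma N^2/(N + I)\, dt$
(`cumulative_fluxes()`, composite trapezoid on the output grid; use
`dt` of 0.1 day or finer). They satisfy the susceptible balance
$S(T) - S(0) + n_S + n_A = bNT$, which the tests enforce to
$10^{-4} N$. In the benchmark configuration, $n_S(100) \approx 26229$
and $n_A(100) \approx 1670$: direct advertising conversions look
negligible.

**Full lineages.** The direct count is misleading, because each
advertising recruit goes on to convert others through sharing. The
agent-based model tracks this: every viewer carries an immutable lineage
label — Type A if their infection chain roots in one of the initially
seeded sharers (Group A), Type B if it roots in an agent recruited by
advertising (Group B) — and a generation number (1 for roots, parent's
generation + 1 for contact conversions). In the same benchmark, Type B
viewers outnumber Type A viewers in essentially every realization:
advertising drives most of the eventual audience *indirectly*, even
though its direct conversions are two orders of magnitude fewer than
sharing's.

## The agent-based scheme

A realization holds an explicit agent array (state, lineage,
generation) and advances in steps of length $\tau$ (default 1 day, the
resolution of daily view counts) with four phases whose intensities are
frozen at start-of-step counts $O(t), P(t)$:

1. **Contact.** $P(t)\,M/N$ attempts (stochastically rounded), where $M$
   is the current agent count. Each attempt draws a sharer uniformly
   *with* replacement — a busy sharer can convert several people in a
   day — and targets are drawn uniformly from the whole current
   population, distinct within the step, since an agent watches the
   video at most once. A susceptible target converts with probability
   $\tau\beta$, becoming a sharer with probability $\beta_1/\beta$ and a
   recovered viewer otherwise, inheriting the sharer's lineage. The
   $M/N$ attempt scaling needs a word: a uniformly drawn target is
   susceptible with probability $O/M$, while the mean-field flux divides
   by the *fixed* reference $N$. Since arrivals triple $M$ over a
   100-day benchmark run, leaving the attempt count at $P(t)$ would
   depress the contact rate by that same factor and the ensemble would
   drift far from the ODE; scaling attempts by $M/N$ makes the expected
   conversion flux exactly $\tau \beta P O / N$ at any population size.
2. **Advertising.** $K \sim \mathrm{Poisson}(\tau \gamma N^2 / (N +
   P(t)))$ — Poisson rather than deterministic rounding so the one-step
   mean is exact and the variance natural — capped at the available
   susceptibles, who become sharers with lineage B, generation 1.
3. **Arrivals.** $\lfloor bN\tau + \text{carry} \rfloor$ new
   susceptibles; the fractional carry makes cumulative inflow match
   $bNt$ exactly.
4. **Recovery.** Each agent infected at the start of the step recovers
   with probability $\tau\alpha$.

Expected one-step increments match $\tau$ times the ODE right-hand side
(verified by Monte-Carlo over thousands of single steps), so ensemble
means converge to a *discrete-time* mean field. At $\tau = 1$ that
discrete flow differs from the continuous ODE by a forward-Euler-type
bias of about 3% of $N$ at the benchmark transient's steepest point;
this is the floor below which the ensemble-vs-ODE distance cannot fall,
however many realizations are averaged. The convergence test therefore
checks that growing the ensemble does not *increase* the distance
(beyond repeat-to-repeat spread), rather than demanding a strict
decrease toward zero. Runs are deterministic given a seed; ensembles
derive per-member child seeds from the master seed by a single draw of
`sample.int`, so any member can be regenerated in isolation.

## Calibration

Observed data enter as daily view counts $g_i$ (day 0 first). Their
prefix sums $\langle R \rangle_i$ estimate the recovered class — everyone
who has watched the video by day $i$ — and are compared with the model's
$R(t_i, \theta)$ through the normalized cost

$$
\mathrm{Er}(\theta) = \frac{\sum_i \left[\langle R\rangle_i - R(t_i, \theta)\right]^2}
     {(\max_i \langle R\rangle_i)^2 \; t_{\max}},
$$

which is invariant to rescaling both series by a common factor, so
errors are comparable across videos of very different popularity. The
model is started from $S_0 = 2\times 10^9$ (platform scale) and
$I_0 = 100$ by default, with $R_0 = 0$ and $N = S_0 + I_0$.

`fit_views()` minimizes Er with Nelder–Mead simplex search. The design
choices that matter:

* **Constraints by construction.** The search runs in unconstrained
  coordinates: $\log \beta, \log \alpha, \log \gamma, \log b$ and
  $\mathrm{logit}(\beta_1/\beta)$. All rates stay positive and
  $0 < \beta_1 < \beta$ holds at every simplex vertex, so the optimizer
  never sees a penalty wall.
* **Free set.** All five rates are free by default; `b` can be pinned
  (set `free_params` to the four others) when the user-growth rate is
  known or assumed.
* **Multistart.** The simplex is initialization-sensitive, so up to
  `n_restarts` (default 5) searches run from multiplicatively jittered
  starts under a fixed seed, stopping early after an essentially perfect
  fit ($\mathrm{Er} < 10^{-12}$) or two consecutive restarts landing in
  the same basin (no improvement beyond 1%). Fits are deterministic
  given series, configuration and seed.
* **Cost integration.** Inside the objective the ODE is solved with
  `lsoda` at `rtol` $10^{-8}$, `atol` $10^{-4}$ individuals — far below
  one view — because the cost is evaluated thousands of times and the
  higher-order Runge–Kutta driver used for trajectory output would
  dominate runtime without changing the fourth significant digit of any
  fitted rate.

## Synthetic data

`generate_view_series()` provides ground-truth series for validating the
whole pipeline: integrate the model, form daily views
$G(i) = R(i) - R(i-1)$, and perturb each day multiplicatively with
mean-preserving log-normal noise $g_i = G(i)\exp(\varepsilon_i -
\sigma^2/2)$, $\varepsilon_i \sim N(0, \sigma^2)$ (a Poisson option
exists for small-count series). Log-normal noise was chosen because
daily views span orders of magnitude across a video's life, so additive
or constant-variance noise would be wildly unrealistic at one end of the
series. The default synthetic audience is $S_0 = 10^6$ — far below
platform scale — so that full five-parameter recovery experiments run in
seconds; the dynamics are scale-free in $N$ apart from the advertising
level $\gamma N$, so nothing about the fit changes qualitatively.

What the generator does *not* emulate: weekday seasonality,
recommendation-driven shocks, rebounds in interest, or the slow decay of
the epidemic analogy itself over multi-year horizons. Passing recovery
tests on synthetic data therefore demonstrates that the estimator is
consistent and well-conditioned under the model's own assumptions — not
that the model captures every feature of real view-count series.

At $\sigma = 0$ a five-parameter fit from a start displaced ±50% in
every rate recovers all rates to well under 1% with Er at round-off
scale; at $\sigma = 0.05$ the median error across seeds stays under 5%,
comfortably within the 20% the test suite demands.

## Numerical choices and degenerate inputs

* Trajectories use adaptive Dormand–Prince 4(5) at `rtol` $10^{-8}$,
  `atol` $10^{-10} N_0$; the linear first integral is conserved to
  $10^{-6} N_0$ on all fixture runs and is checked, not assumed.
* The advertising term is evaluated as the bounded form
  $\gamma N^2/(N+I)$ everywhere, which is finite on the whole closed
  positive quadrant — the $\gamma N / I$ expression that appears in
  phase-plane arguments diverges on the $S$-axis and is never used.
  Inside the right-hand side the formula is applied directly (without
  the user-facing domain validation) because adaptive solvers probe
  trial states with $I$ a hair below zero.
* Quadratures interpolate the trajectory at the requested horizon $T$
  and close the trapezoid range exactly there, so a horizon between grid
  points loses no flux.
* All-zero view series are refused by the cost (its normalization is
  undefined), as are horizons outside a trajectory's range and
  equilibrium queries outside the theory regime.
* Fixture problem sizes: benchmark runs use $N = 10^4$ and 100 days;
  ensembles use 20 realizations (200 for convergence probes); recovery
  experiments use $S_0 = 10^6$ and 200 days. These are the scales at
  which every quantitative claim in the tests was computed.

## Known limitations

The constant-$N$ model is the analysis target; the growing-population
fraction system is exposed as a right-hand side
(`rhs_fractions()`, `simulate_fractions()`) with *no* equilibrium or
stability support — its fixed points solve a cubic and none of the
certificates here transfer. Attribution at real platform scale
($2\times 10^9$ agents) is out of reach for the agent-based model and
out of scope; the ODE integrals cover that regime. The calibration
reports point estimates only — no uncertainty quantification is
attempted, and none should be inferred from restart scatter.
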
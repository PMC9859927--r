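---
title: "Targeted vaccination in multi-group SIR models: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted vaccination in multi-group SIR models: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vaxalloc)
```

## The model

`vaxalloc` studies how to allocate a constrained vaccine supply across the
subgroups of a heterogeneous population during an SIR epidemic. The
population is divided into $n$ groups (age bands, risk classes, ...), and
each group $i$ into six compartments: susceptible, infected and recovered,
each split by vaccination status — $S_i, I_i, R_i$ (unvaccinated) and
$S^V_i, I^V_i, R^V_i$ (vaccinated). All quantities are population
fractions; group sizes $N_i$ normally sum to 1.

Transmission couples every infector/infectee vaccination combination
through four $n \times n$ rate matrices: $\beta^1$ (unvaccinated to
unvaccinated), $\beta^2$ (vaccinated infector), $\beta^3$ (vaccinated
susceptible) and $\beta^4$ (both vaccinated); entry $(i,j)$ is transmission
from group $j$ to group $i$. Recovery rates are $\mu^1_i$ (unvaccinated)
and $\mu^2_i$ (vaccinated). A *weakly protective* vaccine satisfies
$\beta^1 \ge \beta^2$, $\beta^3 \ge \beta^4$ elementwise and
$\mu^1 \le \mu^2$; the constructor enforces these orderings.

Vaccination is a control: group $i$ receives doses at rate $U_i(t)$, with
cumulative doses $W_i(t) = \int_0^t U_i$. Doses are given at random to the
*not-yet-vaccinated* members of a group, so the flow of susceptibles into
$S^V_i$ is

$$\frac{U_i(t)\,S_i}{N_i - W_i(t)},$$

not the more common $U_i S_i$ form (which corresponds to wasting doses on
the already-vaccinated). The denominator has a removable singularity when a
group is fully vaccinated; `model_derivative()` clamps the transfer to zero
once $N_i - W_i < 10^{-12} N_i$, which implements the singular-limit
convention without dividing by a vanishing headroom.

The quantity minimised is the weighted count of infections over the whole
epidemic,

$$H(U) = \sum_i p_i\left(R_i(\infty) + \kappa_i R^V_i(\infty)\right),$$

with per-infection costs $p_i$ (1 to count infections, a case fatality
ratio to count deaths) and a vaccinated-cost multiplier $\kappa_i \le 1$.
`objective_H()` subtracts initially recovered individuals so that an
epidemic that never takes off has cost exactly zero; in all the shipped
examples $R(0) = 0$ and this is invisible.

## Policies and supply constraints

Feasible policies satisfy $\sum_i U_i(t) \le A(t)$ (administration
capacity) and $\sum_i W_i(t) \le B(t)$ (cumulative supply), with $B$
non-decreasing. The package represents $A$ as a step function and $B$ as a
continuous piecewise-linear function, and policies as piecewise-constant
rate matrices with finite support. Three consequences drive the design:

* `cumulative_doses()` is exact (closed-form piecewise-linear integration),
  so feasibility checking and the policy constructions below involve no
  quadrature error. Arbitrary smooth policies can be approximated on a
  user-chosen grid, but every optimal construction used here is bang-bang,
  so exactness holds where it matters.
* `chi_rate()` computes the fastest administrable rate
  $\chi(t)$: the rate cap $A(t)$ while cumulative capacity
  $\int_0^t A$ remains below the available supply $B(t)$, and
  $\min(A(t), B'(t))$ once supply binds, using the right-hand derivative
  of $B$ at kinks.
* `prioritized_policy()` realizes the bang-bang principle: vaccinate at
  rate $\chi(t)$, filling groups in a stated priority order up to
  per-group caps, so the total administered equals
  $\min(\int_0^t \chi,\ \text{total cap})$ — the cumulative form of the
  supply identity. (Two printed variants of that identity equate a rate to
  a cumulative quantity or use max in place of min; both are internally
  inconsistent, and the cumulative min form is the one consistent with the
  constructions it supports.)

`build_tilde_policy()` implements the *vulnerable-first swap*: given any
policy $U$, redirect its total rate to group 1 until $\varepsilon$ doses
have flowed in total, then let the other groups resume their original
schedules (doses originally destined for group 1 after the switch are
dropped). The switch time is solved exactly within a breakpoint interval.
The swap never exceeds the original total rate, so feasibility is
inherited, and the asymptotic theory says it beats the original policy for
every sufficiently small vulnerable-group size.

## The two-group crossover diagnostic

`two_group_example()` builds the canonical illustration: a small,
vulnerable, non-infectious group 1 (size $\varepsilon$, cost
$1/\varepsilon$) and a large, infectious, invulnerable group 2 (size 1,
cost $p^*$), with unvaccinated transmission matrix
$\begin{pmatrix}1&2\\2&4\end{pmatrix}$, vaccine effectiveness multipliers
$\chi$ (infection blocking) and $\rho$ (transmission blocking), unit
recovery rates, $I^*$ initial infections in group 2, administration rate
cap 1 and total supply 1.

One printed form of this example's supply cap reads $B(t)=\max(t,1)$,
under which the supply constraint never binds and every group could
eventually be vaccinated; the surrounding argument, however, uses
$B(\infty) = N_2 = 1$ ("group 2 is the only group that is vaccinated").
The package therefore uses the linear ramp $B(t) = \min(t, 1)$, which
makes that statement true and under which the priority constructions
reproduce the two printed policies exactly: infectious-first
$U = (0,\ \mathbf{1}_{t\le 1})$ and its swap
$\tilde U = (\mathbf{1}_{t \le \min(1,\varepsilon)},\
\mathbf{1}_{\varepsilon < t \le 1})$.

`epsilon_star()` locates the crossover
$\varepsilon^* = \inf(\{\varepsilon : H(\tilde U) > H(U)\} \cup \{1\})$ by
simulating both policies on a 25-point log grid over
$[10^{-3}, 1]$ and bisecting (20 steps, geometric midpoint) the first
bracket where the sign of $H(\tilde U) - H(U)$ changes. The underlying set
need not be an interval; the reported value is the infimum of the
grid-resolved set, and if the swap wins everywhere the diagnostic is
capped at 1 with `capped = TRUE`. If the swap already loses at the
smallest grid point, that grid point is reported (the grid floor is the
resolution limit of the diagnostic). With the default settings
($I^\ast=0.01$, $p^\ast=1$, $\chi=\rho=0.5$) the crossover lands near
$\varepsilon^\ast \approx 0.10$.

## Final size and the small-supply linearization

Once dosing has stopped, the model is an ordinary $2n$-group SIR system:
stack the unvaccinated compartments in slots $1..n$ and the vaccinated
ones in $n+1..2n$, with block transmission matrix
$\beta' = \begin{pmatrix}\beta^1 & \beta^2\\ \beta^3 & \beta^4\end{pmatrix}$,
recovery $\mu' = (\mu^1, \mu^2)$ and costs $p' = (p, \kappa p)$
(`stack_parameters()`). The classical final-size relation then closes the
epidemic:

$$S_i(\infty) = S_i(0)\,
  \exp\!\Big(-\sum_k \tfrac{\beta'_{ik}}{\mu'_k}\,(R_k(\infty)-R_k(0))\Big),
  \qquad R_i(\infty) = S_i(0)+I_i(0)+R_i(0)-S_i(\infty).$$

`solve_final_size()` iterates this map from the attack-maximal side
($S = 0$), which converges to the root the ODE dynamics realize, with
adaptive damping as a safety net and a $10^{-12}$ residual target. Slots
that no transmission chain connects to an initially infected slot are
pinned to their initial state — for unseeded disconnected components the
fixed-point relation admits a spurious epidemic root that plain iteration
from above would otherwise find. Agreement with the simulator at
$10^{-6}$ per component on randomized instances is part of the test suite,
and is the package's guard against both solver and root-selection errors.

Differentiating the fixed point with respect to the initial dose vector
gives the *small-supply linearization*. With
$E_i = \sum_k (\beta'_{ik}/\mu'_k) R_k(\infty)$ the baseline exposure and
$D = \mathrm{diag}(S_i(0)e^{-E_i})$, the Jacobian system is built from

$$Q = \mathrm{diag}\Big(\tfrac{1}{1-e^{-E_i}}\Big)\,(I - DM),
  \qquad M_{ik} = \beta'_{ik}/\mu'_k,$$

and the per-dose marginal cost of vaccinating group $i$ is

$$x = Q^{-T} p', \qquad
  y_i = \frac{S_i(0)}{N_i}\,(x_{i+n} - x_i).$$

One published form of $Q$ carries a plus sign on the $DM$ term; implicit
differentiation gives the minus sign, and the package pins the choice
empirically: with the minus sign the formula matches finite differences of
the simulated objective to better than $10^{-3}$ relative error, while the
plus sign is off by a factor of several. The linear solve uses the
transposed system directly rather than forming an inverse. Rows with
$E_i = 0$ (a slot receiving no infectious force at baseline) make the
linearization singular; `build_Q()` raises an error naming the offending
group rather than returning garbage.

To leading order, $H(U) = H(0) + y^\top W + o(\varepsilon)$ for a total
supply $\varepsilon$: optimal allocation is a knapsack problem solved by
giving the entire supply to $\arg\min_i y_i$
(`optimal_small_supply_policy()`), at the full rate $A(t)$ until
$\int A = \varepsilon$. Ties in the minimum are broken to the lowest index
with a warning — equal minima are measure-zero in parameter space and any
perturbation removes them.

Two structural facts are tested exactly. A *transparent* vaccine
($\beta^1 = \beta^2 = \beta^3 = \beta^4$, $\mu^1 = \mu^2$, $\kappa = 1$)
gives $y \equiv 0$ to machine precision, because the stacked rows and
columns of the two slots of each group coincide. Note the susceptibility
conditions alone ($\beta^3 = \beta^1$, $\beta^4 = \beta^2$,
$\mu^2 = \mu^1$, $\kappa = 1$) do *not* suffice when $\beta^2 < \beta^1$:
such a vaccine still blocks transmission, and its $y$ is strictly
negative. Second, for a weakly protective vaccine every $y_i \le 0$;
`gradient_y()` warns if numerical noise ever violates this.

## Calibration and the synthetic contact fixture

For age-structured applications, transmission is built from a contact
matrix $\Lambda$ (entry $(i,j)$: contacts of a group-$i$ individual with
group-$j$ individuals) as $\beta^1_{ij} = \beta\,\Lambda_{ij}/N_j$. The
scalar $\beta$ is calibrated so the next-generation matrix
$R_{ij} = N_i \beta^1_{ij}/\mu^1_j$ has spectral radius equal to a target
basic reproduction number (default 4); the radius is linear in $\beta$, so
the calibration is exact and invariant to any rescaling of $\Lambda$
(`calibrate_beta()`). The column sums of $R$ (total infectious force) and
their off-diagonal parts (external force) are reported by
`next_generation_matrix()` because they explain the counter-intuitive
knapsack solutions: under uniform mortality the best target is typically a
group with high *external* force and moderate internal force, not the most
infectious group.

`synthetic_contact_fixture()` generates the test substrate: a seeded,
deterministic contact matrix and population vector emulating the
qualitative structure of survey-based contact data — strong assortativity
(a diagonal component with weight `assortativity` on top of
proportionate mixing), per-capita contact activity decaying geometrically
across groups ($a_i = e^{-3\,\mathrm{decay}\,(i-1)/(n-1)}$, so row sums of
$\Lambda$ are exactly $a_i$ and strictly decreasing when `decay > 0`), an
age-pyramid-like population declining across groups, exact reciprocity
($\Lambda_{ij}N_i$ symmetric), and a 0.5% symmetric log-normal jitter so
the fixture is not artificially regular. What it does **not** emulate:
school/work/home setting structure, the empirical bimodality of
parent-child contact bands, or any country's actual age pyramid. Passing
tests on the fixture therefore demonstrate the *method* (calibration,
gradient ranking, knapsack-vs-simulation agreement) on realistic-shaped
inputs, not conclusions about any real population; a loader accepts real
contact/population CSVs with the same layout.

With a steep old-age-skewed fatality profile the fixture reproduces the
expected qualitative findings: the oldest group is the unique knapsack
optimum and matches exhaustive per-group simulation; with uniform costs
the optimum moves to a middle group, not the most infectious one.

## Numerical choices

* **Integrator.** `deSolve::lsoda` (switching stiff/non-stiff), relative
  tolerance $10^{-9}$, absolute $10^{-12}$, both overridable. Integration
  restarts at every policy breakpoint, so rate discontinuities never sit
  inside a solver step; within a segment, cumulative doses are evaluated
  in closed form rather than carried as extra states.
* **"Time infinity".** Simulation stops when total infecteds fall below
  $10^{-10}$ (and the policy's support has ended), via a root function;
  the choice is the package's own, made once: the truncated tail then
  contributes at most $\sim 10^{-9}$ to any final size, well under the
  $10^{-6}$ agreement demanded of the final-size solver. Default horizon
  `t_max = 200` mean infectious periods; non-convergence by then sets a
  flag and `objective_H()` warns rather than errors.
* **Fixed-point solver.** Start at $S=0$, damped iteration, residual
  target $10^{-12}$, adaptive halving of the damping factor on
  non-decreasing residuals, hard error after 10,000 iterations. Near the
  epidemic threshold convergence is linear with rate
  $\approx \beta S_\infty/\mu$, which stays safely below 1.
* **Grids.** The crossover diagnostic uses 25 log-spaced points and 20
  bisection steps; the leverage scan uses the step-0.05 grid on
  $[0.25, 4]$. Test-suite problem sizes — $n \le 4$ random instances,
  20 finite-difference parameter sets, an 8-group fixture — were chosen
  so the whole suite exercises every advertised property in well under a
  minute on one core.
* **Finite-difference oracle.** The gradient tests dose one group with
  $\varepsilon = 10^{-4}$ at rate 1 (so dosing occupies $10^{-4}$ time
  units, effectively instantaneous) and compare $(H(\varepsilon e_i) -
  H(0))/\varepsilon$ with $y_i$ at 1% relative tolerance; the leftover
  $o(\varepsilon)$ bias and solver noise are both orders of magnitude
  below that.

## Known limitations

* No reinfection, waning immunity, demography, or exposed compartment;
  the final-size machinery is specific to SIR-type closure.
* The linearization is a *small-supply* statement. Its error is proved
  only $o(\varepsilon)$; empirically it behaves like
  $O(\varepsilon^2 y)$ on the shipped examples (at supply worth 1% of the
  population, prediction and simulation differ by under 1%), but the
  package asserts that scaling only there. For large supplies the optimal
  policy can bifurcate (e.g. herd-immunity thresholds), and the knapsack
  answer is only a starting heuristic.
* The vulnerable-first swap is an asymptotic guarantee in the
  vulnerable-group size; the crossover diagnostic exists precisely
  because, at finite sizes (around $\varepsilon^* \approx 0.1$ in the
  default two-group setting), vaccinating the infectious group first can
  win.
* Policies are piecewise-constant; this is exact for every construction
  shipped, but users approximating smooth controls must supply their own
  grid.
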
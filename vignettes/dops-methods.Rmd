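---
title: "Budgeted hybrid swarm and dynamically dimensioned search: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Budgeted hybrid swarm and dynamically dimensioned search: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dopsr)
```

## The problem

Calibrating a kinetic model of a biochemical network means minimizing a
sum-of-squared-error objective

$$K(\mathbf p)=\sum_i \left(g_i(t_i,\mathbf x,\mathbf p,\mathbf u)-y_i\right)^2
\quad\text{s.t.}\quad \dot{\mathbf x}=\mathbf f(t,\mathbf x,\mathbf u,\mathbf p),\;
\mathbf p^L\le\mathbf p\le\mathbf p^U,$$

where every evaluation of $K$ costs an ODE integration. Objectives of this
kind are multimodal, derivative-free in practice, and expensive, so the
governing resource is the number of objective evaluations $N$, not wall
time. `dopsr` implements a hybrid meta-heuristic for exactly this regime:
a population-based global phase that is cheap to parallelize conceptually
and finds good basins quickly, followed by a greedy single-solution
refinement phase that spends the remaining budget where the population
search has stopped paying off. Only box constraints are supported;
general nonlinear constraints could be attached by a penalty on the
objective but are outside the package's scope.

## Phase 1: velocity-free multi-swarm particle swarm

`NP` particles (default 40) are initialized uniformly in the box and
partitioned at random into `k` equal sub-swarms (default 5; `NP` must be
divisible by `k`). Particle $i$ in sub-swarm $S_k$ moves by

$$z_{i,j}=\theta_{1,j-1}z_{i,j-1}
+\theta_2 r_1\odot(L_i-z_{i,j-1})
+\theta_3 r_2\odot(G_k-z_{i,j-1}),$$

with $L_i$ the particle's personal best, $G_k$ the sub-swarm best,
$r_1,r_2$ fresh uniform(0,1) vectors, and $\theta_2=\theta_3=1.5$. There
is no velocity term; $\theta_1$ plays the inertia role directly on the
position and is scheduled linearly from $w_{max}=0.9$ to $w_{min}=0.4$
across the evaluation budget (the schedule is indexed by the evaluation
counter, so it spans $N$ regardless of how long each phase lasts).
Proposals leaving the box are reflected; if the reflection itself
overshoots, the coordinate is clamped to the violated bound, so every
evaluated point is feasible. Personal, sub-swarm and global bests are
replaced only on strict improvement, which makes every best-so-far trace
monotone and keeps ties deterministic. Every `regroup_interval` (default
10) iterations the particles are re-partitioned at random, which mixes
information across sub-swarms without touching any memory.

A structural quirk of the velocity-free rule is worth knowing: at
consensus ($z=L=G$) the expected update contracts the position by
$\theta_1$ toward the origin. On test functions whose optimum is the
origin this bias flatters the swarm phase; on estimation problems whose
optimum lies elsewhere in a positive box it pushes proposals toward the
lower bounds, where reflection folds them back. The rule is implemented
as stated, not "fixed"; the consequences are discussed under
*Limitations*.

## The switch

After every iteration the run checks whether the global best has
stagnated: if its total relative change over the last `stagnation_limit`
(default 4) iterations is at most `stagnation_tolerance` (default 1%),
the swarm phase ends. We read the window cumulatively — total change
over the window — rather than step-by-step, because the global best of a
large swarm frequently pauses for a handful of iterations while the
population is still contracting; a step-wise reading fires on those
transients and hands the budget to the refinement phase mid-convergence.
A full window is required, so stagnation can never fire before
`stagnation_limit + 1` recorded values exist. The fraction of budget the
swarm has consumed at the switch, $F = \mathrm{NP}\cdot j/N$, is purely
a consequence of when stagnation fires; `phase1_cap` can force the
switch at a fixed fraction of the budget but defaults to 1 (stagnation
is the only trigger, besides running out of paired evaluations).

## Phase 2: greedy dynamically dimensioned search

The refinement phase starts from the overall best particle and spends
the remaining $N_{dds}$ evaluations one candidate at a time. At
iteration $i$ each dimension is perturbed independently with probability

$$P_i = 1-\frac{\ln i}{\ln N_{dds}},$$

falling from 1 (perturb everything: global moves) to 0 (perturb a single
coordinate: local polish); at least one dimension is always perturbed.
Selected coordinates receive zero-mean Gaussian noise with standard
deviation $\sigma_d = R\,(p^U_d-p^L_d)$, $R=0.2$ by default, reflected
into the box; the candidate replaces the incumbent only if strictly
better. An alternative probability schedule, $1-\log(i/N_{dds})$, is
retained behind `dds_settings(prob_formula = "as-printed")` for
auditability; it saturates at 1 over the whole horizon (every dimension
always perturbed), contradicts the minimum-one-dimension rule, and is
not the default.

## Multi-switch variant

`run_msdops()` allows the search to return to a swarm phase: each
refinement phase records its entry value, and once the incumbent falls
to `switchback_ratio` (default 0.9, i.e. 90%) of that value — and at
least `NP + 1` evaluations remain — a fresh swarm is initialized with
particle 1 set to the incumbent (its cached value reused; objectives are
deterministic by contract) and the rest re-drawn uniformly, maximizing
diversity recovery. Re-entered swarm phases obey the same stagnation
rule. If no refinement phase ever reaches the ratio the run is
trace-identical to `run_dops()` at the same seed — a property the test
suite asserts. The ratio test is only applied to positive objective
values, where "reduced to 90%" is well defined.

## Budget accounting

Every objective call goes through one `eval_ledger`, which enforces the
budget, records the best-so-far trace (one entry per evaluation) and
raises a typed condition at exhaustion. All four variants consume
exactly `total_budget` evaluations; the swarm-only baseline finishes
with a partial particle sweep when the budget is not a multiple of `NP`.
Scaled error — the unit of every convergence claim — is the best-so-far
value divided by the trial's initial best (the best of the `NP` random
initializations, or the single random start of the refinement-only
baseline), so every trial starts at exactly 1.

## The demonstration estimation problem

The bundled cascade (`demo_cascade_model()`) is a six-species,
eight-reaction mass-action network with the initiation / amplification /
inhibition architecture of protease networks such as coagulation: a
trigger activates a zymogen (`TRIG + X -> TRIG + Xa`), the active
protease activates a second zymogen (`Xa + Y -> Xa + Ya`), the
downstream product feeds back positively (`Ya + X -> Ya + Xa`), a
stoichiometric inhibitor neutralizes both active species, both decay,
and the downstream product consumes the trigger (negative feedback,
`Ya + TRIG -> Ya`). Nominal rate constants are order 0.1–2, initial
concentrations order 0.2–5 (arbitrary concentration/time units), giving
fast activation against slower inhibition over a horizon of 10 time
units. Two training experiments differing in initial trigger
concentration (1.0 and 0.2) are observed at 20 time points for the two
active species and combined unweighted. A finite-difference sensitivity
check (`parameter_sensitivities()`) confirms every rate constant moves
the observables, a necessary condition for recovery, and the test suite
asserts it.

Synthetic data are generated by simulating the model at the known
nominal constants and adding independent Gaussian noise (default 0:
noiseless, so the nominal vector attains objective 0 exactly). What the
generator deliberately does **not** emulate: correlated or
heteroscedastic measurement error, missing observations, model
misspecification, and the stiffness and scale (hundreds of parameters)
of real coagulation models — so passing recovery tests demonstrates the
optimizer's mechanics at desk scale, not performance on full-scale
biology. Estimation uses the multiplicative box $0.2\,p_{nom}$ to
$5\,p_{nom}$. ODE integration is `deSolve::lsoda` (rtol 1e-6, atol
1e-8); the mass-action derivative is evaluated in C through deSolve's
compiled-model interface, with an R implementation retained as the
reference (`engine = "r"`) and an equivalence test between the two.
Integration failures inside the objective return a sentinel value
(10^6 times the first finite objective value seen) so a diverging
parameter vector costs one budget unit like any other candidate.

## Numerical and design choices

* **Seeding.** A run is a pure function of its config (including
  `seed`); batches derive trial $t$'s seed as `base_seed + t - 1`, so
  trials are reproducible individually and in aggregate.
* **Ties.** Incumbents and personal bests are kept on ties (strict
  improvement only): deterministic and cheap.
* **Degenerate inputs.** `NP` not divisible by `k`, inverted bounds,
  budgets below one initialization, and empty perturbation sets are
  rejected with informative errors; a refinement horizon of one step
  uses inclusion probability 1.
* **Problem sizes in the tests.** The study-scale checks run the
  defaults ($N = 4000$, 25 trials) for the 10-D test functions, 10
  paired seeds for ablations, and 10 recovery trials; unit tests use
  budgets of a few hundred evaluations.

## Limitations

The contraction bias of the velocity-free update makes the swarm-only
baseline look artificially strong on benchmarks whose optimum is the
origin: given the whole budget it drifts to the origin regardless of the
objective's fine structure. On the 300-dimensional Rastrigin function
this interacts with the stagnation rule — in a minority of seeds the
global best pauses for four iterations early, the run switches, and the
refinement phase cannot polish 300 coordinates at $\sigma=0.2$ of the
box width — so the hybrid does not dominate the swarm-only baseline
there. On the estimation problem the package exists for (optimum away
from the origin, smooth-but-expensive SSE surface) the ordering is the
expected one, and the suite verifies it: the hybrid's median final SSE
beats both the swarm-only and the refinement-only baselines over paired
seeds. Other known limits: no velocity-based swarm variants or
alternative topologies, no noisy objectives, no constraint handling
beyond the box, and integration-failure sentinels assume failures are
rare enough not to distort the search.
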
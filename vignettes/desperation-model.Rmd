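---
title: "The desperation-threshold model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The desperation-threshold model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(desperation)
```

This vignette is the package's own account of the model it implements: the
decision problem, the algorithms, the tunable parameters, and — since several
implementation details are genuinely underdetermined — the design choices we
made, why, and what they change.

## The model

Agents hold a scalar resource level $s$ and repeatedly choose one of three
actions in randomly formed groups of $n$:

* **forage alone** — invest $x$, get $x$ back: net $0$, no social risk;
* **cooperate** — invest $x$; if nobody in the group exploits, receive
  $\alpha x$ with $\alpha > 1$ (net $x(\alpha - 1)$); if an exploiter is
  present the surplus is lost and the investment with it (net $-x$);
* **exploit** — attempt to steal a cooperating group's production: reward
  $\beta$ with probability $1-\gamma$, punishment $-\pi$ with probability
  $\gamma$.

Fitness is linear in resources except at the **desperation threshold**
($s = 0$): every time step spent below it costs a fixed penalty $\omega$.
That single non-linearity is the heart of the model. It makes agents near
the threshold risk-preferring — a successful exploitation is the only
one-shot action that can vault them back over the line, and a punishment
barely worsens an already desperate position — while agents far from it
remain effectively risk-neutral.

Between steps, resources are also shuffled by a mean-reverting
perturbation, $s' = (1-r)\,s + r\,\varepsilon$: the social-mobility
parameter $r$ is one minus the autocorrelation of an agent's resources.

The trustworthiness of the population, $1-p$, is the probability that a
cooperating group contains no exploiter. The policy solver treats $p$ as an
exogenous state variable; the simulator makes it endogenous: each agent
estimates it by watching a finite sample of others.

Default parameters (`model_params()`): $r=0.1$, $x=1$, $\omega=5$,
$\alpha=1.2$, $\beta=5$, $\pi=10$, $\gamma=1/3$, $T=50$, $N=500$, $n=5$,
$K=50$. At these values exploitation is a fair gamble,
$(1-\gamma)\beta = \gamma\pi$, so its only attraction is its variance.

## Computing optimal policies

`solve_policy()` runs finite-horizon backward induction on a discretised
state space: 1001 resource points on $[-50, 50]$ (step $0.1$) crossed with
101 trustworthiness points on $[0, 1]$ (step $0.01$; the resource grid is
the published discretisation, the trustworthiness resolution is our choice,
fine enough to resolve the analytic frontier $1/\alpha$ to two decimals).
Terminal fitness is $f_T(s) = s$; each earlier step computes, per action,
the expectation of $f_{t+1}$ minus $\omega$ times the probability of
landing below the threshold, and takes the argmax. Policies stabilise
within roughly ten steps of the horizon; the $t=1$ map is reported, and the
`policy` object records where the map last changed.

Numerical choices:

* **Transition kernels.** Each action is a mixture of Gaussians, one
  component per outcome, with mean $(1-r)(s+d) + r\mu_0$ for net payoff $d$
  and standard deviation $r \cdot \mathrm{sd}(\varepsilon)$. Components are
  integrated over grid-cell intervals with the Gaussian CDF, so rows sum to
  one by construction; mass outside $[-50, 50]$ is folded into the boundary
  cells rather than renormalised, which conserves probability and keeps
  desperate states desperate. With $r=0$ the kernel degenerates to a point
  mass at the nearest grid cell.
* **Tie-breaking.** Exact ties (within $10^{-12}$) resolve by the fixed
  preference alone > cooperate > exploit. This matters in degenerate
  regimes: with $\pi = 0,\ \gamma = 1$ exploitation is payoff-identical to
  foraging alone and the map shows no exploit region at all.
* **Terminal fitness scaling.** Policies are invariant to the intercept
  and to jointly scaling the slope and $\omega$; they are *not* invariant
  to the slope alone, because the threshold penalty is absolute. Slope 1
  with $\omega = 5$ is the natural reading of a linear fitness function
  penalised by a "fixed amount", and is what we use.

### The perturbation scale, and two readings of its variance

The shuffle is meant to leave the population's resource distribution
unchanged while individual positions decay with autocorrelation $1-r$. Two
noise scales are implemented (`perturbation_variant`):

* `"variance_preserving"` (default):
  $\mathrm{sd}(\varepsilon) = \sigma\sqrt{1-(1-r)^2}/r$, which makes
  $\mathrm{Var}(s') = \sigma^2$ exactly and $\mathrm{Cor}(s, s') = 1-r$;
* `"paper"`: $\mathrm{sd}(\varepsilon) = \sigma\sqrt{(1-r^2)/(1-r)^2}$, an
  alternative published form that yields $\mathrm{Var}(s') \approx 0.82\,
  \sigma^2$ at $r=0.1$ (and is undefined at $r=1$); retained for
  comparison.

Only the first satisfies the stated invariants, so it is the default; the
property tests verify both the moment preservation and the
autocorrelation.

### The exogenous anchor of the solver

During policy computation the perturbation needs a fixed mean and scale
$(\mu_0, \sigma_0)$ — they are inputs, not things the solver can know. This
choice is consequential and underdetermined, so we state it explicitly:
**by default the solver centres the noise at the desperation threshold**
($\mu_0 = 0$) with scale $\sigma_0 = $ `params$sigma`.

Why not centre it at a wealthy population mean? Because the drift term
$r(\mu_0 - s)$ then quietly rescues every near-desperate agent: with
$\mu_0 = 5.5$ an agent just below the threshold is pulled back over it "for
free", cooperation becomes optimal *below* the threshold, and the
unconditional-exploit band retreats to about $-1.5$. Centring at the
threshold makes desperation self-sustaining — the environment neither bails
agents out nor sinks them relative to the survival line — and the exploit
band edge lands exactly at the threshold, which is where the interesting
dynamics (about 9% of a $\mu=5.5,\ \sigma=4$ population exploiting at the
outset) come from. Solvers can be given any anchor via
`solve_policy(mu0 =, sigma0 =)`; the sensitivity is worth exploring.

One consequence worth knowing: with drift toward an anchor, a punishment
costs an agent the drift it would otherwise have ridden, so *deep*
exploitation is not insensitive to punishment severity in this
implementation. Doubling $\pi$ from 10 to 20 moves the near-threshold
exploit band top from $0$ to about $-2.6$ and carves the deep map into
alternating regions (including a free-roll exploit stretch against the grid
floor, where punishment is truncated by the state-space boundary).
Likewise, at $\gamma = 2/3$ the exploit region disappears entirely rather
than persisting at very low $s$. Both are genuine divergences from the
qualitative punishment-insensitivity this model family is known for, and
both trace to the same mechanism; a kernel with much smaller noise and a
flat deep value function would restore them. We document this rather than
hide it — the corresponding test is expected to fail and says so.

## Simulating populations

`run_simulation()` advances $N$ agents per step in five phases: groups are
re-formed at random (no assortment); each agent looks up the policy at its
resources and its own trust estimate; group payoffs are resolved;
resources are perturbed; trust is re-estimated from the decisions just
observed.

* **Group resolution.** Aloners net 0. If a group holds at least one
  exploiter and at least one cooperator, one exploiter drawn uniformly is
  active (the others net 0 — there is nothing left to take), cooperators
  pay $-x$ whether or not the active exploiter is punished, and the active
  exploiter draws its gamble. With no cooperator, exploiters have nobody to
  rob and net 0. With no exploiter, cooperators collect the surplus.
* **Trust.** Each agent samples $K$ distinct others (without replacement,
  self excluded), counts exploit decisions $k$, scales to
  $k' = \mathrm{round}(k N / K)$, and computes
  $\hat p = 1 - \binom{N-1-k'}{n-1}/\binom{N-1}{n-1}$ — the probability
  that at least one of its $n-1$ prospective partners would be an
  exploiter. Trust is $1-\hat p$. Estimates are unbiased but noisy; that
  heterogeneity is intentional and drives the tipping behaviour.
* **Initial trust** is 1: agents have observed nothing yet, and the first
  round of real behaviour immediately corrects it. (Settable via
  `initial_trust`.)
* **Perturbation scale.** The noise is centred on the *current* population
  mean — growth and decline pass through — but its scale is anchored to
  the run's input inequality $\sigma$ (`perturbation_variance =
  "anchored"`, the default). Anchoring makes the shuffle an
  Ornstein-Uhlenbeck-style restoring force: population variance relaxes
  geometrically to $\sigma^2$ instead of accumulating every unit of payoff
  variance forever. With the scale re-read from the realised variance each
  step (`"current"`), punishments ratchet dispersion upward without bound
  — the desperate tail grows a few percent per step and the cooperative
  equilibrium is unreachable from any starting point we tried; we consider
  that reading inconsistent with the model's premise that the shuffle
  leaves the distribution unchanged.

### The two equilibria and their classifier

With $\mu = 5.5,\ \sigma = 4$ the population collapses within a few steps
into the **poverty trap**: enough agents are desperate at the outset
(about 9%) that sampled trust falls below the cooperation frontier, the
well-off switch to foraging alone, nobody produces a surplus, and the
desperate remain desperate. With $\sigma = 3$ exploitation is rare enough
(about 3%) that trust stays high, cooperation compounds, the mean rises
and lifts the tail over the threshold: the **virtuous circle**.

`classify_equilibrium()` labels a trace from its final 10 steps: poverty
trap if mean cooperation is below 5% of the population and exploitation is
present; virtuous circle if mean cooperation exceeds 50% and mean
resources grew over the run; otherwise undetermined (all-alone
populations, and slow transients near the basin boundary). The trap bound
is not zero by design: finite-sample trust puts a floor under cooperation
— an agent whose $K=50$ sample happens to contain at most one exploiter
estimates trust around $0.92$ and cooperates that step regardless of the
true prevalence, so even a fully trapped population shows isolated blips
an order of magnitude below the virtuous level. All thresholds are
arguments.

## Experiments

* `phase_sweep()` maps basins over any two parameters, re-solving the
  policy per cell and majority-voting over replicate seeds (single runs
  near the boundary are coin flips).
* `critical_exploitation_fraction()` scans initial inequality across the
  basin boundary and reports the smallest realised first-round
  exploitation fraction whose majority outcome is the trap, with a
  bootstrap interval. At defaults this lands around six to eight percent
  of the population depending on the seed — the same order as the
  published "about 10%".
* `shock_experiment()` imposes a mid-run reduction of $\sigma$ (rescaling
  about the mean; the perturbation anchor follows). Shocking a trapped
  $\sigma = 4$ population to $\sigma = 3$ at step 16 reproduces the staged
  escape: exploitation drops first (agents lifted over the threshold
  switch to foraging alone), observed behaviour improves so trust
  recovers, then cooperation spreads and resources grow.
* `group_size_experiment()` compares basin boundaries across $n$: smaller
  groups are harder to spoil at a given exploiter prevalence (the trust
  combinatorics above), so they enlarge the virtuous basin.

Social mobility deserves a note: moderate increases of $r$ do little, but
at $r \gtrsim 0.9$ the shuffle dominates the transition kernel, action
consequences dilute, the exploit region collapses, and even a highly
unequal population goes virtuous. In this implementation $r = 0.8$ sits on
the basin boundary at $\sigma = 4.5$; "very high" mobility means 0.9 and
above.

## What the simulations do and do not emulate

The synthetic populations are exactly the model's world: Gaussian initial
resources, no spatial structure, no repeated partners, no reputation, no
kinship, groups re-drawn every step, a single central punisher with
exogenous $\gamma$ and $\pi$. Passing tests therefore demonstrate the
internal logic of the desperation-threshold mechanism — not that real
economies hold any of those assumptions. In particular the two crisp
absorbing equilibria are artefacts of the model's starkness; real
populations mix mechanisms the model deliberately omits.

## Problem sizes

The test suite exercises full-resolution policies ($1001 \times 101$,
$T = 50$) and populations of $N = 500$ for the headline checks, and a
coarse configuration ($201 \times 51$, $T = 20$, $N = 100$) for machinery
tests. Phase-diagram checks use deliberately small grids (two or three
values per axis, three replicates); the boundary-fraction estimate uses
nine $\sigma$ values with five replicates each (45 runs). These sizes were
chosen so a full check runs on a desktop in minutes; all of them are
arguments, and finer grids simply take proportionally longer.

## Known limitations

* The punishment-severity and punishment-probability *insensitivity* of
  deep exploitation does not hold under the variance-preserving kernel
  (see above); the package reproduces the threshold mechanism, the
  frontier, the two equilibria, the phase diagrams and the shock
  transition, but not that particular qualitative claim.
* The solver assumes $p$ static during policy computation; policies are
  not re-solved as the population's mean drifts unless
  `recompute_policy_every` is set.
* Agents snap to the nearest grid cell; no interpolation between grid
  points.
* $N$ must be divisible by $n$; partial groups are rejected.
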
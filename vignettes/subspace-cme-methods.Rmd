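---
title: "Methods: master-equation models of subspace calcium and their deterministic limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: master-equation models of subspace calcium and their deterministic limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadCME)
```

## The model

A dyadic subspace of volume $v$ (liters) exchanges calcium passively with
the bulk cytosol at rate $\beta$ (ms$^{-1}$); the bulk concentration
$c_\infty$ (µM) is held fixed. A channel (or channel pool, or
calmodulin-regulated channel) injects calcium at a state-dependent rate
$\alpha_m$ (µM/ms). The deterministic description is the mass-action
balance $dc/dt = \alpha - \beta(c - c_\infty)$, whose steady state is
$c_* = \alpha/\beta + c_\infty$.

The stochastic description replaces the concentration by the integer
count $n$ of free calcium ions. The package works throughout in ion and
millisecond units, with the single conversion factor

$$ w = v \, N_A \times 10^{-6} \quad \text{(ions per µM)}, $$

using the exact SI Avogadro constant $N_A = 6.02214076\times 10^{23}$
(the value is not negotiable, but note it enters all "ions per subspace"
statements: at $v = 10^{-17}$ L, $w \approx 6.02$, so 0.1 µM is 0.6
ions). The state of the system is the pair $(n, m)$ with $m$ the channel
state, and the transition rates are:

* influx $n \to n+1$ at $\bar\alpha_m = (\alpha_m + \beta c_\infty)\,w$,
* efflux $n \to n-1$ at $n\beta$ (each ion independently leaves),
* two-ion binding $(n, m) \to (n-2, m')$ at $n(n-1)\,u\,k^+/w^2$, where
  $u$ counts the free binding units in state $m$; the combinatorial
  factor $n(n-1)$ makes the propensity converge to the mass-action rate
  $k^+ c^2 u$ as $w \to \infty$ at fixed $c = n/w$,
* two-ion release $(n, m) \to (n+2, m')$ at $u' k^-$, and
* conformational steps $(n, m) \to (n, m')$ that move no ions (the
  calmodulin scheme's pre-association and effector transitions).

The dissociation constant is $\kappa^2 = k^-/k^+$ (µM²). Four schemes are
provided by `make_scheme()`: `unregulated` (one state), the two-state
`single_regulated` channel (activated: closed when calcium-free;
inactivated: open when calcium-free), the aggregated `multi_channel` pool
with $\hat b_t$ identical channels whose influx interpolates linearly in
the number of bound channels, and the four-state `calmodulin` scheme
(pre-associated / unbound / calcium-bound / effector-engaged, with only
the effector state altering conductance).

Two conventions are worth making explicit because they are stated only in
prose in the literature this package follows:

* **Open-state semantics.** Activated channels are open when
  calcium-bound; inactivated channels are open when calcium-free;
  calmodulin-activated channels are open in the effector state only.
  Each scheme carries an `open_fraction` per state; for the multi-channel
  pool `p_open` is the expected open *fraction*
  $\sum_m p_m \cdot (\text{open fraction in } m)$, which reduces to the
  plain sum over open states for single-channel schemes.
* **Exit rates are sums.** In the four-state scheme the total exit rate
  of the calcium-bound, effector-disengaged state is
  $\bar\alpha_0 + n\beta + \gamma^+ + k^-$ — each declared transition
  contributes its own rate. (One printed source formats the last two as a
  product; a generator built that way would not conserve probability,
  and the row-sum tests here enforce the sum reading.)

## Truncation and the stationary solve

The infinite lattice is truncated at $n_{\max}$ with *reflecting*
boundaries: transitions that would leave $[0, n_{\max}]$ are dropped (and
counted). Ordering is n-major with the channel state fastest, so all
couplings stay within a band of width $\sim 2 \times$ the number of
channel states and sparse direct factorization has negligible fill-in.

`n_max` selection (`solve_cme()`, `build_state_space(n_max = "auto")`)
starts from mean + 12 sd of the largest per-state count
($\lceil \lambda + 12\sqrt\lambda \rceil$, Poisson-motivated) and doubles
until the *tail certificate* — the stationary probability of the top
three count levels — falls below `tail_tol` (default $10^{-10}$). Every
stationary result carries that certificate plus the residual
$\max_i |(\pi Q)_i|$. Spaces beyond $10^7$ states are refused.

The solve itself replaces one balance equation with a normalization: we
pin a single state $k$ (set $p_k = 1$), solve the remaining sparse system
$Q^\top_{-k,-k}\,x = -Q^\top_{-k,k}$, and renormalize. A literal dense
normalization row would destroy the bandedness and causes severe LU
fill-in at $10^5$-state problems, which is why the pinned variant is
used. The pin matters: pinning in a region of negligible probability
loses the solution in round-off (errors of several percent were observed
against a dense null-space oracle during development). The pin is
therefore placed at the lattice point nearest the fast-limit
deterministic equilibrium, and if the residual exceeds `residual_tol`
(default $10^{-10}$) the solver re-pins at the argmax of the computed
vector and repeats (up to 3 times). A shifted inverse-iteration fallback
(the smallest-magnitude eigenpair of $Q^\top$) covers the rare case where
the direct solve fails outright. Irreducibility is checked first by
strong connectivity of the transition graph; degenerate rate choices
($k^+ = 0$, disconnected regulator states) are reported as reducibility
errors rather than returning an arbitrary stationary vector.

Small negative entries from round-off (within $-10^{-14}$ of zero) are
clipped before renormalization. Transient solves integrate
$dp/dt = Q^\top p$ with `deSolve::lsoda` (atol $10^{-12}$, rtol
$10^{-10}$) and verify conservation to $10^{-8}$ at every output time.

## Moments, identities, and gating limits

`summarize_moments()` computes joint moments
$\mu_q^m = \sum_n n^q p_n^m$ for $q \le 3$ by direct summation, the
channel-state marginals, conditional means/variances (in ions and µM),
$E[C]$, its CV, and `p_open`. The decomposition
$E[C] = \sum_m \mu_0^m E^m[C]$ holds exactly by construction.

The printed moment hierarchy of the two-state model is *not closed* (the
first-moment balance involves $\mu_2^0$ and $\mu_3^0$), so the package
never integrates moment ODEs as a model; `check_moment_balance()` instead
evaluates those right-hand sides at the CME stationary moments as a
residual diagnostic, which simultaneously validates the generator and the
printed equations. The identity
$\mu_0^1 = (\mu_2^0 - \mu_1^0)/(\kappa^2 w^2)$ is exposed by
`p_bound_identity()`; in the large-system limit it becomes the Hill form
$(E^0[C])^2/(\kappa^2 + (E^0[C])^2)$.

`fast_slow_limits()` returns the two bracketing regimes of the two-state
channel. Slow gating: state transitions occur from a subspace
equilibrated at the current state's influx, giving for the activated
channel $E[C] \approx c_\infty$ and
$p_{\rm open} \approx c_\infty^2/(\kappa^2 + c_\infty^2)$; the
inactivated channel uses the complementary occupancy with the open-state
level $c_{0*} = \alpha_0/\beta + c_\infty$ (this case is the package's
own extension — the bracketing theorems in the literature are stated for
the activated channel, and the sandwich property is asserted in the tests
for that case only). Fast gating: binding equilibrates instantly and the
limit is the mean-field equilibrium, solved through the exact cubic (see
below); when that equation is bistable the *upper* stable root is
reported, which is the branch the volume series approaches in all
single-channel parameter sets examined.

## Mean-field equilibria and bifurcation structure

With the channel pool in binding equilibrium
($b/b_t = \kappa^2/(\kappa^2 + c^2)$), the steady-state concentration
solves

$$ 0 = \alpha_1 \frac{c^2}{\kappa^2 + c^2}
     + \alpha_0 \frac{\kappa^2}{\kappa^2 + c^2}
     - \beta (c - c_\infty). $$

Multiplying by $\kappa^2 + c^2$ gives a cubic whose coefficients are
formed exactly; `polyroot()` supplies all roots, real roots in
$[c_\infty, c_*]$ are polished by Newton iteration to residual
$< 10^{-12}$ and deduplicated within $10^{-8}$ µM. Root-polish before
dedup matters: rounding roots to a grid re-introduces residuals at the
$10^{-11}$ level. This guarantees the full equilibrium set for the
bifurcation diagram — a scanning root-finder can silently miss the middle
branch near a fold. Stability uses the sign of the derivative of the
reduced right-hand side; if `k_plus` and a total channel concentration
are supplied, the 2-D Jacobian of the full $(c, b)$ system is used
instead, which is the correct classification when binding kinetics are
slow (for the parameter sets tested the two agree). The calcium-activated
pool has a finite $\kappa$-window of bistability (containing
$\kappa = 2$ µM for $c_* = 5$ µM, with $\kappa = 0.45$ µM monostable);
the inactivated pool is monostable for every $\kappa$, since its feedback
is negative.

The $(c,b)$ balance is implemented exactly as conventionally printed,
without a stoichiometric factor 2 on the binding flux in $dc/dt$; the
equilibria — the only quantities the analysis consumes — are unaffected
because the binding terms cancel at $db/dt = 0$.

## The deviation analysis

`small_system_deviation()` computes
$\Delta = (E[C]_{v_0} - E[C]_{\rm ref})/E[C]_{\rm ref}$ with the
reference at exactly $10\,v_0$ (reported in percent at the interface).
Two volume scalings are supported: `single_channel` (one channel, influx
in ion units grows with $v$) and `multi_channel` (channel count grows in
proportion: 1 channel at $v_0$ vs 10 channels at $10 v_0$). The reference
is always the CME at the reference volume, never the ODE equilibrium —
in bistable regimes the ODE offers two candidate answers and the CME at
$10 v_0$ is the definition-consistent one. Sensitivity to the reference
multiplier is itself exposed (`ref_multiplier`); measured behavior on the
single-activated sweep parameters is geometric convergence, with the
$10\times$-vs-$20\times$ difference about 0.5 points at $c_* = 5$ µM and
about 2 points at the deviation peak $c_* = 7$ µM.

Default surface grids (`deviation_surface()`) are
$v_0 \in \mathrm{logspace}(10^{-17}, 10^{-15}, 5)$ L and
$c_* \in \{1, 5.75, 10.5, 15.25, 20\}$ µM. The lower end of the volume
grid is the physiological unitary dyad volume $10^{-17}$ L — the natural
origin for a scan of "unitary volume", and the convention used by every
volume series in this model family; on these grids the multi-channel
surfaces reproduce the known figure-level maxima (activated
$\kappa = 0.45$, $k^+ = 0.005$: ~75% suppression; inactivated
$\kappa = 0.63$, $k^+ = 0.05$: ~16%). Grids are fully configurable.

Two empirical notes, both verified against an independent dense-solver
oracle and asserted in the tests at their honest magnitudes: (i) $\Delta$
is not *strictly* nonpositive — in the $\Delta \approx 0$ plateau at
small $c_*$ the single activated channel can show deviations up to about
$+0.6$ points (suppression in the operating regimes is tens of points,
so the sign statement is correct at plotting resolution); (ii) for the
bistable multi-channel pool $E[C]$ versus volume is biphasic for
sufficiently fast binding ($k^+ \gtrsim 0.015$ at $\kappa = 2$): the mean
first climbs toward the upper mean-field equilibrium and then collapses
to the lower branch that the large-system limit selects.

## The stochastic oracle

`ssa_simulate()` is a compiled Gillespie direct-method simulator over the
same propensities (shared with the generator construction, so the two
routes are independent only in the solution method, not the model — which
is exactly what a cross-check of the solver should hold fixed). It uses
R's RNG (reproducible under the config seed), discards a configurable
burn-in, and reports time-weighted occupancy histograms plus batch-means
standard errors (default 20 batches). `compare_to_cme()` reports
z-scores for the mean count and each state marginal and the
total-variation distance between histograms, with a default acceptance
threshold of $|z| < 4$. Batch means underestimate errors when the batch
width is not large against the gating correlation time, so validation
runs should be long ($10^6$ ms for the reference activated channel, where
closed-state dwell times reach seconds).

## What the tests do and do not show

All expected values in the test suite are either closed forms (Poisson
law, exponential relaxation, Hill limits), independent oracles (bisection
root-finding, dense null-space solves, SSA long-run averages), or the
published two-digit values of this model family at their stated
parameters. The test problems are *desk-scale*: lattices up to $\sim
1.5\times 10^5$ states, surfaces on $5\times 5$ grids, SSA runs of
$10^6$ ms. They validate the solver and model construction exhaustively;
they do not validate the biology. In particular the model is spatially
homogeneous (no diffusion gradients or channel geometry inside the dyad),
has no endogenous buffers, treats two-ion binding as one instantaneous
step, and addresses stationary statistics only — transient physiology
(voltage steps, spark dynamics) is outside its scope. The calmodulin
scheme is fully implemented and structurally tested (conservation,
degenerate-rate reduction to the two-state channel), but its published
lobe-specific rate sets are user parameters: the shipped
`calmodulin_template` config carries placeholder zeros to be replaced.

## Parameter defaults

| Parameter | Meaning | Default | Units |
|---|---|---|---|
| `v` | subspace volume | $10^{-17}$ | L |
| `beta` | bulk coupling rate | 0.01 | ms$^{-1}$ |
| `c_inf` | bulk calcium | 0.1 | µM |
| `alpha`, `alpha0`, `alpha1` | per-state influx | — | µM/ms |
| `kappa` | dissociation constant | — | µM |
| `k_plus` | association rate | — | µM$^{-2}$ ms$^{-1}$ |
| `tail_tol` | truncation certificate | $10^{-10}$ | probability |
| `residual_tol` | stationarity residual | $10^{-10}$ | — |
| `ref_multiplier` | large-system reference | 10 | × $v_0$ |

Influx is normally specified through $c_* = \alpha/\beta + c_\infty$
(`alpha_from_c_star()`), matching how the deviation surfaces are
parameterized.
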
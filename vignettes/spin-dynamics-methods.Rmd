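---
title: "Methods: spin dynamics, mean-field theory and the empirical estimators"
author: "demotip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spin dynamics, mean-field theory and the empirical estimators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(demotip)
```

This vignette documents the modelling and numerical choices behind
`demotip`: the microdynamics and the conventions they require, the
mean-field theory and its root-finding, the slow macro dynamics, the
simulated-ensemble conditions, and the two statistical estimators. It is
the place where every genuinely open design decision is recorded.

## 1. Microdynamics

Agents sit on an undirected friendship network. Three binary spins
describe each agent: intrinsic preference $s_1$ (parochial at 0,
altruistic at 1), induced preference $s_2$ (set by social influence and
peer pressure), and voting enthusiasm $s_D$. Non-members with
$|s_1,s_2\rangle = |1,1\rangle$ are *altruists*; members of the
parochial in-group are *parochialists* regardless of spins; everyone
else is an *opportunist*.

**Sliding-window spin semantics.** A spin is up at step $t$ iff at least
one successful Bernoulli trial occurred in its trailing persistence
window, and trials run every step independently of the current state.
This convention is chosen because it makes the stationary closed forms
exact rather than approximate: the stationary probability of $s_1 = 1$
is exactly $p^* = 1-(1-p)^{\tau_1}$, and the stationary enthusiastic
fraction is exactly $(1-p_v)^T$, for which $e^{-p_v T}$ is the standard
large-window approximation. The suite verifies both at $N = 10^4$
against three Monte-Carlo standard errors.

**Synchronous updates.** Neighbourhood eligibility for the $s_2$ trial
is evaluated on the *previous* step's altruist labels, and all agents
update simultaneously. This removes any dependence on agent update
order, at the cost of a one-step information lag that is irrelevant at
the timescales simulated.

**Eligibility conventions.** Two readings of the altruist-count
threshold $\mu$ are implemented and selectable everywhere
(`convention`):

* `"printed"` (default): an agent is eligible iff its neighbourhood
  contains at most $\mu$ *non-altruists* — equivalently at least
  $k - \mu$ altruists for degree $k$. A degree-$k \le \mu$ agent is
  always eligible.
* `"textual"`: eligible iff at least $\mu$ *altruist* neighbours. A
  degree-0 agent is never eligible (for $\mu \ge 1$).

The two coincide only at $k = 2\mu$. The default is the printed form,
used consistently in both the agent model and the mean-field term, so
that simulation and theory can be compared like for like. The
degree-0/low-degree behaviour is not a corner case to hide: it is the
seeding mechanism of the whole transition (see §3).

**Members are pinned.** Once recruited, an agent is permanently
classified parochial and always votes. Rather than simulating the dense
like-minded neighbourhood that would hold its spins down, membership
simply overrides classification. In-group edges gained by members
therefore never influence non-member eligibility (altruists are never
members), which lets the spin dynamics run on the fixed initial
friendship layer while member degrees are tracked for bookkeeping.

**Network model.** Only mean degrees are specified by the theory, so the
generator uses the simplest graph consistent with indiscriminate
friendship formation: Erdős–Rényi with edge probability $k_0/(N-1)$,
plus an ER layer among the initial members with edge probability
$(k_p - k_0)/(n_m - 1)$ so the member mean total degree is $k_p$. A
newly recruited member draws Poisson$(\max(k_p - \text{degree}, 0))$
extra edges to uniformly sampled existing members.

## 2. Mean-field theory

With each neighbour independently altruistic with probability $z$, the
eligibility probability averaged over the degree distribution is

$$E(z) = \sum_k \mathrm{zdf}(k)\, P(\mathrm{Bin}(k, 1-z) \le \mu)$$

under the printed convention (the textual variant replaces the inner
term by $P(\mathrm{Bin}(k, z) \ge \mu)$). Both are evaluated through the
binomial CDF, with the analytic derivative
$\mathrm{d}E/\mathrm{d}z = \sum_k \mathrm{zdf}(k)\, k\,
d_{\mathrm{Bin}}(\mu;\, k-1,\, 1-z)$ used for stability labels and
Newton polishing. The self-consistency equation is
$z = (1-f)\,p^* r^* E(z)$ on $[0, 1-f]$, with $d = 1 - f - z$, so the
three shares sum to one identically.

**Root finding.** `fixed_points()` scans $g(z) = z - (1-f)p^*r^*E(z)$ on
a dense grid ($10^4$ points by default), bisects every sign change to
machine precision, applies one Newton step, and accepts roots with
$|g| < 10^{-10}$. Because $E$ is a polynomial in $z$, roots are
well-separated except at folds; near-tangencies (map slope within
$10^{-6}$ of 1) are flagged as degenerate. A root is *stable* iff the
slope of the right-hand side is below 1 (discrete-map criterion). The
suite cross-checks root sets against an independent $10^6$-point
brute-force scan on randomized parameter draws.

**Region labels.** At least two stable roots: `bistable`. Otherwise the
single stable root is `few-altruists` below $(1-f)/2$ and
`many-altruists` above; the halfway cutoff is a documented convention —
the phase diagram is otherwise only defined graphically.

**Critical threshold.** `critical_threshold()` locates the smallest
$p^*$ at which the low-altruism branch disappears (the saddle-node met
along an upward sweep) by bisection on the root count, to $10^{-6}$.
When no bistable window exists along $p^* \in [0,1]$ it returns `NA`.

## 3. Why the reference scenario uses an overdispersed degree distribution

With a single shared degree $k > \mu$, $E(0) = 0$, so $z = 0$ is an
exact fixed point under either convention: with no altruists nobody is
eligible, and nobody can become an altruist — in the theory *and* in the
agent model. A society started near $z = 0$ then never leaves it, and no
upward sweep can produce the explosive transition, although the bistable
*region* (coexistence of $z = 0$ with a high-altruism root) still exists
and is mapped in the tests with delta degrees ($k = 10$, $\mu = 4$).

Real friendship networks are overdispersed, and that heterogeneity is
exactly what unlocks the transition: agents with $k \le \mu$ friendships
are unconditionally eligible under the printed convention and act as
seeds. The package's reference fold scenario therefore places 20% of
agents at degree 2 and 80% at degree 10 with $\mu = 6$. This is the
simplest distribution with the two necessary ingredients — a seeding
mass at low degree (positive low branch $z \approx (1-f)p^*r^*E(0)$) and
a steep sigmoidal rise from the dense majority (bistability). Along an
upward drift of $p^*$ the low branch then terminates at a genuine
saddle-node near $p^* \approx 0.83$ (at $r^* = 0.9$, $f = 0.1$), where
continuation jumps to the high branch: the measured jump exceeds the
pre-jump increment by two orders of magnitude. A truncated Poisson
(pure ER) degree law at these mean degrees turns out to smooth $E$ so
much that the equation is monostable almost everywhere; the two-point
law keeps the wedge while preserving a realistic mean degree.

## 4. Slow dynamics, elections and reforms

`run_macro()` advances the slow variables once per unit step:

* drift: $f \leftarrow f + p_a(1 - z - f)$ and
  $p \leftarrow p + \epsilon(1 - p)$ (both respect their bounds for unit
  steps and rates $\le 1$);
* election: altruists win strictly iff
  $(z - d)\,e - f > 0$ with $e$ the enthusiastic fraction; the Heaviside
  convention is $H(0) = 0$ (a tie is not a win). The exponential form
  $e = e^{-p_v T}$ is the default for all voting arithmetic, matching
  the closed formulas; the exact form is a switch. Elections are checked
  every step by default; a cadence option evaluates them every $E$ steps
  since no cadence is prescribed by the theory;
* reforms: on a win, $p_a \leftarrow p_a(1-\zeta_a)$ and
  $p_v \leftarrow p_v(1-\zeta_v)$ — the continuous decay is discretized
  multiplicatively precisely so both rates stay non-negative.

**Branch continuation.** The altruist share is re-solved each step by
damped fixed-point iteration warm-started from the previous value
(damping 0.5, tolerance $10^{-12}$), with a Newton polish that only
accepts stable roots; if the tracked branch has vanished the solver
snaps to the nearest remaining stable root. This is what produces the
explosive jump at the fold on the way up and the different return path
on the way down (hysteresis): the suite checks that upward and downward
$p^*$ sweeps differ exactly on the bistable window and nowhere else.

## 5. Simulated index ensembles

`simulate_ensemble()` draws per-society initial rates independently and
uniformly:

| parameter | range | reading |
|---|---|---|
| $p_a$ | $[5\times10^{-5}, 10^{-3}]$ /step | recruitment slow enough that the parochial pool grows on the same timescale as the drift of altruism — the "race" is undecided at the start |
| $p_v$ | $[0.005, 0.06]$ /step | with $T = 20$, enthusiasm $e^{-p_vT}$ spans $\approx 0.30$–$0.90$: disheartened to enthusiastic electorates |
| $p$ | $[0.002, 0.08]$ /step | initial $p^*$ between 0.02 and 0.57 |
| $r$ | $[0.08, 0.35]$ /step | $r^*$ between 0.57 and 0.99, straddling the bistable regime |
| $f_0$ | $[0.02, 0.15]$ | initial parochial pools from marginal to entrenched |

Shared conditions: $\tau_1 = \tau_2 = 10$, $T = 20$, $\mu = 6$, the
reference degree distribution, $\epsilon = 3\times10^{-4}$,
$\zeta_a = \zeta_v = 0.05$, horizon 600 steps. The horizon and
$\epsilon$ are chosen together so that the drift carries a substantial
minority of societies — those with strong peer pressure and low apathy —
across the fold within the run, while the rest remain short of it;
ensembles of 200 societies then typically contain 15–35% reformed
societies.

End states are converted to indices: $DI = p^* + e^{-p_v T} - p^* e^{-p_v T}$
(equivalently $1 - (1-p^*)(1-e^{-p_vT})$, hence in $[0,1]$ before
rescaling, increasing in $p^*$ and decreasing in $p_v$), using the exact
$p^*$ by default (the exponential form is a switch), and
$CSI = 1 - p_a/\langle p_a\rangle$ with $\langle p_a\rangle$ the
ensemble mean of *pre-reform* recruitment rates. The proportionality
constants left unspecified by the index definitions are resolved by
min-max rescaling both indices to $[0,1]$ over the ensemble, which is
the only affine choice that uses no external anchor. Reformed societies
(with $p_a$, $p_v$ decayed toward 0) populate the high-DI/high-CSI arm,
unreformed ones scatter flatly — fitting the changepoint model to the
(DI, CSI) cloud recovers a steep slope above the break and a
near-zero gentle slope below it, the model-generated analogue of the
empirical two-mode pattern.

What the generator deliberately does **not** emulate: the marginal
distributions of real country indices, serial dependence between
indices and turnout, or any country-specific covariates. Passing tests
therefore demonstrate internal consistency of the mechanism and the
estimators, not calibration to any real-world scatter.

## 6. Changepoint regression

The continuous two-segment model
$y = a_1x + b$ for $x < x_c$ and $y = a_2(x-x_c) + a_1x_c + b$ otherwise
is linear in $(a_1, a_2, b)$ for fixed $x_c$. The fitter exploits this:
an exact profiled least-squares fit at each candidate changepoint
(deciles of $x$ by default), then Levenberg–Marquardt refinement of all
four coefficients from the best candidate, with $x_c$ box-constrained to
the interior of the observed range (at least 3 points per side; boundary
optima are flagged). If refinement fails or does not improve, a 512-point
profiled grid solution is used instead. The multistart matters because
the likelihood in $x_c$ is multimodal; the suite asserts that the
returned optimum dominates every grid candidate.

**Intervals.** Slopes and intercept use the asymptotic Wald form
$\hat\sigma^2 (J'J)^{-1}$ with a $t_{n-4}$ quantile. For the changepoint
itself the mean function is not differentiable, and a coverage
simulation (500 replicates at $n = 160$, noise SD 5, run in the
acceptance suite) shows the Wald interval undercovers; the default
$x_c$ interval therefore inverts the F test on the profiled residual sum
of squares, which restores close-to-nominal coverage. Wald and a
percentile pairs bootstrap (2000 resamples by default) remain available
as options. Identifiability caveat: with a slope contrast comparable to
the noise SD the changepoint is only weakly identified and no interval
method is well calibrated; the coverage conditions use a slope contrast
emulating the kinked index relationships the estimator targets
(gentle ≈ 3, steep ≈ 17, break at 6.8 on a 1–10 axis).

**Missing data** are dropped listwise with a message.

## 7. Principal component regression

`pcr_fit()` follows the textbook five steps exactly: centre and
normalize the predictors (unit sample standard deviation — normalization
is applied because the socio-economic columns live on wildly different
scales), centre the response so the intercept-free component regression
is well-posed, eigendecompose $X'X = V\Lambda V'$, regress on the
leading $k$ score vectors, and map back $\beta_k = V_k\gamma_k$.
Eigenvector signs are fixed so each column's largest-magnitude loading
is positive; $\beta_k$ is invariant to the choice, which exists purely
to stabilize comparisons. With $k = m$ the estimate equals ordinary
least squares on the standardized predictors to $10^{-10}$, which the
suite uses as an oracle.

`pcr_select()` fits $k = 1,\dots,m$ and keeps the adjusted-$R^2$
maximizer, exact ties resolving to the smaller $k$. A known limitation,
quantified by the acceptance runs: adjusted $R^2$ admits an extra
component whenever its partial F statistic exceeds 1, so on synthetic
tables whose response lives exactly in the span of the top three
components it recovers $k = 3$ only modally (roughly half of
replicates), with overselection to 4 or 5 otherwise. This is a property
of the selection rule itself, not of the implementation; with noise-free
responses the tie-break recovers $k = 3$ exactly.

## 8. Problem sizes and reproducibility

Defaults used by the tests and the acceptance script: $N = 10^4$ agents
for stationary-fraction checks, 200 societies × 600 steps per ensemble,
20 ensemble seeds for the slope sign test, 500 replicates for CI
coverage, $10^6$-point scans for the root-finding oracle. All
stochastic entry points take an explicit integer seed and are
bitwise-reproducible given it; the workbench writes manifests with
config, seed, versions and checksums so any artifact can be regenerated
from its manifest alone.

## 9. Known limitations

* The mean-field theory ignores degree–degree and spin–spin
  correlations; no pair approximation is provided. Agreement with the
  agent model is verified at frozen $f$ and large $N$, where it is
  within Monte-Carlo error.
* The delta-degree configuration has an absorbing zero-altruism state
  (§3); explosive transitions require low-degree seeding mass, which is
  a modelling statement about network heterogeneity, not a numerical
  artifact.
* Ensemble conditions are uniform draws over documented ranges; no
  attempt is made to match real-world index distributions.
* The changepoint model assumes a single break and homoscedastic
  Gaussian noise; alternative changepoint tests and imputation are out
  of scope.
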
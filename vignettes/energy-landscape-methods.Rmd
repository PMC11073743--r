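---
title: "Multistability of RA disease-activity states: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multistability of RA disease-activity states: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ralandscape)
```

## The problem

Under treat-to-target management, a rheumatoid-arthritis patient's disease
activity is reassessed roughly every three months and therapy is adjusted
toward remission. Over a three-year course this yields, per patient, a short
multivariate time series of routine measurements. Two clinically distinct
questions arise: *where* is the patient (good or poor disease state), and
*how entrenched* is that state — will it persist, or is the patient in a
transitional phase where treatment can still move them? `ralandscape`
answers both by reducing seven routine factors to two coordinates, a
discrete **state number** and a scalar **energy**, and then profiling whole
trajectories by clustering.

## From measurements to spins

Seven factors make up the state, in fixed model order: TJC28, SJC28, STAGE,
DrVAS, PtVAS, ESR1h, RF. Each is binarized to a spin: $-1$ when the
remission criterion is met, $+1$ otherwise. The cutoffs are RF 15 IU/mL,
ESR1h 10 mm (male) / 20 mm (female), PtVAS and DrVAS 10 mm, Steinbrocker
STAGE 1–2 vs 3–4, SJC28 1 and TJC28 1. A value exactly at a numeric cutoff
counts as remission: the joint-count criteria are satisfied *at* one joint
under the Boolean-remission convention, and `factor_profile(inclusive =
FALSE)` is available for the opposite reading. The 7-spin vector is indexed
as a state number $1..128$ with TJC28 as the least significant bit (state 1
= full remission pattern, 128 = fully active disease).

Visits lie on a fixed grid $t = 1..12$. Gaps are filled before binarization:
numeric factors (and HAQ) by linear interpolation between observed
neighbours; STAGE, being an ordinal classification that only ratchets in
practice, by the adjacent observed value. When the neighbours of a STAGE gap
disagree we deterministically carry the *earlier* value forward — the
substitution rule is symmetric in wording but must pick a side, and
carry-forward is the conservative reading for a damage score. Series
shorter than 12 visits are extended by repeating the final observation
(patients reaching stable remission or leaving follow-up), and leading gaps
are back-filled from the first observation, the mirror rule. Imputation
preserves observed values exactly and is idempotent.

## The pairwise maximum-entropy model

The distribution over the $2^7 = 128$ activity patterns is modelled as a
Boltzmann machine
$$P(X) = \frac{e^{-\Phi(X)}}{Z}, \qquad
\Phi(X) = -\sum_i \theta_i x_i - \sum_{i<j} w_{ij} x_i x_j,$$
with symmetric couplings and zero diagonal. This is the maximum-entropy
distribution consistent with the observed single-spin means and pairwise
correlations. Low energy means high probability, i.e. a stable state.

The likelihood treats every patient-visit as an independent draw — a
deliberate simplification (visits are in truth autocorrelated; see
*Limitations*). Fitting is plain gradient ascent with the moment-matching
updates
$$\theta_i \mathrel{+}= \varepsilon\,(\langle x_i\rangle_{\text{data}} -
\langle x_i\rangle_{\text{model}}), \qquad
w_{ij} \mathrel{+}= \varepsilon\,(\langle x_i x_j\rangle_{\text{data}} -
\langle x_i x_j\rangle_{\text{model}}),$$
with $\varepsilon = 0.2$, model expectations computed by exact enumeration
of the 128 states (a guard rejects systems beyond 20 spins, where
enumeration stops being sensible). The log-likelihood is concave, so this
converges globally; we stop when the max-abs moment mismatch — which *is*
the gradient — falls below $10^{-6}$, with an iteration cap of $5\times
10^6$ that in practice is never approached (a 600-patient cohort converges
in a few hundred iterations). Initialisation is the uniform model
$\theta = 0$, $W = 0$; no regularisation is applied. At convergence the
model moments equal the empirical moments to the tolerance, which the tests
exploit as the defining stationarity property.

The package ships a reference parameter set, `ra_reference_params()`, a fit
of this model to a hospital treat-to-target RA registry, together with its
128-row state table (`ra_reference_state_table()`). These serve as the
default landscape in examples and as a regression oracle: recomputing the
table from the parameters must reproduce every energy to $10^{-3}$ (the
parameters are stored to 4 decimals) and both integer columns exactly.

## The energy landscape

States are vertices of the 7-cube; edges join patterns differing in one
factor. On this graph:

* **Dynamics.** `steepest_descent_step()` moves to the lowest-energy
  neighbour if it is strictly lower, else stays; ties (which cannot arise
  from generic real parameters) break to the smallest state number for
  determinism.
* **Minima.** A state is a local minimum when all 7 neighbours have energy
  $\ge$ its own. The non-strict comparison means a perfectly flat landscape
  is all-minima; downstream operations require at least one strict
  attractor and the reference landscape has exactly two: state 81 (only RF
  and PtVAS active — "good stability", the near-remission pattern) and
  state 128 (everything active — "poor stability", the treatment
  dead-end).
* **Basins.** Iterated descent assigns every state to its attractor;
  strict decrease guarantees termination in at most 127 steps.
* **Barriers.** The barrier from minimum $X$ to $Y$ is the minimax path
  level minus $\Phi(X)$: the lowest energy ceiling under which the two
  basins connect. We compute it by sorting states by energy and unioning
  single-flip edges in order until the minima join (union–find); the test
  suite keeps an independent bisection-plus-BFS oracle. The merge level
  between the two reference minima is $-1.4836$, reported as $-1.48$ at
  display precision — the **transition threshold**. 109 of 128 states
  ($\approx 85\%$) sit at or above it (the count includes the saddle state
  itself, which is by definition transitional). With more than two minima
  the pairwise saddle levels assemble into a disconnectivity tree by
  single-linkage merging; `write_disconnectivity_dot()` exports it.
* **Quadrants.** Each state gets a two-letter label: G/P by basin
  (good/poor stability) and L/H by energy below/at-or-above the threshold —
  G-L entrenched near remission, G-H improving but still mobile, P-H active
  and treatable, P-L entrenched active disease. `quadrant_occupancy()`
  tabulates a cohort's counts and HAQ-remission shares per visit. The
  good minimum defaults to the one meeting the most remission criteria
  (state 81 for the reference landscape) and is overridable; the HAQ
  functional-remission cutoff defaults to 0.5, a convention, and is a
  parameter everywhere it is used.

## Trajectory clustering

Each patient becomes a 12-point series of 9-vectors: the seven spins, the
energy of the visit's state, and HAQ. Channels are deliberately left
unscaled by default — spins are $\pm 1$, reference energies span roughly
$[-3.6, 3.8]$ and HAQ $[0,3]$, so no channel dominates; a global z-scoring
flag exists for other parameter sets. Distances are dynamic time warping
with Euclidean point cost and the three unit-weight monotone steps, no
window, no step weighting — warped paths cannot cross, and series of
unequal length remain comparable. The inner recursion is compiled (Rcpp)
because model selection evaluates it hundreds of thousands of times; a
brute-force enumeration of all monotone alignments serves as the
independent oracle in the tests.

Clustering is k-means in the DTW geometry: assign to the nearest center,
update centers as visit-wise means (well-defined because all series share
the 12-point grid — this is the plain-mean update, not a DTW barycenter),
stop on unchanged assignment or 50 iterations. Because the mean update
minimises the lock-step rather than the DTW objective, SSE monotonicity is
checked empirically per run rather than assumed. Choices the procedure
itself does not pin down, made once and kept: 10 random restarts with
centers seeded from the data (best SSE wins), and an emptied cluster is
reseeded with the trajectory farthest from its center. `select_k()` reports
the elbow (SSE) curve and the mean silhouette per $K$ — silhouettes on raw
DTW distances, elbow on squared ones as SSE is defined — and recommends the
silhouette maximiser. Cluster labels carry no fixed meaning; the analysis
scripts name clusters post hoc from their mean basin and energy.

## The synthetic cohort generator

No registry data ship with the package, so every downstream claim is
validated on simulated cohorts with known truth. The generator draws
latent states, dresses them in raw measurements, and degrades the table
the way registry data are degraded:

* **States.** `iid` mode draws each visit independently from the exact
  128-state distribution (the sampling model the likelihood assumes) by
  categorical sampling — exact and cheap at $N = 7$, no MCMC. `glauber`
  mode runs heat-bath single-spin sweeps between visits, giving
  autocorrelated trajectories with the same stationary law, for realism
  checks. `clustered` mode plants three regimes of equal size for recovery
  experiments: *toward-good* starts in a transitional state of the good
  basin and relaxes by steepest descent; *toward-poor* likewise into the
  poor minimum; *unstable* redraws every visit from the transitional
  (at-or-above-threshold) states. Settled patients take brief single-flip
  excursions with probability 0.05 per visit so trajectories are not
  piecewise-constant.
* **Raw values.** Inverse binarization draws uniformly from the correct
  side of each cutoff within physiologic ranges (RF up to 2,200 IU/mL,
  ESR to 130 mm, VAS to 100 mm, joint counts as integers to 28, STAGE from
  \{1,2\} or \{3,4\}), guaranteeing that binarization recovers the latent
  spins exactly.
* **HAQ.** A linear severity model, $0.2 + 0.15 k + N(0, 0.2^2)$ clipped to
  $[0,3]$ with $k$ the active-factor count: about 0.2 in full remission,
  about 1.25 with everything active, in the range seen in treat-to-target
  cohorts.
* **Missingness.** Post-baseline cells are deleted independently (default
  5%) and series are truncated with a per-visit stopping probability
  (default 2%), emulating early remission or drop-out; the first visit is
  never deleted. All randomness flows from one seed; identical
  configurations reproduce byte-identical cohorts.

What passing on these cohorts does and does not show: the generator
reproduces the *statistical* structure the methods assume (Boltzmann
margins, state-linked HAQ, benign missingness), not the clinical structure
of a registry — no treatment effects, no informative drop-out, no
demographic confounding. Recovery results are therefore statements about
the correctness of the implementation, not about registry effect sizes.

## Problem sizes and numerical choices

The validation experiments use a 600-patient × 12-visit i.i.d. cohort for
parameter recovery (max-abs parameter error below 0.1, moments matched to
$10^{-6}$) and a 120-patient three-regime cohort for cluster recovery
(silhouette selects $K = 3$; adjusted Rand index vs truth $\ge 0.9$) —
sizes comparable to the 597-patient registry scale while keeping the whole
suite fast. One instructive wrinkle the analysis scripts surface: running
recovery through the *full* pipeline, with missingness injected and then
imputed, inflates coupling errors slightly (repeat-last-value extension
induces serial dependence the i.i.d. likelihood does not model) — the
clean-sample experiment isolates the fitter, the pipeline experiment the
whole path. Energies are computed on the log scale where overflow is
possible (partition function, probabilities); state enumeration is exact
throughout; all tie-breaks (steepest descent, k-means assignment) are
deterministic.

## Limitations

* The i.i.d. likelihood ignores within-patient autocorrelation; parameters
  remain consistent for the stationary margins under mixing, but standard
  errors (not computed here) would not be.
* The energy landscape is a property of the fitted *population* model;
  individual dynamics are not fitted.
* Binarization discards severity gradations within the nonremission side.
* The HAQ cutoff 0.5 and the good/poor labelling convention are
  configurable conventions, not estimated quantities.
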
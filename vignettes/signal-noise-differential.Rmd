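---
title: "Signal correlations, state-dependent noise correlations, and task information coding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal correlations, state-dependent noise correlations, and task information coding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model and its quantities

`signoise` analyses how the *noise-correlation* structure of large-scale
brain activity reconfigures between rest and task states relative to the
*signal-correlation* structure, and what that reconfiguration means for how
much task information the activity carries.

The substrate is a **beta series**: per subject, a matrix of block-wise
activation coefficients (regions x blocks), estimated by an ordinary
least-squares GLM in which every task block has its own boxcar regressor
convolved with a canonical double-gamma hemodynamic kernel, fit
simultaneously with nuisance regressors. From a beta series with tasks
$t = 1..T$ and blocks $b = 1..B$ per task:

* **Signal correlation (SC)** between regions $i, j$: the Pearson
  correlation, across tasks, of their *mean* activations
  $\bar\beta_i(t)$ — the similarity of their task tuning.
* **Noise correlation (NC)** within a task: the Pearson correlation, across
  that task's blocks, of the block-to-block fluctuations. The task-general
  **tNC** is the unweighted mean of per-task NC matrices (rest excluded);
  the **rNC** is the same estimator applied to interleaved rest blocks.
  SC uses only cross-block means and is bit-invariant to block order; NC
  uses only cross-block fluctuations — the two estimators consume orthogonal
  parts of the data.
* **deltaNC** $= \mathrm{tNC} - \mathrm{rNC}$: the state-dependent NC change
  against the spontaneous baseline.
* **Signal-noise differential** $= \mathrm{SC} \odot \Delta\mathrm{NC}$
  (elementwise). A positive entry (*aligned*) means task-state noise moved
  into the pair's signal direction — putatively information limiting; a
  negative entry (*anti-aligned*) means it moved away — putatively
  information enhancing. Exact zeros form a third, *null* category, which is
  why aligned and anti-aligned percentages need not sum to 100.

Downstream, the differential matrix is thresholded (top 20% of positive or
negative entries by default) and fully connected subsets (**k-cliques**) of
exclusively aligned or anti-aligned pairs are enumerated; their multitask
decodability is measured with a leave-one-block-out, bootstrap-resampled,
ridge-multinomial decoder, with a within-task block-shuffling control that
destroys noise correlations in the training folds only.

## The linear statistical network model

As an analytic companion, `simulate_linear_network()` implements a static
linear superposition model: unit activity is
$x = x_\text{shared} + x_\text{private} + w_d\, s_\text{drive} + w_g\, g$
with all components standard normal, $s_\text{drive}$ present only in the
task state, and default weights $w_d = w_g = 0.75$ with 300 units in 10
networks and 10,000 samples. Because variances add,
population correlations have closed forms — e.g. rest within-network
$\;(1 + w_g^2)/(2 + w_g^2) = 0.60976$, rest between-network
$w_g^2/(2+w_g^2) = 0.21951$, task within-network (within-network drive)
$(1+w_d^2+w_g^2)/(2+w_d^2+w_g^2) = 0.68$ — and `analytic_correlations()`
serves as an exact oracle for the simulator. Under this model any positive
drive moves noise correlations in the direction of the existing shared
structure, i.e. deltaNC aligns with connectivity; departures from that
prediction in data are what the differential analysis quantifies.

Two points the source text leaves open are resolved as configuration rather
than assertion. First, the unit count is stated once as 300/10/30 and once
as 360; the constructor defaults to 300/10/30 and is fully configurable.
Second, whether the stimulus drive is shared within each network or globally
is not stated; `drive_topology` exposes `"within_network"` (default),
`"global"`, and `"network_subset"`. Under within-network drive the analytic
between-network deltaNC is slightly *negative* (task variance grows while
between-network covariance does not); only global drive yields exclusively
positive deltaNC. Both are implemented and documented, neither asserted as
the canonical intent.

## The synthetic-data generator

`scenario_spec()` describes a population: a tuning matrix (regions x tasks
of mean activations — its row correlation *is* the population SC),
state-specific noise covariances (their correlations are the population
rNC/tNC), between-subject tuning jitter, and the block design (defaults:
26 tasks x 16 blocks, plus 16 interleaved rest blocks — the rest-block count
is a convention chosen to match task blocks and equalize estimator variance,
not an empirical fact). Noise is multivariate Gaussian: every quantity the
pipeline estimates is second order (correlations), so Gaussianity is the
minimal sufficient model. Blocks are interleaved round-robin across tasks.
Jitter applies to tuning only; noise covariance is shared across subjects.

What the generator deliberately does **not** emulate: hemodynamic
autocorrelation in the block estimates (blocks are independent draws),
physiological noise, spatial autocorrelation of parcels, between-subject
covariance heterogeneity, and task-set imbalances. Passing tests therefore
demonstrate estimator and pipeline correctness under a known second-order
population, not robustness to every property of real fMRI.

### Aligned and anti-aligned scenarios

`make_alignment_scenarios()` derives two task-noise regimes from a base
scenario: entrywise shifts of the task-state noise correlation by
`+delta * sign(SC)` (aligned) or `-delta * sign(SC)` (anti-aligned), with
rest noise and all marginal variances shared between the two — so decoding
differences cannot come from univariate signal strength. Pairs with
`|SC| <= sc_tol` are treated as zero-signal and left unshifted: a
constant-magnitude shift applied to the arbitrary signs of near-zero SC
pairs makes any realistically sized correlation matrix indefinite, and the
aligned/anti-aligned notion is only defined on pairs that have a signal
direction. PSD violations are an error that names the smallest eigenvalue;
opt-in repair (eigenvalue clipping with re-normalization to unit diagonal)
is logged, never silent.

### The study-conditions scenario

`signal_axis_scenario()` is the canonical scenario used by the acceptance
checks: 60 regions, 26 tasks x 16 blocks + 16 rest blocks, 24 subjects. The
regions form 6 bipolar *systems* of two 5-region *modules* each. All regions
of a system share one orthogonal task-tuning axis pattern — carried
positively by the first module and negatively by the second — plus a weaker
system-common pattern (weight 0.7) carried positively by both. Signal
correlations are therefore +1 within modules, about -0.34 between the two
modules of a system, and exactly 0 between systems (the tuning patterns are
mean-centred and orthonormal). Rest noise is an explicit
factor model: a global component (variance 0.05), a system-shared component
with uniform loadings (0.45 — collinear with the common-mode *signal* but
orthogonal to the bipolar axis), a component along the coding axis itself
(0.25), and private noise filling each region's variance to 1 (0.25 at
rest). Tuning carries no region-private component and no subject jitter.

This geometry was chosen for three reasons. First, it makes the entrywise
SC-sign shift exactly equivalent to strengthening (aligned) or weakening
(anti-aligned) the coding-axis noise component — the geometric picture
behind the aligned/anti-aligned distinction — while keeping both shifted
covariances valid factor models with matched unit variances (the axis
variance must exceed the shift, so `var_axis = 0.25` supports the moderate
shift of 0.2). Second, network-matched cliques on a module pair necessarily
mix both signs of the axis — and the packaged decoding comparison further
requires at least two members from each module, so the clique samples the
axis in a balanced way rather than collapsing onto one module plus a token
member of the other — which gives the block-shuffle control something
real to destroy: aligned shifts concentrate noise *along* the coding axis,
which no decoder can remove, so aligned cliques decode worse and gain
little from seeing the correlation structure; anti-aligned cliques instead
face strong system-shared noise lying on their common-mode signal
component, which a decoder can only discount by learning the correlations —
so destroying them in the training folds costs anti-aligned cliques
accuracy. An ideal-observer analysis of these covariances (full-covariance
versus diagonal linear discriminants) shows the same asymmetry, so the
phenomenon is a property of the population model, not of the particular
classifier. Third, tuning is purely shared because, under marginal-variance
matching, any region-private tuning channel hands the *aligned* scenario a
spuriously clean private-noise subspace (its private noise shrinks as the
shared shift grows) that a covariance-aware decoder exploits — a
variance-bookkeeping artifact that would contaminate the shuffle contrast.

Worth keeping in mind when mapping these synthetic results onto real data:
a regime dominated by region-private tuning with noise correlations *raised*
along positive-SC pairs behaves oppositely — there, higher correlation aids
decoding by cancelling shared noise across differently tuned regions. Real
cortex plausibly contains both regimes; the scenario instantiates the
coding-axis geometry that the aligned/anti-aligned analysis is about. The
clique-identification stage of the packaged checks retains the top 30% of
same-sign differentials (rather than the 20% default) because the scenario's
differentials come in two magnitude tiers (within-module and cross-module)
and both tiers must survive thresholding for module-spanning cliques to
exist.

## Estimation and numerical choices

* **GLM.** Canonical double-gamma kernel (shape 6 positive lobe, shape 16
  undershoot at ratio 1:6, 32 s support, unit peak), sampled at the TR
  (default 1 s; not a data fact, configurable). A block occupies the
  half-open frame interval `[floor(onset/tr), floor((onset+duration)/tr))`,
  0-based. Plain OLS, no prewhitening; rank deficiency is an error naming
  the offending columns. Instruction periods are simply absent from events
  tables. Nuisance signals are accepted as a precomputed matrix.
* **FIR residualization** subtracts, per task and peri-block frame offset
  (onset through 20 s past offset), the cross-block mean response. Frames
  claimed by overlapping extended windows belong to the later block's task
  (logged); the operation is idempotent.
* **Correlations.** Pearson throughout SC/NC; group averaging defaults to
  the plain mean of r with Fisher-z pooling as an option; intersubject SC
  offers leave-one-out (default) and pairwise schemes.
* **Signed modularity.** `Q+`/`Q-` are computed on the positive part and the
  magnitude of the negative part with `e_ij = s_i s_j / v` (sum strengths);
  the printed combination is typographically ambiguous in the source, so the
  standard asymmetric convention `Q* = Q+ - (v-/(v+ + v-)) Q-` is the
  default, the additive sign is a flag, and the choice is recorded in output
  metadata. Diagonals are zeroed before all metrics. Segregation uses
  *mean* within/between weights per region (sum vs mean being unstated
  conventions elsewhere, both documented here).
* **Gradients.** Off-diagonal entries below the `1 - retain_fraction`
  quantile (default top 20% of signed values; absolute-value mode available)
  are zeroed, self-weights are kept, rows are centred, and eigenvectors of
  the region-space covariance give the loadings. The permutation test for
  gradient correspondence permutes region labels with no
  spatial-autocorrelation correction and is therefore anti-conservative for
  smooth maps.
* **Clique search** expands igraph's maximal cliques (Bron-Kerbosch) into
  k-subsets under a configurable work budget with deterministic ordering;
  within budget it is exact (verified against exhaustive subset search).
* **Decoding.** Folds = blocks per task; fold f tests block f of every task.
  Per training fold: optional within-task shuffle, then bootstrap (20
  samples per task, with replacement), then feature z-normalization with
  bootstrap-training statistics applied to train and test, then a
  ridge-penalized multinomial logistic model (penalty `1/n_train`,
  configurable — the inverse-unit-strength convention). Score ties break to
  the lowest class index; all sub-seeds derive from the master seed.
* **Paired statistics.** Wilcoxon signed-rank with the exact null for up to
  100 informative pairs (midranks for ties, zeros dropped; all-zero
  differences give p = 1 by convention), normal approximation beyond;
  Bonferroni correction over the declared family size.
* **Determinism.** Every random stream is derived from a master seed via a
  string-keyed hash (`derive_seed`), so adding a stage never perturbs
  another stage's draws and identical configurations are bit-reproducible.

## Problem sizes used by the checks

The packaged checks run the linear model at its native size (300 units,
10,000 samples, 10 seeds), estimator-recovery and decoding analyses at the
study-conditions scale above (60 regions, 24 subjects), chance-level
controls over 20 permutation seeds, and oracle equivalences on 8-15-node
graphs where brute-force enumeration is feasible. These sizes were chosen so
each property is tested with comfortable statistical margin on a single CPU.

## Known limitations

* The aligned/anti-aligned scenario machinery shifts correlations entrywise;
  strongly heterogeneous shift patterns can leave the PSD cone, and the
  opt-in repair perturbs the intended entry values slightly.
* Exhaustive k-clique enumeration is exponential in the worst case; the work
  budget makes failures explicit rather than silent, but very dense
  thresholded graphs require raising the threshold, not the budget.
* The decoder is one fixed linear model; absolute accuracies depend on its
  regularization, so only paired contrasts (aligned vs anti-aligned,
  shuffled vs unshuffled) should be interpreted.
* Rest blocks are modelled as zero-mean states with their own covariance;
  real interleaved rest carries task-set carry-over effects that the
  generator ignores.
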
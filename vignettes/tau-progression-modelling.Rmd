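---
title: "Modelling tau progression on the structural connectome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling tau progression on the structural connectome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tauspread)
```

## The model

Pathological tau protein accumulates through two interacting processes:
local, prion-like production within a brain region, and transport of
pathology between regions along white-matter connections. `tauspread`
models longitudinal regional tau PET SUVR $s_i(t)$ on a structural
connectome of $R$ regions with the *local FKPP* equation

$$\frac{ds_i}{dt} \;=\;
  -\rho \sum_{j=1}^{R} \mathcal{L}_{ij}\,(s_j - s_{0,j})
  \;+\; \alpha\,(s_i - s_{0,i})\bigl[(s_{\infty,i} - s_{0,i}) -
  (s_i - s_{0,i})\bigr],$$

where $\rho \ge 0$ (per year) is a global transport rate, $\alpha$ (per
year per SUVR) a global net production rate (negative when clearance or
atrophy dominates), $s_{0,i}$ the healthy baseline SUVR of region $i$, and
$s_{\infty,i}$ its carrying capacity. The baselines and capacities are the
regionally varying ingredients: a region with a wide span
$q_{\infty,i} = s_{\infty,i} - s_{0,i}$ accumulates signal faster under
the same $\alpha$, which is how the model expresses regional
vulnerability. Under the change of variables
$q_i = (s_i - s_{0,i})/q_{\infty,i}$ the system becomes a standard
network FKPP equation with $\hat\alpha = \alpha\,q_\infty$ and
$\hat{\mathcal{L}} = Q_\infty^{-1} \mathcal{L}\, Q_\infty$, and
`rescale_to_concentration()` moves trajectories onto that $[0,1]$
concentration scale.

The transport operator is the volume-weighted graph Laplacian
$\mathcal{L} = V^{-1} (D - A)$ with $V = \mathrm{diag}(v/v_r)$, built by
`build_laplacian()` and `volume_weight()` from a streamline-count
adjacency matrix and regional volumes. Volume weighting makes pure
diffusion conserve the volume-weighted total signal
$\sum_i v_i s_i$, which the test suite verifies to $10^{-8}$ relative
drift over 50 simulated years. Group volumes can be formed with
`group_normalised_volumes()`, which normalises each subject by their
largest regional volume before averaging, so entries lie in $(0, 1]$.

Four reduced or extended variants are available through `model_spec()`:

* **global FKPP** — scalar bounds $\min_i s_{0,i}$, $\max_i s_{\infty,i}$
  shared by all regions (no regional vulnerability);
* **diffusion** — $\alpha = 0$, transport only;
* **logistic** — $\rho = 0$, production only, regions decoupled;
* **heterodimer** — coupled healthy/toxic kinetics
  ($k_0, k_1, k_{12}, \tilde k_{1,i}$), whose linearisation about the
  healthy state $p_i = k_0/k_1$ reduces to the FKPP form with linear
  coefficient $k_0 k_{12}/k_1 - \tilde k_{1,i}$ and quadratic coefficient
  $k_0 k_{12}^2 / k_1^2$; the carrying-capacity heterogeneity of the local
  FKPP model corresponds to regionally varying toxic clearance.

Integration uses `deSolve::lsoda` (adaptive, stiff-capable) driving
compiled right-hand sides, with tolerances `rtol = 1e-8`, `atol = 1e-10`
for simulation. Time is measured in years throughout; seed regions are
addressed by label (e.g. `lh_entorhinal`), never by atlas index, because
atlas orderings differ between pipelines.

### Bounds, fixed points, and overshoot

The healthy state $s \equiv s_0$ is a fixed point of every family, and
the baseline is a lower barrier: trajectories started at or above
baseline never drop below it. The upper boundary is more subtle. When the
capacity span $q_\infty$ is constant across regions the box
$[s_0, s_\infty]$ is invariant (the transport operator then satisfies a
maximum principle). With heterogeneous spans, however,
$\hat{\mathcal{L}} = Q_\infty^{-1}\mathcal{L} Q_\infty$ has no maximum
principle at $q = 1$: a low-capacity region fed by a high-capacity
neighbour is held *above* its own carrying capacity, transiently and even
asymptotically — $s \equiv s_\infty$ is not a fixed point unless spans
are constant. At realistic rate scales we measure persistent overshoots
of 0.2-0.4 SUVR in the most inflow-dominated regions. This is a genuine
feature of volume-weighted transport between regions of unequal
capacity, not an integration artefact (it survives tightening the solver
tolerances by four orders of magnitude), and the test suite asserts its
existence rather than pretending the box is invariant.

## Regional parameters from cross-sectional data

`fit_region_mixture()` describes a region's cross-sectional SUVR sample
as a two-component Gaussian mixture (tau-negative and tau-positive
populations), fitted by EM via **mclust** with its deterministic
model-based initialisation, and records AIC scores for the one- and
two-component fits so that regions without a bimodal signal can be
flagged. `derive_regional_params()` then sets

* $s_{0,i}$ = mean of the negative component,
* $s_{\infty,i}$ = 99th percentile of the positive component.

The percentile is parametric by default
($\mu_+ + z_{0.99}\sigma_+$) — reproducible and independent of sample
size — with an empirical alternative (`method = "empirical"`) using the
samples assigned to the positive component.

Tau positivity of a subject is decided by composite regions: the medial
temporal composite (bilateral entorhinal + amygdala) and the neocortical
composite (bilateral middle + inferior temporal). For each composite,
`composite_threshold()` fits a mixture to per-subject composite means and
returns the smallest SUVR at which the posterior probability of the
positive component — including the mixture weights, not just the density
crossing — reaches 50%, located by bisection between the component
means (for an equal-weight, equal-variance mixture this is exactly the
midpoint). `classify_subject()` labels a subject `T+` when the *last*
scan strictly exceeds either composite threshold; a value exactly at the
threshold is negative.

## Hierarchical Bayesian calibration

For subject $n$ with scans $\mathbf{t}^n$ (years from first scan), the
data model is

$$\mathbf{Y}^n \sim \mathcal{N}\!\bigl(\mathbf{f}(\mathbf{y}_0^n,
\theta_n, \mathbf{t}^n),\ \sigma^2 I\bigr), \qquad
\theta_n = (\rho_n, \alpha_n),$$

with the initial condition fixed at the first observed scan. Subject
rates are exchangeable draws from population laws
$\rho_n \sim \mathcal{N}(\rho_\mu, \rho_\sigma)$ truncated to
$[0, \infty)$ (with the truncation normalisation included in the
density) and $\alpha_n \sim \mathcal{N}(\alpha_\mu, \alpha_\sigma)$.
Priors are weakly informative:
$\rho_\mu, \rho_\sigma, \alpha_\sigma, \sigma \sim
\mathrm{Lognormal}(0, 1)$ and $\alpha_\mu \sim \mathcal{N}(0, 1)$
(production can be negative). All are overridable through the `priors`
argument of `fit_hierarchical()`.

Fixing $\mathbf{y}_0^n$ at the first scan absorbs that scan's noise into
the initial condition. The first scan's residual is then identically
zero, so the fitted $\sigma$ estimates the residual spread over
$(T_n - 1) R$ informative observations divided by $T_n R$ — a downward
bias of $\sqrt{(T-1)/T}$ (about 18% at three scans). The synthetic
generator reproduces exactly this convention (noise on follow-up scans
only), keeping the calibration experiments internally consistent; the
bias is a documented limitation of the fixed-initial-condition design,
not of the sampler.

### The sampler

`fit_hierarchical()` uses an adaptive Metropolis-within-Gibbs scheme
designed around the structure of the posterior:

* **Subject block.** Conditional on the population parameters and
  $\sigma$, the subject posteriors are mutually independent. All
  subjects' rates are therefore proposed simultaneously by Gaussian
  random walks and evaluated with *one* stacked ODE solve (an $NR$-state
  system of independent copies), with per-subject accept/reject.
  Proposals with $\rho_n < 0$ are rejected through the prior support.
* **Population and noise blocks.** $(\log\rho_\mu, \log\rho_\sigma)$,
  $(\alpha_\mu, \log\alpha_\sigma)$ and $\log\sigma$ are updated by
  random-walk steps that require no ODE solves (the noise update uses
  cached residual sums of squares); several of these cheap sub-sweeps
  run per iteration.
* **Adaptation.** Proposal scales adapt by Robbins-Monro toward a 0.35
  acceptance rate during warm-up only, so retained draws come from a
  fixed kernel. Runs are exactly reproducible given the seed and
  configuration, which the test suite asserts draw-for-draw.

Because subject rates are updated *conditionally* on the population
parameters, the centred parameterisation mixes well here and no
non-centred reparameterisation is needed (the funnel pathology is a
property of joint gradient-based samplers). Convergence is summarised by
split-$\hat R$ for every parameter, with a warning outside
$(0.99, 1.01)$; divergence-style failures appear as counted ODE-solve
rejections. Default settings are 4 chains of 2000 retained draws after
1000 warm-up sweeps; the calibration experiments below use 2 chains of
500 at desk scale.

Inside the sampler, ODE solves run at `rtol = 1e-6`, `atol = 1e-8` —
looser than the simulation default, for speed. `check_ode_sensitivity()`
compares a sampler-tolerance solve against a `1e-10/1e-12` reference so
that the tolerance gap can be checked to be orders of magnitude below the
observation noise on any given problem.

## Model comparison and controls

`compute_bic()` scores in-sample fit as
$\mathrm{BIC} = k\log n - 2\log L$, where $L$ is the total data
likelihood at the best *retained posterior draw* (the draw of all sampled
quantities jointly maximising the total log-likelihood, scanned over
every retained draw), $n$ counts scans × regions over subjects, and $k$
counts free parameters: $2N + 5$ for the two-rate FKPP forms,
$N + 3$ for the single-rate diffusion and logistic models.

`compute_elpd()` scores out-of-sample predictive accuracy on held-out
scans (see `holdout_split()`): for each subject the held-out likelihood
is averaged over posterior draws with a numerically stable
log-mean-exp, then summed over subjects.

`spatial_shuffle()` implements the negative control: one random
permutation of region indices applied identically to every subject's
SUVR columns and to $(s_0, s_\infty)$, leaving the connectome fixed.
Refitting on shuffled data destroys the correspondence between
concentration gradients and graph edges, so the transport posterior
collapses toward zero *when the original signal was genuinely
network-mediated*. Two practical points emerged in building this
control. First, transport must actually dominate the observable signal
change for the control to be informative: at desk scale (10 regions,
3-4 scans, noise 0.05 SUVR) a transport rate of 0.02/yr is only weakly
identified, and with an uninformative likelihood the Lognormal(0,1)
prior — whose median is 1 — pulls both the true and shuffled posteriors
to the same place. The packaged control experiment therefore runs at
$\rho_\mu = 0.05$, $\alpha_\mu = 0.02$ on early-disease cohorts
(onset 1-6 years, strong seed gradients), where the shuffled posterior
demonstrably collapses. Second, shuffled and true posteriors are
compared by the Mann-Whitney U test on pooled draws
(`compare_posteriors_mwu()`, 10 shuffle repeats by default) at the 0.01
level, together with the direction of the median shift.

## The synthetic cohort generator

All validation runs on synthetic data with known ground truth, because
the motivating imaging cohorts are access-controlled.

* `generate_connectome()` draws a connected weighted graph: a random
  spanning tree guarantees connectivity, extra edges reach the requested
  density, weights are log-normal (heavy-tailed, like streamline
  counts), and normalised volumes are uniform on $[0.2, 1]$.
* `generate_regional_params()` draws baselines in 1.0-1.3 SUVR and
  capacity spans of 0.4-1.4 SUVR, matching the spread of
  mixture-derived capacities across cortex.
* `generate_crosssectional_suvr()` emits per-region two-component
  mixtures whose positive component is placed so its Gaussian 99th
  percentile equals the true capacity, so the calibration pipeline can
  be round-tripped.
* `generate_cohort()` draws subject rates from the population laws
  (defaults: $\rho_\mu = 0.007$, $\rho_\sigma = 0.011$,
  $\alpha_\mu = 0.130$, $\alpha_\sigma = 0.100$ per year — the fitted
  values for an established-pathology amyloid- and tau-positive
  population — and $\sigma = 0.05$ SUVR, the order of typical tau PET
  residual variability), seeds the bilateral entorhinal analogue at
  $(s_0 + s_\infty)/2$, evolves each subject through a uniform 10-25
  year disease-duration phase under their own rates, and then observes
  1-2-yearly scans with i.i.d. Gaussian noise on follow-ups. The onset
  phase matters: an established-pathology cohort has tau well beyond
  the seed regions, which is the regime in which production-only models
  are competitive and pure diffusion fails — the qualitative
  model-comparison ordering the package reproduces. Early-disease
  cohorts are obtained with `onset_years = c(0, 0)`.

What the generator does **not** emulate: the spatial autocorrelation and
hub structure of real tractography; tracer-specific off-target binding;
atrophy-coupled SUVR decline; signal-dependent (non-i.i.d.) noise; scan
scheduling correlated with disease stage. Green tests therefore
demonstrate internal consistency of the estimation machinery under the
model's own assumptions — parameter recovery, calibration, ranking of
model families, and the shuffle control — not fidelity to any particular
imaging cohort.

## Experiment scales

The packaged experiments run at desk scale, chosen to keep the full
validation suite in the minutes range on a single core while preserving
the shape of the study design: 8-10-region connectomes, cohorts of 8-20
subjects with 3-5 scans, 2 chains × 500 retained draws, 20 replicates
for the coverage and ranking experiments, 10 shuffle repeats. The
parameter-recovery experiment uses the generating values
$\rho_\mu = 0.02$, $\alpha_\mu = 0.15$, $\sigma = 0.05$; the
simulation-based-calibration variant draws population truths from
informative priors (so generated dynamics stay in the observable regime)
and checks rank-uniformity of the truth within posterior draws.

## Known limitations

* $s_0$ and $s_\infty$ are fixed during dynamics; if baselines or
  capacities themselves drift with disease, that drift is folded into
  $\alpha$.
* The fixed-initial-condition convention biases $\sigma$ downward by
  $\sqrt{(T-1)/T}$ and treats the first scan as noise-free.
* i.i.d. noise underestimates uncertainty in high-signal regions; a
  signal-proportional noise model would need a different likelihood.
* The random-walk sampler needs more iterations per effective draw than
  a gradient-based sampler would; at the default problem sizes this is
  amply covered by the chain lengths, and split-$\hat R$ is reported so
  under-mixing is visible.
* With a single scan per subject the subject posterior is prior-driven;
  forecasts from one scan are population forecasts (the iterative
  forecasting experiment quantifies exactly this).
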
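---
title: "A spiking model of odor information segregation in the glomerular layer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A spiking model of odor information segregation in the glomerular layer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glomsim)
```

## The scientific question

The olfactory system recognizes odors almost independently of their
concentration, yet it can also report how concentrated an odor is.
`glomsim` implements a spiking-network model of the first processing
stage of the olfactory bulb — the glomerular layer — built to test
whether this *segregation* of odor identity and odor intensity can
arise there, from circuit interactions alone.  The model's claim is
architectural: mitral cells (MC) and external tufted cells (ET) are
given *identical* intrinsic parameters, so any division of labour
between them (MC output correlating with odor identity, ET output
with concentration) must be produced by the wiring.

## Neurons

Every cell is a two-variable quadratic ("Izhikevich") neuron,

$$C\,\dot v = k\,(v - v_r)(v - v_t) - u + I(t), \qquad
  \dot u = a\,\bigl(b\,(v - v_r) - u\bigr),$$

with the after-spike reset $v \ge v_{peak} \Rightarrow v \leftarrow
c,\ u \leftarrow u + d$.  Four parameter sets are shipped
(`ob_param_table()`): mitral and external tufted cells share one set
($C = 40$ pF, $k = 1$, $v_r = -55$ mV, $v_t = -50$ mV, $a = 0.4$
ms$^{-1}$, $b = 2.6$, $v_{peak} = 35$ mV, $c = -50$ mV, $d = 200$);
periglomerular (PG) and short axon (SA) interneurons have their own
sets, with *negative* recovery sensitivity ($b = -0.94$ and $-0.68$),
meaning their recovery variable amplifies depolarization instead of
opposing it.  The recovery increment `d` is implemented numerically
as tabulated; its nominal unit (the product of `b` and a voltage)
is inherited from the recovery equation.

Integration is classical fourth-order Runge–Kutta at a fixed step of
0.1 ms, with each neuron's input current held constant across the
step.  Numerical choices worth stating explicitly:

* the reset is checked once, **after** a completed RK4 step, never
  inside substages — the simplest deterministic treatment of the
  discontinuity.  Accuracy is guarded by a convergence test (halving
  `dt` changes a 0.5 s spike count by at most one spike) and by
  agreement within ±1 spike with a forward-Euler reference at
  `dt` = 0.0005 ms;
* the spike time is the end of the step that triggered the reset,
  which is unambiguous for fixed-step integration;
* initial conditions are rest: $v = v_r$, $u = 0$.  With zero input
  this is an exact fixed point, and it is preserved exactly by RK4,
  so an unstimulated network stays silent;
* membrane overshoot beyond $v_{peak}$ within the triggering step is
  clamped only in *recorded traces*; the integrated state is reset
  anyway, so dynamics are unaffected.

```{r fi}
fi_curve(neuron_params("MC"), c(0, 10, 20, 40, 60))
```

## The circuit

The network (`build_glomerular_layer()`) is an ensemble of 16
glomeruli, each holding one MC, one ET, one PG and one SA cell
(multiplicity is configurable; one of each is the shipped
condition).  Within a glomerulus, the olfactory-receptor-neuron
(ORN) input current drives MC, ET and PG; MC excites PG; PG inhibits
MC (the model's only inhibitory synapse); ET excites PG and its home
SA.  Across glomeruli, each SA projects excitatorily to the PG *and*
ET cells of every **other** glomerulus — full inter-glomerular
connectivity with the swept weight `sa_weight`.  Two structural
facts carry the results:

* the ET/SA sub-network receives nothing from MC or PG, so ET
  activity reflects only the external input and the activity shared
  through SA cells — a substrate for pooling total input intensity;
* MC output is a balance between its private ORN drive and PG
  inhibition, and PG pools the lateral (SA) signal — a substrate for
  subtracting the global intensity from the local pattern.

Synapses are current-based and exponential: a presynaptic spike at
$t_0$ contributes $\pm w\,e^{-(t - t_0)/\tau}$ pA to the
postsynaptic input current, with a single $\tau$ = 10 ms for all
synapses and no transmission delay — the simplest kinetics
consistent with a rate-level readout.  Because $\tau$ is shared, the
engine aggregates all afferents of a neuron into one decaying
current, which is exact.  Between stimuli the network is fully
re-initialized (states to rest, synaptic currents to zero):
exposures are independent experiments.

## Stimuli

There is deliberately no receptor-transduction model.  An odor is a
combinatorial code: a vector of sensitivities $S$ (one per
glomerulus) drawn i.i.d. from Uniform(0, 40) pA under a seed, and an
exposure at concentration factor $c$ injects the constant currents
$R = \min(S\,c,\ 40)$ — linear in concentration with a hard
saturation ceiling of 40 pA applied after the product, preserving
linearity below the ceiling.  The study conditions are fixed by the
generator defaults: 6 odors (labelled A–F) × 16 glomeruli, 6
concentration factors $\{0.4, 0.6, 0.8, 1.0, 1.2, 1.4\}$, hence 36
stimuli of 0.5 s each.  The morphing series interpolates between
odors C and E at concentration 1: 21 convex mixtures
$(1-\alpha)R_C + \alpha R_E$, $\alpha = 0, 0.05, \dots, 1$, clipped
after mixing (the endpoints rarely clip, so the order is mostly
moot).

What the generator does *not* emulate: receptor binding dynamics,
sniff-cycle temporal structure, correlated sensitivities across
glomeruli, and trial-to-trial noise.  Passing tests therefore show
that the *circuit* segregates identity from intensity for
combinatorially coded constant inputs; they do not show robustness
to temporally structured or noisy input.

## Readout and metrics

The readout is the mean firing rate of each MC (or ET) over the 0.5
s exposure — spike count divided by duration, so rates are quantized
in 2 Hz steps.  Three measures are computed on the resulting
36 × 16 matrices (`metrics_report()`):

* **Fisher's discriminant ratio** with odors as classes:
  $\mathrm{trace}(S_B)/\mathrm{trace}(S_W)$, where $S_B = \sum_i n_i
  (\mu_i - \mu)(\mu_i - \mu)^T$ and $S_W = \sum_i \sum_{x \in i} (x
  - \mu_i)(x - \mu_i)^T$.  The trace-ratio scalarization with
  class-size weights is one of several textbook multiclass variants;
  it is translation- and scale-invariant, which is what the
  comparisons here need.  Absolute FDR values are therefore
  comparable only within one convention (see *Limitations*).
* **Concentration correlation**: per odor, Pearson's $r$ between
  response and the six concentration factors, summarized as mean ±
  sd across odors.  The shipped reading (`method = "pooled"`) treats
  every neuron's response as an observation, so an odor contributes
  16 × 6 (response, concentration) pairs: a population whose cells
  uniformly track total intensity scores near 1, while a
  combinatorially patterned population is penalized for its
  across-cell heterogeneity.  This is the reading under which the
  *input* layer scores ≈ 0.53 for uniform panels — a value that
  follows analytically from the uniform sensitivity distribution —
  and it is what makes the input a meaningful baseline.  Two
  alternatives are kept behind the `method` flag: `"mean"`
  (scalarize each sample by its mean over glomeruli; exactly 1 for
  any response linear in concentration, hence useless as a baseline
  but handy as a sanity check) and `"pc1"`.
* **PCA** (column-centered, unscaled — all features share units)
  with explained-variance fractions, and **bisecting k-means**
  hierarchical clustering: the cluster with the largest
  within-cluster sum of squares is recursively split by 2-means (10
  seeded restarts, lowest inertia wins, ties broken by restart
  index) down to singletons; node height is the mean distance of the
  cluster's members to the cluster centroid; trees are exported as
  Newick.  A divisive construction is used because the partition
  facts of interest (which stimuli share a branch at the two-cluster
  level) are exactly its first split, making the analysis robust to
  the several readings of "hierarchical clustering based on
  k-means".

## Calibration of the fixed weights

The four Table-of-parameters cell types and the stimulus statistics
are fixed, but the non-swept synaptic weights are free parameters of
the model family.  They were calibrated once, against the
*qualitative* target behaviours — and then frozen in
`inst/extdata/default_config.txt`:

| key | value | role |
|---|---|---|
| `w_orn_mc` | 1.0 | MC receives the full ORN current |
| `w_orn_et` | 0.8 | slightly reduced private drive lets the shared lateral signal dominate ET sooner |
| `w_orn_pg` | 0.2 | PG inhibition should track the *global* (lateral) signal, not the local input |
| `w_mc_pg` | 10 | weak local feedback |
| `w_et_pg` | 10 | weak local feedforward inhibition |
| `w_et_sa` | 140 | strong drive so SA rates report total network activity |
| `w_pg_mc` | 250 | inhibition strong enough to over-suppress MC beyond the optimum |
| `sa_scale` | 1 | pA per arbitrary unit of `sa_weight` |

The calibration targets were: (i) MC output forms
concentration-invariant odor clusters with a discrimination optimum
*interior* to the sweep grid; (ii) ET output collapses onto a
one-dimensional concentration axis (PC1 share above 95%) at that
optimum; (iii) the optimum sits in the 10–30 range of the
arbitrary-unit weight axis, which fixes the unit (`sa_scale`).
Under the shipped defaults the seed-averaged MC discriminant ratio
peaks at `sa_weight` = 19 (its exact position varies by ±1 across
panel ensembles because the peak is shallow), the ET concentration
correlation rises to ≈ 0.91 and plateaus, the MC concentration
correlation attains its *minimum* at the same weight, and the ET
discriminant ratio decays towards zero — the full qualitative
signature of identity/intensity segregation.

Mechanistically: at `sa_weight` = 0 the glomeruli decouple (the
package tests verify bit-identical equivalence with isolated
single-glomerulus simulations); as the weight grows, SA-mediated
pooling makes PG inhibition proportional to total stimulus
intensity, which subtracts the concentration component from MC
output (normalization) while the same pooled signal homogenizes ET
rates into a pure intensity code; past the optimum, inhibition
overwhelms MC activity and identity information degrades.

## Degenerate inputs, ties, tolerances

* A zero stimulus produces zero spikes (rest fixed point).
* FDR is undefined when every class is internally constant
  (within-scatter 0); this is signalled as an error.
* Per-odor correlation for an odor with constant response is
  undefined; such odors are flagged, excluded and reported.
* 2-means on a cluster of two points returns the only bipartition
  directly; clusters of identical points split at height 0.
* NaN emergence during integration aborts with the step index; with
  the shipped parameters and currents bounded by the 40 pA ceiling
  plus synaptic load this does not occur.
* Non-finite stimuli, mismatched lengths and negative concentrations
  are rejected at the interface.

## Problem sizes

The shipped experiments use the study conditions throughout: 16
glomeruli (64 neurons), 0.5 s exposures at `dt` = 0.1 ms (5000 RK4
steps), 36 stimuli for the odor-concentration grid, 57 for the
morphing experiment, and sweeps over integer weights with 10
independent odor panels (360 simulated exposures per weight).  The
compiled engine simulates all exposures of a sweep point in one
batched pass.

## Known limitations

* Absolute discriminant-ratio values depend on the chosen
  scalarization of the between/within scatter ratio; only
  comparisons under a fixed convention (MC vs input vs ET) are
  meaningful.  The shipped convention is the class-size-weighted
  trace ratio.
* The 2 Hz rate quantization of the 0.5 s readout makes smooth
  quantities (e.g. the morph trajectory's projection on the C→E
  axis) monotone only up to single-spike fluctuations.
* Synapses are current-based with a single shared time constant; no
  conductances, no NMDA/GABA_B kinetics, no transmission delays, no
  granule-cell layer, and no biphasic SA→ET transmission.
* One cell per type per glomerulus is the shipped condition;
  `cells_per_type` exposes multiplicity (with weights scaled by
  presynaptic count) for exploration only.
* Whether ORN input to PG is weighted like MC/ET input is not
  constrained by the circuit description; it is exposed as
  `w_orn_pg` and calibrated (0.2) rather than assumed equal.

## Reproducing the experiments

```{r exp1, eval = FALSE}
cfg <- network_config()          # shipped calibrated defaults
e1 <- run_experiment1(cfg, seed = 1)
e1                               # FDR / PCC / PC1 for input, MC, ET

m <- run_morphing(cfg, seed = 1)
plot_dendrogram(m$trees$mc)      # mixtures join their dominant odor

sw <- sa_weight_sweep(cfg, weights = 10:30, seeds = 1:10)
sweep_summary(sw)$argmax         # discrimination optimum of the sweep
plot_sweep(sw)
```

The repository's `scripts/acceptance.R` recomputes the headline
numbers of the study from scratch (sweep over 10 panels, metrics at
the discrimination optimum) and writes them as JSON.
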
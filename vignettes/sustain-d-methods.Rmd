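---
title: "SUSTAIN-d: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SUSTAIN-d: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sustaind)
```

## The model

SUSTAIN-d is a population-level decomposition of the SUSTAIN category-learning
model. Where SUSTAIN recruits abstract clusters in response to surprising
classification errors, SUSTAIN-d maintains a pool of neuron-like units in the
stimulus feature space (the unit hypercube $[0,1]^n$) and lets *virtual
clusters* — flocks of units with near-identical tuning — emerge from a simple
recurrent learning rule. A flock plays the role of one SUSTAIN cluster and is
an analogue of a hippocampal cell assembly (concept cells, place cells).

On each trial a stimulus $x \in [0,1]^n$ is presented. Each active unit $i$
computes an attention-weighted distance and an exponential receptive-field
activation

$$\mathrm{dist}_i = \Big[\textstyle\sum_j a_j\,|\,\mathrm{pos}_{ij}-x_j|^r\Big]^{1/r},
\qquad \mathrm{act}_i = \zeta\, e^{-\zeta\,\mathrm{dist}_i},$$

with $r = 1$ (city-block, appropriate for separable feature dimensions) and
non-negative attention weights $a_j$ summing to 1. Only the $K$ most activated
connected units — $K = \max(1, \mathrm{round}(k \cdot m))$ for winner
proportion $k$ and population size $m$ — produce output (k-winners-take-all).
Winner outputs propagate through connection weights to category evidence
$\mathrm{evidence}_j = \sum_i w_{ij}\,\mathrm{out}_i$, and a softmax with
inverse temperature $\phi$ yields choice probabilities.

Learning is local and error-driven:

* **Recruitment.** On the first trial, or whenever the evidence for the
  correct category is not strictly maximal (ties count as errors), the $K$
  nearest unconnected units are connected and placed exactly at the stimulus.
* **Neural flocking.** Each winner takes a Kohonen step toward the stimulus,
  $\Delta\mathrm{pos}_i = \eta_{\mathrm{pos}}(x - \mathrm{pos}_i)$, then a
  recurrent step toward the winners' centroid,
  $\Delta\mathrm{pos}_i = \eta_{\mathrm{group}}(\mathrm{group} -
  \mathrm{pos}_i)$. The centroid itself is invariant under the second step;
  with $\eta_{\mathrm{group}} = 1$ the winners become exactly co-located,
  which is what welds them into an assembly.
* **Attention.** Gradient ascent on the summed activation of winners minus
  non-winners, divided by the number of active units, then projected back to
  the simplex by clipping negatives and renormalising. Attention thereby
  concentrates on diagnostic features.
* **Connection weights.** Cross-entropy descent through the softmax with a
  one-hot target, divided by $K$: $\Delta w_{ij} =
  (\eta_{\mathrm{cw}}/K)\,(t_j - p_j)\,\phi\,\mathrm{out}_i$.

The divisions by $K$ (weights) and by the active-unit count (attention) make
aggregate behaviour independent of how many units realise each flock: because
recruits are co-located and update identically, the per-trial choice
probabilities are the same from 50 units to tens of thousands
(`scale_invariance_max_prob_dev` in the acceptance output is at machine
precision). This is the property that lets the same model be read at
behavioural and at neural-population scale.

## Numerical choices

Three knife-edge decisions in the model are comparisons of real numbers that
can be exactly tied given binary stimuli, and whose resolution must not
depend on population size (flock membership indices are not comparable across
sizes):

* **k-WTA ties.** Activations equal within a relative band of $10^{-9}$ are
  tied; ties resolve by recruitment-event id (newest first), then lowest unit
  index. Newest-first guarantees that freshly recruited units — placed at the
  stimulus, hence maximally active — win their trigger trial and learn.
* **Error detection.** Evidence differences within a $10^{-9}$ relative band
  count as ties, hence as errors. This keeps recruit-or-not decisions
  identical across population sizes when a weight crosses zero.
* **Attention subgradient.** At $|\mathrm{pos}_{ij} - x_j| = 0$ (with
  $r = 1$) the subgradient 0 is used.

The softmax subtracts the maximum before exponentiating, so probabilities are
well-defined up to $|\phi \cdot \mathrm{evidence}| = 700$ and beyond.
Distances of unconnected or lesioned units are never computed; such units
cannot win, output, or update, and the weights of never-connected units are
exactly zero.

Within a trial, the attention and weight updates are computed from the same
forward-pass configuration that selected the winners (pre-move positions);
position updates are applied afterwards. The recorded per-trial probability
is the one the learning updates act on — after recruitment re-runs the
forward pass, an error trial therefore contributes chance-level error.

## Default parameters and where they come from

The fitted parameter values for the behavioural curves are not published as
numbers, and the human reference curves are an external asset not shipped
here. The package therefore documents its own fixture parameter set,
`default_shepard_params()`:

| parameter | value | meaning |
|---|---|---|
| `zeta` | 2 | tuning steepness; broad enough that a flock generalises across neighbouring stimuli |
| `phi` | 2 | decision certainty (inverse softmax temperature) |
| `eta_pos` | 0.05 | Kohonen rate; small, so flocks stay near their recruitment site |
| `eta_group` | 1 | full recurrent contraction (co-located flocks) |
| `eta_attn` | 0.02 | attention rate; concentrates attention over a few blocks |
| `eta_cweights` | 0.01 | weight rate; paces learning over the 16-block horizon |
| `k_prop` | 0.01 | winner proportion (the parameter-search setting) |
| `n_units` | 1000 | desk-scale population |

These values were chosen with the package's own grid machinery against the
qualitative human signature of the six Shepard–Hovland–Jenkins problems:
block-error ordering I < II ≤ {III, IV, V} < VI and modal virtual-cluster
counts (2, 4, 6, 6, 6, 8). Two regimes matter. If weight learning is fast,
the curves are recruitment-limited (errors stop as soon as each stimulus has
a flock) and the ordering flattens. The defaults sit in the weight-limited
regime, where a type I flock receives 8 training trials per block and a type
VI flock only 2, which reproduces the human ordering with gradual curves
(type I mean block error ≈ 0.13, type VI ≈ 0.22). Broad tuning (`zeta = 2`)
is needed so that flocks covering two same-category stimuli are not punished
by their receptive-field falloff, which would otherwise make the
rule-plus-exception problems harder than type VI.

The modal flock counts arise from recruitment *and* attention jointly: each
error recruits a co-located flock at the current stimulus, and the learned
attention metric merges flocks that differ only on ignored features (type I:
attention collapses onto the diagnostic feature, leaving two virtual
clusters; type VI: attention stays uniform, eight clusters). Flocks are
counted operationally as single-linkage components at attention-weighted
distance 0.1, validated against recruitment events in noiseless runs.

The shipped reference curves (`inst/extdata/reference_curves_synthetic.tsv`)
are the model's own output under these defaults — clearly synthetic, present
so the fitting machinery (`fit_parameters()`, a two-stage coarse-to-fine grid
search sharing fixed trial sequences across parameter sets) is testable
offline. They regenerate bit-identically from their seeds.

## Spatial simulations

For unsupervised foraging the whole population is treated as relevant to the
context (all units connected, no recruitment, attention fixed uniform over
the two arena dimensions, no category output). The agent performs a random
walk in the unit square (axis-aligned steps of 0, 0.025, 0.05, or 0.075;
out-of-bounds proposals resampled), and each step the $K$ nearest units take
a Kohonen step with annealed rate $\eta_t = \eta_0/(1+\rho t)$
($\rho = 4\times10^{-12}$, negligible at desk scale) followed by the
recurrent contraction. `default_spatial_params()` uses 500 units, $k = 0.02$
and $\zeta = 12$ (a receptive-field length scale of about 1/12 of the
arena), chosen once so that the resulting ~50 flocks have field spacings
resolvable by the 40×40 activation maps.

Activation maps accumulate the summed winner activation of a fresh test walk
into a 40×40 occupancy grid and divide by visit counts; unvisited bins are
missing, never zero. (Positions are binned directly at the 40×40 resolution;
re-binning a finer 100×100 grid by a non-integer factor is equivalent up to
fine-bin quantisation.) The spatial autocorrelogram is the standard
lag-indexed Pearson correlation over mutually valid bins (≥ 20 required).
Gridness uses the expanding-annulus method: the central peak (contiguous
region above correlation 0.3, minimum 2 bins) is excised; for outer radii 8
to 20 bins in steps of 2, the annulus is rotated in 30° increments by
bilinear interpolation and the interim score is
$\min(r_{60}, r_{120}) - \max(r_{30}, r_{90}, r_{150})$; the grid score is
the maximum interim score. The trivial 0° self-correlation is excluded from
the comparison set. The pipeline is validated against analytic fields: a sum
of three plane waves at 60° separations scores far above 0.5, a square
lattice scores negative, and a radially symmetric field scores near zero.

Two diagnostics summarise self-organisation. *Assembly formation*: the
fraction of units lying in exactly co-located clusters of three or more —
near 1 with the recurrent update, near 0 without it, which is the package's
operationalisation of "no self-organisation without recurrence". (Plain
competitive learning still gathers units into loose clumps, so a looser
clustering criterion would not discriminate.) *Tiling regularity*: the
coefficient of variation of nearest-neighbour distances among flock
centroids, compared with matched uniform-random point sets; flocking yields
CVs around 0.28 against a uniform control around 0.55.

## Robustness experiments

Update noise adds an independent $n$-dimensional Gaussian draw (SD 0, 0.5,
or 1.0) to **each winner's** net displacement per trial. Per-winner draws are
what make population size matter: the recurrent contraction averages the
noise over the $K$ winners, so larger populations (larger $K$ at fixed
proportion) hold their flocks together while small populations diffuse. An
alternative reading — noise applied to all connected units' positions each
trial — is available via `apply_update_noise()` on any displacement matrix,
but the per-winner update form is the default throughout. Note that at
SD 0.5 in a unit cube the perturbation is of the same order as the
inter-flock distances, so absolute performance is strongly degraded at desk
scale; the reported contrast is the paired ordering (recurrence on ≤
recurrence off), which holds seed by seed.

Lesions remove a uniform sample of connected units permanently at trial 60;
removed units keep their weights but never again win or update. A 20-unit
model ($K = 1$) loses entire concepts and must re-recruit, while a
10,000-unit model barely notices 25 lost units — the degradation contrast
reported by the acceptance script. After a total lesion the next error
triggers fresh recruitment and the model recovers within the remaining
blocks.

The prototype baseline (one unit per category label, supervised prototype
update, no flocking) exists as the comparator that fails on non-linearly
separable structure: on exclusive-or both category centroids converge to the
centre of the cube, the two prototypes become indistinguishable, and
performance stays at chance while SUSTAIN-d learns the problem.

## The anterior/posterior dual-bank model

Two banks differing in tuning breadth (anterior broad, posterior narrow;
`anterior$zeta < posterior$zeta` enforced) learn independently — own
recruitment sites, positions, attention — and are linked only through the
shared category response: a single softmax over the summed per-bank
evidence, a shared recruitment trigger, and weight updates driven by the
shared output probabilities. Each bank's `phi` acts as its evidence gain
inside the shared softmax; this is the package's reading of the model's
twelve free parameters (six per bank), one consistent interpretation of how
a duplicated decision parameter can enter a single decision.

`default_dual_params()` (anterior $\zeta = 1$, $\phi = 2$; posterior
$\zeta = 8$, $\phi = 0.28$; both banks $\eta_{\mathrm{cw}} = 0.2$) was
calibrated the same way as the single-bank fixture, against the qualitative
competition signature. The gains matter: because activation scales with
$\zeta$, a narrow bank at equal gain trivially dominates every problem, and
a gain exactly compensating the peak activation ($\phi_P = \phi_A
\zeta_A/\zeta_P = 0.25$) makes the banks tie. Slightly above that balance
point the structural asymmetry decides: on type I the anterior bank's broad,
*correct* generalisation lets it drive the response early and accumulate the
connection-weight mass before the shared error signal vanishes, while on
type VI its early generalisation is wrong and self-cancelling, so the
posterior bank's clean per-stimulus memorisation takes over. The faster
weight rate concentrates learning in that decisive early phase. The
acceptance script reports the end-of-training anterior-minus-posterior
weight-mass gap (positive on I, negative on VI) and the posterior bank's
blocks to 90% standalone accuracy (reached on VI, censored at 17 on I).

## What the synthetic data do and do not show

All test inputs are generated in code: the six binary-feature structures
with seeded block-randomised sequences, bounded random walks, analytic
periodic fields, and model-generated reference curves. These reproduce the
*structure* of the modelled experiments — they are not human data, and
passing tests show that the implementation realises the model's mechanisms
and their documented consequences at desk scale, not that the model fits any
particular participant sample. Problem sizes were chosen once for routine
desk use: 1,000 units and 25 seeded sequences for the six problems, 10,000
units for the lesion/noise contrasts, 50,000-step walks with 25,000-step
test walks and 6 simulations for the spatial runs. Full-scale settings
(3.2 × 10⁶ units, $k = 5\times10^{-5}$, 500,000-step walks, 100 simulations)
are plain parameter changes in the same functions.

## Known limitations

* Flock counting by a fixed linkage threshold (0.1) is calibrated for binary
  feature cubes; heavily noised runs blur the notion of a flock.
* The noise experiments at SD ≥ 0.5 sit in a saturated regime at desk scale
  (near-chance absolute performance); only orderings are meaningful there.
* The dual-bank competition signature depends on the documented gain
  calibration; it is a demonstration of the competitive mechanism, not a fit
  to regional imaging data.
* The spatial simulations make no claim about path integration, boundary
  coding, or head direction; grid-like scores emerge from tiling alone, and
  at desk scale only a minority-to-majority fraction of runs score positive,
  varying with seed.
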
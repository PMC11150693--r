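---
title: "Two-stage sparse multi-objective EEG channel selection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage sparse multi-objective EEG channel selection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Non-invasive brain-computer interfaces record EEG from tens of scalp
electrodes, but for a given task most channels carry noise or redundant
signal. Channel selection seeks a small electrode subset that keeps the
task's classification accuracy. Two goals pull against each other — delete
many channels, classify well — so the natural formulation is a
two-objective maximization whose solutions form a Pareto front of
accuracy-versus-montage-size trade-offs, from which a practitioner picks a
working point.

`tsmoea` implements a connectivity-based formulation. Each recording
window is summarized by an `m x m` channel-connectivity matrix (Pearson
correlation by default; phase-locking value and a history-1 transfer
entropy are provided as alternatives). Because functional connectivity
between most channel pairs is near zero, these matrices are approximately
sparse, and the search is organized around that sparsity.

## Decision variables and objectives

The decision vector holds one threshold per unordered channel pair,
flattened in row-major upper-triangle order; for `m` channels there are
`d = m(m-1)/2` variables (1891 for the packaged 62-channel montage). Given
per-sample connectivity matrices `D_k` and a threshold vector `x`, an
off-diagonal entry survives filtering when its magnitude meets its pair
threshold, `B_k[i,j] = D_k[i,j] * 1(|D_k[i,j]| >= x[ij])`. A channel is
deleted when, *in every sample*, it has zero filtered connectivity with
more than `s` of the other channels; the deleted channel's row and column
are zeroed, giving matrices `C_k` and the deletion count `m_d`.

Two objective pairs are used in turn:

* **Late stage (the target problem):** maximize `(m_d, f2)`, where `f2`
  is the cross-validated accuracy (percent) of a classifier fed the
  upper-triangle entries of `C_k` as features.
* **Early stage (a smoothed surrogate):** maximize `(f1*, f2)` with
  `f1* = 0.5 * zero(C)/N_C + 0.5 * m_d/m`, the average of the zero-entry
  ratio of `C` and the deleted-channel fraction. `m_d` moves in unit steps
  and is hard to improve when `s` is demanding; `f1*` responds
  continuously to every additional zeroed pair, which keeps selection
  pressure alive early on and prevents stagnation at `m_d = 0`.

Zeros for `f1*` are counted over off-diagonal upper-triangle entries only:
the diagonal is structurally nonzero for correlation-type inputs and would
dilute the ratio identically for every solution. Solutions retaining fewer
than two channels are infeasible for a connectivity-based classifier and
receive `f2 = 0` rather than being repaired, which keeps evaluation total
and lets dominance discard them naturally.

The default classifier is a linear SVM with a cost grid `{0.1, 1, 10}`
scored by stratified 5-fold cross-validation; the best candidate's CV
accuracy is `f2`. The fold shuffle uses its own fixed seed so that every
solution in a run is scored on identical folds — otherwise objective noise
would leak into selection. The classifier sits behind a small contract
(`classifier_spec`) so it can be swapped without touching the optimizer.

## Electrode geometry and score assignment

Channel positions live on a unit sphere (so the largest possible
inter-electrode distance is 2), with hemisphere codes +1 (left), 0
(midline), -1 (right), inferred from the 10-20 naming convention when a
montage file lacks an explicit column. Each pair receives a score from the
distance matrix `DM` and the hemisphere labels:

* same hemisphere: `(DM - R) / (2 (Max(DM) + R))`
* different hemispheres, `DM < R`: `DM / (2 (Max(DM) + R))`
* different hemispheres, `DM >= R`: `(DM + R) / (2 (Max(DM) + R))`

Distant, cross-hemisphere pairs score highest. The scores express a prior
from the connectivity literature: nearby same-hemisphere electrodes tend
to be strongly correlated (their thresholds should stay low so the pair
survives filtering), while long-range cross-hemisphere coupling is weaker
and its pairs are the first candidates for thresholding away. Midline
channels are treated as "different hemisphere" when paired with a lateral
channel and "same" when paired with each other — the literal reading of
the equality test on hemisphere codes. Two boundary conventions are worth
stating: scores can be negative (same-hemisphere pairs closer than `R`),
which is harmless because every consumer either compares scores or
min-max-normalizes them; and `Min(DM)` is carried in the score object for
inspection but does not enter the formula.

The channel radius defaults to `R = 1.0`. A robustness study over the
feasible range (0.2 to 2, the sphere's diameter) identifies 1.0 as the
best-performing setting, and we adopt it as the default while leaving `R`
configurable; small `R` makes almost every pair take the "far" branch and
weakens the geometric prior.

## The two-stage algorithm

Solutions use a hybrid encoding: a real vector `dec` in `[0,1]^d` and a
binary `mask`, with the effective threshold vector their elementwise
product. The mask carries sparsity explicitly — a masked-off pair has
threshold 0 and never filters anything.

**Initialization** draws `dec` uniformly and, per individual, a sparsity
level `rho ~ U(0,1)`; `ceiling(rho * d)` mask bits are switched on one at
a time by binary tournaments on the scores (high scores win under the
default bias). The population therefore spans the whole sparsity range
with geometry-informed active sets. The bias direction is exposed
(`score_bias`) because the prior admits both readings; the default
activates high-score pairs, which makes distant cross-hemisphere pairs the
first to be thresholded away, consistent with the score-based `dec`
mutation below.

**Variation.** Parents come from binary tournaments on Pareto rank then
crowding distance. Real vectors recombine by simulated binary crossover
(distribution index 20, crossover probability 1). Masks evolve by
score-based single-bit operators restricted to one randomly chosen
sequential variable group per invocation: a 0-to-1 flip activates the
higher-scoring of two candidates where the first parent is 0 and the
second 1; a 1-to-0 flip deactivates the lower-scoring candidate in the
opposite difference set; mutation works the same way on the individual's
own bits. Each invocation changes at most one bit, so sparsity drifts
slowly and dominance feedback can track it. Decision variables are grouped
into `k = 10` contiguous blocks of size `round(d/k)` (the last block takes
the remainder); `k` is not dictated by the problem and is exposed in the
configuration.

**Stage-dependent `dec` mutation.** In the early stage each coordinate is
selected with probability `1/d` and nudged by at most `alpha = 0.1`:
upward with probability equal to its min-max-normalized score, downward
otherwise. High-score (distant, cross-hemisphere) pairs thus drift toward
large thresholds and get filtered out, injecting the geometric prior into
the search direction itself. The late stage switches to conventional
polynomial mutation (index 20, probability `1/d`), an exploitation move
once the surrogate has done its job.

**Transition.** The run starts on the surrogate objectives and relabels
every cached evaluation to `(m_d, f2)` — at zero evaluation cost — when
either trigger fires: the early stage has consumed `mu * MaxFE`
evaluations (`mu = 0.2` by default), or the population realizes at least
`m - 2` distinct `m_d` values. The diversity trigger uses `m - 2` because
retaining at least two channels caps the meaningful deletion range at
`[0, m-2]`; we test *reached or exceeded* rather than strict equality
since the count can step past the target between generational checks and
the transition must be monotone. The budget comparison is inclusive
(`fe >= mu * MaxFE`) so the boundary is deterministic. With `mu = 0` the
run is late-stage only; with `mu = 1` only the diversity trigger can end
the early stage. Once late, never early again.

**Selection and accounting.** Survivor selection is NSGA-II style
(non-dominated sorting, crowding-distance truncation, index tie-break for
determinism): the dominance-based machinery the tournament operators
presuppose. Every objective evaluation increments the FE counter by
exactly one — including cache hits, since identical filtered patterns from
distinct thresholds would otherwise make the budget depend on cache
behavior. Offspring batches are truncated when fewer evaluations remain
than the batch needs. Each run is a pure function of its configuration
seed: identical seeds give bit-identical archives.

The hypervolume history uses the offset reference point
`z = (min f1 - 0.1, min f2 - 0.1)` with minima over the *non-dominated*
subset, so dominated points can neither contribute area nor move the
reference. Reporting `f2` in percent keeps the two objectives on
comparable magnitudes in the hypervolume.

## The synthetic generator

`synth_spec()`/`synth_generate()` produce windowed recordings in which a
planted subset `S` of channels mixes a shared latent series with
independent noise, and all other channels are pure noise. For a channel in
`S`, `x = a_c * rho * z + noise_sd * e` with the class amplitude
`a_c = 1 -/+ delta/2`. This construction was chosen for its closed form:
at `delta = 0` the expected within-`S` correlation is
`rho^2 / (rho^2 + noise_sd^2)`, which the tests verify directly, and the
class-dependent amplitude puts label information into the correlation
features, as the accuracy objective requires. Ground truth is
channel-level (which channels are informative), matching the deletion
granularity of the optimizer. Defaults (`rho = 0.9`, `delta = 1`,
`noise_sd = 1`, `T = 250`, 60 windows per class) give within-`S`
correlations around 0.17 (low class) and 0.64 (high class) against a
near-zero background — visibly sparse connectivity with a clearly planted
block.

What the generator does *not* emulate matters for interpreting results.
Real EEG class information is distributed, nonstationary and noisy:
accuracy degrades gradually as informative channels are removed, which is
exactly what makes the empirical accuracy-versus-deletion trade-off a
staircase with many Pareto-optimal montage sizes. In the synthetic
problem, by contrast, the class signal is a single global amplitude
factor, so *any* surviving informative pair is a near-perfect
discriminant at `T = 250`: the classifier scores 100% until nearly
everything is deleted. The true Pareto front then collapses to essentially
two points — maximal deletion with perfect accuracy, and total deletion
with the infeasibility penalty — and an elitist archive correctly contains
only those. A run on the defaults therefore demonstrates budget
accounting, determinism, stage logic and the optimizer's ability to find
maximally sparse accurate solutions (its best solution deletes all noise
channels plus the informative surplus), but it cannot exhibit a populated
accuracy-deletion staircase, and archive-diversity measures that
presuppose one will come up short. Tests of front *shape* on real-data
surrogates would need a generator with distributed, window-level class
variability, which is beyond what this construction claims to model.

## Numerical choices and degenerate inputs

* Pair order is row-major upper-triangle everywhere (thresholds, scores,
  features, CSV output); `pair_table()` is the single source of truth.
* Filtering compares `|D|` to the threshold with `>=`, so a zero threshold
  keeps everything and threshold 1 removes every entry with magnitude
  below 1; the diagonal is never touched.
* "More than `s`" is strict; `s` must lie in `[0, m-1]`.
* Transfer entropy uses a plug-in estimator on equal-width amplitude bins
  with history length 1 and natural logarithms; a two-point window has a
  single transition and returns exactly 0. The analytic signal for
  phase-locking is the standard FFT construction (no sub-band
  decomposition).
* Simulated binary crossover copies coordinates whose parents differ by
  less than 1e-12 (avoiding spurious floating-point drift on identical
  parents); all variation output is clipped to `[0, 1]`.
* Constant channels make the Pearson matrix undefined and raise an error
  naming the channel; degenerate CV folds (a single-class training fold)
  predict that class rather than aborting the run.
* Sequential grouping rounds the nominal block size half up, and the last
  block absorbs the remainder.

## Problem sizes in the tests

The unit and property suites run on small instances (3-10 channels, up to
five samples, hundreds of Monte-Carlo draws) chosen so each oracle
comparison is exhaustive or statistically well-powered. The end-to-end
synthetic experiment uses 16 channels, 6 informative, 120 windows of 250
samples, a population of 40 and a 2000-evaluation budget — large enough
that the two-stage machinery, caching and budget truncation are all
exercised, and small enough to re-run twice for the bit-for-bit
determinism check. The packaged 62-channel montage is used for the
geometry checks at full scale (1891 decision variables).

## Known limitations

* The synthetic accuracy landscape is binary in practice (see above); the
  generator is a correctness harness, not a benchmark of front quality on
  realistic data.
* The SVM grid is small by design; `f2` is a cross-validated point
  estimate and inherits its variance. Any classifier honoring the
  contract can replace it.
* Transfer entropy's plug-in estimator is biased upward at short window
  lengths; it is provided for completeness, while Pearson correlation is
  the default connectivity measure (cheapest, and adequate for
  threshold-based filtering).
* The montage ships standard spherical 10-20 positions generated from the
  canonical angles, not digitized electrode locations; distances feed a
  heuristic prior, so cap-level accuracy is not required.
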
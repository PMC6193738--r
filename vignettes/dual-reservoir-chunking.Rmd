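---
title: "Unsupervised chunking with mutually supervising reservoirs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised chunking with mutually supervising reservoirs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Chunking is the segmentation of a continuous stream of stimuli into
frequently recurring units. Statistical approaches detect chunk boundaries
from unequal transition probabilities between stream elements, but humans can
also chunk streams whose transition probabilities are perfectly uniform —
for example random walks on a community-structured graph in which every node
has the same degree. `dualrc` implements a dynamical alternative: two
recurrent rate networks ("reservoirs") receive the same input stream, and
each network's linear readout is trained to reproduce a transformed version
of the *other* network's output. No external teacher exists; the pair
converges on whatever response both networks can agree on, which in practice
is a phasic response time-locked to the recurring chunks.

## The model

Each module is a rate network of `N` neurons,

$$\tau \dot{x}_i = -x_i + g \sum_j J^{GG}_{ij} r_j + J^{GZ}_i z
  + \sum_\mu J^{GI}_{i\mu} I_\mu(t) + \sigma \xi_i, \qquad r_i = \tanh x_i,$$

with membrane time constant `tau = 10` ms, recurrent gain `g = 1.5` (weakly
chaotic, the "edge of chaos"), recurrent weights drawn from
`N(0, 1/(pN))` with connection probability `p`, feedback weights uniform on
`[-1, 1]`, and a one-to-one input projection with standard-Gaussian weights
(multi-input fan-in is available via `fan_in`). The readout is `z = w^T r`
over a subset of `n` neurons; `w` starts at `N(0, 1/n)` and is the only
plastic part of the system. We integrate with an Euler–Maruyama step of
`dt = 1` ms.

**Noise discretization.** The model's noise term is written as a Wiener
process inside the drift, which is dimensionally ambiguous under explicit
discretization. We add `sigma * sqrt(dt/tau) * N(0,1)` per step, which makes
the stationary noise variance independent of `dt`; a literal per-step
`sigma * N(0,1)` would change the physical noise level whenever `dt`
changed. This is a declared convention of this package. A consequence is
that the *effective* per-step noise at `sigma = 0.3` is about three times
larger than the literal `(dt/tau) * sigma` reading; noise-level comparisons
below are made in this package's own units.

**Teaching signals.** Each module's raw output is normalized by its
trailing-window mean and SD over `T = 15` s (exact ring-buffer moments, a
growing window before 15 s of history exists, SD floored at `1e-6`). With
one readout per module the teaching signal for module *i* is the rectified
sigmoid `f_i = [tanh(ẑ_j / β)]₊` of the partner's normalized output
(`β = 3`). With `K` readouts per module, readout `a` of one module is paired
with readout `a` of the other and the partner's remaining readouts enter
subtractively with strength `γ = 0.5`, so the readouts compete for chunks;
the competition can optionally be routed through interneurons that low-pass
the normalized outputs with time constant `τ_y = τ`. Teaching signals are
always in `[0, 1)`.

**Learning.** Readout weights follow FORCE learning: recursive least squares
on the error `e = z - f`, one shared inverse-correlation matrix `P` per
module (its readouts share the regressor stream and, in this implementation,
the readout subset), `P(0) = I/α` with `α = 100`, updates every 2 ms. With
these conventions the recursion is exactly batch ridge regression with
penalty `α`, which the test suite asserts to `1e-8`. Both modules update
simultaneously; teaching signals use the partner's normalized output of the
same tick, before that tick's weight update. A 1-s washout precedes
learning; the initial state is `x(0) ~ N(0, 0.25)`.

## Input encoding

Symbols occupy 200-ms slots. This value is chosen so that the 2400-ms
selectivity-sorting window used in the reservoir analyses spans a contiguous
12-symbol cycle of three 4-symbol chunks, making the analysis window
self-consistent; image slots are 250 ms as specified for the visual stream.
Each symbol occurrence drives its own input channel with a
difference-of-exponentials pulse (rise 20 ms, decay 50 ms, peak normalized
to 1, truncated beyond the symbol window plus eight decay constants where it
is below 3e-4 of its peak); pulses superpose linearly. The pulse constants
are a modeling choice — the stimulus response is specified only
qualitatively, as a slow rise and decay — and are configurable in
`pulse_kinetics()`.

Image streams feed the flattened `H x W x 3` pixel array directly: each
reservoir neuron reads `round(0.1 * H*W*3)` random pixels with Gaussian
weights, and currents are piecewise constant per 250-ms slot. Noise slots
show clipped Gaussian pixels around mid-gray (SD 0.2). Default frames are
seeded smooth random RGB fields (bilinearly upsampled coarse noise) so any
two frames are distinguishable; PNG input is supported.

## What the generators emulate — and what they do not

`stream_single_chunk()` alternates one chunk (default a-b-c-d) with i.i.d.
fillers of length 5–8 drawn from the 22 letters the chunk does not use;
`stream_multi_chunk()` draws chunks by occurrence probability (default three
chunks at 1/3), with or without filler separators, and supports overlapping
chunks that share symbols; `chunk_size_regime(s)` builds the chunk-size
experiment (alphabet `5s`, fillers from `4s` letters, lengths `s+2`–`s+5`);
`community_graph()` builds the canonical 15-node, degree-4, 3-community
topology (all within-community pairs connected except the two boundary
nodes, which instead bridge to the adjacent community in a ring; no single
edge list is canonical for such stimulus graphs, so this construction is the
default and an explicit edge list can be supplied);
`stream_graph_walk()` random-walks it with uniform 1/4 transitions and
annotates maximal same-community runs, because community-selective readouts,
not node-level chunks, are what is evaluated; `stream_biased_letters()`
draws i.i.d. letters for the frequency-bias experiments. Fillers are not
screened for accidental chunk-like substrings: in the base regimes chunk and
filler alphabets are disjoint, so collisions cannot occur. In the
multi-chunk separated regime filler lengths keep the 5–8 range (stated only
for the single-chunk experiment; we reuse it).

These are idealized stimuli: symbols are perfectly timed, noiseless and
drawn from small alphabets. Passing tests on them show that the learning
mechanism works as specified, not that it would segment natural speech or
video.

## Analyses

* **Chunk correlation** (`chunk_correlation()`): windowed Pearson
  correlation between a readout trace and the 0/1 chunk-presence indicator,
  per 15-s learning step during training. Degenerate (zero-variance) traces
  report 0 with a flag. The claim that a linear 0-to-1 ramp inside chunks
  attains correlation 0.5 is not reproduced by the Pearson formula at any
  duty cycle we can construct analytically; we ship the plain Pearson
  definition and note the discrepancy rather than renormalizing toward it.
* **Readout assignment** (`assign_readouts()`): greedy maximum-correlation
  matching with lower-index tie-breaks. Greedy matching is not optimal on
  unstructured matrices (it reaches the exhaustive-search optimum in only
  ~70% of uniform random 3x3 draws) but is near-always optimal on the
  diagonally dominant matrices produced by successful learning, which is
  the regime it is used in.
* **Selectivity** (`classify_selectivity()`): a neuron is phasic for a chunk
  if its trial-averaged activity exceeds its own mean + 3 SD (computed over
  the full presentation period) continuously for more than 100 ms inside
  that chunk's window; neurons selective for several chunks are excluded
  from ensemble statistics. Note an implication of the 3-SD rule: a burst
  occupying more than ~10% of the presentation period inflates its own
  threshold beyond reach, so "phasic" genuinely means brief.
* **Activation phase** (`activation_phase()`): circular mean of activity
  over a 2400-ms window. The printed prefactor `T/π` would map a point mass
  at `t0` to `2 t0`; we use `T/(2π)` so phases live in `[0, T)` and a point
  mass maps to its own time. Zero-resultant profiles (uniform or antipodal
  activity) raise an undefined-phase condition.
* **PC diagnostics** (`pca_report()`): eigendecomposition of the
  time-centered rate covariance; output and readout weights are projected
  onto the leading `M` eigenvectors and the within-self / between-partner
  mean squared reconstruction errors are reported per `M`. Centering makes
  the within-self curve exactly non-increasing and zero at full rank;
  eigenvectors are oriented so their correlation with the readout trace is
  nonnegative (signs are otherwise arbitrary).
* **Strong weights** (`weight_stats()`): threshold one population SD of the
  pooled weight distribution; the headline is the fraction of strong weights
  originating from chunk-encoding neurons.

## Numerical and design choices

* Shared readout subset and shared `P` per module: standard multi-output
  FORCE; halves memory and compute relative to per-readout matrices.
* The regularization scale is exposed because the literature's two
  conventions disagree about whether large `α` is the stable or the unstable
  direction; converged behavior here is insensitive to `α` across four
  orders of magnitude (the residual error is set by the partner's
  unpredictable fluctuations, not by the learning rate).
* Feedback carries the raw readout `z`, not the normalized `ẑ`.
* Normalization statistics keep running during held-out evaluation; weights
  are frozen but dynamics, feedback and noise remain active.
* Cross-module coupling (`couple_reservoirs()`) rebuilds both recurrent
  matrices as all-to-all `N(0, 1/((1+q)N))` and adds Bernoulli(`q`) cross
  connections from the same distribution, entering through the recurrent
  gain; `q = 0` reduces exactly to the disconnected system.
* Determinism: every stochastic function takes a seed and restores the
  global RNG; the compiled engine draws all noise from R's RNG stream, so a
  configuration plus seed reproduces results bit-identically.

## Convergence behavior of the mutual-supervision error

On a learnable fixed target, the RLS trainer converges to mean absolute
error below 0.01 (shown in the test suite's classic-FORCE check). In the
dual system the error `e = z - f` does not keep decreasing across learning
steps: it starts around 0.1 (with small random initial weights, `e ≈ -f`)
and stays at that level while the chunk correlation rises, because the
teaching signal carries the partner's privately chaotic fluctuations, which
are unpredictable from the local reservoir state. The converged mean |e|
reported by the acceptance script is therefore an honest property of this
implementation's conventions (in particular the noise discretization), and
sits roughly an order of magnitude above the near-perfect tracking that the
same trainer achieves on an externally supplied, learnable target.

## Measuring learning speed

Comparing how fast two training regimes reach their correlation plateaus is
noisy at desk scale: the greedy readout-to-chunk assignment churns during
early learning steps, and windowed Pearson correlations fluctuate between
15-s steps. The learning-speed comparison therefore tracks the *finally*
assigned readout-chunk pairs backward through training, smooths each curve
with a 3-step running mean, and reports the first step reaching 90% of the
final smoothed level. On contiguous versus filler-separated three-chunk
streams this shows both effects expected of undisrupted chunk repetition:
the plateau is reached earlier and is higher.

## An empirically empty ensemble criterion

The 3-SD/100-ms phasic rule turns out to select nothing in this package's
single-chunk simulations: trial-averaged responses of chunk-wired neurons
peak 3–4 SD above their window mean, but stay above 3 SD for less than
100 ms. Two properties conspire: a response occupying more than ~10% of the
averaging window inflates its own threshold beyond reach (see above), and
shared chaotic fluctuations inflate the per-neuron SD that defines the
threshold. Consequently the strong-weight-by-ensemble comparison across
noise levels degenerates (both fractions are 0). We keep the rule as
specified — it behaves correctly on synthetic phasic responses, as the test
suite shows — and report the degenerate outcome rather than softening the
threshold; analyses that need a non-trivial partition at desk scale can
lower `threshold_sd` explicitly.

## Problem sizes

The figure-level experiments are run at desk scale: training duration is
controlled by the number of 15-s learning steps (the bookkeeping unit is
fixed at 15 s regardless of scale), and reservoirs of 200–300 neurons are
used where the reference configurations call for 300–800. Two facts
justify the reduction: learning reaches its correlation plateau within about ten steps,
and performance saturates for reservoirs of 200 neurons or more. The
acceptance script uses 10 seeds per condition (5 per condition for the
coupling ratio, per its prescribed setup); the test suite's stochastic
checks use 10 seeds with 6–10 learning steps.

## Known limitations

* Rate neurons only; no spiking variant, no plastic recurrent or feedback
  weights, no reward modulation.
* The teaching-signal wiring presumes the number of readouts matches the
  number of chunks to find; nothing infers that number.
* Graded statistical significance machinery (U tests and the like) is out
  of scope; comparisons are descriptive.
* The image pathway treats pixels as independent input channels; there is
  no feature extraction, so image identity is only linearly decodable
  through pixel overlap.
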
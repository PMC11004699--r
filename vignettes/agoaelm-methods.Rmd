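---
title: "Methods: grasshopper-optimized ELM classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: grasshopper-optimized ELM classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agoaelm)
```

## The optimization model

The grasshopper optimizer moves `N` agents through a box-bounded
D-dimensional search space. Each iteration, agent `i` is pulled by every
other agent through the social-force kernel

$$ s(d) = f\,e^{-d/l} - e^{-d}, $$

which repels at short range, attracts at intermediate range, and decays
to zero. The working position update is

$$ x_i^d \leftarrow c \sum_{j \ne i} c\,\frac{ub_d - lb_d}{2}\,
   s(|x_j^d - x_i^d|)\,\frac{x_j^d - x_i^d}{d_{ij}} + \hat T_d, $$

with $d_{ij}$ the Euclidean inter-agent distance and $\hat T$ the best
position found so far. The comfort coefficient
$c = c_{max} - l\,(c_{max} - c_{min})/L$ decays linearly over the run,
shrinking the interaction zone and shifting the swarm from exploration
to exploitation. Note that `c` appears twice — once outside the sum and
once inside — so the effective inner scaling is $c^2 (ub-lb)/2$; we keep
this doubled form deliberately, since it is the form the method is
defined with, and the benchmark validation shows it behaves as intended.
Gravity and wind drift terms exist in the general grasshopper model; the
working update omits them, so they are retained only as optional
configuration (`gravityConstant`, `windStrength`) with zero defaults.

After each update all coordinates are clamped into the box, and the
target is replaced only on strict improvement, which makes the recorded
best-so-far trace non-increasing by construction.

### The two amendments

The amended variant (AGOA) addresses premature convergence with:

1. **Singer chaotic streams.** Three states $r_1, r_2, r_3 \in (0,1)$
   are advanced once per iteration by the quartic singer map
   $r \mapsto 1.07(7.9r - 23.3r^2 + 28.7r^3 - 13.3r^4)$. The general
   swarm model assigns $r_1, r_2, r_3$ to the social, gravity and wind
   terms, but the working update has only two force terms; we give the
   streams these roles: $r_1$ scales the social summation, $r_2$ scales
   the target attraction, and $r_3$ supplies the interpolation fraction
   of the quasi-opposition draw. This keeps all three streams active in
   the roles the model family assigns to stochastic multipliers while
   preserving the update's structure. The baseline GOA uses the update
   verbatim, with no stream multipliers.
2. **Quasi-opposition-based learning.** For each updated agent $x$, a
   candidate is drawn uniformly between the box center
   $m = (Lb + Ub)/2$ and the reflected point $Lb + Ub - x$; whichever
   of the pair has the lower objective value survives, with ties kept
   by the original. Each quasi-opposite candidate costs one objective
   evaluation, and `evaluationsUsed` reports the true total (the
   amended variant spends `2N` evaluations per iteration versus `N` for
   the baseline), so budget comparisons stay honest.

### Numerical choices

* **Singer safeguard.** The raw quartic exceeds 1 on part of (0,1) —
  its maximum is about 1.0093 near $r = 0.328$ — and once a state
  leaves the unit interval the iteration diverges. Excursions are
  therefore reflected back by $r \leftarrow |r| \bmod 1$, with an exact
  0 remapped to $10^{-6}$. A scan of $10^5$ iterates from several seeds
  confirms the safeguarded stream stays strictly inside (0,1).
* **Coincident agents.** A pair at zero distance contributes zero
  force (the limit convention), never a division failure.
* **Stream advancement** is once per iteration, not per agent: all
  agents in an iteration share the same $r_1, r_2, r_3$.
* **Non-finite objective values** are recorded as $+\infty$ and the run
  continues.
* Determinism: one seeded generator per run; the same
  `GoaControl` always yields a bit-identical result.

### Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `populationSize` (N) | 50 | swarm size; the benchmark protocol value |
| `maxIterations` (L) | 100 | iteration budget; likewise |
| `cMax`, `cMin` | 1, 0.01 | comfort schedule endpoints; 0.01 is the published baseline setting, 1 the customary upper endpoint |
| `attractionIntensity` (f) | 0.5 | social-force attraction strength; the customary value |
| `attractionLengthScale` (l) | 1.5 | social-force length scale; likewise |
| `useChaos`, `useQobl` | off | both on = AGOA |

The social-force kernel's printed form in the method's source material
is corrupted; the standard kernel above, with the customary $f = 0.5$,
$l = 1.5$, is used. Similarly, the printed quasi-opposite formula is not
well-formed; the standard center-to-opposite uniform draw is
implemented.

## Benchmark validation

Five classic test functions (sphere; shifted quadratic
$\sum(x_i+0.5)^2$; $\sum|x_i| + \prod|x_i|$; noisy quartic; Rosenbrock)
with their published ranges, all with minimum 0. Two transcription
ambiguities were resolved as follows: the shifted quadratic's printed
upper summation limit $n-1$ would leave the last coordinate
unconstrained and is treated as a typo (the sum runs to $n$; a
floor-step variant of the classic form is available via `f2Step`), and
the product term of the third function gets its missing subscript
($\prod |x_i|$). The Rosenbrock sum genuinely runs to $n-1$ because it
couples consecutive coordinates.

The harness runs each optimizer repeatedly (default 35 runs, matching
the published protocol; population 50, 100 iterations) with
consecutive seeds and reports the per-(function, optimizer) mean and
standard deviation of the final best fitness. The published comparison
table's problem dimension is unstated, so its absolute values are not
reproducible; the package instead verifies the *ordering* — the amended
variant's mean no worse than the baseline's — at an explicit D = 10
with 20 paired seeds, which one CPU completes in about a minute.

## The ELM head and its coupling to the optimizer

The hidden-layer output matrix is $H_{ij} = f(w_j \cdot x_i + b_j)$
(sigmoid by default; the output layer is linear). Output weights solve
$H\beta = T$ as the minimum-norm least-squares solution via thin SVD
with the conventional rank cutoff
$\max(n, L_h)\,\varepsilon\,\sigma_{max}$. Binary labels are encoded
one-hot with two columns, matching the two-unit output layer;
prediction takes the argmax, ties to the lowest class index.

The optimizer sees an ELM configuration as a flat agent vector — row-major
`W` then `b`, length $L_h d + L_h$ — searched in the box
$[-1, 1]$ per component (the natural scale for sigmoid pre-activations
on standardized features; configurable via `weightRange`). Its fitness
is the training sum of squared errors with $\beta$ re-solved in closed
form for every candidate, so the optimizer only ever navigates the
hidden layer. The hidden node count is a free design choice (no
published value exists); the package default is 50, and the image
pipeline uses 20 to keep the agent dimension at $20 \times 9216 + 20$
manageable on one CPU. An optional validation-split fitness exists in
principle but the default is the literal training-SSE objective.

## The convolutional feature extractor

The feature stack follows the published architecture: five
convolutions (96@11×11 stride 4, 256@5×5 pad 2, then 3×3 layers with
384, 384, 256 filters at pad 1), each followed by per-channel batch
normalization and ReLU, with 3×3 stride-2 max-pooling after layers 1, 2
and 5, flattening 6×6×256 = 9216 features. Two reconciliations were
needed: the stated "padding 2" for layer 1 is arithmetically
incompatible with the printed 55×55×96 output ((227−11+4)/4 is not an
integer), so padding 0 is used to honor the printed shape chain; and the
pooling hyperparameters are unstated but forced to 3×3 stride 2 by the
printed shapes. The whole chain is shape-checked at construction.

Pretrained filters are out of scope, so the default filters are seeded
random with unit-norm columns — a random-projection feature extractor
that preserves the architecture's geometry — and externally supplied
filter tensors of the same shapes can be plugged in. Batch
normalization at inference uses each channel map's own statistics
(shift 0, scale 1, $\varepsilon = 10^{-8}$); nothing is trained, so
there are no running averages. Published training hyperparameters
(learning rate, batch size, epochs, softmax head) have no referent in
this closed-form setup and are not implemented. Grayscale input is
replicated across the three channels; images are bilinearly resized to
227×227 and clamped to [0,1].

## Metrics

All eight metrics derive from the binary confusion counts. The
Matthews correlation coefficient is implemented in its standard form
$(TP \cdot TN - FP \cdot FN)/\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}$ —
the printed variant (no square root, a different numerator) cannot lie
in the $[-1, 1]$ range the metric is defined to have. Values are
reported on the 0–1 scale with a `percent` option. A metric with a zero
denominator is `NA` (undefined) rather than 0 or an error, so degenerate
predictions still produce a usable report.

## Synthetic data: what it does and does not show

The restricted clinical MRI dataset cannot be redistributed, so the
package generates its own two-class stand-ins:

* **Feature clusters** — two isotropic unit-variance Gaussians separated
  by `classSeparation` standard deviations along a random axis. With
  separation 6 the Bayes error is $\Phi(-3) \approx 0.0013$, so a
  well-functioning classifier should be nearly perfect.
* **Toy brain images** — a dark background, a mid-gray head ellipse,
  Gaussian pixel noise; positives add one bright elliptical blob placed
  uniformly within the inner 60% of the head (so resizing never clips
  it). Defaults: 227×227 pixels, blob semi-axes 12–30 px, intensity
  lift 0.35, noise SD 0.05, half the images positive — a clearly
  learnable but non-trivial contrast at the default noise level.

These emulate the *task shape* (two classes, one bright focal lesion,
80/20 stratified split) but none of the physics of MRI — no modality
contrast, bias fields, partial-volume effects, anatomical variability,
or co-registration artifacts. Passing tests therefore demonstrate that
the machinery is implemented correctly and that the optimizer genuinely
improves the classifier head on images of this kind; they say nothing
about clinical accuracy, and the published clinical metric values are
deliberately not used as targets.

## Problem sizes used in validation

The test-suite and acceptance runs use desk-scale instances chosen to
exercise every code path at meaningful sizes: benchmark ordering at
D = 10, N = 50, L = 100 with 20 paired seeds; the image pipeline at 200
images with 20 hidden nodes, a 12-agent swarm and 15 iterations (the
9216-dimensional features make each agent a ~184,000-dimensional
decision vector, and the closed-form $\beta$ re-solve dominates the
cost); smaller instances elsewhere. These sizes are the package's own
validation choices; all protocol constants (35 runs, population 50, 100
iterations, 80/20 split) remain available as defaults where they apply.

## Known limitations

* The baseline GOA, run un-amended at these budgets, converges slowly on
  the harder functions; the amended variant's advantage is partly
  because its $r_2$ stream contracts positions toward the target
  region and partly the extra greedy quasi-opposite evaluations — the
  honest evaluation accounting makes the latter visible.
* The hidden node count is fixed during optimization; tuning it is a
  natural extension.
* Random-projection convolutional features are weaker than pretrained
  ones; the plug-in filter hook exists for users who have real filters.
* Only binary classification is wired through the pipeline, though the
  ELM core itself is k-class.
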
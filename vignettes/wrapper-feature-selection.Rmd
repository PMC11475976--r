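---
title: "Benchmarking binary metaheuristic feature selection with transfer functions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking binary metaheuristic feature selection with transfer functions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respfs)
```

## The problem

Respiratory-sound diagnosis tables are wide and badly imbalanced: a typical
corpus has on the order of 920 recordings, of which only 35 are healthy, each
summarized by 75 audio descriptors. Selecting a small, discriminative feature
subset matters both for classifier quality and for interpretability, but with
2^75 candidate subsets the search must be heuristic. `respfs` implements the
standard recipe for this problem — continuous population-based metaheuristics
*discretized* by transfer functions and scored by a *wrapper* objective — as
a reproducible benchmarking harness, with a synthetic generator standing in
for the original recordings so that every claim in this package is testable
from code alone.

## The wrapper objective

A candidate solution is a point $x \in [-4, 4]^D$ ($D$ = 75 features). A
transfer function $T$ maps each coordinate of the candidate's *move* $\Delta$
(the step that produced it: the PSO velocity, `child - parent` for GA,
`new - old` position otherwise; the position itself for the initial
population) to a bit probability, and the binary mask $m$ is drawn
coordinate-wise: $m_j = 1$ iff $u_j < T(\Delta_j)$, $u_j \sim U(0,1)$. The
mask is scored by fitting a $K$-nearest-neighbour
classifier ($K = 5$, Euclidean distance on the masked columns) on the
training partition and evaluating on a fixed held-out partition:

$$
\mathrm{fitness}(m) \;=\; \alpha \cdot \mathrm{MCC}_{\text{test}}(m)
\;+\; (1 - \alpha)\left(1 - \frac{|m|}{D}\right),
\qquad \alpha = 0.99 .
$$

The Matthews correlation coefficient is used rather than accuracy because a
35:885 class ratio makes accuracy nearly meaningless; MCC is a
confusion-matrix correlation in $[-1, 1]$ that a constant predictor cannot
inflate (we define it as 0 when its denominator vanishes). For more than two
classes the K-category generalization (Gorodkin's $R_K$) is used. The
weight $\alpha = 0.99$ is the dominant convention in the wrapper
feature-selection literature: classification quality dominates, and the
subset-size term only breaks ties among masks of equal MCC in favour of
smaller subsets. It is configurable via `fitness_config()`.

### Evaluation protocol and its deliberate leak

One stratified 80/20 split (seed 42) is reused both inside the optimization
loop and for final reporting, reproducing the single-fixed-split protocol of
the study this package emulates. This *leaks test information into
selection*: the selected subset is tuned to the particular held-out sample,
and reported MCCs are optimistically biased. We keep the protocol because
the benchmark's purpose is comparing optimizers and transfer functions under
identical conditions, not estimating generalization error. For an honest
estimate, evaluate the final mask on a second split that the objective never
saw, e.g. `evaluate_mask(mask, table, stratified_split(table,
split_spec(seed = 4242)))`. Stratification is on by default: with only 35
minority samples, an unstratified 20% draw can lose the minority class
entirely.

## Transfer functions

Eight functions in two families (`tf_value()`, ids `S1`–`S4`, `V1`–`V4`):

| id | form | id | form |
|----|------|----|------|
| S1 | $1/(1+e^{-2x})$       | V1 | $|\mathrm{erf}((\sqrt\pi/2)\,x)|$ |
| S2 | $1/(1+e^{-x})$        | V2 | $|\tanh x|$ |
| S3 | $1/(1+e^{-x/2})$      | V3 | $|x/\sqrt{1+x^2}|$ |
| S4 | $1/(1+e^{-x/3})$      | V4 | $|(2/\pi)\arctan((\pi/2)\,x)|$ |

The transfer function's argument is the candidate's move, and this is what
gives the two families their opposite characters. As a population converges,
moves shrink toward 0. S-functions are sigmoids with $T(0) = 0.5$: a settled
coordinate keeps its bit on half the time, so S-shaped masks hover around
$D/2$ features. V-functions vanish at the origin: a settled coordinate
almost surely yields a 0 bit, so V-shaped masks empty out as the search
converges and only coordinates that still earn fitness by moving stay
selected. This is the mechanism behind the benchmark's signature pattern —
V-shaped functions select a small fraction of the features S-shaped ones do
— and it disappears if $T$ is instead applied to raw positions, whose
magnitudes do not shrink with convergence (uniform positions on $[-4,4]$
actually make $E[V(x)] \approx 0.87$, *denser* than S). Applying $T$ to the
velocity/step is also the construction of the original S-vs-V binary
particle-swarm literature.

Binarization uses the stochastic *set-bit* rule above for both families.
The literature sometimes uses a *flip* rule for V-shaped functions (flip the
current bit with probability $T(\cdot)$); it is available via
`binarize(..., v_rule = "flip")` but is stateful and not the default. A
deterministic 0.5 threshold is not offered: with S-functions it freezes the
mask of any coordinate sign pattern, collapsing the search.

The optimizer box is $[-4, 4]$ because all eight functions saturate there
(S1(4) ≈ 0.9997, V2(4) ≈ 0.9993): a wider box only flattens gradients.

## The six optimizers

All are population-based maximizers behind one interface
(`run_optimizer()`), with global elitism (the best-ever evaluation is
returned and the convergence curve is non-decreasing), box clipping after
every move, and full determinism given `(algorithm, seed, objective)`. The
emulated study names the algorithms and its population/iteration budget
(100 x 50, 25 trials) but not their internal parameters; we use the
canonical published forms:

* **GA** — real-coded, tournament size 2, arithmetic (blend) crossover with
  rate 0.9, per-gene Gaussian mutation (rate $1/D$, sd $0.1(ub-lb)$),
  elitism of 1.
* **PSO** — inertia 0.9 → 0.4 linearly, $c_1 = c_2 = 2$, velocity clamped to
  $\pm 0.5(ub-lb)$, global-best topology.
* **GWO** — coefficient $a$: 2 → 0; each wolf moves to the mean of the three
  leader-guided positions.
* **TLO** — teacher phase (teaching factor drawn from {1, 2}) and learner
  phase with pairwise difference moves, greedy acceptance in both; note this
  costs two evaluation rounds per iteration.
* **WOA** — 0.5 encircle/spiral switch, spiral constant $b = 1$, $a$: 2 → 0,
  random-agent exploration while $|A| \ge 1$.
* **EO** — equilibrium pool of the 4 best-ever solutions plus their mean,
  $a_1 = 2$, $a_2 = 1$, generation probability 0.5.

Budget contract: `pop_size` initial evaluations plus at most `pop_size` per
iteration (TLO: `2 * pop_size`); the returned `n_evaluations` makes this
auditable. Ties on fitness keep the incumbent, so re-visiting an equal mask
never churns the reported best. The wrapper objective memoizes evaluations
on the mask bit-string — on small $D$ this makes exhaustive-oracle testing
cheap — while still consuming RNG draws per binarization so that
trajectories remain reproducible.

## The synthetic generator

`generate_feature_table()` emulates the study's data shape without its
recordings: `n_informative` columns get class means stepped by
`effect_size * noise_sd` (Gaussian, equal within-class variance); the rest
are class-independent noise. Defaults copy the study's class sizes
(35:885 binary; 35:810:75 three-class) and 75 features. Location-shifted
Gaussians are the simplest structure that makes subset recovery
well-defined; they do *not* model the heavy tails, inter-feature
correlation, or block structure of real audio descriptors, so passing
benchmarks here demonstrates the machinery's correctness, not clinical
performance.

`generate_audio_dataset()` exercises the extraction stage end to end: one
class is band-limited tones (220/660 Hz carriers) with periodic impulse
bursts, the other broadband noise. Only statistical separability is
intended — chroma, spectral-shape and cepstral descriptors differ strongly
between the classes — not lung-sound realism.

### Instance sizes used in the test suite

Scaled studies in the tests fix the following sizes, chosen once as the
smallest instances on which each question is well-posed:

* *Exhaustive oracle*: $D = 8$, 60 + 60 rows — all 255 non-empty masks are
  enumerable, and 3 planted features at effect 2 give the optimum a clear
  basin.
* *Recovery*: 5 planted among 75 at effect 3, 500 + 500 rows. The test-set
  size is the binding constraint: recovery of all planted features is only
  identifiable if the held-out MCC still increases when the 4th and 5th
  informative features enter. With 200 held-out rows the planted-subset MCC
  ladder is 0.85 / 0.94 / 0.99 / 1.00 / 1.00; with 40 held-out rows it
  saturates at two features and the size penalty then *rewards* dropping
  planted features, making "recover the subset" the wrong question.
* *Family effect*: a 30:170 imbalanced table, two algorithms x {S1, V2},
  5 trials at population 20 / 15 iterations — the sparsity gap between
  families is an order of magnitude, so the scaled grid resolves it easily.

## Audio descriptors

The 75 features are 15 frame-level descriptors x 5 pooled statistics
(min, max, mean, population sd, skewness $g_1$), pooled over *all* entries
of each descriptor's coefficients-x-frames matrix — the only pooling
consistent with 5 values per method. Analysis uses a Hann window, frame
2048, hop 512, frames fully inside the signal. The descriptor set: chroma
from the STFT, from a log-frequency (constant-Q style) filterbank, its
energy-normalized variant (CENS), and a variable-Q variant with broadened
low-frequency bands; MFCC (20 coefficients off a 128-band mel spectrogram,
orthonormal DCT-II); the mel spectrogram itself; RMS; spectral centroid,
bandwidth, contrast (7 octave sub-bands from 200 Hz), flatness, roll-off
(85%); degree-1 polynomial fits per spectrogram column; tonnetz (6-d tonal
centroid projection); and zero-crossing rate. The chroma CQT/CENS/VQT
variants are computed from triangular log-frequency filterbanks applied to
the STFT magnitude rather than a true constant-Q transform; for
summary-statistic features this preserves the descriptors' character while
keeping the extractor dependency-free. `write_extractor_settings()` records
the effective configuration per run.

Numerical conventions, chosen where the conventions differ across tools and
frozen here: population standard deviation (ddof = 0) everywhere, including
benchmark aggregation; skewness is the bias-uncorrected moment coefficient
$g_1$, defined as 0 for zero-variance input; spectral quantities floor
power at $10^{-10}$ before logs; the dispersion-ratio filter shifts a
feature by $1 - \min(x)$ when any value is non-positive so its geometric
mean exists; equal filter scores rank by column index; KNN distance ties
resolve to the earlier training row and vote ties to the class of the
nearest neighbour among the tied classes.

## The harness

`run_benchmark()` runs the factorial grid with per-trial seeds
`base_seed + trial + hash(algorithm, transfer function)`, so cells are
independent, resumable (completed trial keys are skipped on re-run), and
insensitive to execution order. `aggregate_benchmark()` produces per-cell
and per-family tables — a family aggregate pools the 4 functions x trials
of that family per algorithm, which is 100 values per algorithm at the
default 25 trials. `report_benchmark()` writes the summary CSVs, a fitness
dispersion box plot and a selected-feature-count scatter.

```{r family-effect, eval = FALSE}
gen <- generate_feature_table(synthetic_table_spec(
  class_sizes = c(healthy = 20, diseased = 500), seed = 1))
cfg <- benchmark_config(n_trials = 3, pop_size = 20, n_iterations = 15,
                        base_seed = 1)
summary <- aggregate_benchmark(run_benchmark(gen$table, cfg))
summary$per_family
```

At this scale (the same one `scripts/acceptance.R` uses) the S-family holds
a small mean-MCC edge over the V-family, as in the full-size study. The
V-sparsity gap, however, is convergence-bound: after 15 iterations only the
fast-per-iteration convergers — elitist GA and greedy two-phase TLO — have
settled enough for V-shaped masks to thin out (about 1.8x fewer features
than S-shaped in the scaled two-algorithm comparison), while EO, PSO, GWO
and WOA still carry mid-density masks. The mechanism ties the gap directly
to convergence — V-masks thin as steps shrink — so longer budgets (the
study-scale 100 x 50 design) are where V-shaped sparsity develops fully.

## Known limitations

* The Gaussian generator cannot validate behaviour under correlated or
  heavy-tailed features; rankings of the six optimizers on real descriptor
  tables may differ.
* The fixed-split protocol overstates absolute MCC (see above); only
  comparisons between methods under the identical split are meaningful.
* The audio extractor's filterbank chroma is an approximation to true
  constant-Q analysis; per-frame values differ from other implementations
  even though the pooled statistics behave equivalently.
* KNN is used exactly as in the emulated protocol — unscaled features by
  default (`standardize = TRUE` is available); with descriptors on very
  different scales the distance is dominated by large-magnitude features.
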
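---
title: "Methods: hybrid genetic-neural pattern recognition for gas sensor arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid genetic-neural pattern recognition for gas sensor arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enose)
```

## The problem

Metal-oxide (MOS) gas sensors are cheap and sensitive but poorly selective:
each element responds to many volatile compounds. An electronic nose works
around this by reading an *array* of partially selective sensors and
classifying the joint response pattern. `enose` implements one such
pattern-recognition pipeline for an eight-channel array (O3, LPG/LNG, NOx,
alcohol, smoke, VOC, CO, NH3 channels, sampled at 1 Hz as voltages), aimed
at odor-fingerprint tasks such as telling decaying fish from decaying meat
day by day.

The pipeline has five stages:

1. **Smoothing (SMMA).** A causal windowed mean of width $K$ samples,
   $\mathrm{S}(t) = \frac{1}{K}\sum_{i=t-K+1}^{t} x(i)$, with partial
   windows at the start so the output length equals the input length. This
   is online filtering: the oldest sample leaves the window as the newest
   enters.
2. **Normalization.** Division by the per-channel saturation voltage maps
   every reading into $[0, 1]$, making channels comparable.
3. **Gradient features.** The rate of change of the smoothed, normalized
   signal, evaluated whenever $t$ is a positive multiple of $K$:
   $$T(t) = \frac{S(t) - S(0)}{t} \ (t \le K), \qquad
     T(t) = \frac{S(t) - S(t-K)}{K} \ (t > K).$$
   Both branches coincide at $t = K$, the first grid point; $t = 0$ is
   excluded because the first branch would divide by zero.
4. **GA + ANN stages.** A real-coded genetic algorithm denoises the event's
   feature vectors (below); a small backpropagation network per reference
   class scores the denoised vector.
5. **Database matching.** A query's gradient profile is compared with each
   stored class signature channel by channel; identification succeeds when
   at least 6 of the 8 channels agree (below).

## The GA stage

A chromosome is a vector of $L = 8$ genes in $[0,1]$ — one normalized
sensor feature per channel. The per-gene fitness is the oscillatory
function
$$f(x) = x + K\,\lvert\sin(32x)\rvert, \qquad 0 \le x < \pi,$$
with $K$ the preprocessing window; angles are radians, and the factor 32
puts roughly ten oscillations on the unit interval. Genes in $[0,1]$
automatically satisfy the domain constraint. Because $f$ takes a scalar
while a chromosome is an 8-vector, chromosome fitness is defined as the
*mean* per-gene fitness; averaging keeps the fixed stopping threshold of
0.5 meaningful for any chromosome length.

The initial population is created from the sensors' observed values: the
smoothed, normalized 8-channel vectors at the gradient epochs, sampled with
replacement and jittered (sd 0.01, clipped to $[0,1]$). A configurable
fraction of the population may instead be drawn uniformly; the default
fraction of seeded individuals is 1, since the method defines its initial
population from the sensed data. Evolution is the canonical generational
loop: roulette-wheel (fitness-proportionate) selection, one-point crossover
with probability 0.18, per-gene uniform-resampling mutation with
probability 0.01, and elitist preservation of the single best chromosome,
which makes the best fitness non-decreasing. The loop stops when the best
fitness reaches the threshold (0.5) or after 200 generations; the default
population size is 1500. Roulette selection and a single elite were chosen
as the textbook defaults for this style of GA; the operator set is fixed to
one-point crossover (multipoint and uniform variants are out of scope).

Because observed feature vectors usually score far above 0.5, the GA
typically terminates at generation 0 and the elite is the
highest-fitness observed vector (after jitter) — a *denoised
representative* of the event. That elite 8-vector is what the neural stage
consumes.

## The ANN stage

One feedforward network per reference class: 8 inputs, one hidden layer
(default 8 units — the hidden width is deliberately flexible), one logistic
output. The logistic sigmoid is used throughout, matching the classical
backpropagation formulation and keeping outputs in $(0,1)$ alongside the
normalized targets (0.9 for the class's own events, 0.1 otherwise).
Training is full-batch gradient descent with momentum on the classical
batch objective $E = \tfrac12\sum_i (P_i - Y_i)^2$:
$$\Delta w \leftarrow -\eta\,\partial E/\partial w + \mu\,\Delta w_{prev},$$
with learning rate $\eta = 0.01$, momentum $\mu = 0.2$, and learning goal
0.0002. Batch updates make the result independent of sample order. Two
error metrics are recorded every epoch: the mean squared error (the default
stopping metric, compared against the goal) and the normalized
absolute-deviation target value
$$d = \frac{1}{m}\sum_{i=1}^{m} \frac{\lvert Y_i - P_i\rvert}{Y_{max}},$$
which is exposed as an alternative stopping metric (`stop_metric =
"target_d"`). Weight gradients are validated against central finite
differences in the test suite. Inside the full pipeline the per-class
training budget defaults to 3000 epochs — the one-vs-rest scores only need
to separate, not to reach the goal — while standalone training defaults to
50000.

## The matching rule

Each reference record stores the gradient profile of the class's *averaged*
training events (averaging the 30 training replicates suppresses noise by
$\sqrt{30}$) plus the GA-elite feature vector. A query channel matches a
stored channel when their similarity is at least 0.80 at **every** shared
epoch, where the similarity of two gradients is 0 if their signs differ and
otherwise $1 - \lvert g_q - g_r\rvert / \max(\lvert g_q\rvert, \lvert
g_r\rvert)$. Gradients below $\varepsilon = 10^{-6}$ (normalized units)
are treated as sign 0 and match only sign 0. Identification succeeds when
at least 6 of 8 channels match; the verdict is the top-ranked successful
record (ranked by matched channels, then mean similarity, ties kept in
database order) or `"unidentified"`. "At least 80%" is implemented
inclusively ($\ge 0.80$); `strict_inequality = TRUE` flips the boundary.

"Same pattern" needed a concrete definition; gradient sign agreement was
chosen because the sign of the windowed slope is the coarsest pattern
descriptor that survives noise, and the relative-difference similarity
because it is scale-free across channels of very different amplitude. Both
the threshold and the channel quorum are configuration keys so alternative
readings remain testable.

When trained networks are attached, the network stage refines the match:
among the records that pass the matching rule, the top-ranked one whose
one-vs-rest network accepts the event's elite features (score $\ge$ 0.5) is
preferred, falling back to the plain match verdict when none is accepted.
The network can therefore re-order successful candidates but never
overrule the matching rule.

## The synthetic study generator

No public recordings exist for this kind of decay experiment, so the
package ships a simulator whose events have the statistical structure of
such studies: channel $c$ follows
$$v_c(t) = b_c + A_c\,(1 - e^{-t/\tau_c}) + \delta t + \epsilon_t,
  \qquad \epsilon_t \sim N(0, \sigma^2),$$
clipped to $[0, s_c]$ — a saturating rise from baseline $b_c$ toward
$b_c + A_c$ with time constant $\tau_c$, a slow positive drift $\delta$
(the natural drift of MOS elements), and Gaussian read noise. Events are
1000 samples at 1 Hz; a study simulates 50 events per class, split 30
train / 20 test by a seeded permutation. Four built-in classes
(`fish_fresh`, `fish_day3`, `meat_fresh`, `meat_day3`) have hand-chosen,
documented amplitude patterns — decayed fish drives NH3 hardest, decayed
meat is broader across VOC/smoke — that are illustrative fingerprints, not
fits to measurements.

Default parameter choices, with reasoning:

* **Baseline 0.4 V, saturation 5 V** per channel: typical MOS divider
  output levels with a 5 V circuit.
* **Drift $\delta = 3\times10^{-4}$ V/s** (0.3 V over a 1000 s event): at
  the upper end of plausible slow drift, and deliberately non-zero — it
  keeps the plateau-phase gradient strictly positive, which the every-epoch
  sign-matching rule needs (see sizing note below).
* **Noise sd 0.002 V** (2 mV) in the built-in classes: millivolt-scale ADC
  noise.
* **Window $K = 10$ samples**: the smoothing/gradient window is a required
  configuration value; 10 s balances noise suppression against temporal
  resolution for $\tau$ in the tens of seconds.

**Sizing of the high-SNR benchmark.** The reference two-class benchmark
(`benchmark_specs()`: `fish_day3` vs `meat_day3`) uses read noise 0.3 mV.
The every-epoch rule is the binding constraint in the plateau phase, where
the true gradient is only the drift slope $\delta/s = 6\times10^{-5}$ s⁻¹.
The gradient noise there is
$\sqrt{2}\,(\sigma/s)/K^{3/2} \approx 2.7\times10^{-6}$ for
$\sigma = 0.3$ mV, so the 20% relative band around the drift slope is a
$4.4\sigma$ margin per epoch — wide enough that all ~99 epochs pass on
every channel of the true class, while rise-phase amplitude ratios between
the two classes (up to 1.9× on NH3) push several channels of the wrong
class far outside the band. At the 2 mV default the same arithmetic gives
under $1\sigma$, so full-length events become `"unidentified"`: the
matching rule is intentionally stringent, and the benchmark documents the
regime in which it operates.

## What the simulator does and does not emulate

It reproduces saturating multi-channel responses, repeatable class
fingerprints, drift, read noise, and the train/test protocol. It does not
model humidity or temperature covariates, sensor aging or poisoning,
cross-event baseline wander, correlated noise, or hardware effects (heater
and load-resistance electronics, wireless transport). A pipeline that
passes on these synthetic studies is verified as an *algorithm* —
equations, operators, decision rule, end-to-end class recovery under known
conditions — not validated against real decay chemistry; real recordings
ship with none of the simulator's guarantees, and published success rates
on proprietary recordings are not reproducible here.

## Numerical choices and degenerate inputs

* SMMA uses cumulative sums (exact up to floating rounding) and partial
  leading windows; `K = 1` is the identity.
* Gradient grids exclude `t = 0`; series must exceed one window.
* Normalization rejects values above saturation instead of clipping —
  an out-of-range reading means a mis-set saturation constant.
* Similarity of two sub-$\varepsilon$ gradients is defined as 1 (both
  "flat" is agreement); the similarity threshold uses $\ge$.
* Fitness-proportionate selection falls back to uniform when total
  fitness is 0; chromosomes of length 1 cannot cross over and are cloned.
* `matrix`-seeded populations clip jittered genes back to $[0,1]$, keeping
  every operator closed on the gene domain.
* All stage seeds derive deterministically from one global seed; equal
  seeds give bitwise-equal studies, populations, and networks.

## Problem sizes used in the shipped checks

The test suite and the acceptance script size their studies to run on a
single CPU in minutes: the end-to-end benchmark uses the full 50
events/class, 30/20 split, 1000-sample events over 20 (tests) or 10
(acceptance script) independent study seeds; unit tests use 4–8 events of
150–300 samples. The GA contract is checked at the full default operating
point (population 1500); network convergence on a 20-sample separable toy
set.

## Known limitations

* The every-epoch matching rule makes long plateaus informative only
  through drift; arrays with negligible drift would need epoch windowing
  or a per-epoch quorum instead ("80% of epochs" rather than "all
  epochs"), which the configuration does not currently offer.
* The GA's oscillatory fitness ignores between-channel structure; it
  selects a representative epoch vector rather than estimating a latent
  noiseless vector.
* One-vs-rest scalar-output networks scale linearly in class count and do
  not calibrate scores across classes.
* The similarity normalizer $\max(|g_q|, |g_r|)$ makes near-zero reference
  gradients fragile; the $\varepsilon$ sign convention mitigates but does
  not remove this.
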
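---
title: "Estimating single-channel open probability: models, conventions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating single-channel open probability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patchPo)
```

# The estimation problem

A cell-attached patch over a membrane expressing epithelial sodium channels
(ENaC) carries an unknown number N of channels, each switching between a
closed and a conducting state. At a fixed pipette potential each open
channel adds a unitary current $i$ (inward, so negative, around
$-0.3\,$pA), and the recorded current visits $N+1$ roughly equidistant
levels. Two quantities are wanted: the per-channel open probability $P_o$
(the stationary fraction of time one channel conducts) and $i$ itself.
Neither is directly observable — the patch current only reveals how many
channels are open *simultaneously* — so both are inferred from the
*amplitude histogram* of the trace.

The whole-cell counterpart works at the population level: in a two-electrode
voltage clamp (TEVC) recording from an oocyte, the amiloride-sensitive
current fraction $\Delta I_{Ami}$ is proportional to $N \cdot i \cdot P_o$,
and ratios of $\Delta I_{Ami}$ across pharmacological epochs isolate changes
in $P_o$ alone.

# The patch model

## Amplitude histogram and constrained Gaussian mixture

Samples are binned at a fixed width (default $0.01\,$pA). The histogram is
fit by least squares with a sum of Gaussian components,

$$f(x) = \sum_{k=0}^{N} \frac{A_k}{\sqrt{2\pi}\,\sigma_k}
  \exp\!\left(-\tfrac12 \frac{(x-\mu_k)^2}{\sigma_k^2}\right) \cdot w,$$

where $w$ is the bin width (density at the bin center times width
approximates the bin count), $A_k$ is the number of points attributed to
level $k$ and the means are *structurally constrained* to be equidistant:

$$\mu_k = \mu_0 + k\, i .$$

This constraint encodes the physical assumption that all channels in the
patch have the same unitary amplitude; it is built into the model
parameterization rather than penalized, so fitted means are exactly
equidistant. The $\sigma_k$ are free per component by default (open-channel
noise can widen upper levels); `sharedSigma = TRUE` pools them, which
stabilizes sparsely occupied levels. The objective is unweighted least
squares on the per-bin counts — the histogram, not the raw samples, is the
data being fit.

## From weights to occupancies to $P_o$

Normalized weights give the occupation probabilities
$P_k = A_k / \sum_j A_j$: the fraction of time exactly $k$ channels were
open. For $N$ *independent, identical* channels these must follow the
binomial law

$$B(k \mid P_o, N) = \binom{N}{k} P_o^{\,k} (1-P_o)^{N-k},$$

and $P_o$ is estimated by least squares between the observed $P_k$ and
$B(k \mid P_o, N)$.

## Anchoring conventions and the channel-count scan

The observed levels must be mapped onto open-channel counts $0..N$, and the
data cannot decide the mapping:

* **baseline_closed** (default): the least-inward level is the all-closed
  state; observed level $j$ means $j$ channels open. If $N$ exceeds the
  observed open levels, the unseen upper levels were "never visited".
* **top_open**: the most extreme observed level is the all-open state with
  all $N$ channels conducting; the baseline remains all-closed, and
  intermediate observed levels stack directly below the top. This is the
  right reading for a high-$P_o$ patch whose single "open" level may in
  fact carry the summed current of two or more channels that are almost
  always simultaneously open.

Unobserved intermediate levels enter the default objective with observed
probability zero — they genuinely were not observed, and a candidate
$(N, P_o)$ that predicts substantial mass there should pay for it. Because
one can also argue for scoring only the observed levels, an
`objective = "observed_only"` variant is provided; the two agree whenever
every level $0..N$ is observed. The published per-recording values the
package's defaults are aimed at do not disambiguate the two conventions,
and no claim is made that either reproduces any specific historical fit.

`scanChannelCount()` repeats the fit over a range of $N$. On occupancy
profiles in each convention's home regime the direction of the trend is
systematic — the estimate falls with assumed $N$ under baseline_closed and
rises under top_open — so the default $N$ (the observed open-level count,
the *minimum* channel count consistent with the data) bounds $P_o$ from
above under the default anchoring. These directions are not theorems for
arbitrary profiles: a strongly non-binomial profile (negative $R^2$) can
break the baseline_closed direction, and a closed-dominant profile breaks
the top_open one; the property suite therefore checks them on noisy-binomial
and open-dominant profiles respectively, which is exactly the regime where
each convention is scientifically meaningful.

Ties in $R^2$ across the scan resolve to the smallest $N$
(`bestChannelCount()`), honoring the minimum-channel-count rule.

# Numerical choices

* **Histogram alignment.** Bin edges place the *first bin center on the
  minimum sample*. A quantized noise-free trace then puts every level
  exactly on a bin center, so degenerate fits are exact rather than
  half-bin-width biased.
* **Level counting.** Strong peaks (local maxima holding at least 5% of the
  maximum bin count, minimum separation half the level spacing) fix the
  spacing estimate; the equidistant grid is then extended outward, accepting
  weak local maxima (at least 20 points) at grid positions. The extension
  matters: the all-open level of a six-channel patch at $P_o = 0.34$ holds
  only $0.34^6 \approx 0.15\%$ of samples, far below any prominence
  threshold that tolerates noise, yet it is a real, visible level.
* **Mixture optimization.** Levenberg–Marquardt (`minpack.lm::nls.lm`)
  with analytic grid initialization from peak detection, box constraints
  ($\sigma_k \ge w/5$, $\sigma_k \le |i|$, $A_k \ge 0$), and a fixed
  (deterministic, RNG-free) sequence of up to five jittered restarts. The
  best attempt is always returned; non-convergence is flagged, never
  silently accepted.
* **Quasi-discrete histograms.** When every level cluster is narrower than
  half a bin (noise-free traces), the Gaussian location is unidentifiable
  within a bin for the optimizer. Such histograms are fit analytically:
  cluster weights are the exact counts and $(\mu_0, i)$ come from a
  count-weighted linear regression of cluster mean against level index.
* **Binomial fit.** Grid search at $10^{-4}$ resolution refined by
  `stats::optimize` to $10^{-12}$; for $N = 1$ the closed-form minimizer
  $(1 - P_0 + P_1)/2$ is used, so the two-level case is exact. $R^2$ is
  $1 - SS_{res}/SS_{tot}$ with $SS_{tot}$ about the mean of the observed
  probabilities entering the objective.
* **Degenerate inputs.** A trace with a single detected level returns
  $P_o = 0$ flagged `"no open levels detected"` rather than an error; a
  requested $N$ below the observed open levels is a mapping error.

# The synthetic-data generator

`simulatePatchTrace()` draws, per channel, a discrete-time two-state Markov
chain at the sampling rate with per-step switch probability
$1 - e^{-\text{rate}\,\Delta t}$ — exact for the two-state chain observed at
sample resolution and reproducible bit-for-bit from the seed. Rates derive
from the stationary $P_o$ and the mean open dwell: closing rate
$1/\tau_o$, opening rate $P_o/((1-P_o)\tau_o)$. Defaults mirror the
experimental conditions the analysis is aimed at: $10\,$kHz sampling,
$0.05\,$pA Gaussian noise, zero-phase Gaussian low-pass at $0.1\,$kHz
($-3\,$dB), $i = -0.35\,$pA, $60\,$s records.

The default mean open dwell is $0.5\,$s. ENaC gates slowly — reported open
and closed dwells run from hundreds of milliseconds to seconds — and the
dwell scale is *not* a free detail under heavy filtering: a $0.1\,$kHz
filter has a rise time of a few milliseconds, so if dwells are pushed into
the few-millisecond range (e.g. a 50 ms open dwell at $P_o \approx 0.9$
forces ~7 ms closures), brief sojourns are attenuated below detectability
and the recovered $P_o$ biases upward by several points. At the 0.5 s
default, dwell times sit two orders of magnitude above the filter rise time
and recovery at the tested operating points is unbiased.

`simulateTevcTrace()` generates the macroscopic current
$I(t) = \text{leak} + N i P_o(t)\,b(t)\,s(t)\,r(t) + \text{noise}$ at
$20\,$Hz: $b(t)$ is the amiloride block (complete by default, a residual
fraction is configurable), $s(t)$ a per-epoch conductance scale (e.g. a
low-Na$^+$ bath), and $r(t) = (1-\rho)^{t/60}$ run-down at fraction $\rho$
per minute. Protease exposure multiplies $P_o$ (clamped to $[0,1]$) from
the epoch start onward; MTSET sets $P_o$ to its post-modification value
instantaneously, with an optional conductance factor to explore the caveat
that sulfhydryl modification might also reduce unitary conductance. The
protease epoch is modelled as blocked (amiloride is co-applied during
incubation to prevent sodium loading).

**What the generator does not emulate** — and hence what passing tests do
not show about real data: baseline drift and seal instability, capacitive
transients and solution-exchange artifacts, sodium self-inhibition,
channel-mode switching or flicker (bursting) kinetics, cooperative gating
between channels, and heterogeneity of $i$ or $P_o$ across channels in one
patch. The binomial model's independence-and-identity assumption is imposed
by the generator; on real patches it is an approximation the analysis
cannot itself verify.

# The whole-cell estimators

$\Delta I_{Ami}$ is measured per amiloride application as the difference
between the mean current over the trailing 5 s (configurable) of the
preceding plateau epoch and the trailing 5 s of the amiloride epoch;
trailing windows skip exchange transients at epoch boundaries. Fold change
is $\Delta I_{Ami}(\text{after})/\Delta I_{Ami}(\text{before})$ across a
treatment; run-down is deliberately *not* corrected, matching the
experimental design in which treated groups are compared against
mock-treated controls whose fold change sits below 1. The MTSET relative
activity is $\Delta I_{Ami}(\text{before})/\Delta I_{Ami}(\text{after})$,
which equals the baseline $P_o$ exactly when modification drives $P_o$ to
1.0 with conductance unchanged — in a noise-free simulation this identity
is exact, and it is how the estimator is validated. Group summaries report
mean, sample SD ($n-1$) and $n$; inferential testing is left to standard
routines (`kruskal.test`, `aov`, `wilcox.test`) on the exported tables.

# Test problem sizes

The validation suite simulates at the scale the estimators are designed
for: 60 s patch records at 10 kHz ($6\times10^5$ samples) for the recovery
checks — ten six-channel low-$P_o$ recordings, seven single-channel
high-$P_o$ recordings, and an eleven-patch ensemble with three to seven
channels per patch — with shorter records for structural unit tests.
Whole-cell protocols run about 10 minutes of simulated time at 20 Hz.

# Known limitations

* Channel counting is bounded below only: levels never visited in a finite
  record are invisible, so $N$ from observed levels underestimates crowded
  patches and the default $P_o$ is correspondingly an upper bound
  (baseline_closed) or lower bound (top_open).
* The constrained mixture assumes level-independent spacing; rectification
  or stacked-conductance effects that compress upper levels would bias $i$.
* Heavily filtered fast gating (dwells within an order of magnitude of the
  filter rise time) biases $P_o$ toward the majority state; the package
  does not attempt missed-event correction.
* The MTSET estimator inherits its assumptions: complete modification,
  $P_o \to 1$, unchanged unitary conductance. If modification reduces
  conductance, baseline activity is overestimated; the simulator's
  `mtsetConductanceFactor` exists to quantify that sensitivity.
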
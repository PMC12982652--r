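---
title: "Dynamic digital markers from two-time-scale Markov chains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic digital markers from two-time-scale Markov chains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddmarker)
```

## The model

Digital phenotyping streams — actigraphy, phone usage, sleep patterns —
are sampled daily, while the clinical states that generate them evolve
over weeks to months. `ddmarker` models this as a two-time-scale Markov
chain: a slow *macro-state* \(M\) (a clinical regime such as acute,
persistent, residual, stable or prodromal) and, within each macro-state,
fast *micro-states* \(m\) (daily behavioural symbols such as regulated
routine R, withdrawn W, no-regular-usage N, fragmented F). The pair
\((M, m)\) is flattened into a single state space — the packaged example
uses \(5 \times 4 = 20\) states — with one transition per day governed by
a row-stochastic matrix \(P\).

Three orders of markers are computed from a chain:

1. **First order — occupancy.** The stationary distribution
   \(\pi = \pi P\), marginalized over micro-states, gives the long-run
   fraction of days spent in each clinical regime.
2. **Second order — overall variability.** The entropy rate
   \(H = -\sum_i \pi_i \sum_j P_{ij} \log_2 P_{ij}\) (bits/day)
   summarizes day-to-day unpredictability across the whole trajectory.
   Because it averages over regimes, very different clinical courses can
   share similar values.
3. **Third order — regulation of variability.** The macro-centric
   entropy rate conditions on one macro-state: the within-macro block of
   \(P\) is extracted, each row renormalized to remove the (small) mass
   that leaks to other regimes, and
   \(H_M = -\sum_i \tilde\pi^{(M)}_i \sum_j \tilde P^{(M)}_{ij}
   \log_2 \tilde P^{(M)}_{ij}\)
   is evaluated with the block's own stationary vector
   \(\tilde\pi^{(M)}\). \(H_M\) measures how tightly daily behaviour is
   regulated *within* a regime and is the discriminating marker when
   occupancy and global entropy overlap. Mixing time (days until the
   state distribution is within total-variation \(\varepsilon\) of
   \(\pi\) from the worst start) and mean recurrence time
   (\(1/\pi_i\)) complete the dynamical picture: behavioural
   inflexibility and inertia, in days.

### The conditioning construction

Several constructions could define "the micro dynamics of one
macro-state in isolation". We take the within-macro block of \(P\) and
renormalize each row, because it is the transition law of the chain
conditional on *not leaving* the macro-state on that day, which is
exactly the situation of an observation window fully contained in one
occupancy period. An alternative weights the block by the conditional
slice of the global stationary vector instead of the block's own fixed
point; both are available (`pi_source = "block"` — the default — or
`"global"`), they coincide when leakage is zero, and they differ
negligibly for strongly lumped chains like the packaged example.

## The packaged example chain and its normalization caveat

`example_psychosis_chain()` loads a 20-state illustrative matrix for a
hypothetical psychosis trajectory (prodromal period, acute episodes,
mostly stable long-run behaviour). As distributed, its rows do not all
sum to 1 — some fall short by 40% or more, presumably a casualty of
rounding and transcription in print. Since every analytic quantity
requires a stochastic matrix, rows are always renormalized on load; the
original row sums are kept in the chain's `normalization` report and any
row off by more than `warn_tol` (default 1%) is flagged. A consequence
worth stating plainly: summary values quoted alongside the original
table (occupancies, entropy rates) are **not recoverable** from the
renormalized matrix — the renormalization redistributes enough mass to
change the stationary distribution and every entropy rate downstream.
The package therefore treats the example as a structural illustration,
and all quantitative guarantees are established on chains with exact
rows (the generator below) where ground truth is unambiguous.

```{r}
ch <- example_psychosis_chain()
summary(ch$normalization$original_sum)
run_metrics(ch)
```

## Finite-window estimation

In practice \(H_M\) must be estimated from a finite window of \(T\)
days. The plug-in estimator counts ordered adjacent symbol pairs within
the window, row-normalizes the counts into \(\hat P\), takes the source
frequencies as \(\hat\pi\) (the standard finite-sample-stable choice; an
eigenvector of \(\hat P\) would add noise without reducing bias), and
evaluates the entropy-rate formula. Unobserved transitions drop out via
the \(0 \log 0 = 0\) convention; `pseudo_count` offers optional Laplace
smoothing and defaults to 0.

The estimator is biased downward at small \(T\), most strongly for
high-entropy regimes: with few observed transitions, behaviour looks
more regular than it is. The bias decays as \(T\) grows, which is
precisely the signature `entropy_rate_grid()` displays across its
default grid \(T \in \{15, 30, 90\}\) days — realistic observation
horizons (two weeks to a season) for digital phenotyping. Windows are
taken fully inside one macro-state run (`macro_window_segments()`), or
simulated directly from the conditional block chain
(`simulate_conditional()`); the latter is the default harness because
macro sojourns may be much shorter than 90 days, making fully-contained
long windows rare in free-running trajectories. The default 300 windows
per cell keep standard errors in the low millibits while a full grid
runs in well under a minute. Standard errors are the spread of
per-window estimates over \(\sqrt{n}\); with overlapping trajectory
windows (`step = 1`) they are optimistic, and a disjoint mode
(`step = T`) is available.

```{r}
entropy_rate_grid(ch, T_grid = c(15, 30), n_reps = 100, seed = 1,
                  macros = c("A", "D"))
```

## Detecting regime shifts without labels

When the macro-state is unobserved, the sliding-window entropy series
(`sliding_entropy_series()`) tracks the macro-centric entropy of
whichever regime the stream currently occupies, up to finite-window
bias. Regime changes then appear as mean shifts, and
`detect_changepoints()` flags them with either a CUSUM statistic
(maximum excursion of cumulative deviations from the mean; the default,
robust for short series) or binary segmentation (best variance-reducing
split). Both are calibrated by a seeded permutation test — 1000
shuffles of the series by default, significance level 0.05 — rather
than asymptotic thresholds, because entropy series are short and
autocorrelated. Detected segments can be classified to the nearest
analytic \(H_M\) (`classify_regime()`), with an explicit
`"indeterminate"` band for values ambiguous between two regimes, and a
sustained-deviation alarm (`K` = 3 consecutive windows outside the
baseline mean ± 2 sd) operationalizes "sustained departure from
baseline".

Caveat: that sliding-window entropy approximates macro-centric entropy
under unobserved labels is demonstrated here empirically on synthetic
chains; it is not a theorem, and window length trades localization
against bias.

## The synthetic generator

`chain_recipe()` + `build_chain()` construct chains from interpretable
handles: per-macro **dwell** (per-day stay probability; mean sojourn
\(1/(1-d)\) days, so 0.99 means the weeks-to-months scale), **preference
weights** for where the process goes when it leaves, and a per-macro
Dirichlet **concentration** controlling within-block entropy
(large → near-uniform rows, \(H_M \to \log_2 m\); small → peaked,
low-entropy regimes). Cross-macro mass lands on destination micro-states
in proportion to the destination block's stationary distribution, which
keeps the two time scales separable. Rows sum to 1 exactly by
construction, and `recover_recipe()` round-trips the dwell parameters to
numerical precision.

What the generator emulates: geometric macro sojourns, macro-dependent
daily symbol dynamics, rare cross-regime transitions. What it does not:
non-geometric dwell distributions, covariate- or treatment-driven
inhomogeneity, measurement noise or missing days, and any claim about
how raw sensor values map to the four-symbol alphabet (the
threshold-based mapping in `threshold_symbolize()` is illustrative
plumbing only). Passing tests on generated chains therefore validate
the estimators and detectors under the stated model, not the fidelity
of the model to any particular device stream.

## Numerical choices

* Logarithms are base 2 throughout; units bits/day; \(0 \log 0 = 0\).
* Stationary vectors are found by a dense linear solve of the balance
  equations with the normalization row appended; power iteration on the
  half-lazy chain \((P + I)/2\) (always aperiodic, same fixed point)
  is the cross-check and fallback. The two agree to \(10^{-9}\) on
  every chain tested.
* Irreducibility is established by strong-component analysis of the
  positive-transition graph before any solve; reducible chains are
  rejected with their classes named rather than silently averaged.
* Mixing time uses max-over-start total variation with
  \(\varepsilon = 0.25\) (the usual convention) and a hard iteration cap
  that turns periodic chains into errors instead of hangs.
* Ordinal symbolization breaks ties by index order; approximate entropy
  uses the classical definition with self-matches and Chebyshev
  distance; Lempel–Ziv follows the exhaustive (LZ76) parsing.
* Change-point p-values use the add-one permutation estimator
  \((1 + \#\{{\rm perm} \ge {\rm obs}\})/(n_{\rm perm} + 1)\), so they
  are never exactly zero, and segments shorter than `min_seg` (2) are
  never split.
* Agreement between analytic occupancies and long simulations is judged
  at 3 standard errors computed by batch means (200 batches), since
  Markov samples are autocorrelated and the naive binomial SE would be
  anti-conservative. Property tests use \(10^6\)-day runs for
  occupancy/recurrence checks and \(10^5\)-day windows for estimator
  consistency; both finish in seconds.

## Known limitations

* The conditional-block construction assumes the macro-label process is
  Markov at the day scale; long-memory clinical courses violate this.
* Plug-in estimates are reported without bias correction to keep the
  estimator elementary and transparent; Miller–Madow-style corrections
  could be layered on the same `empirical_transition_model` objects.
* Overlapping-window standard errors understate uncertainty; use
  disjoint windows when the series is long enough.
* The packaged example matrix supports structural demonstrations only,
  for the normalization reasons above.
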
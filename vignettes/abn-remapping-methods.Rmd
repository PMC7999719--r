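---
title: "Population-level remapping analysis of adult-born neuron calcium events: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-level remapping analysis of adult-born neuron calcium events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem this package addresses

Adult-born granule cells (ABNs) of the dentate gyrus fire extremely sparsely
— on the order of one calcium transient per minute — and each transient is
typically polyphasic, decomposing under deconvolution into several unitary
events with individual times and amplitudes. `abnremap` analyses such
deconvolved event trains at the population level across a contextual
fear-conditioning paradigm (preconditioning home cage `preC`, pre-shock
context `preS`, post-shock context `postS`, a long home-cage consolidation
recording, and a retrieval `test`), asking three questions:

1. Which neurons change their activity between periods, given that the
   event trains are temporally aggregated and a naive bootstrap would
   overstate significance?
2. Is the population active in one period the *same* population as in
   another (population-vector similarity and clustering), or a different
   one?
3. Does the population's activity pattern *remap* gradually during memory
   consolidation, and which neurons carry the remap?

Every stage is exercised end-to-end on a bundled synthetic-experiment
generator, so the statistical machinery is testable without access to any
recording.

## Data model

An experiment holds one event table (mouse, neuron, session, time in seconds
from session start, amplitude in arbitrary fluorescence units), the session
durations, and a hypnogram of the consolidation recording (wake / NREM / REM
intervals; sleep means NREM plus REM). Invariants are enforced at
construction: nondecreasing times within a neuron-session, times inside the
session, positive amplitudes. "Activity" is amplitude-weighted throughout —
the sum of unitary-event amplitudes per minute — because the deconvolution's
amplitude information is part of the signal; event counting is available
behind a flag (`weighted = FALSE`).

Binning uses half-open bins `[t, t + delta)` anchored at the session start
(the convention must be fixed somewhere; half-open bins conserve total
amplitude exactly and give each event exactly one bin). An event at exactly
the session end is assigned to the last bin.

## Temporal aggregation and the bootstrap block length

The circular autocorrelation of the 1-s-binned population activity (the
Pearson correlation of the series with itself rotated by k bins) measures how
strongly events aggregate in time: a flat function means Poisson-like timing,
a decaying one means bursts. A three-parameter exponential
`a + b * exp(-lag / tau)` is fitted to the positive lags by
Levenberg–Marquardt least squares; the bootstrap block length is the smallest
lag at which the fitted decay has shrunk to within 5% of its asymptote
(`tau * log(20)`, rounded up to a whole second). The 5% tolerance is a
package choice: it maps a tau of ~3–4 s, typical of polyphasic transients
whose unitary events spread over a few seconds, onto a ~10 s block, the
scale at which such data stop being autocorrelated. A non-decaying or
degenerate fit falls back to a configurable default (10 s) with a warning.
The autocorrelation of a constant series is undefined (0/0) and is returned
as an all-zero, degenerate-flagged result rather than an error, so population
pipelines keep running on silent segments.

Amplitude-weighted binning feeds the autocorrelation by default; whether
counts or amplitudes are used barely moves the fitted decay, and the
amplitude-weighted choice keeps the statistic consistent with every other
stage.

## Responsiveness: moving block bootstrap

Per-neuron changes between two sessions are tested on the difference of mean
1-s-binned activity. Because bins within a burst are correlated, the series
are resampled with the moving block bootstrap (Künsch construction:
overlapping blocks, uniform start positions, no circular wrap, overhang
truncated), with one block length shared by all neurons of an experiment —
the population-level estimate above. Confidence intervals are percentile
intervals of the replicate distribution at the Bonferroni-adjusted level
(`alpha / n_comparisons`; the comparison count is a config item, 2 for the
preC–preS / preS–postS family). A neuron is `increase` when the interval for
(B − A) lies above zero, `decrease` below, `no_change` otherwise; a neuron
silent in both sessions is `no_change` with a missing-data flag.

Two implementation details matter. First, the two series receive internal
RNG substreams keyed by a canonical ordering of their contents rather than
their argument position, so swapping the sessions negates the replicate
distribution exactly and labels are antisymmetric by construction. Second,
resampling the two groups is independent (the paradigm gives no pairing of
time bins across sessions).

A known limitation, visible in the package's own null-calibration tests: with
~1 transient/min and 10-minute sessions a series contains on the order of ten
transients, and percentile bootstrap intervals built from so few effective
observations are mildly liberal — the null rejection rate runs near 8-10% at a
nominal 5%, and no block length between 10 and 60 s removes the excess,
because it stems from the effective sample size, not from residual
correlation. Users should read borderline per-neuron calls accordingly;
population-level fractions (which is how these labels are used) are far less
sensitive.

The active/inactive classifier resamples a period's time bins with
replacement and calls a neuron active when at least 95% of replicates contain
an event-bearing bin. Because the criterion ignores temporal order, plain
(not block) resampling is appropriate; with k event-bearing bins among n,
the number of resampled bins that carry events is exactly Binomial(n, k/n)
per replicate, and the implementation draws from that marginal directly —
distributionally identical to materialising all n draws, but fast enough for
10,000 replicates across a population. Overlap between active sets is
reported as the Jaccard index, both conditional fractions, and a
hypergeometric enrichment p-value, since the field uses both descriptive and
inferential overlap summaries.

## Population vectors, similarity, and cluster significance

An activity vector stacks per-neuron mean activities over a window, mice
concatenated in a fixed id order. To limit the leverage of outlier neurons,
values above each mouse's 95th percentile (linear-interpolation percentile,
R's type 7 — the common default; the choice of percentile method is a
package decision) are truncated to that percentile, per mouse and per
window. Note that this truncation is a fixed transformation of the raw
window, not an idempotent operator: re-truncating already-truncated values
would lower the interpolated percentile again, which is why truncation is
always applied exactly once, to the raw means.

Two scalings serve two displays: `vector_01` min-max rescales each whole
concatenated vector to [0, 1] (the session-comparison convention), and
`neuron_max` divides each neuron by its own maximum across windows so every
neuron peaks at 1 (the consolidation time-course convention). A constant
vector cannot be rescaled and is returned all-zero with a degenerate flag.

Similarity between vectors is the cosine (normalized dot product), which is
scale-invariant and lies in [0, 1] for nonnegative vectors; angular distance
is `1 - cosine`. Clustering is agglomerative with Ward linkage on that
angular distance. Ward's criterion formally assumes squared Euclidean
distances, so Ward-on-angular is a pragmatic convention rather than a
geometric one; it is retained deliberately because it is the convention of
this analysis style, and the significance calibration below does not depend
on the linkage being proper.

Significance of clusters is calibrated by resampling: in each of 10,000
replicates every vector's entries are independently permuted across neuron
positions — destroying inter-vector correlation while preserving each
vector's marginal distribution — and the linkage is recomputed, giving a
reference distribution for every merge-height rank. Each observed merge gets
a permutation p-value against its same-rank reference (with the +1
correction), Bonferroni-corrected over the k−1 merges, and merges are
accepted bottom-up: a merge is significant only if every tighter merge below
it is. The bottom-up rule exists because genuinely tight structure lowers
all later Ward heights, so upper merges would otherwise inherit spurious
significance; it also makes the result expressible as a single dendrogram
cut (at the largest significant height), which is how memberships are
reported. Under exchangeable null vectors the observed tree is one draw from
the permutation orbit, so the family-wise rate of spurious significant
clusters is at or below alpha by construction. The permutation scheme is the
package's choice among several defensible nulls (bootstrap over neurons,
label shuffling); it is the one that leaves per-vector marginals untouched.

## The remapping index

For 15-min consolidation bins, with `A` and `C` the activity vectors of the
first and last bins and `Bt` the vector of bin t, the remapping index is

    RI(t) = (AD(C, Bt) - AD(A, Bt)) / (AD(A, Bt) + AD(C, Bt)),

with `AD = 1 - cosine`. RI is +1 when Bt matches the first bin, −1 when it
matches the last, 0 when equidistant, and inherits cosine's scale
invariance. The orientation deserves a note: the common printed form of this
ratio has the numerator order reversed, which would assign −1 to a perfect
match with the *first* bin, contradicting the verbal definition and the
downward drift the index is meant to reveal. The package implements the
verbal convention by default and exposes the literal printed sign under
`sign_convention = "printed"`; the run report always echoes the convention
used. When Bt matches both references (A and C collinear), the ratio is
0/0; the only consistent reading is equidistance, so the index is defined
as 0 with a degenerate flag.

State-restricted traces (sleep, wake) recompute each bin's mean activity
over only the qualifying hypnogram time within the bin, and drop bins with
less than 60 s of qualifying dwell — a floor below which a bin's mean rests
on too little time to be meaningful. The reference vectors A and C are
always taken from the all-state binning, and state-restricted matrices are
scaled by the all-state per-neuron maxima, so all three traces live on one
scale and are directly comparable. REM-restricted traces are refused by
default: REM occupies well under 10% of the consolidation period in both the
emulated and the real setting, leaving almost no bins above the dwell floor.

The trend of RI against bin-center time (Pearson r, two-sided p,
least-squares slope per minute; bin-center minutes, not bin indices, are the
time axis, which fixes the slope's units) is computed over the
*non-reference* bins only. The first and last bins are +1 and −1 by
construction, so including them would drag the correlation of any series —
even a stationary null — toward −1; excluding them is what makes the null
calibration of the trend test come out at its nominal rate.

Per-neuron remapping classification correlates each neuron's per-bin mean
activity (truncated, unscaled — per-neuron scaling cannot change a
correlation) with bin time, adjusts across neurons by Benjamini–Hochberg,
and labels a neuron `decreasing`/`increasing` only when both p < 0.05 and
q < 0.05 with the matching sign. A constant-activity neuron has no defined
correlation and is `non_remapping` with p = 1. Group activity profiles then
compare the decreasing and increasing groups' mean scaled activity in
learning (preS and postS averaged), consolidation, and test, by bootstrap
with Bonferroni correction over the three periods; the subgroup similarity
analysis repeats the session-clustering within the remapping and
non-remapping subsets.

## The synthetic-experiment generator

The generator emulates the statistical structure the analysis assumes, not
the biophysics. Transient onsets are a (possibly time-varying) Poisson
process at ~1/min per neuron; each transient becomes a burst of
1 + Poisson(1) unitary events with exponentially distributed offsets (mean
3 s, so the population autocorrelation decays within roughly 10 s) and
lognormal amplitudes (sdlog 0.3). Sessions follow the paradigm timings
(10 / 10 / 5 / 150 / 10 minutes). Planted structure:

* 28% of neurons are context-responsive (4x rate in preS); of these, a 10%
  subpopulation is shock-suppressed (back to baseline in postS) and a 16%
  subpopulation is the `decreasing` remapping group.
* During consolidation the decreasing group's rate declines linearly by the
  cross-fade factor (4x start to end) while a 10% `increasing` group rises
  symmetrically; everyone else is stationary. The linear (rather than
  exponential) cross-fade is the simplest monotone choice consistent with a
  gradual remap.
* The test session is driven by the increasing population (6x) while
  learning-active neurons are damped (0.3x): retrieval recruits a different
  population.
* Baseline rates vary across neurons as lognormal multipliers (sdlog 0.5).
  This heterogeneity is essential, not cosmetic: without a shared per-neuron
  rate pattern, session vectors of stationary populations are mutually
  exchangeable noise and no home-cage/context cluster can exist even in
  principle. Real populations always carry such rate structure.
* The hypnogram alternates wake and NREM bouts (exponential dwells with a
  floor) with occasional short REM bouts, keeping REM well under 10% of
  time — deliberately sparse, so the pipeline's refusal to compute
  REM-restricted traces is exercised.

The null generator (`generate_null_experiment`) zeroes every fraction and
forces every effect — including baseline heterogeneity, which is an effect
size from the analysis's point of view — to 1, yielding stationary,
homogeneous, independent neurons: the type-I-error harness for the whole
pipeline.

What the generator does *not* emulate: indicator dynamics and deconvolution
artefacts (events arrive error-free), behaviour-locked activity within a
session, slow nonstationarities other than the planted cross-fade, and
between-mouse differences beyond independent sampling. Passing recovery
tests on this generator therefore demonstrates that the statistics recover
the structure they model, not that real recordings satisfy that model.

## Problem sizes and reproducibility

The test suite runs the null-calibration studies at 100 neurons x 200
generator seeds with 1,000 bootstrap / permutation replicates, and the
recovery studies at the default 96-neuron experiment across 5 seeds — sizes
at which the Monte-Carlo error of the checked rates is a small fraction of
the tolerances being asserted, while a full run of the suite stays in the
tens of minutes. Production analyses (the `analysis/` drivers) use 10,000
replicates, the level at which percentile quantiles at alpha = 0.05 are
stable to the third decimal.

Every stochastic operation takes an explicit seed and evaluates under a
local RNG scope, so identical configs and seeds give bit-identical event
tables, labels, and run reports, and no call disturbs the caller's RNG
state. The run report records every seed, threshold, block length, and sign
convention actually used.

## Known limitations

* Percentile bootstrap intervals are mildly liberal at this data sparsity
  (see the responsiveness section); the package reports the calibrated
  rates honestly rather than inflating intervals ad hoc.
* Ward linkage on angular distance is geometrically improper (retained as
  the field convention; the permutation calibration does not rely on it).
* The 95th-percentile truncation is a fixed, non-idempotent transformation;
  it is applied exactly once to raw window means.
* Cluster significance depends on the chosen permutation null; alternatives
  (neuron bootstrap) are defensible and would shift borderline calls.
* With ~10 consolidation bins, per-neuron trend tests have limited power for
  weakly remapping neurons; recovered remapping fractions understate planted
  fractions accordingly.
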
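# abnremap

Population-level analysis of sparse, deconvolved unitary calcium event trains
from hippocampal adult-born neurons (ABNs) recorded across a contextual
fear-conditioning paradigm: home cage (`preC`), pre-shock context (`preS`),
post-shock context (`postS`), a 150-min consolidation recording with a
wake/NREM/REM hypnogram, and retrieval (`test`).

ABNs fire at ~1 calcium transient per minute, and each transient is
polyphasic — a burst of unitary events. The package answers, with statistics
built for exactly this sparsity and burstiness:

* **Who responds?** Per-neuron activity changes between sessions, tested by a
  moving block bootstrap whose block length is estimated from the circular
  autocorrelation of population activity (burst aggregation decays within
  ~10 s), with Bonferroni-corrected percentile intervals.
* **Same population or a different one?** Per-period population activity
  vectors (per-mouse 95th-percentile truncation, 0–1 rescaling), their cosine
  similarity matrix cos(A,B) = A·B / (‖A‖‖B‖), and Ward clustering on the
  angular distance 1 − cos, with significant merges calibrated against a
  10,000-replicate permutation reference distribution of linkages.
* **Does activity remap during consolidation?** The remapping index of each
  15-min bin vector B_t between the first (A) and last (C) bin vectors,

      RI(t) = [AD(C,B_t) − AD(A,B_t)] / [AD(A,B_t) + AD(C,B_t)],  AD = 1 − cos,

  so RI = +1 at a perfect match to the first bin, −1 to the last, 0 when
  equidistant; its linear trend over time, overall and restricted to sleep or
  wake via the hypnogram; per-neuron remapping classification (Pearson r vs
  time, BH-FDR q < 0.05); and group activity profiles of
  decreasing/increasing/non-remapping neurons across learning, consolidation
  and test.

A synthetic-experiment generator (`generate_experiment`,
`generate_null_experiment`) emulates the statistical structure of such
recordings — compound-Poisson bursts, context-responsive and shock-suppressed
subpopulations, cross-fading remapping groups, a bout-structured hypnogram —
so the whole pipeline is developed and tested without any recording data.

## Worked example

The `analysis/` directory holds the numbered drivers of the full workflow;
each reads the tables written by its predecessors through the package's own
readers and writes its results under `results/`:

```sh
Rscript analysis/01_simulate.R              # synthetic experiment -> event/hypnogram tables
Rscript analysis/02_event_statistics.R      # acf, block length, responsiveness, active sets
Rscript analysis/03_population_similarity.R # activity vectors, similarity, clusters
Rscript analysis/04_remapping.R             # RI traces, classification, group profiles
```

On the default configuration (seed 1, 4 mice × 24 neurons) this prints,
among other things:

```
acf decay tau = 3.37 s -> block length 11 s
preC -> preS: 30% increase, 0% decrease, 70% no change
preS -> postS: 1% increase, 19% decrease, 80% no change
significant clusters (family-wise alpha 0.05):
  {preC, preS, postS}
all  : r = -0.989, p = 3.5e-06, slope = -0.0058 / min (10 bins)
sleep: r = -0.965, p = 0.0001, slope = -0.0039 / min (10 bins)
wake : r = -0.913, p = 0.0015, slope = -0.0047 / min (10 bins)
remapping classification: decreasing=7, increasing=4, non_remapping=85
```

Reading: the event trains are temporally aggregated on a ~10 s scale, which
sets the bootstrap block; roughly the planted 28% of neurons raise their
activity on context exposure and roughly the planted 10% drop after the
shock; the home-cage and context sessions share one significant population
cluster from which the test session is excluded (retrieval recruits a
different population); and the population vector drifts monotonically from
the start toward the end of consolidation (r ≈ −0.99), whether the animal is
asleep or awake. `results/run_report.json` aggregates every statistic with
the seeds, thresholds, block length and sign convention used.

## Layout

```
R/                  package code: event trains & autocorrelation, bootstrap
                    machinery, responsiveness, population similarity,
                    remapping, synthetic generator, IO and pipeline
analysis/           numbered workflow drivers (simulate -> statistics ->
                    similarity -> remapping)
scripts/acceptance.R
tests/testthat/     unit, property and acceptance suites
vignettes/          methods vignette: models, parameters, design decisions
```
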
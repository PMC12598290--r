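---
title: "Data balancing and QC arithmetic for multiplexed WGS: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Data balancing and QC arithmetic for multiplexed WGS: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqbalance)
```

# The problem

High-throughput flow cells are shared by many indexed libraries, and each
library's share of the run is proportional to its effective molar
concentration in the pool. Automated library prep leaves those
concentrations heterogeneous, so an equal-volume 96-plex pool routinely
shows per-sample read totals spreading more than two-fold. The samples at
the bottom of the spread miss their coverage target and force additional
sequencing. Because cohort projects sequence each pool over several flow
cells anyway, the first flow cell can double as a measurement: its
demultiplexed index ratios estimate every library's relative
concentration, and the remaining flow cells can be loaded from a re-pooled
mix whose volumes compensate the measured imbalance. That is
initial-run-based data equalization (iDeal), the centerpiece of this
package; the same index-ratio idea applied on a small sacrificial run of a
low-throughput sequencer (with previously sequenced libraries as anchors)
is its single-flow-cell ancestor.

# The model behind `ideal()`

Let $t_i$ be sample $i$'s reads after the initial equal-volume run(s),
$n$ the number of active samples, and $K$ flow cells of $R$ reads remain.

* **Concentration estimation.** With pooled volume $w_i$, the per-volume
  read rate $t_i / w_i$ is proportional to the library's effective
  concentration. `relative_concentration()` normalizes these rates to
  mean 1, giving $c_i$. Zero-read samples are failed libraries: they are
  excluded from the normalization, marked `failed-library`, and left for a
  fresh pool rather than forced into the plan.
* **Equal final target.** $T = (\sum_i t_i + K R)/n$ is the only final
  total compatible with "every sample equal" under read conservation. The
  deficit is $d_i = \max(T - t_i, 0)$; samples with $d_i = 0$ already meet
  the target, are excluded (`deficit-met`) and receive volume 0. This
  clamped equal-total rule is the minimal-assumption formalization of
  "as even a read distribution as possible".
* **Volumes.** A sample's expected catch per µL is proportional to $c_i$,
  so the raw volume is $u_i = d_i / c_i$. Absolute pipetting scale is
  arbitrary (the loading concentration is set downstream), so volumes are
  normalized to put the largest at `vmax` (default 30 µL); anything that
  lands below `vmin` (default 1 µL) is raised to `vmin` and flagged
  `below_pipettable`, since volumes below ~1 µL are not reliably
  pipettable. Both bounds are configurable.
* **Prediction.** Under the noiseless multinomial model the remaining runs
  deliver $K R \, c_i v_i / \sum_j c_j v_j$ to sample $i$, and when
  neither clamp triggers every expected final equals $T$ exactly — the
  closed-loop identity the test suite asserts. `fitted()`, `predict()`,
  `residuals()` and `simulate()` expose this model; `summary()` reports
  the spread before and after.

Two scheduling variants are covered by the same interface: one initial +
two balanced flow cells (the patterned-flow-cell configuration), and
pooled multi-flow-cell initial rounds (e.g. three initial + three balanced
on nanoball platforms) by passing a list of initial runs, which are summed
before estimating $c_i$.

**Open choice — equal totals vs equal coverage.** When read lengths differ
between the initial and remaining runs, equal read totals and equal
coverage diverge. The package targets equal totals; callers can fold a
read-length weight into `reads_per_run` if equal bases are wanted.

# Spread metrics

Evenness is summarized three ways on cumulative totals: the max/min ratio
(the "exceeds two-fold" headline of unbalanced pools), the maximum
relative deviation from the mean in percent (the "under 10%" claim for
balanced output — this is the package's reading of that figure), and the
population CV. `spread_metrics()` reports all three.

# The simulator

`run_ideal_experiment()` is the study condition generator for everything
stochastic:

* **Concentration heterogeneity**: lognormal, $\sigma = 0.2$, normalized
  to mean 1. The production distribution of library concentrations is not
  published; $\sigma = 0.2$ is this package's calibration, chosen because
  it puts a 96-plex equal-volume run in the observed regime (max/min
  ratio above 2 in the large majority of seeds) without being extreme.
* **Run noise**: each run multiplies every sample's effective loading by
  an independent lognormal factor with mean 1 and CV 3% (default) —
  pooling pipetting error plus clustering bias — before a multinomial
  draw allocates exactly `reads_per_flowcell` reads. Read conservation is
  exact by construction.
* **Scale**: 10⁷ reads per flow cell rather than the ~10⁹ of a production
  flow cell. All balancing arithmetic is scale-invariant (the test suite
  asserts this), and at 10⁷ the multinomial noise per sample (~0.3%) is
  already far below the 3% run noise, so desk-scale results carry over.
* **Determinism**: one seed drives the entire experiment; identical seeds
  give byte-identical outputs.

What the simulator does *not* emulate: index hopping, adapter cross-talk,
lane effects, duplication, quality degradation, or correlated (batch)
concentration errors. Passing tests therefore demonstrate the balancing
arithmetic and its noise robustness, not immunity to those effects; in
particular a systematic error in concentration estimation (e.g. index
bias) would propagate to all balanced runs and is visible in the simulator
only through the run-noise term on the initial run.

A consequence worth noting: adding a *full-size* balanced flow cell can
slightly worsen the relative spread, because the estimation error from the
single initial run scales with the rebalanced share, while splitting a
*fixed* balanced yield across more flow cells always helps (per-run noise
averages out). The test suite asserts the second, true property.

# Planning arithmetic

Cycle budgets: a kit's usable cycles minus index cycles, split evenly
between the two mates — `floor((actual − idx1 − idx2)/2)`. Yields are
decimal (1 Gb = 10⁹ bp) and instrument-style labels round to the nearest
integer Gb, which reproduces the familiar 90/97/155 Gb flow-cell labels
simultaneously. Coverage uses a 3.0 Gb genome by default (the value that
makes ~90 Gb ≈ 30×), configurable. One deliberately non-derived number:
the 259 bp paired-end protocol exceeds 2 × 259 = 518 > 500 nominal cycles,
so that kit's usable cycle count is a configuration value, not computed.
The HiSeq rapid-run figure of 3×10⁸ reads per flow cell is interpreted as
clusters (read pairs), since 90 Gb at 150 bp paired-end requires
3×10⁸ × 300 bp.

# Library QC defaults

| Parameter | Default | Unit | Why |
|---|---|---|---|
| RNA/DNA ladder offset | 30 | nt | denatured ssDNA runs ~30 nt faster than the RNA ladder |
| adapter total | 140 | bp | standard paired Y-adapter footprint |
| dsDNA molar mass | 660 | g/mol/bp | textbook constant |
| freemix threshold | 0.03 | fraction | inclusive (≥); stricter than the 5% used elsewhere |
| max duplication | 0.20 | fraction | package choice; guidance is only "reasonably low" |
| max base skew | 0.02 | fraction | package choice; |A−T| and |G−C| gaps |

The duplication and base-skew cutoffs are explicitly artifact choices —
published practice is qualitative — and both are arguments, not constants.
Sizing chain sanity: a 616 nt reading → 646 bp library → 506 bp insert,
consistent with a 550 bp-insert protocol after shearing variance. Apparent
sizes above ~1000 bp on native dsDNA electrophoresis are the Y-adapter
migration artifact; size PCR-free libraries denatured.

# Coverage accessibility

`aggregate_mean_coverage()` averages per-bin depth across samples
(tracks must share contig, binning and extent; depth is computed upstream
with a MAPQ ≥ 20 floor, recorded as provenance). A bin is *low* when its
cohort mean falls below `rel_threshold` (default 0.25) of the profile's
global mean; runs of at least `min_region_bins` (default 2) low bins
become inaccessible regions, the complement accessible. There is no
field-standard numeric definition of "inaccessible" — such calls are
usually made visually on browser tracks — so both knobs are package
choices and no particular region count is promised on real data. `protocol_diff()` returns intervals
accessible under one protocol but not another (the longer-read-length
payoff). Coordinates are 0-based half-open throughout; BED output matches.

# Pedigree enumeration

A trio is counted per child with both parents present in the dataset —
which uniformly covers parents+child and grandparents+parent trios. A
hepta-family is a child whose parents and all four grandparents are
present (7 distinct members); each such child anchors one family, so full
siblings yield one each, and every hepta-family contains exactly its three
trios. Duos default to the mother-reference reading (present mother,
absent father) and are disjoint from trios; both choices are arguments
because the published "pairs" definition is underspecified. Pedigrees are
validated acyclic by founder peeling.

# Problem sizes and numerical notes

The shipped tests run 96-sample experiments at 10⁷ reads per flow cell,
Monte-Carlo properties over 25–100 seeds at 24–48 samples, and pedigree
oracles on ≤30-individual graphs — sizes chosen so the whole suite
completes in well under a minute while keeping multinomial noise an order
of magnitude below the effects being tested. Exact identities (closed-loop
equality, mass conservation, plant-and-recover) are asserted to at worst
1e-9 relative tolerance; everything else is a property over seeded draws.
Degenerate inputs fail loudly: zero-concentration pools, all-zero runs,
zero global mean profiles, cyclic pedigrees and sub-minimum pool sizes are
errors, not warnings.
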
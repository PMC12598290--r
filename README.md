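# seqbalance

Quality-control arithmetic and data balancing for large-scale multiplexed
short-read whole-genome sequencing.

When 96 libraries share a flow cell, each sample's data volume is set by its
relative library concentration — and library prep leaves those
concentrations uneven enough that per-sample read totals in an equal-volume
pool commonly spread more than two-fold. Samples at the bottom of that
spread end up under-covered and need costly top-up runs. `seqbalance`
implements the production fix used by high-throughput genome-cohort
facilities, **initial-run-based data equalization (iDeal)**:

1. Sequence the equal-volume pool on one flow cell. Each sample's share of
   demultiplexed reads (its *index ratio*) estimates its relative
   concentration *c*ᵢ (normalized to mean 1).
2. Re-pool with per-sample volumes *v*ᵢ ∝ *d*ᵢ / *c*ᵢ, where
   *d*ᵢ = max(*T* − *t*ᵢ, 0) is the sample's deficit against the equal
   final target *T* = (Σ*t*ᵢ + *K·R*)/*n* for *K* remaining flow cells of
   *R* reads, and *t*ᵢ the initial-run totals.
3. Sequence the remaining flow cells with the adjusted pool. In the
   noiseless multinomial model the cumulative totals
   *t*ᵢ + *K·R·c*ᵢ*v*ᵢ/Σ*c*ⱼ*v*ⱼ all equal *T* exactly; in practice the
   final spread drops from >2-fold to a few percent.

Around that core the package provides the rest of the facility's desk
arithmetic: cycle-budget planning (a 300-cycle kit holding 325 usable
cycles supports 162 bp paired-end when run without index reads; 338 cycles
with dual 8 bp indexes supports 161 bp), flow-cell yield and coverage
(3×10⁸ read pairs × 2 × 150 bp ≈ 90 Gb ≈ 30× on a 3.0 Gb genome),
pooled-library quantification against a previously sequenced reference
pool, PCR-free library sizing against RNA ladders (observed 616 nt + 30 nt
ladder offset = 646 bp library; minus ~140 bp adapters ≈ 506 bp insert),
dsDNA molarity, contamination (freemix ≥ 3%) and duplication/base-balance
filters, cohort mean-coverage aggregation with accessible/inaccessible
region classification, pedigree pair/trio/hepta-family enumeration from
PED files, and a fully seeded simulator.

## Worked example

Two samples pooled equally produce 100 and 300 reads in the initial run,
and one more flow cell of 400 reads remains:

```r
library(seqbalance)
dc  <- demux_counts(c("A", "B"), c(100, 300))
fit <- ideal(dc, runs = 1, reads_per_run = 400, vmin = 0)
summary(fit)
#> Initial-run-based data equalization (iDeal)
#>
#> Call: ideal(counts = dc, runs = 1, reads_per_run = 400, vmin = 0)
#>
#> 2 samples; 2 planned, 0 deficit-met, 0 failed
#> Target 400 reads/sample over 1 remaining run(s) of 400 reads
#>
#> Initial run   : Spread over 2 samples: max/min 3.000, max deviation 50.00%, CV 50.00%
#> Expected final: Spread over 2 samples: max/min 1.000, max deviation 0.00%, CV 0.00%
#> Re-pool volumes: 3.333-30.000 uL (0 raised to vmin)
```

Sample A (estimated concentration 0.5, deficit 300) gets the maximum 30 µL;
sample B (concentration 1.5, deficit 100) gets 3.333 µL, so A captures 3/4
of the remaining 400 reads and both samples finish at the 400-read target.
`coef()`, `fitted()`, `residuals()`, `predict()`, `simulate()` and
`plot()` expose the fit; `write_rebalance_plan()` emits the bench TSV.

At production scale, a simulated 96-plex on three flow cells:

```r
ex <- run_ideal_experiment(seed = 42)
ex
#> Simulated iDeal experiment: 96 samples, 1 initial + 2 balanced runs
#> Initial: Spread over 96 samples: max/min 2.885, max deviation 52.95%, CV 19.69%
#> Final  : Spread over 96 samples: max/min 1.107, max deviation 5.67%, CV 2.39%
```

The initial equal-volume run spreads more than two-fold; after
rebalancing, every sample's cumulative total sits within ~6% of the mean.

A thin command-line wrapper ships at
`system.file("cli", "seqbalance.R", package = "seqbalance")` with
subcommands `plan`, `size`, `qcfilter`, `quantify`, `rebalance`,
`pedigree` and `simulate`.

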
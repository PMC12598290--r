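test_that("index ratios become mean-1 relative concentrations", {
  dc <- demux_counts(paste0("S", 1:4), c(80, 120, 100, 100))
  expect_equal(as.numeric(relative_concentration(dc)),
               c(0.8, 1.2, 1.0, 1.0))
  dc2 <- demux_counts(c("A", "B"), c(100, 300))
  expect_equal(as.numeric(relative_concentration(dc2)), c(0.5, 1.5))
  eq <- demux_counts(paste0("S", 1:5), rep(250, 5))
  expect_equal(as.numeric(relative_concentration(eq)), rep(1, 5))
  # unequal pooling volumes enter through the per-volume rate
  dv <- demux_counts(c("A", "B"), c(100, 300), volume = c(1, 3))
  expect_equal(as.numeric(relative_concentration(dv)), c(1, 1))
})

test_that("zero-read samples are flagged failed and dropped from the mean", {
  dc <- demux_counts(c("A", "B", "C"), c(0, 100, 300))
  conc <- relative_concentration(dc)
  expect_identical(attr(conc, "failed"), "A")
  expect_true(is.na(conc[["A"]]))
  expect_equal(mean(conc, na.rm = TRUE), 1)
  expect_equal(as.numeric(conc[c("B", "C")]), c(0.5, 1.5))
})

test_that("demux container enforces its invariants", {
  expect_error(demux_counts("A", 1), "two samples")
  expect_error(demux_counts(c("A", "A"), c(1, 2)), "unique")
  expect_error(demux_counts(c("A", "B"), c(-1, 2)), "non-negative")
  expect_error(demux_counts(c("A", "B"), c(1, 2), volume = 0), "positive")
  dc <- demux_counts(c("A", "B"), c(1, 2))
  expect_equal(attr(dc, "total_reads"), 3)
})

test_that("cumulative totals sum over runs with union of samples", {
  r1 <- demux_counts(c("A", "B"), c(300, 100), run_id = "r1")
  r2 <- demux_counts(c("A", "B"), c(100, 300), run_id = "r2")
  expect_equal(cumulative_totals(list(r1, r2)), c(A = 400, B = 400))
  expect_equal(cumulative_totals(list(r1)), c(A = 300, B = 100))
  # union with a sample missing from one run, against elementwise sum
  r3 <- demux_counts(c("B", "C"), c(10, 20), run_id = "r3")
  expect_equal(cumulative_totals(list(r1, r3)), c(A = 300, B = 110, C = 20))
  set.seed(3)
  runs <- lapply(1:3, function(i)
    demux_counts(paste0("S", 1:6), rpois(6, 100), run_id = paste0("x", i)))
  manual <- Reduce(`+`, lapply(runs, function(r)
    stats::setNames(r$reads, r$sample_id)))
  expect_equal(cumulative_totals(runs), manual)
})

test_that("spread metrics quantify evenness as documented", {
  m <- spread_metrics(c(100, 200))
  expect_equal(m$maxmin_ratio, 2)
  expect_equal(m$max_rel_dev, 100 * 50 / 150)
  expect_equal(m$cv, 100 * 50 / 150)
  m2 <- spread_metrics(c(90, 100, 110))
  expect_equal(m2$maxmin_ratio, 11 / 9)
  expect_equal(m2$max_rel_dev, 10)
  m3 <- spread_metrics(rep(42, 8))
  expect_equal(m3$maxmin_ratio, 1)
  expect_equal(m3$max_rel_dev, 0)
  expect_equal(m3$cv, 0)
  expect_error(spread_metrics(c(0, 1)), "positive")
  expect_error(spread_metrics(5), "2")
})

test_that("the two-sample worked rebalance is exact", {
  dc <- demux_counts(c("A", "B"), c(100, 300))
  fit <- ideal(dc, runs = 1, reads_per_run = 400, vmax = 30, vmin = 0)
  expect_equal(fit$target, 400)
  expect_equal(fit$plan$volume, c(30, 10 / 3), tolerance = 1e-12)
  expect_equal(fitted(fit), c(A = 400, B = 400))
  expect_equal(unname(residuals(fit)), c(0, 0))
})

test_that("samples at or above the equal target are excluded deficit-met", {
  dc <- demux_counts(paste0("S", 1:4), c(900, 100, 100, 100))
  fit <- ideal(dc, runs = 1, reads_per_run = 400, vmin = 0)
  p <- fit$plan
  expect_equal(fit$target, 400)
  expect_true(p$excluded[1L])
  expect_identical(p$reason[1L], "deficit-met")
  expect_equal(p$volume[1L], 0)
  # remaining samples share the run equally (equal deficits, equal conc)
  expect_equal(p$volume[-1L], rep(30, 3))
  expect_equal(p$expected_final_reads[-1L], rep(100 + 400 / 3, 3))
})

test_that("symmetric input gives the symmetric plan at vmax", {
  dc <- demux_counts(paste0("S", 1:6), rep(1000, 6))
  fit <- ideal(dc, runs = 2, reads_per_run = 6000)
  expect_equal(fit$plan$volume, rep(30, 6))
  expect_equal(unname(fitted(fit)), rep(fit$target, 6))
})

test_that("plans are invariant to rescaling round-1 reads", {
  set.seed(21)
  reads <- rpois(12, 500) + 1
  f1 <- ideal(demux_counts(paste0("S", 1:12), reads),
              runs = 2, reads_per_run = sum(reads))
  f2 <- ideal(demux_counts(paste0("S", 1:12), reads * 37),
              runs = 2, reads_per_run = 37 * sum(reads))
  expect_equal(f1$plan$volume, f2$plan$volume, tolerance = 1e-10)
  expect_equal(f2$target, 37 * f1$target)
})

test_that("re-pool volume decreases strictly with round-1 reads", {
  set.seed(8)
  reads <- sort(sample(100:900, 10))
  fit <- ideal(demux_counts(paste0("S", 1:10), reads),
               runs = 2, reads_per_run = 5000, vmin = 0)
  vol <- fit$plan$volume[!fit$plan$excluded]
  expect_true(all(diff(vol) < 0))
})

test_that("noiseless closed loop equalizes final totals exactly", {
  conc <- c(0.6, 0.8, 1.0, 1.2, 1.4)
  r <- 1e6
  round1 <- simulate_run(conc, 10, r, noise_cv = 0, expectation = TRUE,
                         run_id = "init")
  fit <- ideal(round1, runs = 2, reads_per_run = r, vmin = 0)
  rounds <- lapply(1:2, function(k)
    simulate_run(conc, fit$plan$volume, r, noise_cv = 0,
                 expectation = TRUE))
  tot <- cumulative_totals(c(list(round1), rounds))
  expect_equal(spread_metrics(tot)$max_rel_dev, 0, tolerance = 1e-9)
  expect_equal(unname(tot), rep(fit$target, 5), tolerance = 1e-6)
})

test_that("excluded and planned samples partition and respect bounds", {
  set.seed(14)
  for (i in 1:10) {
    n <- sample(5:30, 1)
    reads <- rpois(n, 300) * sample(c(1, 1, 1, 0), n, replace = TRUE,
                                    prob = c(0.9, 0.05, 0.04, 0.01))
    if (sum(reads > 0) < 2) next
    fit <- ideal(demux_counts(paste0("S", 1:n), reads),
                 runs = 2, reads_per_run = 2 * sum(reads))
    p <- fit$plan
    expect_identical(p$excluded, !is.na(p$reason))
    expect_true(all(p$volume[p$excluded] == 0))
    expect_true(all(p$volume[!p$excluded] >= fit$vmin - 1e-12))
    expect_true(all(p$volume <= fit$vmax + 1e-12))
    expect_true(all(p$reason[reads == 0] == "failed-library"))
  }
})

test_that("volumes under the pipettable floor are raised and flagged", {
  # extreme concentration spread forces a tiny raw volume for S2
  dc <- demux_counts(c("S1", "S2", "S3"), c(10, 10000, 20))
  fit <- ideal(dc, runs = 1, reads_per_run = 50000, vmax = 30, vmin = 1)
  p <- fit$plan
  expect_true(p$below_pipettable[2L])
  expect_equal(p$volume[2L], 1)
})

test_that("demux tables round-trip through TSV and stats-CSV readers", {
  path <- system.file("extdata", "demux_example.tsv",
                      package = "seqbalance")
  dc <- read_demux_tsv(path)
  expect_equal(dc$reads, c(100, 300))
  tmp <- tempfile(fileext = ".csv")
  writeLines(c("SampleID,# Reads", "A,\"1,000\"", "B,3000",
               "Undetermined,99"), tmp)
  dc2 <- read_demux_stats_csv(tmp)
  expect_equal(dc2$sample_id, c("A", "B"))
  expect_equal(dc2$reads, c(1000, 3000))
  expect_error(read_demux_stats_csv(tmp, sample_col = "Nope"), "not found")
})

test_that("rebalance plans round-trip through the TSV writer", {
  dc <- demux_counts(c("A", "B"), c(100, 300))
  fit <- ideal(dc, runs = 1, reads_per_run = 400, vmin = 0)
  tmp <- tempfile(fileext = ".tsv")
  write_rebalance_plan(fit, tmp)
  expect_true(startsWith(readLines(tmp, n = 1L), "#"))
  back <- read_rebalance_plan(tmp)
  expect_equal(back$volume_uL, round(fit$plan$volume, 4))
  expect_identical(back$excluded, fit$plan$excluded)
})
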
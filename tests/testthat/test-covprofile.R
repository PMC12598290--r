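test_that("aggregation averages per bin and is permutation-invariant", {
  t1 <- depth_track("S1", "chrT", 1000, c(10, 20, 30))
  t2 <- depth_track("S2", "chrT", 1000, c(30, 20, 10))
  prof <- aggregate_mean_coverage(list(t1, t2))
  expect_equal(prof$mean_depth, c(20, 20, 20))
  expect_equal(prof$global_mean, 20)
  expect_equal(prof$n_samples, 2L)
  # single track aggregates to itself
  expect_equal(aggregate_mean_coverage(list(t1))$mean_depth, t1$depths)
  # permutation and duplication invariance
  prof_rev <- aggregate_mean_coverage(list(t2, t1))
  expect_equal(prof_rev$mean_depth, prof$mean_depth)
  dup <- aggregate_mean_coverage(list(t1, t2, t1, t2))
  expect_equal(dup$mean_depth, prof$mean_depth)
  # incompatible binning is refused
  t3 <- depth_track("S3", "chrT", 500, c(1, 2, 3))
  expect_error(aggregate_mean_coverage(list(t1, t3)), "incompatible")
})

test_that("cohort mean depth concentrates on the truth", {
  tracks <- simulate_depth_tracks(n_samples = 400, n_bins = 50,
                                  mean_depth = 30, depth_noise_cv = 0.2,
                                  seed = 10)
  prof <- aggregate_mean_coverage(tracks)
  # per-bin sd of the mean is 30*0.2/sqrt(400) = 0.3; allow 4 sd
  expect_true(all(abs(prof$mean_depth - 30) < 4 * 0.3))
})

test_that("planted dropouts are recovered exactly as inaccessible regions", {
  planted <- data.frame(start_bin = c(11, 41), end_bin = c(20, 44),
                        factor = c(0, 0.1))
  tracks <- simulate_depth_tracks(n_samples = 3, n_bins = 100,
                                  mean_depth = 30,
                                  planted_regions = planted,
                                  depth_noise_cv = 0, seed = 1)
  prof <- aggregate_mean_coverage(tracks)
  regions <- classify_accessibility(prof, rel_threshold = 0.25,
                                    min_region_bins = 2)
  inac <- regions[regions$label == "inaccessible", ]
  expect_equal(inac$start, c(10, 40) * 1000)
  expect_equal(inac$end, c(20, 44) * 1000)
  # accessible complement tiles the rest of the contig
  expect_equal(sum(regions$end - regions$start), 100 * 1000)
  expect_true(all(regions$start[-1L] == regions$end[-nrow(regions)]))
})

test_that("short low runs are filtered and the call is idempotent", {
  prof <- flat_profile(100)
  prof$mean_depth[50] <- 0  # single isolated low bin
  prof$global_mean <- mean(prof$mean_depth)
  r <- classify_accessibility(prof, 0.25, min_region_bins = 2)
  expect_identical(nrow(r[r$label == "inaccessible", ]), 0L)
  # flat profile: nothing inaccessible
  r0 <- classify_accessibility(flat_profile(50))
  expect_identical(nrow(r0[r0$label == "inaccessible", ]), 0L)
  expect_identical(classify_accessibility(flat_profile(50)), r0)
})

test_that("lowering the threshold never grows the inaccessible set", {
  set.seed(33)
  tracks <- simulate_depth_tracks(10, 200, 30,
                                  planted_regions = data.frame(
                                    start_bin = c(21, 101),
                                    end_bin = c(30, 120),
                                    factor = c(0.05, 0.3)),
                                  depth_noise_cv = 0.15, seed = 33)
  prof <- aggregate_mean_coverage(tracks)
  inac_bins <- function(thr) {
    r <- classify_accessibility(prof, thr, min_region_bins = 1)
    sum(r$end[r$label == "inaccessible"] -
          r$start[r$label == "inaccessible"])
  }
  widths <- vapply(c(0.5, 0.4, 0.3, 0.2, 0.1), inac_bins, numeric(1))
  expect_true(all(diff(widths) <= 0))
})

test_that("protocol differences isolate the planted extra gap", {
  gap_b <- data.frame(start_bin = 61, end_bin = 70, factor = 0)
  shared <- data.frame(start_bin = 11, end_bin = 20, factor = 0)
  ta <- simulate_depth_tracks(2, 100, 30, planted_regions = shared,
                              depth_noise_cv = 0, seed = 1)
  tb <- simulate_depth_tracks(2, 100, 30,
                              planted_regions = rbind(shared, gap_b),
                              depth_noise_cv = 0, seed = 1)
  pa <- aggregate_mean_coverage(ta)
  pb <- aggregate_mean_coverage(tb)
  d <- protocol_diff(pa, pb)
  expect_equal(nrow(d), 1L)
  expect_equal(d$start, 60 * 1000)
  expect_equal(d$end, 70 * 1000)
  # identical profiles differ nowhere; the two directions are disjoint
  expect_identical(nrow(protocol_diff(pa, pa)), 0L)
  d_rev <- protocol_diff(pb, pa)
  expect_true(nrow(d_rev) == 0L ||
                all(d_rev$end <= d$start | d_rev$start >= d$end))
})

test_that("depth tracks and profiles round-trip through bedGraph", {
  tr <- depth_track("S1", "chr22", 500, c(5, 10, 0, 7.5))
  tmp <- tempfile(fileext = ".bedGraph")
  write_bedgraph(tr, tmp)
  back <- read_bedgraph_track(tmp, sample_id = "S1")
  expect_equal(back$depths, tr$depths)
  expect_equal(back$bin_size, tr$bin_size)
  expect_identical(back$contig, "chr22")
  # region sets write as 4-column BED with half-open coordinates
  prof <- aggregate_mean_coverage(list(tr, tr))
  bed <- tempfile(fileext = ".bed")
  regions <- classify_accessibility(prof, 0.25, min_region_bins = 1)
  write_bed(regions, bed, label = "inaccessible")
  got <- utils::read.table(bed, sep = "\t")
  expect_equal(got$V2, 1000)
  expect_equal(got$V3, 1500)
})

test_that("degenerate profiles are refused", {
  z <- aggregate_mean_coverage(list(depth_track("S", "c", 100, c(0, 0))))
  expect_error(classify_accessibility(z), "degenerate")
  expect_error(depth_track("S", "c", 100, c(-1, 2)), "non-negative")
})
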
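#' Simulate relative library concentrations
#'
#' Library preparation leaves per-sample concentrations heterogeneous even
#' under automation; a lognormal with sigma around 0.2 reproduces the
#' commonly observed >2-fold max/min spread across a 96-plex initial run.
#' Draws are normalized to mean 1.
#'
#' @param n_samples Number of libraries (default 96).
#' @param conc_sigma Lognormal sigma on the log scale (default 0.2);
#'   0 gives all-equal concentrations.
#' @param seed Optional RNG seed.
#' @return Numeric vector of length `n_samples`, mean exactly 1.
#' @export
simulate_concentrations <- function(n_samples = 96, conc_sigma = 0.2,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (conc_sigma < 0) stop("conc_sigma must be >= 0", call. = FALSE)
  x <- if (conc_sigma == 0) rep(1, n_samples)
       else stats::rlnorm(n_samples, meanlog = 0, sdlog = conc_sigma)
  x / mean(x)
}

# lognormal multiplier with mean 1 and coefficient of variation cv
rlnorm_mean1 <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate one multiplexed sequencing run
#'
#' Each sample's probability of capturing a read is proportional to
#' `concentration * volume * eps`, with `eps` a per-sample multiplicative
#' lognormal noise of mean 1 and coefficient of variation `noise_cv`
#' (run-to-run pooling and clustering noise). Reads are then drawn
#' multinomially so the run total is exact.
#'
#' @param concentration True (or estimated) relative concentrations.
#' @param volumes Pooled volume per sample, uL; zero-volume samples get
#'   zero reads.
#' @param total_reads Reads delivered by the run.
#' @param noise_cv Multiplicative noise CV (default 0.03).
#' @param run_id Run identifier.
#' @param seed Optional RNG seed.
#' @param expectation If `TRUE`, return the noiseless expected (real-valued)
#'   counts `p * total_reads` instead of a multinomial draw.
#' @param sample_id Sample names; defaults to S001, S002, ...
#' @return A [demux_counts()] object (volumes replaced by 1 for zero-volume
#'   entries to satisfy the container; their reads are 0).
#' @export
simulate_run <- function(concentration, volumes, total_reads,
                         noise_cv = 0.03, run_id = "simrun", seed = NULL,
                         expectation = FALSE,
                         sample_id = sprintf("S%03d", seq_along(concentration))) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(concentration)
  volumes <- rep_len(volumes, n)
  if (total_reads <= 0) stop("total_reads must be positive", call. = FALSE)
  if (any(volumes < 0) || any(concentration < 0))
    stop("volumes and concentrations must be non-negative", call. = FALSE)
  w <- concentration * volumes
  if (all(w == 0)) stop("all effective loadings are zero", call. = FALSE)
  if (!expectation) w <- w * rlnorm_mean1(n, noise_cv)
  p <- w / sum(w)
  reads <- if (expectation) p * total_reads
           else as.numeric(stats::rmultinom(1, size = total_reads, prob = p))
  demux_counts(sample_id, reads, volume = ifelse(volumes > 0, volumes, 1),
               run_id = run_id)
}

#' Run a full simulated iDeal experiment
#'
#' End-to-end: true concentrations are drawn, `initial_runs` equal-volume
#' flow cells are sequenced, relative concentrations are estimated from the
#' summed initial counts, [ideal()] fits the re-pooling plan, and the
#' remaining `balanced_runs` flow cells are sequenced with the adjusted
#' volumes. Defaults reproduce the 96-plex, three-flow-cell design (one
#' initial + two rebalanced) with reads scaled to 1e7 per flow cell so the
#' experiment runs at desk speed; the balancing arithmetic is
#' scale-invariant in the per-run read count.
#'
#' @param n_samples Libraries in the pool (default 96).
#' @param conc_sigma Lognormal sigma of true concentrations (default 0.2).
#' @param run_noise_cv Per-run multiplicative noise CV (default 0.03).
#' @param reads_per_flowcell Reads per flow cell (default 1e7).
#' @param initial_runs Equal-volume initial flow cells (default 1).
#' @param balanced_runs Re-pooled flow cells (default 2).
#' @param vmax,vmin Pipetting bounds passed to [ideal()].
#' @param equal_volume Volume used in the initial pool, uL (default 10).
#' @param seed RNG seed; fixing it makes the whole experiment reproducible.
#' @param noiseless If `TRUE`, use expected (real-valued) reads with zero
#'   noise throughout; the final spread is then exactly zero.
#' @return Object of class `"ideal_experiment"`: list with `rounds` (per-run
#'   [demux_counts()]), `fit` (the `"ideal"` object), `true_concentration`,
#'   `initial_spread` and `final_spread` ([spread_metrics()]), and
#'   `final_totals`.
#' @examples
#' ex <- run_ideal_experiment(n_samples = 8, reads_per_flowcell = 1e5,
#'                            seed = 1)
#' ex$initial_spread$maxmin_ratio
#' ex$final_spread$max_rel_dev
#' @export
run_ideal_experiment <- function(n_samples = 96, conc_sigma = 0.2,
                                 run_noise_cv = 0.03,
                                 reads_per_flowcell = 1e7,
                                 initial_runs = 1, balanced_runs = 2,
                                 vmax = 30, vmin = 1, equal_volume = 10,
                                 seed = NULL, noiseless = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  if (noiseless) run_noise_cv <- 0
  conc <- simulate_concentrations(n_samples, conc_sigma)
  ids <- sprintf("S%03d", seq_len(n_samples))

  rounds <- vector("list", initial_runs + balanced_runs)
  for (k in seq_len(initial_runs)) {
    rounds[[k]] <- simulate_run(conc, equal_volume, reads_per_flowcell,
                                noise_cv = run_noise_cv,
                                run_id = sprintf("initial%d", k),
                                expectation = noiseless, sample_id = ids)
  }
  initial_totals <- cumulative_totals(rounds[seq_len(initial_runs)])

  fit <- ideal(pool_initial_runs(rounds[seq_len(initial_runs)]),
               runs = balanced_runs, reads_per_run = reads_per_flowcell,
               vmax = vmax, vmin = vmin)

  vol <- stats::setNames(fit$plan$volume, fit$plan$sample_id)[ids]
  for (k in seq_len(balanced_runs)) {
    rounds[[initial_runs + k]] <- simulate_run(
      conc, vol, reads_per_flowcell, noise_cv = run_noise_cv,
      run_id = sprintf("balanced%d", k), expectation = noiseless,
      sample_id = ids)
  }
  final_totals <- cumulative_totals(rounds)

  structure(
    list(rounds = rounds, fit = fit, true_concentration = conc,
         initial_spread = spread_metrics(initial_totals),
         final_spread = spread_metrics(final_totals),
         final_totals = final_totals,
         config = list(n_samples = n_samples, conc_sigma = conc_sigma,
                       run_noise_cv = run_noise_cv,
                       reads_per_flowcell = reads_per_flowcell,
                       initial_runs = initial_runs,
                       balanced_runs = balanced_runs, seed = seed)),
    class = "ideal_experiment"
  )
}

#' @export
print.ideal_experiment <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Simulated iDeal experiment: %d samples, %d initial + %d balanced runs\n",
    cfg$n_samples, cfg$initial_runs, cfg$balanced_runs))
  cat("Initial: "); print(x$initial_spread)
  cat("Final  : "); print(x$final_spread)
  invisible(x)
}

#' Simulate per-sample binned depth tracks
#'
#' Generates depth tracks at a common binning with multiplicative lognormal
#' noise around `mean_depth`, optionally with planted low-coverage regions
#' (e.g. factor 0 for a dropout, 0.1 for a poorly accessible region) shared
#' by every sample — the test surface for accessibility classification.
#'
#' @param n_samples Number of tracks.
#' @param n_bins Bins per track.
#' @param mean_depth True mean depth (fold).
#' @param planted_regions data.frame with columns `start_bin`, `end_bin`
#'   (1-based, inclusive) and `factor`, or `NULL`; regions must not overlap.
#' @param depth_noise_cv Per-bin lognormal noise CV (0 = deterministic).
#' @param bin_size Bin width in bp (default 1000).
#' @param contig Contig name.
#' @param mapq_floor Mapping-quality floor recorded as provenance
#'   (default 20).
#' @param seed Optional RNG seed.
#' @return List of [depth_track()] objects.
#' @export
simulate_depth_tracks <- function(n_samples, n_bins, mean_depth,
                                  planted_regions = NULL,
                                  depth_noise_cv = 0.1, bin_size = 1000,
                                  contig = "chr22", mapq_floor = 20,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  base <- rep(mean_depth, n_bins)
  if (!is.null(planted_regions) && nrow(planted_regions)) {
    pr <- planted_regions[order(planted_regions$start_bin), , drop = FALSE]
    if (any(pr$start_bin < 1) || any(pr$end_bin > n_bins) ||
        any(pr$start_bin > pr$end_bin))
      stop("planted regions outside track extent", call. = FALSE)
    if (nrow(pr) > 1L && any(pr$start_bin[-1L] <= pr$end_bin[-nrow(pr)]))
      stop("planted regions overlap", call. = FALSE)
    for (i in seq_len(nrow(pr)))
      base[pr$start_bin[i]:pr$end_bin[i]] <-
        mean_depth * pr$factor[i]
  }
  lapply(seq_len(n_samples), function(s) {
    depth_track(sprintf("S%03d", s), contig = contig, bin_size = bin_size,
                depths = base * rlnorm_mean1(n_bins, depth_noise_cv),
                mapq_floor = mapq_floor)
  })
}
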
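#' Relative library concentrations from demultiplexed counts
#'
#' In an equal-volume pool, each sample's share of demultiplexed reads (its
#' index ratio) reflects the relative concentration of its library. More
#' generally the per-volume read rate `reads/volume` is normalized to mean 1
#' across samples. Samples with zero reads are failed libraries: they get
#' `NA` and are excluded from the normalization.
#'
#' @param counts A [demux_counts()] object.
#' @return Named numeric vector of class `"relative_concentration"`, mean 1
#'   over observed samples; attribute `failed` lists zero-read sample ids.
#' @examples
#' dc <- demux_counts(paste0("S", 1:4), c(80, 120, 100, 100))
#' relative_concentration(dc)  # 0.8 1.2 1.0 1.0
#' @export
relative_concentration <- function(counts) {
  stopifnot(inherits(counts, "demux_counts"))
  if (attr(counts, "total_reads") <= 0)
    stop("run has no reads", call. = FALSE)
  rate <- counts$reads / counts$volume
  failed <- counts$sample_id[rate <= 0]
  rate[rate <= 0] <- NA_real_
  conc <- rate / mean(rate, na.rm = TRUE)
  structure(stats::setNames(conc, counts$sample_id),
            failed = failed, class = "relative_concentration")
}

#' @export
print.relative_concentration <- function(x, ...) {
  cat(sprintf("Relative concentrations (%d samples, mean 1)\n", length(x)))
  print(stats::setNames(as.numeric(x), names(x)))
  failed <- attr(x, "failed")
  if (length(failed))
    cat("Failed libraries (zero reads):", paste(failed, collapse = ", "), "\n")
  invisible(x)
}

#' Initial-run-based data equalization (iDeal)
#'
#' Fits a re-pooling plan from the demultiplexed counts of an equal-volume
#' initial run. Relative concentrations are estimated from the index
#' ratios; the plan then assigns each sample a volume for the re-pooled
#' library so that, after `runs` further flow cells of `reads_per_run`
#' reads each, cumulative per-sample totals come out as even as possible.
#'
#' The equal final target is `T = (sum(t) + runs * reads_per_run) / n` over
#' active samples, where `t` are initial-run totals. Each sample's deficit
#' `max(T - t, 0)` is divided by its relative concentration to give a raw
#' volume; volumes are scaled so the largest equals `vmax`, and any volume
#' below `vmin` is raised to `vmin` and flagged as below the pipettable
#' range. Samples already at or above target are excluded (`deficit-met`),
#' and zero-read samples are excluded as `failed-library` for re-runs in a
#' fresh pool. When neither clamp triggers, the expected finals under the
#' noiseless multinomial model are all exactly `T`.
#'
#' @param counts A [demux_counts()] object for the initial equal-volume
#'   run, or a list of them (pooled initial rounds are summed first).
#' @param runs Number of remaining (re-pooled) flow cells, `K >= 1`.
#' @param reads_per_run Reads delivered by each remaining flow cell.
#' @param vmax,vmin Pipetting bounds in uL (defaults 30 and 1).
#' @param concentration Optional externally supplied relative
#'   concentrations (named or in sample order); estimated from `counts`
#'   when `NULL`.
#' @return Object of class `"ideal"`; see [coef.ideal()], [fitted.ideal()],
#'   [predict.ideal()], [residuals.ideal()], [simulate.ideal()],
#'   [plot.ideal()]. The plan itself is the `plan` element, a data.frame
#'   with per-sample `volume`, `excluded`, `reason`, `below_pipettable` and
#'   `expected_final_reads`.
#' @examples
#' dc <- demux_counts(c("A", "B"), c(100, 300))
#' fit <- ideal(dc, runs = 1, reads_per_run = 400, vmin = 0)
#' fit$plan$volume                # 30.000 3.333
#' fitted(fit)                    # both 400
#' @export
ideal <- function(counts, runs = 2, reads_per_run, vmax = 30, vmin = 1,
                  concentration = NULL) {
  cl <- match.call()
  if (is.list(counts) && !inherits(counts, "demux_counts"))
    counts <- pool_initial_runs(counts)
  stopifnot(inherits(counts, "demux_counts"))
  if (runs < 1) stop("runs must be >= 1", call. = FALSE)
  if (reads_per_run <= 0) stop("reads_per_run must be positive", call. = FALSE)
  if (!(vmax > vmin && vmin >= 0))
    stop("need vmax > vmin >= 0", call. = FALSE)

  ids <- counts$sample_id
  t_i <- stats::setNames(counts$reads, ids)
  if (is.null(concentration)) {
    conc <- relative_concentration(counts)
  } else {
    if (!is.null(names(concentration))) {
      if (!all(ids %in% names(concentration)))
        stop("concentration names do not cover all samples", call. = FALSE)
      conc <- as.numeric(concentration[ids])
    } else {
      if (length(concentration) != length(ids))
        stop("concentration length does not match samples", call. = FALSE)
      conc <- as.numeric(concentration)
    }
    conc <- stats::setNames(conc, ids)
    conc[!is.na(conc) & conc <= 0] <- NA_real_
  }
  failed <- is.na(conc) | conc <= 0

  n_active <- sum(!failed)
  if (n_active < 1L) stop("all samples failed; empty plan", call. = FALSE)
  target <- (sum(t_i[!failed]) + runs * reads_per_run) / n_active
  deficit <- pmax(target - t_i, 0)
  deficit[failed] <- 0

  reason <- rep(NA_character_, length(ids))
  reason[failed] <- "failed-library"
  reason[!failed & deficit == 0] <- "deficit-met"
  planned <- is.na(reason)
  if (!any(planned))
    stop("no sample has a remaining deficit; empty plan", call. = FALSE)

  volume <- stats::setNames(numeric(length(ids)), ids)
  raw <- deficit[planned] / conc[planned]
  volume[planned] <- raw * (vmax / max(raw))
  below <- planned & volume < vmin & volume > 0
  volume[below] <- vmin

  expected <- t_i
  wt <- conc[planned] * volume[planned]
  expected[planned] <- t_i[planned] + runs * reads_per_run * wt / sum(wt)

  plan <- data.frame(
    sample_id = ids,
    volume = as.numeric(volume),
    excluded = !planned,
    reason = reason,
    below_pipettable = as.logical(below),
    deficit = as.numeric(deficit),
    expected_final_reads = as.numeric(expected),
    stringsAsFactors = FALSE
  )
  structure(
    list(call = cl, counts = counts, concentration = conc, plan = plan,
         target = target, runs = runs, reads_per_run = reads_per_run,
         vmax = vmax, vmin = vmin,
         initial_spread = spread_metrics(t_i[t_i > 0])),
    class = "ideal"
  )
}

# Sum reads of several equal-volume initial runs over the union of samples.
pool_initial_runs <- function(runs) {
  tot <- cumulative_totals(runs)
  demux_counts(names(tot), tot, volume = runs[[1L]]$volume[1L],
               run_id = paste(vapply(runs, attr, "", "run_id"),
                              collapse = "+"))
}

#' @export
print.ideal <- function(x, ...) {
  cat("Initial-run-based data equalization (iDeal)\n\n")
  cat("Call: "); print(x$call)
  n <- nrow(x$plan)
  cat(sprintf("\n%d samples; %d planned, %d deficit-met, %d failed\n",
              n, sum(!x$plan$excluded),
              sum(x$plan$reason %in% "deficit-met"),
              sum(x$plan$reason %in% "failed-library")))
  cat(sprintf("Target %.0f reads/sample over %d remaining run(s) of %s reads\n",
              x$target, x$runs, format(x$reads_per_run, big.mark = ",")))
  invisible(x)
}

#' Estimated relative concentrations from an iDeal fit
#' @param object An `"ideal"` object.
#' @param ... Unused.
#' @return Named numeric vector, mean 1 over observed samples.
#' @export
coef.ideal <- function(object, ...) {
  stats::setNames(as.numeric(object$concentration),
                  names(object$concentration))
}

#' Expected cumulative per-sample totals under the fitted plan
#' @param object An `"ideal"` object.
#' @param ... Unused.
#' @return Named numeric vector of expected final reads.
#' @export
fitted.ideal <- function(object, ...) {
  stats::setNames(object$plan$expected_final_reads, object$plan$sample_id)
}

#' Predict cumulative totals under the fitted volumes
#'
#' Evaluates the noiseless model `t + runs * reads_per_run * share` with the
#' fitted volumes, optionally for a different number of remaining runs or
#' per-run yield than the plan was built for.
#'
#' @param object An `"ideal"` object.
#' @param runs,reads_per_run Override the fitted schedule; defaults keep it.
#' @param ... Unused.
#' @return Named numeric vector of predicted final reads.
#' @export
predict.ideal <- function(object, runs = object$runs,
                          reads_per_run = object$reads_per_run, ...) {
  p <- object$plan
  planned <- !p$excluded
  out <- stats::setNames(object$counts$reads, p$sample_id)
  wt <- object$concentration[planned] * p$volume[planned]
  out[planned] <- out[planned] + runs * reads_per_run * wt / sum(wt)
  out
}

#' Deviations of expected finals from the equal target
#' @param object An `"ideal"` object.
#' @param ... Unused.
#' @return Named numeric vector `expected_final_reads - target`; zero
#'   everywhere when no clamp triggered.
#' @export
residuals.ideal <- function(object, ...) {
  fitted(object) - object$target
}

#' @export
summary.ideal <- function(object, ...) {
  fin <- fitted(object)
  structure(
    list(fit = object,
         initial = object$initial_spread,
         expected_final = spread_metrics(fin[fin > 0]),
         volume_range = range(object$plan$volume[!object$plan$excluded]),
         n_below = sum(object$plan$below_pipettable)),
    class = "summary.ideal"
  )
}

#' @export
print.summary.ideal <- function(x, ...) {
  print(x$fit)
  cat("\nInitial run   : "); print(x$initial)
  cat("Expected final: "); print(x$expected_final)
  cat(sprintf("Re-pool volumes: %.3f-%.3f uL (%d raised to vmin)\n",
              x$volume_range[1L], x$volume_range[2L], x$n_below))
  invisible(x)
}

#' Simulate sequencing of the remaining flow cells under the plan
#'
#' Draws the planned runs from the multinomial read-sampling model using the
#' estimated concentrations and fitted volumes, and returns cumulative final
#' totals, one column per replicate.
#'
#' @param object An `"ideal"` object.
#' @param nsim Number of replicates.
#' @param seed Optional RNG seed.
#' @param noise_cv Per-run multiplicative lognormal noise CV (default 0.03).
#' @param ... Unused.
#' @return data.frame of final totals, `nsim` columns, rownames sample ids.
#' @export
simulate.ideal <- function(object, nsim = 1, seed = NULL, noise_cv = 0.03,
                           ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- object$plan
  conc <- object$concentration
  conc[is.na(conc)] <- 0
  out <- matrix(NA_real_, nrow(p), nsim,
                dimnames = list(p$sample_id, paste0("sim_", seq_len(nsim))))
  for (s in seq_len(nsim)) {
    tot <- stats::setNames(object$counts$reads, p$sample_id)
    for (k in seq_len(object$runs)) {
      run <- simulate_run(conc, p$volume, object$reads_per_run,
                          noise_cv = noise_cv, sample_id = p$sample_id)
      tot <- tot + stats::setNames(run$reads, run$sample_id)[p$sample_id]
    }
    out[, s] <- tot
  }
  as.data.frame(out)
}

#' Stacked per-sample read totals for an iDeal plan
#'
#' Bars show the initial-run reads with the expected contribution of each
#' remaining flow cell stacked on top; the dashed line marks the equal
#' final target.
#'
#' @param x An `"ideal"` object.
#' @param col Colours for the initial run and each remaining run.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.ideal <- function(x, col = c("#2166AC", "#F4A582", "#B2182B"), ...) {
  p <- x$plan
  add <- (p$expected_final_reads - x$counts$reads) / x$runs
  h <- rbind(initial = x$counts$reads,
             matrix(rep(add, each = x$runs), nrow = x$runs,
                    dimnames = list(paste0("run", 1L + seq_len(x$runs)))))
  col <- rep_len(col, 1L + x$runs)
  graphics::barplot(h, names.arg = p$sample_id, col = col, border = NA,
                    las = 2, ylab = "reads", ...)
  graphics::abline(h = x$target, lty = 2)
  invisible(x)
}

#' Write a re-pooling plan as TSV
#'
#' Columns `sample_id`, `volume_uL`, `excluded`, `reason`,
#' `below_pipettable`, `expected_final_reads`; volumes with 4 decimals; a
#' `#` header line records the package version for provenance.
#'
#' @param fit An `"ideal"` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rebalance_plan <- function(fit, path) {
  stopifnot(inherits(fit, "ideal"))
  p <- fit$plan
  out <- data.frame(
    sample_id = p$sample_id,
    volume_uL = sprintf("%.4f", p$volume),
    excluded = p$excluded,
    reason = ifelse(is.na(p$reason), ".", p$reason),
    below_pipettable = p$below_pipettable,
    expected_final_reads = sprintf("%.4f", p$expected_final_reads),
    stringsAsFactors = FALSE
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seqbalance %s rebalance plan; target=%.4f runs=%d",
                     as.character(utils::packageVersion("seqbalance")),
                     fit$target, fit$runs), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a re-pooling plan TSV
#' @param path File written by [write_rebalance_plan()].
#' @return data.frame with numeric `volume_uL` and `expected_final_reads`.
#' @export
read_rebalance_plan <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  df$volume_uL <- as.numeric(df$volume_uL)
  df$expected_final_reads <- as.numeric(df$expected_final_reads)
  df
}
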
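#' Demultiplexed per-sample read counts for one run
#'
#' @param sample_id Character vector of sample names (unique).
#' @param reads Non-negative per-sample read counts.
#' @param volume Per-sample pooled volume in uL; scalar volumes are
#'   recycled. Equal volumes correspond to the standard equal-volume
#'   initial pool.
#' @param run_id Run identifier.
#' @return Object of class `"demux_counts"`: a data.frame with columns
#'   `sample_id`, `reads`, `volume` and attributes `run_id`, `total_reads`.
#' @export
demux_counts <- function(sample_id, reads, volume = 1, run_id = "run1") {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id))
    stop("sample ids must be unique", call. = FALSE)
  if (length(sample_id) < 2L)
    stop("at least two samples are required", call. = FALSE)
  if (length(reads) != length(sample_id))
    stop("reads and sample_id lengths differ", call. = FALSE)
  if (any(!is.finite(reads)) || any(reads < 0))
    stop("reads must be finite and non-negative", call. = FALSE)
  volume <- rep_len(as.numeric(volume), length(sample_id))
  if (any(volume <= 0))
    stop("pooled volumes must be positive", call. = FALSE)
  out <- data.frame(sample_id = sample_id, reads = as.numeric(reads),
                    volume = volume, stringsAsFactors = FALSE)
  structure(out, run_id = run_id, total_reads = sum(out$reads),
            class = c("demux_counts", "data.frame"))
}

#' @export
print.demux_counts <- function(x, ...) {
  cat(sprintf("Demultiplexed counts '%s': %d samples, %s reads\n",
              attr(x, "run_id"), nrow(x),
              format(attr(x, "total_reads"), big.mark = ",")))
  print.data.frame(utils::head(as.data.frame(x), 6L), row.names = FALSE)
  if (nrow(x) > 6L) cat(sprintf("... and %d more samples\n", nrow(x) - 6L))
  invisible(x)
}

#' Read demultiplexed counts from a generic TSV
#'
#' Tab-separated with header columns `sample_id`, `reads` and optionally
#' `volume` (defaults to 1 uL, i.e. an equal-volume pool). Lines starting
#' with `#` are comments.
#'
#' @param path File path.
#' @param run_id Run identifier to attach.
#' @return A [demux_counts()] object.
#' @export
read_demux_tsv <- function(path, run_id = basename(path)) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("sample_id", "reads") %in% names(df)))
    stop("demux TSV needs sample_id and reads columns", call. = FALSE)
  vol <- if ("volume" %in% names(df)) df$volume else 1
  demux_counts(df$sample_id, df$reads, vol, run_id = run_id)
}

#' Read a demultiplexing-statistics CSV (bcl2fastq / BCL Convert style)
#'
#' Reads the per-sample read counts out of a `Demultiplex_Stats`-style CSV
#' by naming the sample and read-count columns, which vary across software
#' versions (`"SampleID"` + `"# Reads"`, `"Sample_ID"` + `"NumberReads"`, ...).
#' Rows named `Undetermined` are dropped.
#'
#' @param path File path.
#' @param sample_col,reads_col Header names of the sample and count columns.
#' @param run_id Run identifier to attach.
#' @return A [demux_counts()] object with equal volumes.
#' @export
read_demux_stats_csv <- function(path, sample_col = "SampleID",
                                 reads_col = "# Reads",
                                 run_id = basename(path)) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c(sample_col, reads_col) %in% names(df)))
    stop(sprintf("columns '%s' and '%s' not found in %s",
                 sample_col, reads_col, path), call. = FALSE)
  keep <- df[[sample_col]] != "Undetermined"
  demux_counts(df[[sample_col]][keep],
               as.numeric(gsub(",", "", df[[reads_col]][keep])),
               run_id = run_id)
}

#' Cumulative per-sample read totals across runs
#'
#' Missing samples in a run contribute zero; the union of sample ids is
#' taken in order of first appearance.
#'
#' @param runs List of [demux_counts()] objects.
#' @return Named numeric vector of per-sample totals.
#' @export
cumulative_totals <- function(runs) {
  if (inherits(runs, "demux_counts")) runs <- list(runs)
  stopifnot(length(runs) >= 1L,
            all(vapply(runs, inherits, logical(1), "demux_counts")))
  ids <- unique(unlist(lapply(runs, `[[`, "sample_id")))
  tot <- stats::setNames(numeric(length(ids)), ids)
  for (r in runs) tot[r$sample_id] <- tot[r$sample_id] + r$reads
  tot
}

#' Evenness metrics for per-sample data totals
#'
#' Summarizes how uneven per-sample read totals are: the max/min ratio
#' (initial equal-volume runs commonly exceed 2), the maximum relative
#' deviation from the mean in percent (rebalanced totals should sit under
#' ~10%), and the coefficient of variation in percent (population sd).
#'
#' @param totals Strictly positive per-sample totals, length >= 2.
#' @return Object of class `"spread_metrics"`: list with `maxmin_ratio`,
#'   `max_rel_dev` (%), `cv` (%), and `n`.
#' @export
spread_metrics <- function(totals) {
  totals <- as.numeric(totals)
  if (length(totals) < 2L || any(!is.finite(totals)) || any(totals <= 0))
    stop("totals must be >= 2 strictly positive values", call. = FALSE)
  m <- mean(totals)
  structure(
    list(maxmin_ratio = max(totals) / min(totals),
         max_rel_dev = 100 * max(abs(totals - m)) / m,
         cv = 100 * sqrt(mean((totals - m)^2)) / m,
         n = length(totals)),
    class = "spread_metrics"
  )
}

#' @export
print.spread_metrics <- function(x, ...) {
  cat(sprintf(
    "Spread over %d samples: max/min %.3f, max deviation %.2f%%, CV %.2f%%\n",
    x$n, x$maxmin_ratio, x$max_rel_dev, x$cv))
  invisible(x)
}
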
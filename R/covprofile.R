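#' Binned depth track for one sample
#'
#' Per-bin mean depth over a uniformly binned contig, computed upstream
#' from alignments restricted to a mapping-quality floor (conventionally
#' MAPQ >= 20, so only confidently mapped reads count).
#'
#' @param sample_id Sample name.
#' @param contig Contig name.
#' @param bin_size Bin width in bp.
#' @param depths Numeric vector of per-bin mean depths (fold), >= 0.
#' @param mapq_floor Mapping-quality floor used upstream; provenance only.
#' @param start Genomic start of the first bin (0-based; default 0).
#' @return Object of class `"depth_track"`.
#' @export
depth_track <- function(sample_id, contig, bin_size, depths,
                        mapq_floor = 20, start = 0) {
  depths <- as.numeric(depths)
  if (any(!is.finite(depths)) || any(depths < 0))
    stop("depths must be finite and non-negative", call. = FALSE)
  if (bin_size <= 0) stop("bin_size must be positive", call. = FALSE)
  structure(
    list(sample_id = sample_id, contig = contig, bin_size = bin_size,
         depths = depths, mapq_floor = mapq_floor, start = start),
    class = "depth_track"
  )
}

#' @export
print.depth_track <- function(x, ...) {
  cat(sprintf("Depth track %s: %s, %d bins of %d bp, mean %.2fx (MAPQ>=%s)\n",
              x$sample_id, x$contig, length(x$depths), x$bin_size,
              mean(x$depths), x$mapq_floor))
  invisible(x)
}

check_compatible_tracks <- function(tracks) {
  stopifnot(length(tracks) >= 1L,
            all(vapply(tracks, inherits, logical(1), "depth_track")))
  ref <- tracks[[1L]]
  same <- vapply(tracks, function(t) {
    t$contig == ref$contig && t$bin_size == ref$bin_size &&
      t$start == ref$start && length(t$depths) == length(ref$depths)
  }, logical(1))
  if (!all(same))
    stop("tracks have incompatible contig/binning/extent", call. = FALSE)
  ref
}

#' Mean coverage profile across samples
#'
#' Per-bin arithmetic mean of depth across many samples' tracks. Averaging
#' over a large cohort (the reference design uses 1,000 samples per
#' platform/protocol) washes out individual sampling noise and exposes
#' systematic accessibility differences between protocols.
#'
#' @param tracks List of [depth_track()] objects with identical binning.
#' @return Object of class `"aggregate_profile"`: contig, bin_size, start,
#'   `mean_depth` per bin, `n_samples` and `global_mean`.
#' @export
aggregate_mean_coverage <- function(tracks) {
  ref <- check_compatible_tracks(tracks)
  depth <- rowMeans(vapply(tracks, `[[`, numeric(length(ref$depths)),
                           "depths"))
  structure(
    list(contig = ref$contig, bin_size = ref$bin_size, start = ref$start,
         mean_depth = depth, n_samples = length(tracks),
         global_mean = mean(depth)),
    class = "aggregate_profile"
  )
}

#' @export
print.aggregate_profile <- function(x, ...) {
  cat(sprintf(
    "Aggregate profile: %s, %d bins of %d bp over %d samples, mean %.2fx\n",
    x$contig, length(x$mean_depth), x$bin_size, x$n_samples, x$global_mean))
  invisible(x)
}

# logical per-bin inaccessibility mask after the run-length filter
inaccessible_mask <- function(profile, rel_threshold, min_region_bins) {
  low <- profile$mean_depth < rel_threshold * profile$global_mean
  r <- rle(low)
  r$values <- r$values & r$lengths >= min_region_bins
  inverse.rle(r)
}

mask_to_regions <- function(mask, contig, bin_size, start, label) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(contig = rep(contig, sum(keep)),
             start = start + starts[keep] * bin_size,
             end = start + ends[keep] * bin_size,
             label = rep(label, sum(keep)),
             stringsAsFactors = FALSE)
}

#' Classify accessible and inaccessible regions of an aggregate profile
#'
#' Bins whose cohort mean depth falls below `rel_threshold` times the
#' profile's global mean, in runs of at least `min_region_bins` consecutive
#' bins, are called inaccessible; the complement is accessible. No
#' universal numeric definition of "inaccessible" exists, so both knobs are
#' deliberate package choices — tune them to your protocol comparison.
#'
#' @param profile An [aggregate_mean_coverage()] result.
#' @param rel_threshold Fraction of the global mean below which a bin is
#'   low (default 0.25).
#' @param min_region_bins Minimum run length in bins (default 2).
#' @return data.frame of class `"region_set"` with columns `contig`,
#'   `start`, `end` (0-based half-open) and `label`
#'   (`accessible`/`inaccessible`), sorted and merged.
#' @export
classify_accessibility <- function(profile, rel_threshold = 0.25,
                                   min_region_bins = 2) {
  stopifnot(inherits(profile, "aggregate_profile"))
  if (profile$global_mean <= 0)
    stop("degenerate profile: global mean depth is zero", call. = FALSE)
  mask <- inaccessible_mask(profile, rel_threshold, min_region_bins)
  out <- rbind(
    mask_to_regions(mask, profile$contig, profile$bin_size, profile$start,
                    "inaccessible"),
    mask_to_regions(!mask, profile$contig, profile$bin_size, profile$start,
                    "accessible")
  )
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("region_set", "data.frame")
  out
}

#' Regions accessible under one protocol but not another
#'
#' The interesting output of a protocol comparison: intervals readable
#' with protocol `a` (e.g. 161/162 bp paired-end) that drop out under
#' protocol `b` (e.g. 150 bp paired-end). Computed as the bin-level set
#' difference of the two inaccessibility classifications.
#'
#' @param a,b [aggregate_mean_coverage()] profiles on identical binning.
#' @param rel_threshold,min_region_bins Passed to the classification of
#'   both profiles.
#' @return data.frame of class `"region_set"` with the differential
#'   intervals labelled `gained`.
#' @export
protocol_diff <- function(a, b, rel_threshold = 0.25, min_region_bins = 2) {
  stopifnot(inherits(a, "aggregate_profile"),
            inherits(b, "aggregate_profile"))
  if (a$contig != b$contig || a$bin_size != b$bin_size ||
      a$start != b$start || length(a$mean_depth) != length(b$mean_depth))
    stop("profiles have incompatible binning", call. = FALSE)
  mask_a <- inaccessible_mask(a, rel_threshold, min_region_bins)
  mask_b <- inaccessible_mask(b, rel_threshold, min_region_bins)
  out <- mask_to_regions(mask_b & !mask_a, a$contig, a$bin_size, a$start,
                         "gained")
  class(out) <- c("region_set", "data.frame")
  out
}

#' Read a bedGraph depth track
#'
#' Uses `rtracklayer` for parsing; intervals must form a uniform binning of
#' one contig.
#'
#' @param path bedGraph file.
#' @param sample_id Sample name to attach.
#' @param mapq_floor Provenance annotation (default 20).
#' @return A [depth_track()] object.
#' @export
read_bedgraph_track <- function(path, sample_id = basename(path),
                                mapq_floor = 20) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("rtracklayer is required for bedGraph input", call. = FALSE)
  gr <- rtracklayer::import(path, format = "bedGraph")
  gr <- sort(gr)
  w <- unique(GenomicRanges::width(gr))
  ctg <- unique(as.character(GenomicRanges::seqnames(gr)))
  if (length(w) != 1L || length(ctg) != 1L)
    stop("bedGraph must be a uniform binning of one contig", call. = FALSE)
  st <- GenomicRanges::start(gr) - 1L
  if (any(diff(st) != w))
    stop("bedGraph bins are not contiguous", call. = FALSE)
  depth_track(sample_id, contig = ctg, bin_size = w, depths = gr$score,
              mapq_floor = mapq_floor, start = st[1L])
}

#' Write a depth track or aggregate profile as bedGraph
#'
#' @param x A [depth_track()] or [aggregate_mean_coverage()] object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(x, path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("rtracklayer is required for bedGraph output", call. = FALSE)
  depths <- if (inherits(x, "depth_track")) x$depths else x$mean_depth
  n <- length(depths)
  gr <- GenomicRanges::GRanges(
    x$contig,
    IRanges::IRanges(start = x$start + (seq_len(n) - 1L) * x$bin_size + 1L,
                     width = x$bin_size),
    score = depths)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Write a region set as BED
#'
#' The label column becomes the BED name field; coordinates are already
#' 0-based half-open.
#'
#' @param regions A `"region_set"` data.frame.
#' @param path Output file.
#' @param label Optional filter: write only rows with this label
#'   (e.g. `"inaccessible"`).
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path, label = NULL) {
  stopifnot(is.data.frame(regions))
  if (!is.null(label)) regions <- regions[regions$label == label, ,
                                          drop = FALSE]
  df <- data.frame(regions$contig, regions$start, regions$end,
                   regions$label)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
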
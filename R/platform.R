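#' Cycle budget for a sequencing reagent kit
#'
#' A reagent kit nominally rated for, say, 300 cycles usually contains
#' surplus chemistry: the cycles actually usable (`actual_cycles`) exceed the
#' kit label, and index reads consume cycles from the same budget.
#'
#' @param actual_cycles Total usable chemistry cycles in the kit.
#' @param index1_cycles,index2_cycles Cycles consumed by the two index reads.
#' @param kit_nominal_cycles The kit's advertised cycle count; informational.
#' @return An object of class `"cycle_budget"`.
#' @examples
#' cycle_budget(325)            # 300-cycle kit run without index reads
#' cycle_budget(338, 8, 8)      # 300-cycle kit with dual 8 bp indexes
#' @export
cycle_budget <- function(actual_cycles, index1_cycles = 0L, index2_cycles = 0L,
                         kit_nominal_cycles = NULL) {
  stopifnot(length(actual_cycles) == 1L, is.finite(actual_cycles))
  if (is.null(kit_nominal_cycles)) kit_nominal_cycles <- actual_cycles
  if (actual_cycles < 0 || index1_cycles < 0 || index2_cycles < 0)
    stop("cycle counts must be non-negative", call. = FALSE)
  if (kit_nominal_cycles > actual_cycles)
    stop("actual_cycles must be at least kit_nominal_cycles", call. = FALSE)
  if (index1_cycles + index2_cycles > actual_cycles)
    stop("index cycles exceed the available cycle budget", call. = FALSE)
  structure(
    list(kit_nominal_cycles = kit_nominal_cycles,
         actual_cycles = actual_cycles,
         index1_cycles = index1_cycles,
         index2_cycles = index2_cycles),
    class = "cycle_budget"
  )
}

#' @export
print.cycle_budget <- function(x, ...) {
  cat(sprintf("Cycle budget: %d usable cycles (kit %d), index %d+%d\n",
              x$actual_cycles, x$kit_nominal_cycles,
              x$index1_cycles, x$index2_cycles))
  cat(sprintf("Max symmetric paired read length: %d bp\n",
              max_symmetric_read_length(x)))
  invisible(x)
}

#' Longest symmetric paired-end read length a cycle budget supports
#'
#' After the index reads take their cycles, the remainder is split evenly
#' between Read 1 and Read 2. This is how a 300-cycle kit holding 325 usable
#' cycles supports 162 bp paired-end sequencing when run without index reads,
#' and one holding 338 cycles supports 161 bp paired-end with dual 8 bp
#' indexes.
#'
#' @param budget A [cycle_budget()], or a bare count of usable cycles.
#' @return Integer read length in bp (same for both mates).
#' @examples
#' max_symmetric_read_length(cycle_budget(325))       # 162
#' max_symmetric_read_length(cycle_budget(338, 8, 8)) # 161
#' @export
max_symmetric_read_length <- function(budget) {
  if (!inherits(budget, "cycle_budget")) budget <- cycle_budget(budget)
  avail <- budget$actual_cycles - budget$index1_cycles - budget$index2_cycles
  if (avail < 0) stop("negative available cycles", call. = FALSE)
  as.integer(avail %/% 2L)
}

#' Total base yield of a sequencing run
#'
#' @param clusters Number of clusters (read pairs when paired) passing filter.
#' @param read_length Read length in bp.
#' @param paired Whether sequencing is paired-end (doubles the yield).
#' @return Yield in bp.
#' @examples
#' run_yield_bp(3e8, 150)  # ~90 Gb, one human genome at ~30x
#' @export
run_yield_bp <- function(clusters, read_length, paired = TRUE) {
  if (any(clusters < 0) || any(read_length < 0))
    stop("clusters and read_length must be non-negative", call. = FALSE)
  clusters * read_length * (if (isTRUE(paired)) 2 else 1)
}

#' Expected fold coverage from a base yield
#'
#' @param yield_bp Sequenced bases.
#' @param genome_size_bp Genome size; defaults to 3.0e9 for human.
#' @return Fold coverage (real-valued; round for display).
#' @examples
#' expected_coverage(9.0e10)  # 30
#' @export
expected_coverage <- function(yield_bp, genome_size_bp = 3.0e9) {
  if (genome_size_bp <= 0)
    stop("genome_size_bp must be positive", call. = FALSE)
  if (any(yield_bp < 0)) stop("yield_bp must be non-negative", call. = FALSE)
  yield_bp / genome_size_bp
}

#' Flow cells needed to reach a coverage target
#'
#' @param n_samples Samples sharing the pool.
#' @param target_coverage Desired fold coverage per sample.
#' @param per_flowcell_yield_bp Base yield of one flow cell.
#' @param genome_size_bp Genome size per sample.
#' @return Integer count of flow cells (0 when nothing is demanded).
#' @examples
#' flowcells_needed(96, 30, 3.0e12)  # ceil(8.64e12 / 3e12) = 3
#' @export
flowcells_needed <- function(n_samples, target_coverage, per_flowcell_yield_bp,
                             genome_size_bp = 3.0e9) {
  if (per_flowcell_yield_bp <= 0)
    stop("per_flowcell_yield_bp must be positive", call. = FALSE)
  if (n_samples < 1 || target_coverage < 0 || genome_size_bp <= 0)
    stop("invalid coverage plan", call. = FALSE)
  demand <- n_samples * target_coverage * genome_size_bp
  as.integer(ceiling(demand / per_flowcell_yield_bp))
}

#' Format a base yield as an instrument-style label
#'
#' Decimal units (1 Gb = 1e9 bp), rounded to the nearest integer, matching
#' labels such as "97Gb" for 3e8 clusters at 162 bp paired-end.
#'
#' @param yield_bp Yield in bases.
#' @return Character label, e.g. `"97Gb"` or `"3Tb"`.
#' @export
yield_label <- function(yield_bp) {
  ifelse(yield_bp >= 1e12,
         paste0(round(yield_bp / 1e12), "Tb"),
         paste0(round(yield_bp / 1e9), "Gb"))
}

#' Built-in sequencing platform presets
#'
#' Platform/mode/protocol rows with read length and per-flow-cell output
#' labels, shipped as JSON under `extdata`. Cluster counts are recorded only
#' where public (HiSeq 2500 rapid run: 3e8 read pairs per flow cell); other
#' rows carry aggregate output labels.
#'
#' @return A data.frame with one row per platform protocol.
#' @export
platform_presets <- function() {
  path <- system.file("extdata", "platform_presets.json",
                      package = "seqbalance", mustWork = TRUE)
  as.data.frame(jsonlite::fromJSON(path))
}
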
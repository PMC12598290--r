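#' Dye-based measurement of a pooled library
#'
#' Pools of 96 equal-volume libraries are quantified with a dye assay
#' (e.g. Qubit) and compared against a previously sequenced pool whose
#' loading behaviour is known.
#'
#' @param pool_id Pool identifier.
#' @param dye_conc Dye-based concentration, ng/uL.
#' @param volume Available volume, uL.
#' @param is_reference Whether this pool has already been sequenced
#'   successfully and anchors the quantification.
#' @param reference_loading_volume For reference pools, the loading volume
#'   (uL) that produced good cluster density.
#' @return Object of class `"pool_measurement"`.
#' @export
pool_measurement <- function(pool_id, dye_conc, volume = 100,
                             is_reference = FALSE,
                             reference_loading_volume = NULL) {
  if (dye_conc < 0) stop("dye_conc must be non-negative", call. = FALSE)
  if (volume <= 0) stop("volume must be positive", call. = FALSE)
  if (isTRUE(is_reference) && is.null(reference_loading_volume))
    stop("reference pools need a reference_loading_volume", call. = FALSE)
  structure(
    list(pool_id = pool_id, dye_conc = dye_conc, volume = volume,
         is_reference = isTRUE(is_reference),
         reference_loading_volume = reference_loading_volume),
    class = "pool_measurement"
  )
}

#' Loading volume for a new pool, relative to a sequenced reference pool
#'
#' Equalizes loaded DNA mass: the new pool is loaded at the volume that
#' carries the same mass the reference pool carried when it clustered well,
#' so `new_conc * volume == ref_conc * ref_volume` exactly.
#'
#' @param new_pool,reference [pool_measurement()] objects; `reference` must
#'   carry a `reference_loading_volume`.
#' @return Loading volume in uL.
#' @examples
#' ref <- pool_measurement("P0", 2.0, is_reference = TRUE,
#'                         reference_loading_volume = 100)
#' loading_volume(pool_measurement("P1", 2.5), ref)  # 80
#' @export
loading_volume <- function(new_pool, reference) {
  stopifnot(inherits(new_pool, "pool_measurement"),
            inherits(reference, "pool_measurement"))
  if (new_pool$dye_conc <= 0 || reference$dye_conc <= 0)
    stop("concentrations must be positive to compare pools", call. = FALSE)
  if (is.null(reference$reference_loading_volume))
    stop("reference pool lacks a known-good loading volume", call. = FALSE)
  reference$reference_loading_volume * reference$dye_conc / new_pool$dye_conc
}

#' Correct an RNA-ladder size reading to a DNA library size
#'
#' PCR-free libraries carry Y-shaped adapters and migrate anomalously
#' (>1000 bp apparent) on native dsDNA electrophoresis, so sizing is done
#' denatured against an RNA ladder. RNA ladders migrate about 30 nt slower
#' than DNA ladders, so the reading is shifted up by that offset: a 616 nt
#' reading corresponds to a 646 bp library.
#'
#' @param observed Apparent size against the RNA ladder, nt.
#' @param offset RNA-vs-DNA ladder migration offset, nt (default 30).
#' @return Corrected library size in bp.
#' @export
correct_library_size <- function(observed, offset = 30) {
  if (any(observed <= 0))
    stop("observed size must be positive", call. = FALSE)
  observed + offset
}

#' Insert size of a library
#'
#' The genomic fragment inside a library molecule: corrected library size
#' minus the total adapter sequence (~140 bp for standard paired adapters).
#' A 646 bp library thus holds a ~506 bp insert.
#'
#' @param corrected_library_bp Corrected library size, bp.
#' @param adapter_total Total adapter bases, bp (default 140).
#' @return Insert size in bp.
#' @export
insert_size <- function(corrected_library_bp, adapter_total = 140) {
  if (any(adapter_total >= corrected_library_bp))
    stop("adapter_total must be smaller than the library size", call. = FALSE)
  corrected_library_bp - adapter_total
}

#' Molar concentration of a dsDNA library
#'
#' Converts a mass concentration to molarity using 660 g/mol per bp of
#' double-stranded DNA; loading is governed by molarity, which falls as
#' library size grows at fixed mass concentration.
#'
#' @param dye_conc Mass concentration, ng/uL.
#' @param library_size_bp Library size, bp.
#' @return Molar concentration in nM.
#' @examples
#' molar_concentration(0.66, 1000)  # 1 nM
#' @export
molar_concentration <- function(dye_conc, library_size_bp) {
  if (any(dye_conc <= 0) || any(library_size_bp <= 0))
    stop("dye_conc and library_size_bp must be positive", call. = FALSE)
  dye_conc * 1e6 / (660 * library_size_bp)
}

#' Partition samples by estimated contamination
#'
#' Samples whose freemix (estimated fraction of foreign DNA) meets or
#' exceeds the threshold are excluded from downstream joint analyses. The
#' default 3% cutoff is inclusive and stricter than the 5% used by gnomAD.
#'
#' @param records data.frame with columns `sample_id` and `freemix`.
#' @param threshold Exclusion threshold on freemix (default 0.03); a sample
#'   with `freemix >= threshold` is excluded.
#' @return List with data.frames `kept` and `excluded`; together they
#'   partition the input.
#' @export
filter_contamination <- function(records, threshold = 0.03) {
  stopifnot(is.data.frame(records),
            all(c("sample_id", "freemix") %in% names(records)))
  fm <- records$freemix
  if (any(is.na(fm)) || any(fm < 0) || any(fm > 1))
    stop("freemix must be present and within [0, 1]", call. = FALSE)
  drop <- fm >= threshold
  list(kept = records[!drop, , drop = FALSE],
       excluded = records[drop, , drop = FALSE])
}

#' Sequence-level QC flags for one sample
#'
#' Checks that the duplication rate is reasonably low and that base
#' composition is balanced between the complementary pairs A/T and G/C.
#' The numeric defaults (20% duplication, 2 percentage-point skew) are this
#' package's choices; adjust to your facility's norms.
#'
#' @param record A list or one-row data.frame with optional fields
#'   `duplication_rate`, `base_frac_A`, `base_frac_T`, `base_frac_G`,
#'   `base_frac_C`.
#' @param max_dup Maximum acceptable duplication rate.
#' @param max_base_skew Maximum acceptable |A-T| or |G-C| fraction gap.
#' @return Character vector of flags, possibly empty; `"not-evaluated"`
#'   entries mark metrics that were absent.
#' @export
sequence_qc_flags <- function(record, max_dup = 0.20, max_base_skew = 0.02) {
  record <- as.list(record)
  val <- function(f) {
    v <- record[[f]]
    if (is.null(v) || length(v) == 0L || is.na(v)) NA_real_ else as.numeric(v)
  }
  flags <- character(0)
  dup <- val("duplication_rate")
  if (is.na(dup)) {
    flags <- c(flags, "duplication:not-evaluated")
  } else if (dup > max_dup) {
    flags <- c(flags, "duplication")
  }
  a <- val("base_frac_A"); t <- val("base_frac_T")
  g <- val("base_frac_G"); c_ <- val("base_frac_C")
  if (any(is.na(c(a, t, g, c_)))) {
    flags <- c(flags, "base-balance:not-evaluated")
  } else {
    if (abs(a - t) > max_base_skew) flags <- c(flags, "base-skew-AT")
    if (abs(g - c_) > max_base_skew) flags <- c(flags, "base-skew-GC")
  }
  flags
}

#' Read a per-sample QC metric table
#'
#' Tab-separated with a header; expects `sample_id` and `freemix`, and
#' optionally `duplication_rate` and `base_frac_A/T/G/C`.
#'
#' @param path File path.
#' @return data.frame.
#' @export
read_qc_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("sample_id", "freemix") %in% names(df)))
    stop("QC table needs sample_id and freemix columns", call. = FALSE)
  df
}
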
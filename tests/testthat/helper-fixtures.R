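# Shared in-code fixtures for the test suite.

# Random three-generation pedigree: n_fam families, each a complete
# 7-member hepta structure with members independently dropped.
random_pedigree <- function(n_fam = 5, drop_prob = 0.3, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (f in seq_len(n_fam)) {
    p <- function(role) sprintf("F%d_%s", f, role)
    members <- rbind(
      c(p("PGF"), NA, NA), c(p("PGM"), NA, NA),
      c(p("MGF"), NA, NA), c(p("MGM"), NA, NA),
      c(p("FA"), p("PGF"), p("PGM")),
      c(p("MO"), p("MGF"), p("MGM")),
      c(p("CH"), p("FA"), p("MO")))
    keep <- stats::runif(7) > drop_prob
    rows[[f]] <- members[keep, , drop = FALSE]
  }
  m <- do.call(rbind, rows)
  if (nrow(m) < 1L) m <- rbind(c("X1", NA, NA), c("X2", NA, NA))
  pedigree_graph(m[, 1L], m[, 2L], m[, 3L])
}

# Brute-force pedigree oracles by exhaustive subset checking; independent
# of the row-wise logic in the package.
oracle_trios <- function(g) {
  ids <- g$id
  if (length(ids) < 3L) return(0L)
  hits <- 0L
  for (sub in utils::combn(ids, 3L, simplify = FALSE)) {
    for (child in sub) {
      others <- setdiff(sub, child)
      i <- match(child, g$id)
      fa <- g$father_id[i]; mo <- g$mother_id[i]
      if (!is.na(fa) && !is.na(mo) && setequal(others, c(fa, mo)) &&
          fa != mo)
        hits <- hits + 1L
    }
  }
  hits
}

oracle_duos <- function(g, role = "mother") {
  ids <- g$id
  if (length(ids) < 2L) return(0L)
  hits <- 0L
  for (sub in utils::combn(ids, 2L, simplify = FALSE)) {
    for (child in sub) {
      parent <- setdiff(sub, child)
      i <- match(child, g$id)
      pcol <- if (role == "mother") g$mother_id[i] else g$father_id[i]
      ocol <- if (role == "mother") g$father_id[i] else g$mother_id[i]
      other_in <- !is.na(ocol) && ocol %in% ids
      if (!is.na(pcol) && pcol == parent && !other_in)
        hits <- hits + 1L
    }
  }
  hits
}

oracle_heptas <- function(g) {
  # per-child exhaustive walk over explicitly materialized 7-member sets
  hits <- 0L
  for (i in seq_len(nrow(g))) {
    fa <- g$father_id[i]; mo <- g$mother_id[i]
    if (is.na(fa) || is.na(mo) || !(fa %in% g$id) || !(mo %in% g$id)) next
    gp <- c(g$father_id[match(fa, g$id)], g$mother_id[match(fa, g$id)],
            g$father_id[match(mo, g$id)], g$mother_id[match(mo, g$id)])
    if (any(is.na(gp)) || !all(gp %in% g$id)) next
    members <- c(g$id[i], fa, mo, gp)
    if (length(unique(members)) == 7L) hits <- hits + 1L
  }
  hits
}

# tiny flat aggregate profile with planted low windows
flat_profile <- function(n_bins = 100, depth = 30, contig = "chrT",
                         bin_size = 1000) {
  aggregate_mean_coverage(list(
    depth_track("S1", contig, bin_size, rep(depth, n_bins))))
}
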
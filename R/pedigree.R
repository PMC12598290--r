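#' Pedigree graph from individual and parent identifiers
#'
#' @param id Individual identifiers (unique, non-missing).
#' @param father_id,mother_id Parent identifiers; `"0"`, `""` or `NA` mean
#'   unknown. Parents referenced but absent from `id` are treated as not in
#'   the dataset (they cannot anchor a trio).
#' @param sex Optional sex codes (1 = male, 2 = female, 0 = unknown).
#' @param family_id Optional family identifiers.
#' @return Object of class `"pedigree_graph"`: a data.frame with columns
#'   `id`, `father_id`, `mother_id`, `sex`, `family_id` (unknown parents
#'   are `NA`).
#' @export
pedigree_graph <- function(id, father_id, mother_id, sex = 0,
                           family_id = NA_character_) {
  id <- as.character(id)
  if (anyDuplicated(id)) stop("individual ids must be unique", call. = FALSE)
  norm <- function(p) {
    p <- as.character(p)
    p[p %in% c("0", "") | is.na(p)] <- NA_character_
    p
  }
  g <- data.frame(id = id, father_id = norm(father_id),
                  mother_id = norm(mother_id),
                  sex = rep_len(as.integer(sex), length(id)),
                  family_id = rep_len(as.character(family_id), length(id)),
                  stringsAsFactors = FALSE)
  if (any(!is.na(g$father_id) & g$father_id == g$id) ||
      any(!is.na(g$mother_id) & g$mother_id == g$id))
    stop("an individual cannot be its own parent", call. = FALSE)
  check_acyclic(g)
  class(g) <- c("pedigree_graph", "data.frame")
  g
}

# peel founders repeatedly; leftovers imply a parent-link cycle
check_acyclic <- function(g) {
  present <- g$id
  repeat {
    fathers <- ifelse(g$father_id %in% present, g$father_id, NA)
    mothers <- ifelse(g$mother_id %in% present, g$mother_id, NA)
    is_parent <- present %in% c(fathers, mothers)
    founders <- vapply(seq_along(present), function(i) {
      is.na(fathers[i]) && is.na(mothers[i])
    }, logical(1))
    if (!length(present)) return(invisible(TRUE))
    if (!any(founders))
      stop("pedigree contains a parent-link cycle", call. = FALSE)
    keep <- !founders
    present <- present[keep]
    g <- g[keep, , drop = FALSE]
  }
}

#' Read a 6-column PED file
#'
#' Whitespace-separated: family, individual, father, mother, sex,
#' phenotype; `0` encodes unknown parents.
#'
#' @param path PED file path.
#' @return A [pedigree_graph()].
#' @export
read_ped <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#",
                          col.names = c("family_id", "id", "father_id",
                                        "mother_id", "sex", "phenotype"))
  pedigree_graph(df$id, df$father_id, df$mother_id, sex = df$sex,
                 family_id = df$family_id)
}

#' Enumerate trios in a pedigree
#'
#' One trio per individual whose father and mother are both present in the
#' dataset. This covers parents-and-child trios and grandparents-and-parent
#' trios uniformly: a parent whose own parents are present is the child of
#' that trio.
#'
#' @param g A [pedigree_graph()].
#' @return data.frame with columns `child`, `father`, `mother`; zero rows
#'   when no trios exist.
#' @export
find_trios <- function(g) {
  stopifnot(inherits(g, "pedigree_graph"))
  has <- !is.na(g$father_id) & g$father_id %in% g$id &
         !is.na(g$mother_id) & g$mother_id %in% g$id
  data.frame(child = g$id[has], father = g$father_id[has],
             mother = g$mother_id[has], stringsAsFactors = FALSE)
}

#' Enumerate hepta-families (seven-member three-generation families)
#'
#' A hepta-family is a child, both parents, and both sets of grandparents:
#' seven distinct members. One family is reported per qualifying child, so
#' full siblings each anchor their own hepta-family.
#'
#' @param g A [pedigree_graph()].
#' @return data.frame with columns `child`, `father`, `mother`,
#'   `paternal_grandfather`, `paternal_grandmother`,
#'   `maternal_grandfather`, `maternal_grandmother`.
#' @export
find_hepta_families <- function(g) {
  stopifnot(inherits(g, "pedigree_graph"))
  trios <- find_trios(g)
  parents_of <- function(ids, col) {
    m <- match(ids, g$id)
    p <- g[[col]][m]
    ifelse(!is.na(p) & p %in% g$id, p, NA_character_)
  }
  pf <- parents_of(trios$father, "father_id")
  pm <- parents_of(trios$father, "mother_id")
  mf <- parents_of(trios$mother, "father_id")
  mm <- parents_of(trios$mother, "mother_id")
  ok <- !is.na(pf) & !is.na(pm) & !is.na(mf) & !is.na(mm)
  out <- data.frame(child = trios$child[ok], father = trios$father[ok],
                    mother = trios$mother[ok],
                    paternal_grandfather = pf[ok],
                    paternal_grandmother = pm[ok],
                    maternal_grandfather = mf[ok],
                    maternal_grandmother = mm[ok],
                    stringsAsFactors = FALSE)
  distinct <- apply(out, 1L, function(r) length(unique(r)) == 7L)
  out[distinct, , drop = FALSE]
}

#' Enumerate parent-offspring duos
#'
#' Pairs where exactly one parent is present in the dataset, counted per
#' offspring. The default mother reference follows the convention of
#' anchoring pairs on mothers (or grandmothers, which this per-offspring
#' rule covers when the offspring is itself a parent). A child with both
#' parents present forms a trio, not duos; set `include_trio_children =
#' TRUE` to count those pairs too.
#'
#' @param g A [pedigree_graph()].
#' @param reference_role `"mother"`, `"father"` or `"either"`: which present
#'   parent anchors a duo.
#' @param include_trio_children Count parent pairs for children whose other
#'   parent is also present (default `FALSE`, keeping duos and trios
#'   disjoint).
#' @return data.frame with columns `offspring`, `parent`, `parent_role`.
#' @export
find_duos <- function(g, reference_role = c("mother", "father", "either"),
                      include_trio_children = FALSE) {
  stopifnot(inherits(g, "pedigree_graph"))
  reference_role <- match.arg(reference_role)
  f_in <- !is.na(g$father_id) & g$father_id %in% g$id
  m_in <- !is.na(g$mother_id) & g$mother_id %in% g$id
  both <- f_in & m_in
  pick <- function(parent_in, other_in) {
    if (include_trio_children) parent_in else parent_in & !other_in
  }
  out <- data.frame(offspring = character(0), parent = character(0),
                    parent_role = character(0), stringsAsFactors = FALSE)
  if (reference_role %in% c("mother", "either")) {
    k <- pick(m_in, f_in)
    out <- rbind(out, data.frame(offspring = g$id[k],
                                 parent = g$mother_id[k],
                                 parent_role = rep("mother", sum(k)),
                                 stringsAsFactors = FALSE))
  }
  if (reference_role %in% c("father", "either")) {
    k <- pick(f_in, m_in)
    out <- rbind(out, data.frame(offspring = g$id[k],
                                 parent = g$father_id[k],
                                 parent_role = rep("father", sum(k)),
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Count family structures in a pedigree
#'
#' @param g A [pedigree_graph()].
#' @param ... Passed to [find_duos()].
#' @return Named list with `n_duos`, `n_trios`, `n_hepta_families`.
#' @export
pedigree_structure_counts <- function(g, ...) {
  list(n_duos = nrow(find_duos(g, ...)),
       n_trios = nrow(find_trios(g)),
       n_hepta_families = nrow(find_hepta_families(g)))
}
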
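#' Collective pattern analysis: per-group occurrence statistics
#'
#' Searches every catalog pattern in the compound set and tabulates, per
#' pattern, the presence count and percentage in the full set and in the
#' \code{direct} and \code{inconclusive} groups. A percentage is the number
#' of compounds containing the pattern divided by the group size (times
#' 100); matching is presence-only, so multiple occurrences within one
#' molecule count once. Rows are ordered by descending full-set count, ties
#' by ascending pattern id.
#'
#' @param catalog a \linkS4class{SubstructureCatalog}.
#' @param compounds a \linkS4class{CompoundSet} with group labels.
#' @param incidence optional precomputed logical matrix (compounds x
#'   patterns), e.g. from \code{\link{matchMatrix}} or a fixture ground
#'   truth; computed when NULL.
#' @return the occurrence table: a data.frame with columns
#'   \code{pattern_id}, \code{name}, \code{count_all}, \code{count_direct},
#'   \code{count_inconclusive}, \code{pct_all}, \code{pct_direct},
#'   \code{pct_inconclusive}, \code{active}. Percentages are carried at full
#'   precision; round only for display.
#' @export
collectivePatternAnalysis <- function(catalog, compounds, incidence = NULL) {
  pd <- catalog@data
  if (nrow(pd) == 0L) {
    return(data.frame(pattern_id = character(0), name = character(0),
                      count_all = integer(0), count_direct = integer(0),
                      count_inconclusive = integer(0), pct_all = numeric(0),
                      pct_direct = numeric(0), pct_inconclusive = numeric(0),
                      active = logical(0)))
  }
  if (is.null(incidence)) incidence <- matchMatrix(compounds, catalog)
  stopifnot(ncol(incidence) == nrow(pd))
  grp <- compoundGroups(compounds)
  idx_dir <- grp == "direct"
  idx_inc <- grp == "inconclusive"
  n_all <- length(grp); n_dir <- sum(idx_dir); n_inc <- sum(idx_inc)
  cnt <- function(rows) {
    if (sum(rows) == 0L) rep(0L, ncol(incidence))
    else as.integer(colSums(incidence[rows, , drop = FALSE]))
  }
  count_all <- cnt(rep(TRUE, n_all))
  count_direct <- cnt(idx_dir)
  count_inconclusive <- cnt(idx_inc)
  pct <- function(count, n) if (n == 0L) rep(NA_real_, length(count)) else 100 * count / n
  tab <- data.frame(
    pattern_id = pd$pattern_id,
    name = pd$name,
    count_all = count_all,
    count_direct = count_direct,
    count_inconclusive = count_inconclusive,
    pct_all = pct(count_all, n_all),
    pct_direct = pct(count_direct, n_dir),
    pct_inconclusive = pct(count_inconclusive, n_inc),
    active = count_all >= 1L,
    stringsAsFactors = FALSE
  )
  tab <- tab[order(-tab$count_all, tab$pattern_id), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "group_sizes") <- c(all = n_all, direct = n_dir,
                                inconclusive = n_inc)
  tab
}

#' Partition patterns into active and inactive
#'
#' A pattern is active when present in at least one compound of the set.
#' The inactive list is retained as a negative fingerprint.
#'
#' @param table an occurrence table from
#'   \code{\link{collectivePatternAnalysis}}.
#' @return list with character vectors \code{$active} and \code{$inactive}.
#' @export
classifyActive <- function(table) {
  list(active = table$pattern_id[table$active],
       inactive = table$pattern_id[!table$active])
}

# shared id-sorting: descending statistic, ascending pattern_id on ties
.sortIds <- function(ids, stat) {
  ids[order(-stat, ids)]
}

#' Extract Primary Positive Substructures
#'
#' Patterns present in at least \code{thresholdPct} percent of the chosen
#' group (default: 40\% of the direct interactors). The threshold is
#' inclusive.
#'
#' @param table occurrence table.
#' @param thresholdPct inclusive percentage threshold.
#' @param group \code{"direct"}, \code{"all"} or \code{"inconclusive"}.
#' @return pattern ids sorted by descending percentage (ties by id).
#' @export
extractPrimary <- function(table, thresholdPct = 40, group = "direct") {
  pctcol <- paste0("pct_", match.arg(group, c("direct", "all", "inconclusive")))
  pct <- table[[pctcol]]
  keep <- !is.na(pct) & pct >= thresholdPct
  .sortIds(table$pattern_id[keep], pct[keep])
}

# the 4-Atom scheme: counted atoms (defined H included, [R] excluded) and
# distinct elements, looked up from the catalog cache
.fourAtomScheme <- function(ids, catalog, minAtoms, minElements) {
  pd <- catalog@data
  i <- match(ids, pd$pattern_id)
  pd$counted_atoms[i] >= minAtoms & pd$distinct_elements[i] >= minElements
}

#' Extract 4-Atom-focused Substructures
#'
#' Patterns present in at least \code{thresholdPct} percent of the full set
#' (default 20\%) that also pass the 4-atom scheme: at least
#' \code{minAtoms} counted atoms (defined hydrogens count, attachment points
#' do not) and at least \code{minElements} distinct elements.
#'
#' @inheritParams extractPrimary
#' @param catalog the \linkS4class{SubstructureCatalog} carrying the cached
#'   counted-atom statistics.
#' @param minAtoms minimum counted atoms (inclusive).
#' @param minElements minimum distinct elements (inclusive).
#' @return pattern ids sorted by descending percentage (ties by id).
#' @export
extractFourAtom <- function(table, catalog, thresholdPct = 20, minAtoms = 4,
                            minElements = 2, group = "all") {
  pctcol <- paste0("pct_", match.arg(group, c("all", "direct", "inconclusive")))
  pct <- table[[pctcol]]
  keep <- !is.na(pct) & pct >= thresholdPct &
    .fourAtomScheme(table$pattern_id, catalog, minAtoms, minElements)
  .sortIds(table$pattern_id[keep], pct[keep])
}

#' Extract Basic Scaffolds
#'
#' Heteroaromatic ring-system patterns, selected independent of occurrence
#' frequency: any pattern containing an aromatic ring with at least one ring
#' heteroatom qualifies.
#'
#' @param catalog a \linkS4class{SubstructureCatalog}.
#' @return pattern ids in catalog order.
#' @export
extractBasicScaffolds <- function(catalog) {
  pd <- catalog@data
  pd$pattern_id[pd$is_heteroaromatic_scaffold]
}

#' Extract Secondary Positive Substructures
#'
#' Patterns present in at least \code{minCount} of the inconclusive
#' compounds (an absolute count: the rule is stated as 40\% of 12 compounds
#' = 5 compounds, and the printed count wins over the exact percentage),
#' passing the same 4-atom scheme, and not already in any of the excluded
#' lists.
#'
#' @inheritParams extractFourAtom
#' @param minCount inclusive minimum presence count in the inconclusive
#'   group.
#' @param exclude character vector of pattern ids to exclude (typically the
#'   union of the other three fingerprint components).
#' @return pattern ids sorted by descending inconclusive count (ties by id).
#' @export
extractSecondary <- function(table, catalog, minCount = 5,
                             exclude = character(0), minAtoms = 4,
                             minElements = 2) {
  keep <- table$count_inconclusive >= minCount &
    .fourAtomScheme(table$pattern_id, catalog, minAtoms, minElements) &
    !(table$pattern_id %in% exclude)
  .sortIds(table$pattern_id[keep], table$count_inconclusive[keep])
}

#' Extract the full focused fingerprint
#'
#' Runs the four extraction rules and assembles a
#' \linkS4class{FocusedFingerprint}. Basic Scaffolds are reordered by
#' descending full-set occurrence to fix the left-right column order of the
#' binary pattern distribution scheme.
#'
#' @inheritParams extractFourAtom
#' @param primaryPct inclusive percentage threshold for the primary rule.
#' @param fourAtomPct inclusive percentage threshold for the 4-atom rule.
#' @param secondaryMinCount inclusive count threshold for the secondary rule.
#' @param fourAtomGroup denominator group for the 4-atom rule.
#' @return a \linkS4class{FocusedFingerprint}.
#' @export
extractFingerprint <- function(table, catalog, primaryPct = 40,
                               fourAtomPct = 20, minAtoms = 4,
                               minElements = 2, secondaryMinCount = 5,
                               fourAtomGroup = "all") {
  primary <- extractPrimary(table, thresholdPct = primaryPct)
  four_atom <- extractFourAtom(table, catalog, thresholdPct = fourAtomPct,
                               minAtoms = minAtoms, minElements = minElements,
                               group = fourAtomGroup)
  basic <- extractBasicScaffolds(catalog)
  cnt <- table$count_all[match(basic, table$pattern_id)]
  cnt[is.na(cnt)] <- 0L
  basic <- .sortIds(basic, cnt)
  secondary <- extractSecondary(table, catalog, minCount = secondaryMinCount,
                                exclude = union(union(primary, four_atom), basic),
                                minAtoms = minAtoms, minElements = minElements)
  new("FocusedFingerprint",
      primary = primary, fourAtom = four_atom, basicScaffold = basic,
      secondary = secondary,
      ruleConfig = list(primary_pct = primaryPct, four_atom_pct = fourAtomPct,
                        min_atoms = minAtoms, min_elements = minElements,
                        secondary_min_count = secondaryMinCount,
                        four_atom_group = fourAtomGroup))
}

#' Write fingerprint JSON
#'
#' @param fingerprint a \linkS4class{FocusedFingerprint}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeFingerprint <- function(fingerprint, path) {
  jsonlite::write_json(
    list(primary = fingerprint@primary,
         four_atom = fingerprint@fourAtom,
         basic_scaffold = fingerprint@basicScaffold,
         secondary = fingerprint@secondary,
         rule_config = fingerprint@ruleConfig),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname writeFingerprint
#' @export
readFingerprint <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_chr <- function(x) if (length(x) == 0L) character(0) else as.character(x)
  new("FocusedFingerprint",
      primary = as_chr(j$primary), fourAtom = as_chr(j$four_atom),
      basicScaffold = as_chr(j$basic_scaffold),
      secondary = as_chr(j$secondary),
      ruleConfig = as.list(j$rule_config))
}
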
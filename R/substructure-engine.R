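#' Parse one catalog pattern
#'
#' Parses a SMILES-like catalog pattern and populates the counted-atom
#' statistics. \code{[R]} tokens are wildcard attachment points (they do not
#' count as atoms); \code{[H]} tokens are defined, irreplaceable hydrogens
#' (they do count). Distinct elements are counted over the counted atoms,
#' hydrogen included, attachment points excluded.
#'
#' @param id pattern identifier (e.g. \code{"0044"}).
#' @param name human-readable pattern name.
#' @param smiles_pattern the pattern string.
#' @param rMatchesH if TRUE (default), an attachment point may also be
#'   unsubstituted (maps to hydrogen); if FALSE it must bear a heavy atom.
#' @return one-row data.frame with columns \code{pattern_id}, \code{name},
#'   \code{smiles_pattern}, \code{counted_atoms}, \code{defined_h},
#'   \code{distinct_elements}, \code{is_heteroaromatic_scaffold},
#'   \code{smarts} (the translated query) and \code{normal_form} (the
#'   canonical dedup key).
#' @examples
#' parsePattern("0044", "hydroxy-H, defined (1H; OH)", "O[H]")
#' @export
parsePattern <- function(id, name, smiles_pattern, rMatchesH = TRUE) {
  g <- .parseSmilesGraph(smiles_pattern, id = id)
  st <- .patternStats(g)
  data.frame(
    pattern_id = as.character(id),
    name = as.character(name),
    smiles_pattern = smiles_pattern,
    counted_atoms = st$counted_atoms,
    defined_h = st$defined_h,
    distinct_elements = st$distinct_elements,
    is_heteroaromatic_scaffold = st$is_heteroaromatic_scaffold,
    smarts = .graphToSmarts(g, rMatchesH = rMatchesH),
    normal_form = .patternNormalForm(g),
    stringsAsFactors = FALSE
  )
}

#' Build a SubstructureCatalog
#'
#' @param pattern_id,name,smiles_pattern parallel character vectors.
#' @param provenance free-text provenance string.
#' @param rMatchesH attachment-point semantics, see \code{\link{parsePattern}}.
#' @return a \linkS4class{SubstructureCatalog}.
#' @export
makeCatalog <- function(pattern_id, name = pattern_id, smiles_pattern,
                        provenance = "", rMatchesH = TRUE) {
  stopifnot(length(pattern_id) == length(smiles_pattern))
  name <- rep_len(name, length(pattern_id))
  rows <- lapply(seq_along(pattern_id), function(i) {
    parsePattern(pattern_id[i], name[i], smiles_pattern[i],
                 rMatchesH = rMatchesH)
  })
  new("SubstructureCatalog", data = do.call(rbind, rows),
      provenance = provenance)
}

#' Read / write a substructure catalog CSV
#'
#' Catalog CSVs carry \code{pattern_id}, \code{name}, \code{smiles_pattern};
#' cached statistics columns are ignored on read (they are recomputed) and
#' written out for reference.
#'
#' @param path CSV file path.
#' @param rMatchesH attachment-point semantics, see \code{\link{parsePattern}}.
#' @return a \linkS4class{SubstructureCatalog}.
#' @export
readCatalog <- function(path, rMatchesH = TRUE) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                       colClasses = c(pattern_id = "character"))
  need <- c("pattern_id", "name", "smiles_pattern")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0L) {
    stop(sprintf("catalog CSV lacks column(s): %s", paste(miss, collapse = ", ")))
  }
  makeCatalog(d$pattern_id, d$name, d$smiles_pattern,
              provenance = path, rMatchesH = rMatchesH)
}

#' @rdname readCatalog
#' @param catalog a \linkS4class{SubstructureCatalog}.
#' @param header_comment optional \code{#} header lines.
#' @export
writeCatalog <- function(catalog, path, header_comment = NULL) {
  writeTableCsv(catalog@data[, c("pattern_id", "name", "smiles_pattern",
                                 "counted_atoms", "defined_h",
                                 "distinct_elements",
                                 "is_heteroaromatic_scaffold")],
                path, header_comment = header_comment)
}

#' Substructure presence matching
#'
#' \code{matchMatrix} evaluates every catalog pattern against every compound
#' and returns a logical presence matrix (compounds x patterns).
#' \code{matchesPattern} is the scalar form. Matching is presence-only
#' (quantity-blind) and stereo-blind; defined \code{[H]} positions must bear
#' a hydrogen in the molecule; attachment points follow the semantics fixed
#' when the catalog was parsed.
#'
#' @param compounds a \linkS4class{CompoundSet}, or a character vector of
#'   SMILES.
#' @param catalog a \linkS4class{SubstructureCatalog}, or a one-row pattern
#'   data.frame from \code{\link{parsePattern}}.
#' @return \code{matchMatrix}: logical matrix with compound ids as rownames
#'   and pattern ids as colnames. \code{matchesPattern}: logical vector.
#' @examples
#' cat <- makeCatalog("p1", "phenol-like", "O[H]")
#' matchesPattern(c("Oc1ccccc1", "COc1ccccc1"), cat)
#' @export
matchMatrix <- function(compounds, catalog) {
  smiles <- if (is(compounds, "CompoundSet")) {
    canonicalSmiles(compounds)
  } else {
    stats::setNames(as.character(compounds),
                    names(compounds) %||% as.character(compounds))
  }
  pd <- if (is(catalog, "SubstructureCatalog")) catalog@data else catalog
  out <- matrix(FALSE, nrow = length(smiles), ncol = nrow(pd),
                dimnames = list(names(smiles), pd$pattern_id))
  if (length(smiles) == 0L || nrow(pd) == 0L) return(out)
  for (i in seq_along(smiles)) {
    mol <- .obMol(smiles[[i]])
    out[i, ] <- vapply(pd$smarts, function(sm) .obMatches(mol, sm), FALSE,
                       USE.NAMES = FALSE)
  }
  out
}

#' @rdname matchMatrix
#' @export
matchesPattern <- function(compounds, catalog) {
  m <- matchMatrix(compounds, catalog)
  if (ncol(m) == 1L) stats::setNames(m[, 1L], rownames(m)) else m
}

#' Define a heavy-atom substitution scheme
#'
#' A scheme is a set of disjoint classes of interchangeable atom
#' specifications used to derivatize catalog fragments (scaffold
#' fragmentation / substructure hopping). Each class member is an element
#' symbol; lower case restricts to aromatic positions, upper case with
#' \code{aromatic = "any"} applies anywhere.
#'
#' @param classes list of character vectors, e.g.
#'   \code{list(c("c", "n"), c("O", "S"))} for aromatic C<->N and O<->S.
#' @param positions \code{"all"}, \code{"ring-only"} or
#'   \code{"sidechain-only"}.
#' @param maxSubstitutions maximum substitutions per fragment (>= 1).
#' @return an object of class \code{SubstitutionScheme} (a validated list).
#' @export
substitutionScheme <- function(classes = list(c("c", "n"), c("O", "S")),
                               positions = c("all", "ring-only",
                                             "sidechain-only"),
                               maxSubstitutions = 1L) {
  positions <- match.arg(positions)
  stopifnot(maxSubstitutions >= 1L)
  parsed <- lapply(classes, function(cl) {
    data.frame(
      element = vapply(cl, function(e) {
        paste0(toupper(substring(e, 1, 1)), substring(e, 2))
      }, ""),
      aromatic_only = vapply(cl, function(e) {
        substring(e, 1, 1) %in% letters
      }, FALSE),
      stringsAsFactors = FALSE
    )
  })
  all_members <- unlist(lapply(parsed, function(p) p$element))
  if (anyDuplicated(all_members)) {
    stop("substitution classes must be disjoint")
  }
  structure(list(classes = parsed, positions = positions,
                 maxSubstitutions = as.integer(maxSubstitutions)),
            class = "SubstitutionScheme")
}

# integer-valence sanity check for a substitution product
.validValences <- function(g) {
  A <- g$atoms; B <- g$bonds
  bsum <- numeric(nrow(A))
  if (nrow(B) > 0L) {
    contrib <- ifelse(B$aromatic, 1, B$order)
    for (k in seq_len(nrow(B))) {
      bsum[B$a1[k]] <- bsum[B$a1[k]] + contrib[k]
      bsum[B$a2[k]] <- bsum[B$a2[k]] + contrib[k]
    }
  }
  for (i in seq_len(nrow(A))) {
    if (A$isR[i]) next
    vals <- .DEFAULT_VALENCE[[A$element[i]]]
    if (is.null(vals)) next
    if (bsum[i] + A$hdef[i] > max(vals) + A$charge[i]) return(FALSE)
  }
  TRUE
}

#' Enumerate heavy-atom substituted derivatives of a fragment
#'
#' Applies a substitution scheme to a catalog fragment: every combination of
#' up to \code{maxSubstitutions} within-class atom replacements is generated,
#' chemically invalid products are discarded, and duplicates are removed by
#' canonical normalization. The input fragment is always element one of the
#' result.
#'
#' @param fragment a one-row pattern data.frame (from
#'   \code{\link{parsePattern}}) or a pattern SMILES string.
#' @param scheme a \code{\link{substitutionScheme}}; an empty scheme returns
#'   the input alone.
#' @param idPrefix prefix for generated pattern ids.
#' @return data.frame of patterns (same columns as
#'   \code{\link{parsePattern}}).
#' @examples
#' enumerateSubstitutions("c1ccccc1",
#'   substitutionScheme(list(c("c", "n")), maxSubstitutions = 1))
#' @export
enumerateSubstitutions <- function(fragment, scheme = substitutionScheme(),
                                   idPrefix = "sub") {
  if (is.character(fragment)) {
    fragment <- parsePattern(idPrefix, idPrefix, fragment)
  }
  g0 <- .parseSmilesGraph(fragment$smiles_pattern, id = fragment$pattern_id)
  seen <- .patternNormalForm(g0)
  out <- list(fragment)
  if (length(scheme$classes) == 0L) return(fragment)

  ring_atom <- rep(FALSE, nrow(g0$atoms))
  if (nrow(g0$bonds) > 0L) {
    rb <- g0$bonds[g0$bonds$in_ring, , drop = FALSE]
    ring_atom[unique(c(rb$a1, rb$a2))] <- TRUE
  }
  pos_ok <- switch(scheme$positions,
                   "all" = rep(TRUE, nrow(g0$atoms)),
                   "ring-only" = ring_atom,
                   "sidechain-only" = !ring_atom)

  # all single-site replacements available on a graph
  moves <- function(g) {
    res <- list()
    for (cl in scheme$classes) {
      for (i in seq_len(nrow(g$atoms))) {
        if (g$atoms$isR[i] || !pos_ok[i]) next
        row <- which(cl$element == g$atoms$element[i] &
                       (!cl$aromatic_only | g$atoms$aromatic[i]))
        if (length(row) == 0L) next
        for (j in seq_len(nrow(cl))) {
          if (cl$element[j] == g$atoms$element[i]) next
          if (cl$aromatic_only[j] && !g$atoms$aromatic[i]) next
          res[[length(res) + 1L]] <- list(atom = i, element = cl$element[j])
        }
      }
    }
    res
  }

  frontier <- list(g0)
  counter <- 0L
  for (depth in seq_len(scheme$maxSubstitutions)) {
    nxt <- list()
    for (g in frontier) {
      for (mv in moves(g)) {
        g2 <- g
        g2$atoms$element[mv$atom] <- mv$element
        if (!.validValences(g2)) next
        nf <- tryCatch(.patternNormalForm(g2), error = function(e) NA_character_)
        if (is.na(nf) || nf %in% seen) next
        # product must survive canonical parsing (chemical validity)
        smi <- tryCatch(.graphToSmiles(g2), error = function(e) NA_character_)
        if (is.na(smi)) next
        probe <- .obCanonical(gsub("\\[R\\]", "*", smi))
        if (is.na(probe)) next
        seen <- c(seen, nf)
        counter <- counter + 1L
        row <- parsePattern(sprintf("%s_%d", idPrefix, counter),
                            sprintf("%s (derivative %d)", fragment$name, counter),
                            smi)
        out[[length(out) + 1L]] <- row
        nxt[[length(nxt) + 1L]] <- g2
      }
    }
    frontier <- nxt
    if (length(frontier) == 0L) break
  }
  do.call(rbind, out)
}

#' @describeIn deduplicate Remove catalog entries sharing a normalized
#'   pattern; the earlier identifier wins.
#' @export
setMethod("deduplicate", "SubstructureCatalog", function(x, ...) {
  d <- x@data
  key <- d$normal_form
  keep_first <- !duplicated(key)
  kept_for <- d$pattern_id[match(key, key[keep_first])]
  report <- data.frame(removed_id = d$pattern_id[!keep_first],
                       kept_id = kept_for[!keep_first],
                       normal_form = key[!keep_first],
                       stringsAsFactors = FALSE)
  list(catalog = new("SubstructureCatalog",
                     data = d[keep_first, , drop = FALSE],
                     provenance = x@provenance),
       report = report)
})

#' Merge and deduplicate catalogs
#'
#' Concatenates catalogs in order and removes duplicate patterns by
#' normalized form; the earlier identifier wins, honoring established
#' nomenclature of prior catalogs.
#'
#' @param ... \linkS4class{SubstructureCatalog} objects.
#' @return a deduplicated \linkS4class{SubstructureCatalog}.
#' @export
catalogDedup <- function(...) {
  cats <- list(...)
  d <- do.call(rbind, lapply(cats, function(x) x@data))
  # dedup on the raw table: the merged intermediate may repeat ids
  keep <- !duplicated(d$normal_form) & !duplicated(d$pattern_id)
  new("SubstructureCatalog", data = d[keep, , drop = FALSE],
      provenance = paste(Filter(nzchar, vapply(cats, function(x) x@provenance, "")),
                         collapse = " + "))
}
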
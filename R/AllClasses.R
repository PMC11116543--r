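#' @import methods
NULL

.COMPOUND_GROUPS <- c("direct", "inconclusive", "library", "unassigned")

#' CompoundSet: a curated table of molecules
#'
#' An ordered collection of compound records, each carrying the structure as
#' given (\code{smiles_input}), its canonical isomeric SMILES
#' (\code{smiles_canonical}), a group membership (\code{direct},
#' \code{inconclusive}, \code{library} or \code{unassigned}), target
#' annotations and opaque external identifiers. The \code{direct} and
#' \code{inconclusive} groups model the two curated subsets of a multitarget
#' dataset (proven/strongly suggested direct interactors vs. compounds with
#' inconclusive evidence); \code{library} marks screening-library members.
#'
#' @slot data data.frame with columns \code{compound_id}, \code{name},
#'   \code{smiles_input}, \code{smiles_canonical}, \code{group},
#'   \code{source_ref} and list-columns \code{targets}, \code{external_ids}.
#' @slot label character scalar naming the set.
#' @exportClass CompoundSet
setClass("CompoundSet",
  representation(data = "data.frame", label = "character"),
  prototype(data = data.frame(), label = "")
)

setValidity("CompoundSet", function(object) {
  d <- object@data
  msgs <- character(0)
  need <- c("compound_id", "name", "smiles_input", "smiles_canonical",
            "group", "source_ref")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0L) {
    msgs <- c(msgs, paste("missing columns:", paste(miss, collapse = ", ")))
  } else {
    if (anyDuplicated(d$compound_id)) {
      msgs <- c(msgs, "compound_id values must be unique")
    }
    bad <- !d$group %in% .COMPOUND_GROUPS
    if (any(bad)) {
      msgs <- c(msgs, paste("invalid group label(s):",
                            paste(unique(d$group[bad]), collapse = ", ")))
    }
  }
  if (length(object@label) != 1L) msgs <- c(msgs, "label must be a single string")
  if (length(msgs) > 0L) msgs else TRUE
})

#' SubstructureCatalog: a table of substructure patterns
#'
#' Each row is one catalog pattern: a SMILES-like string that may contain
#' \code{[H]} tokens (defined, irreplaceable hydrogens) and \code{[R]} tokens
#' (attachment points). Cached per-pattern statistics follow the counting
#' rule: heavy atoms and defined hydrogens count, attachment points do not;
#' distinct elements are counted over the counted atoms.
#'
#' @slot data data.frame with columns \code{pattern_id}, \code{name},
#'   \code{smiles_pattern}, \code{counted_atoms}, \code{defined_h},
#'   \code{distinct_elements}, \code{is_heteroaromatic_scaffold},
#'   \code{smarts}, \code{normal_form}.
#' @slot provenance character scalar.
#' @exportClass SubstructureCatalog
setClass("SubstructureCatalog",
  representation(data = "data.frame", provenance = "character"),
  prototype(data = data.frame(), provenance = "")
)

setValidity("SubstructureCatalog", function(object) {
  d <- object@data
  msgs <- character(0)
  need <- c("pattern_id", "name", "smiles_pattern", "counted_atoms",
            "defined_h", "distinct_elements", "is_heteroaromatic_scaffold",
            "smarts", "normal_form")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0L) {
    msgs <- c(msgs, paste("missing columns:", paste(miss, collapse = ", ")))
  } else if (nrow(d) > 0L) {
    if (anyDuplicated(d$pattern_id)) msgs <- c(msgs, "pattern_id values must be unique")
    if (any(d$counted_atoms < 1L)) msgs <- c(msgs, "counted_atoms must be >= 1")
    if (any(d$defined_h > d$counted_atoms)) {
      msgs <- c(msgs, "defined_h cannot exceed counted_atoms")
    }
  }
  if (length(msgs) > 0L) msgs else TRUE
})

#' FocusedFingerprint: the four rule-extracted substructure sets
#'
#' Holds the pattern identifiers of the Primary Positive Substructures
#' (conjunctive screening filter), the 4-Atom-focused Substructures (the
#' scoring set), the Basic Scaffolds (heteroaromatic ring systems, selected
#' irrespective of frequency) and the Secondary Positive Substructures
#' (manual-triage support), together with the rule thresholds that produced
#' them.
#'
#' @slot primary character vector of pattern ids.
#' @slot fourAtom character vector of pattern ids.
#' @slot basicScaffold character vector of pattern ids.
#' @slot secondary character vector of pattern ids.
#' @slot ruleConfig named list of the thresholds used.
#' @exportClass FocusedFingerprint
setClass("FocusedFingerprint",
  representation(primary = "character", fourAtom = "character",
                 basicScaffold = "character", secondary = "character",
                 ruleConfig = "list"),
  prototype(primary = character(0), fourAtom = character(0),
            basicScaffold = character(0), secondary = character(0),
            ruleConfig = list())
)

setValidity("FocusedFingerprint", function(object) {
  msgs <- character(0)
  for (nm in c("primary", "fourAtom", "basicScaffold", "secondary")) {
    v <- slot(object, nm)
    if (anyDuplicated(v)) msgs <- c(msgs, sprintf("duplicate ids in %s", nm))
  }
  if (length(msgs) > 0L) msgs else TRUE
})

#' BinaryPatternMatrix: compounds x patterns presence matrix with scores
#'
#' The binary pattern distribution scheme: one row per compound, one 0/1
#' column per fingerprint pattern (4-Atom columns first, then Basic Scaffold
#' columns, each ordered by occurrence). The per-compound score is the number
#' of 4-Atom patterns present; rows are ordered by descending score.
#'
#' @slot bits integer matrix (0/1) with compound ids as rownames and pattern
#'   ids as colnames.
#' @slot fourAtomIds character, the columns contributing to the score.
#' @slot basicScaffoldIds character.
#' @slot scores named integer vector, parallel to the rows.
#' @exportClass BinaryPatternMatrix
setClass("BinaryPatternMatrix",
  representation(bits = "matrix", fourAtomIds = "character",
                 basicScaffoldIds = "character", scores = "integer"),
  prototype(bits = matrix(integer(0), 0, 0), fourAtomIds = character(0),
            basicScaffoldIds = character(0), scores = integer(0))
)

setValidity("BinaryPatternMatrix", function(object) {
  msgs <- character(0)
  b <- object@bits
  if (!identical(colnames(b), c(object@fourAtomIds, object@basicScaffoldIds))) {
    msgs <- c(msgs, "columns must be fourAtomIds then basicScaffoldIds")
  }
  if (length(object@scores) != nrow(b)) {
    msgs <- c(msgs, "scores must parallel the rows")
  } else if (nrow(b) > 0L) {
    fa <- object@fourAtomIds
    rs <- as.integer(rowSums(b[, fa, drop = FALSE]))
    if (!identical(rs, unname(object@scores))) {
      msgs <- c(msgs, "score must equal the row sum over 4-Atom columns")
    }
    if (is.unsorted(rev(object@scores))) {
      msgs <- c(msgs, "rows must be sorted by descending score")
    }
    if (!all(b %in% c(0L, 1L))) msgs <- c(msgs, "cells must be 0/1")
  }
  if (length(msgs) > 0L) msgs else TRUE
})

# ---- show methods -----------------------------------------------------------

setMethod("show", "CompoundSet", function(object) {
  d <- object@data
  tab <- table(factor(d$group, levels = .COMPOUND_GROUPS))
  cat(sprintf("CompoundSet '%s' with %d compound(s)\n",
              object@label, nrow(d)))
  cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  if (nrow(d) > 0L) {
    shown <- utils::head(d$compound_id, 5L)
    cat("  ids:", paste(shown, collapse = ", "),
        if (nrow(d) > 5L) "..." else "", "\n")
  }
})

setMethod("show", "SubstructureCatalog", function(object) {
  d <- object@data
  cat(sprintf("SubstructureCatalog with %d pattern(s)\n", nrow(d)))
  if (nzchar(object@provenance)) cat("  provenance:", object@provenance, "\n")
  if (nrow(d) > 0L) {
    cat(sprintf("  counted atoms: %d-%d; %d heteroaromatic scaffold(s)\n",
                min(d$counted_atoms), max(d$counted_atoms),
                sum(d$is_heteroaromatic_scaffold)))
  }
})

setMethod("show", "FocusedFingerprint", function(object) {
  cat("FocusedFingerprint\n")
  cat(sprintf("  primary:        %d pattern(s)\n", length(object@primary)))
  cat(sprintf("  4-atom:         %d pattern(s)\n", length(object@fourAtom)))
  cat(sprintf("  basic scaffold: %d pattern(s)\n", length(object@basicScaffold)))
  cat(sprintf("  secondary:      %d pattern(s)\n", length(object@secondary)))
})

setMethod("show", "BinaryPatternMatrix", function(object) {
  cat(sprintf("BinaryPatternMatrix: %d compound(s) x %d pattern(s) (%d scoring)\n",
              nrow(object@bits), ncol(object@bits), length(object@fourAtomIds)))
  if (nrow(object@bits) > 0L) {
    cat(sprintf("  scores: max=%d min=%d\n",
                max(object@scores), min(object@scores)))
  }
})

# ---- basic accessors --------------------------------------------------------

#' @describeIn CompoundSet number of compounds
#' @param x a CompoundSet
#' @export
setMethod("length", "CompoundSet", function(x) nrow(x@data))

#' @describeIn SubstructureCatalog number of patterns
#' @param x a SubstructureCatalog
#' @export
setMethod("length", "SubstructureCatalog", function(x) nrow(x@data))

#' Subset a CompoundSet by position, id or logical mask
#' @param x a CompoundSet
#' @param i index vector (integer, logical, or compound ids)
#' @param j,drop,... ignored
#' @export
setMethod("[", "CompoundSet", function(x, i, j, ..., drop = FALSE) {
  d <- x@data
  if (is.character(i)) i <- match(i, d$compound_id)
  new("CompoundSet", data = d[i, , drop = FALSE], label = x@label)
})

#' Subset a SubstructureCatalog by position, id or logical mask
#' @param x a SubstructureCatalog
#' @param i index vector (integer, logical, or pattern ids)
#' @param j,drop,... ignored
#' @export
setMethod("[", "SubstructureCatalog", function(x, i, j, ..., drop = FALSE) {
  d <- x@data
  if (is.character(i)) i <- match(i, d$pattern_id)
  new("SubstructureCatalog", data = d[i, , drop = FALSE],
      provenance = x@provenance)
})
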
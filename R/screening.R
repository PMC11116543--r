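#' Conjunctive primary-substructure filter
#'
#' Keeps only the library molecules that contain every required pattern
#' (logical AND over the Primary Positive Substructures). Patterns listed in
#' \code{excludedIds} are dropped from the requirement first — the published
#' workflow excluded the defined-hydroxy pattern because requiring it
#' over-restricted the library. Input order is preserved.
#'
#' @param library a \linkS4class{CompoundSet}.
#' @param catalog a \linkS4class{SubstructureCatalog}.
#' @param requiredIds pattern ids that must all be present.
#' @param excludedIds pattern ids removed from the requirement.
#' @return the filtered \linkS4class{CompoundSet} (a subset of the input).
#' @export
conjunctiveFilter <- function(library, catalog, requiredIds,
                              excludedIds = character(0)) {
  required <- setdiff(requiredIds, excludedIds)
  if (length(required) == 0L) {
    stop("no required patterns remain after exclusions")
  }
  missing <- setdiff(required, patternIds(catalog))
  if (length(missing) > 0L) {
    stop(sprintf("required pattern id(s) not in catalog: %s",
                 paste(missing, collapse = ", ")))
  }
  inc <- matchMatrix(library, catalog[required])
  keep <- rowSums(inc) == length(required)
  library[which(keep)]
}

#' Build the binary pattern distribution scheme
#'
#' One row per compound, one 0/1 column per fingerprint pattern: 4-Atom
#' columns first, then Basic Scaffold columns (each already ordered by
#' occurrence in the fingerprint). Cells record presence only (quantity is
#' ignored). The per-compound score is the number of 4-Atom patterns
#' present; rows are sorted by descending score, ties by ascending compound
#' id.
#'
#' @param compounds a \linkS4class{CompoundSet} (e.g. the filtered library).
#' @param fingerprint a \linkS4class{FocusedFingerprint} with non-empty
#'   4-Atom and Basic Scaffold components.
#' @param catalog the \linkS4class{SubstructureCatalog}.
#' @param incidence optional precomputed logical incidence matrix over
#'   \code{c(fourAtomIds, basicScaffoldIds)} columns.
#' @return a \linkS4class{BinaryPatternMatrix}.
#' @export
buildBinaryMatrix <- function(compounds, fingerprint, catalog,
                              incidence = NULL) {
  fa <- fingerprint@fourAtom
  bs <- fingerprint@basicScaffold
  if (length(fa) == 0L || length(bs) == 0L) {
    stop("fingerprint must have non-empty 4-Atom and Basic Scaffold sets")
  }
  # a pattern may satisfy both rules; it appears once, in the scoring block
  bs <- setdiff(bs, fa)
  cols <- c(fa, bs)
  if (is.null(incidence)) {
    incidence <- matchMatrix(compounds, catalog[cols])
  } else {
    incidence <- incidence[, cols, drop = FALSE]
  }
  bits <- matrix(as.integer(incidence), nrow = nrow(incidence),
                 dimnames = dimnames(incidence))
  scores <- as.integer(rowSums(bits[, fa, drop = FALSE]))
  ord <- order(-scores, rownames(bits))
  bits <- bits[ord, , drop = FALSE]
  scores <- stats::setNames(scores[ord], rownames(bits))
  new("BinaryPatternMatrix", bits = bits, fourAtomIds = fa,
      basicScaffoldIds = bs, scores = scores)
}

#' Rank candidates by 4-Atom score
#'
#' @param matrix a \linkS4class{BinaryPatternMatrix}.
#' @return data.frame (\code{compound_id}, \code{score}) in descending score
#'   order, ties by ascending compound id; stable across runs.
#' @export
rankCandidates <- function(matrix) {
  data.frame(compound_id = rownames(matrix@bits),
             score = unname(matrix@scores),
             stringsAsFactors = FALSE)
}

#' Default scaffold-class definitions
#'
#' The twelve selection classes of the published workflow, as inclusion /
#' exclusion substructure queries plus an inclusive 4-Atom score window:
#' the top-score pseudo-class (no structural query), 1,2,5-oxadiazoles,
#' pyrroles (no indoles), pyridines (no quinolines, but isoquinolines
#' qualify), thiazoles (benzothiazoles included), pyrimidines (no
#' quinazolines), quinolines, thiophenes (benzothiophenes included), indoles,
#' furans (no benzofurans), pyridyl-cations (typically an empty class),
#' quinazolines (no quinazolinones) and benzofurans.
#'
#' @param path optional JSON file to read class definitions from instead
#'   (fields \code{class_name}, \code{include_pattern}, \code{exclude_patterns},
#'   \code{score_window}, \code{top_n}).
#' @return list of class definition lists.
#' @export
defaultScaffoldClasses <- function(path = system.file("extdata",
                                                      "scaffold_classes.json",
                                                      package = "capscore")) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(j, function(cl) {
    list(class_name = cl$class_name,
         include_pattern = cl$include_pattern %||% NA_character_,
         exclude_patterns = as.character(unlist(cl$exclude_patterns %||% list())),
         score_window = if (!is.null(cl$score_window)) {
           as.integer(unlist(cl$score_window))
         },
         top_n = if (!is.null(cl$top_n)) as.integer(cl$top_n))
  })
}

#' Scaffold-class-based candidate selection
#'
#' For each class definition: members are the molecules matching the
#' inclusion query and none of the exclusion queries; the member list is
#' then restricted to the inclusive score window (on the 4-Atom score) or to
#' the top \code{top_n} by rank. The top-score pseudo-class has no
#' structural query and uses only its score window. A compound may appear in
#' several classes.
#'
#' @param matrix a \linkS4class{BinaryPatternMatrix} of the candidates.
#' @param library the \linkS4class{CompoundSet} the matrix was built from.
#' @param classDefs list of class definitions
#'   (\code{\link{defaultScaffoldClasses}} format).
#' @return named list (one entry per class) of data.frames with
#'   \code{compound_id} and \code{score}, in descending score order.
#' @export
classSelect <- function(matrix, library, classDefs = defaultScaffoldClasses()) {
  ranked <- rankCandidates(matrix)
  smiles <- canonicalSmiles(library)[ranked$compound_id]
  out <- list()
  for (cl in classDefs) {
    if (is.null(cl$class_name)) stop("class definition without class_name")
    members <- rep(TRUE, nrow(ranked))
    if (!is.null(cl$include_pattern) && !is.na(cl$include_pattern)) {
      inc_pat <- tryCatch(
        parsePattern(cl$class_name, cl$class_name, cl$include_pattern),
        error = function(e) {
          stop(sprintf("class '%s': unparseable include pattern: %s",
                       cl$class_name, conditionMessage(e)))
        })
      members <- members & unname(matchesPattern(smiles, inc_pat))
    }
    for (ex in cl$exclude_patterns) {
      ex_pat <- tryCatch(
        parsePattern(cl$class_name, cl$class_name, ex),
        error = function(e) {
          stop(sprintf("class '%s': unparseable exclude pattern: %s",
                       cl$class_name, conditionMessage(e)))
        })
      members <- members & !unname(matchesPattern(smiles, ex_pat))
    }
    sel <- ranked[members, , drop = FALSE]
    if (!is.null(cl$score_window)) {
      w <- range(cl$score_window)
      sel <- sel[sel$score >= w[1] & sel$score <= w[2], , drop = FALSE]
    }
    if (!is.null(cl$top_n)) {
      sel <- utils::head(sel, cl$top_n)
    }
    rownames(sel) <- NULL
    out[[cl$class_name]] <- sel
  }
  out
}

#' Summarize a scaffold-class selection
#'
#' @param selection result of \code{\link{classSelect}}.
#' @return data.frame with per-class \code{n}, \code{score_min},
#'   \code{score_max} and \code{score_mean} (1 decimal); empty classes
#'   report NA statistics.
#' @export
summarizeSelection <- function(selection) {
  rows <- lapply(names(selection), function(nm) {
    s <- selection[[nm]]$score
    if (length(s) == 0L) {
      data.frame(class_name = nm, n = 0L, score_min = NA_integer_,
                 score_max = NA_integer_, score_mean = NA_real_,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(class_name = nm, n = length(s), score_min = min(s),
                 score_max = max(s), score_mean = round(mean(s), 1),
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Write a binary pattern matrix CSV
#'
#' First columns \code{compound_id} and \code{score}, then one 0/1 column
#' per pattern in matrix order.
#'
#' @param matrix a \linkS4class{BinaryPatternMatrix}.
#' @param path output path.
#' @param header_comment optional \code{#} header lines.
#' @return invisibly, the path.
#' @export
writeBinaryMatrix <- function(matrix, path, header_comment = NULL) {
  d <- data.frame(compound_id = rownames(matrix@bits),
                  score = unname(matrix@scores),
                  stringsAsFactors = FALSE, check.names = FALSE)
  d <- cbind(d, as.data.frame(matrix@bits, check.names = FALSE))
  writeTableCsv(d, path, header_comment = header_comment)
}
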
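#' @include AllClasses.R
NULL

#' Compound identifiers
#' @param x a CompoundSet or BinaryPatternMatrix
#' @return character vector of compound ids
#' @export
setGeneric("compoundIds", function(x) standardGeneric("compoundIds"))

#' Canonical SMILES of a CompoundSet
#' @param x a CompoundSet
#' @return named character vector of canonical SMILES
#' @export
setGeneric("canonicalSmiles", function(x) standardGeneric("canonicalSmiles"))

#' Group labels of a CompoundSet
#' @param x a CompoundSet
#' @return named character vector of group labels
#' @export
setGeneric("compoundGroups", function(x) standardGeneric("compoundGroups"))

#' Underlying record table
#' @param x a CompoundSet or SubstructureCatalog
#' @return the data.frame of records
#' @export
setGeneric("recordTable", function(x) standardGeneric("recordTable"))

#' Pattern identifiers
#' @param x a SubstructureCatalog
#' @return character vector of pattern ids
#' @export
setGeneric("patternIds", function(x) standardGeneric("patternIds"))

#' Remove duplicate records
#'
#' @param x a CompoundSet (duplicate = identical canonical isomeric SMILES)
#'   or SubstructureCatalog (duplicate = identical normalized pattern).
#' @param ... further arguments for methods
#' @return a list with the deduplicated object (\code{$set} or
#'   \code{$catalog}) and a \code{$report} data.frame mapping each removed
#'   record to the kept one.
#' @export
setGeneric("deduplicate", function(x, ...) standardGeneric("deduplicate"))

#' Pattern presence bits
#' @param x a BinaryPatternMatrix
#' @return the 0/1 integer matrix
#' @export
setGeneric("patternBits", function(x) standardGeneric("patternBits"))

#' Per-compound 4-Atom scores
#' @param x a BinaryPatternMatrix
#' @return named integer vector
#' @export
setGeneric("patternScores", function(x) standardGeneric("patternScores"))

#' Fingerprint component accessors
#' @param x a FocusedFingerprint
#' @return character vector of pattern ids
#' @export
setGeneric("primaryIds", function(x) standardGeneric("primaryIds"))

#' @rdname primaryIds
#' @export
setGeneric("fourAtomIds", function(x) standardGeneric("fourAtomIds"))

#' @rdname primaryIds
#' @export
setGeneric("basicScaffoldIds", function(x) standardGeneric("basicScaffoldIds"))

#' @rdname primaryIds
#' @export
setGeneric("secondaryIds", function(x) standardGeneric("secondaryIds"))

#' @rdname primaryIds
#' @export
setGeneric("ruleConfig", function(x) standardGeneric("ruleConfig"))

setMethod("compoundIds", "CompoundSet", function(x) x@data$compound_id)
setMethod("compoundIds", "BinaryPatternMatrix", function(x) rownames(x@bits))
setMethod("canonicalSmiles", "CompoundSet", function(x) {
  stats::setNames(x@data$smiles_canonical, x@data$compound_id)
})
setMethod("compoundGroups", "CompoundSet", function(x) {
  stats::setNames(x@data$group, x@data$compound_id)
})
setMethod("recordTable", "CompoundSet", function(x) x@data)
setMethod("recordTable", "SubstructureCatalog", function(x) x@data)
setMethod("patternIds", "SubstructureCatalog", function(x) x@data$pattern_id)
setMethod("patternBits", "BinaryPatternMatrix", function(x) x@bits)
setMethod("patternScores", "BinaryPatternMatrix", function(x) x@scores)
setMethod("primaryIds", "FocusedFingerprint", function(x) x@primary)
setMethod("fourAtomIds", "FocusedFingerprint", function(x) x@fourAtom)
setMethod("fourAtomIds", "BinaryPatternMatrix", function(x) x@fourAtomIds)
setMethod("basicScaffoldIds", "FocusedFingerprint", function(x) x@basicScaffold)
setMethod("basicScaffoldIds", "BinaryPatternMatrix", function(x) x@basicScaffoldIds)
setMethod("secondaryIds", "FocusedFingerprint", function(x) x@secondary)
setMethod("ruleConfig", "FocusedFingerprint", function(x) x@ruleConfig)
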
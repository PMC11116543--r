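#' Canonicalize SMILES strings
#'
#' Converts SMILES to Open Babel canonical isomeric SMILES. The output is
#' deterministic and idempotent; stereo descriptors are preserved, so two
#' stereoisomers keep distinct canonical forms while rewritings of the same
#' molecule (atom-order permutations, kekule vs. aromatic) collapse to one
#' form.
#'
#' @param smiles character vector of SMILES strings.
#' @param strict error on unparseable input (default) instead of returning
#'   \code{NA_character_}.
#' @return character vector of canonical SMILES.
#' @examples
#' canonicalizeSmiles(c("OCC", "CCO"))   # identical output
#' @export
canonicalizeSmiles <- function(smiles, strict = TRUE) {
  out <- .obCanonical(smiles)
  if (strict && anyNA(out)) {
    bad <- smiles[is.na(out)]
    stop(sprintf("unparseable SMILES: %s",
                 paste(sQuote(utils::head(bad, 5L)), collapse = ", ")))
  }
  out
}

#' Construct a CompoundSet from vectors
#'
#' Canonicalizes every structure; rows whose SMILES do not parse are dropped
#' and collected into the attached failure report (attribute
#' \code{"failures"}), never silently discarded.
#'
#' @param smiles character vector of input SMILES.
#' @param compound_id identifiers (default \code{cpd_1 ...}).
#' @param name compound names.
#' @param group group labels (\code{direct}, \code{inconclusive},
#'   \code{library}, \code{unassigned}).
#' @param targets list of character vectors of target names.
#' @param external_ids list of named character vectors (registry ->
#'   identifier), carried as opaque strings.
#' @param source_ref literature reference strings (e.g. PMIDs).
#' @param label set label.
#' @return a \linkS4class{CompoundSet}; \code{attr(, "failures")} is a
#'   data.frame of unparseable rows.
#' @export
makeCompoundSet <- function(smiles,
                            compound_id = NULL,
                            name = NULL,
                            group = "unassigned",
                            targets = NULL,
                            external_ids = NULL,
                            source_ref = NA_character_,
                            label = "compound set") {
  n <- length(smiles)
  if (is.null(compound_id)) compound_id <- sprintf("cpd_%d", seq_len(n))
  if (is.null(name)) name <- compound_id
  group <- rep_len(as.character(group), n)
  source_ref <- rep_len(as.character(source_ref), n)
  if (is.null(targets)) targets <- rep(list(character(0)), n)
  if (is.null(external_ids)) external_ids <- rep(list(character(0)), n)
  stopifnot(length(compound_id) == n, length(name) == n,
            length(targets) == n, length(external_ids) == n)

  canonical <- .obCanonical(smiles)
  ok <- !is.na(canonical)
  failures <- data.frame(compound_id = compound_id[!ok],
                         smiles_input = smiles[!ok],
                         reason = rep("unparseable SMILES", sum(!ok)),
                         stringsAsFactors = FALSE)
  d <- data.frame(compound_id = compound_id[ok],
                  name = name[ok],
                  smiles_input = smiles[ok],
                  smiles_canonical = canonical[ok],
                  group = group[ok],
                  source_ref = source_ref[ok],
                  stringsAsFactors = FALSE)
  d$targets <- targets[ok]
  d$external_ids <- external_ids[ok]
  out <- new("CompoundSet", data = d, label = label)
  attr(out, "failures") <- failures
  out
}

#' Read a compound table
#'
#' Reads CSV (header row, UTF-8), SMILES \code{.smi} (one record per line,
#' \code{SMILES<TAB>ID}) or SDF v2000 files into a
#' \linkS4class{CompoundSet}. Unparseable structures are collected into the
#' \code{"failures"} attribute of the result rather than dropped silently.
#'
#' @param path file path.
#' @param format \code{"csv"}, \code{"smi"} or \code{"sdf"}; default guessed
#'   from the file extension.
#' @param column_map named list mapping roles to column names for CSV input;
#'   \code{smiles} is required, \code{id}, \code{name}, \code{group},
#'   \code{targets} (separator \code{;}) and \code{source_ref} are optional.
#' @param label set label (defaults to the file name).
#' @param allowEmpty accept a file with zero parseable rows (used for
#'   intermediate artifacts that may legitimately be empty); off by default
#'   so silent empty inputs fail loudly.
#' @return a \linkS4class{CompoundSet}.
#' @export
readCompounds <- function(path,
                          format = c("auto", "csv", "smi", "sdf"),
                          column_map = list(smiles = "smiles"),
                          label = basename(path),
                          allowEmpty = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", smi = "smi", txt = "smi",
                     sdf = "sdf", mol = "sdf",
                     stop("cannot guess format from extension; pass `format`"))
  }
  if (format == "csv") {
    d <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                         check.names = FALSE)
    if (is.null(column_map$smiles) || !column_map$smiles %in% names(d)) {
      stop(sprintf("SMILES column '%s' not found in %s",
                   column_map$smiles %||% "<unset>", path))
    }
    pick <- function(role, default) {
      col <- column_map[[role]]
      if (!is.null(col) && col %in% names(d)) d[[col]] else default
    }
    smiles <- as.character(d[[column_map$smiles]])
    n <- nrow(d)
    targets_raw <- pick("targets", rep(NA_character_, n))
    targets <- lapply(targets_raw, function(t) {
      if (is.na(t) || !nzchar(t)) character(0) else strsplit(t, ";")[[1]]
    })
    set <- makeCompoundSet(
      smiles,
      compound_id = as.character(pick("id", sprintf("cpd_%d", seq_len(n)))),
      name = as.character(pick("name", sprintf("cpd_%d", seq_len(n)))),
      group = as.character(pick("group", rep("unassigned", n))),
      targets = targets,
      source_ref = as.character(pick("source_ref", rep(NA_character_, n))),
      label = label
    )
  } else if (format == "smi") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "[\t ]+")
    smiles <- vapply(parts, `[[`, "", 1L)
    ids <- vapply(seq_along(parts), function(i) {
      if (length(parts[[i]]) >= 2L) parts[[i]][[2L]] else sprintf("cpd_%d", i)
    }, "")
    set <- makeCompoundSet(smiles, compound_id = ids, label = label)
  } else {
    sdf <- ChemmineR::read.SDFset(path)
    smi <- ChemmineR::sdf2smiles(sdf)
    set <- makeCompoundSet(as.character(ChemmineR::smile(smi)),
                           compound_id = ChemmineR::cid(sdf), label = label)
  }
  if (length(set) == 0L && !allowEmpty) {
    stop(sprintf("no parseable compound rows in %s", path))
  }
  set
}

#' @describeIn deduplicate Remove compounds sharing a canonical isomeric
#'   SMILES; the first occurrence (input order) is kept and the report maps
#'   each removed id to the kept id.
#' @export
setMethod("deduplicate", "CompoundSet", function(x, ...) {
  d <- x@data
  key <- d$smiles_canonical
  keep_first <- !duplicated(key)
  kept_for <- d$compound_id[match(key, key[keep_first])]
  report <- data.frame(removed_id = d$compound_id[!keep_first],
                       kept_id = kept_for[!keep_first],
                       smiles_canonical = key[!keep_first],
                       stringsAsFactors = FALSE)
  list(set = new("CompoundSet", data = d[keep_first, , drop = FALSE],
                 label = x@label),
       report = report)
})

#' Write a CompoundSet or tabular result
#'
#' \code{writeCompounds} writes a \linkS4class{CompoundSet} as CSV or
#' \code{.smi}; \code{readCompounds} on the output reproduces the set
#' (round-trip safe). \code{writeTableCsv} writes any data.frame as CSV,
#' optionally with provenance header comments (lines starting \code{#},
#' skipped on re-read).
#'
#' @param set a \linkS4class{CompoundSet}.
#' @param path output file path.
#' @param format \code{"csv"} or \code{"smi"}.
#' @param header_comment optional character vector written as \code{#} lines.
#' @return invisibly, the path.
#' @export
writeCompounds <- function(set, path, format = c("csv", "smi"),
                           header_comment = NULL) {
  format <- match.arg(format)
  d <- set@data
  if (format == "smi") {
    con <- file(path, open = "wt")
    on.exit(close(con))
    if (!is.null(header_comment)) {
      # .smi carries no comments; provenance goes into a sidecar-free world
    }
    writeLines(paste(d$smiles_canonical, d$compound_id, sep = "\t"), con)
  } else {
    out <- d[, c("compound_id", "name", "smiles_input", "smiles_canonical",
                 "group", "source_ref")]
    out$targets <- vapply(d$targets, paste, "", collapse = ";")
    writeTableCsv(out, path, header_comment = header_comment)
  }
  invisible(path)
}

#' @rdname writeCompounds
#' @param x a data.frame.
#' @export
writeTableCsv <- function(x, path, header_comment = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header_comment)) {
    writeLines(paste0("# ", header_comment), con)
  }
  utils::write.csv(x, con, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
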
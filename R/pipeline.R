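# Workflow orchestration: each stage reads its inputs from the configured
# paths (or the previous stage's artifact in the run directory) and writes
# its artifacts with a provenance header, so a rerun under the same config
# is byte-identical and any stage subset can be replayed.

.STAGES <- c("simulate", "curate", "analyze", "fingerprint", "screen",
             "score", "select", "physchem", "bioval")

# tiny polynomial hash over the deparsed config (provenance stamp only)
.configHash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Default run configuration
#'
#' Houses every numeric rule constant of the workflow: the primary rule
#' threshold (40\% of the direct group), the 4-atom rule (20\% of the full
#' set, >= 4 counted atoms, >= 2 distinct elements), the secondary count
#' (>= 5 inconclusive compounds), the hit-calling threshold (20\%
#' inhibition, mean + SEM) and the potency cutoff (50 uM).
#'
#' @param ... overrides merged over the defaults (named, possibly nested).
#' @return config list.
#' @export
defaultRunConfig <- function(...) {
  config <- list(
    paths = list(mds = NULL, catalog = NULL, library = NULL, assay = NULL,
                 class_defs = NULL),
    rules = list(primary_pct = 40, four_atom_pct = 20, min_atoms = 4,
                 min_elements = 2, secondary_min_count = 5,
                 hit_threshold_pct = 20, hit_rule = "mean_plus_sem",
                 potency_cutoff_uM = 50),
    exclusions = character(0),
    column_map = list(smiles = "smiles_input", id = "compound_id",
                      name = "name", group = "group",
                      source_ref = "source_ref", targets = "targets"),
    seed = 1L,
    fixture = NULL
  )
  mods <- list(...)
  merge_in <- function(base, mod) {
    for (nm in names(mod)) {
      base[[nm]] <- if (is.list(mod[[nm]]) && is.list(base[[nm]])) {
        merge_in(base[[nm]], mod[[nm]])
      } else mod[[nm]]
    }
    base
  }
  merge_in(config, mods)
}

#' @rdname defaultRunConfig
#' @param path JSON config file.
#' @export
readRunConfig <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(defaultRunConfig, j)
}

.artifact <- function(outDir, name) file.path(outDir, name)

.needInput <- function(config, outDir, role, artifact, stage) {
  p <- config$paths[[role]]
  if (!is.null(p) && file.exists(p)) return(p)
  a <- .artifact(outDir, artifact)
  if (file.exists(a)) return(a)
  stop(sprintf(
    "stage '%s' needs input '%s': not in config$paths and no artifact '%s' in %s",
    stage, role, artifact, outDir))
}

#' Run the pattern-scoring workflow
#'
#' Executes the requested stages in canonical order:
#' \code{simulate} (synthetic fixture inputs), \code{curate} (read +
#' canonicalize + deduplicate), \code{analyze} (collective pattern
#' analysis), \code{fingerprint} (rule extraction), \code{screen}
#' (conjunctive primary filter), \code{score} (binary pattern matrix +
#' ranking), \code{select} (scaffold-class selection), \code{physchem}
#' (descriptors + group statistics), \code{bioval} (hit calling + two-point
#' IC50). Every output CSV/JSON carries a header with the config hash and
#' seed; a rerun with the same config and inputs is byte-identical.
#'
#' @param config from \code{\link{defaultRunConfig}} /
#'   \code{\link{readRunConfig}}.
#' @param stages subset of the stage names (default: all that have inputs).
#' @param outDir run directory, created if missing.
#' @return invisibly, a named list of artifact paths.
#' @export
runPipeline <- function(config = defaultRunConfig(), stages = .STAGES,
                        outDir = "capscore_run") {
  bad <- setdiff(stages, .STAGES)
  if (length(bad) > 0L) {
    stop(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  }
  stages <- .STAGES[.STAGES %in% stages]
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stamp <- sprintf("capscore run: config_hash=%s seed=%d",
                   .configHash(config), config$seed)
  made <- list()
  put <- function(name, writer) {
    path <- .artifact(outDir, name)
    writer(path)
    made[[name]] <<- path
    path
  }
  rules <- config$rules

  if ("simulate" %in% stages) {
    if (is.null(config$fixture)) stop("stage 'simulate' needs config$fixture")
    fx <- do.call(fixtureSpec, config$fixture)
    study <- generateCompoundSet(fx)
    put("mds.csv", function(p) {
      mds <- study$set[compoundGroups(study$set) %in% c("direct", "inconclusive")]
      writeCompounds(mds, p, header_comment = stamp)
    })
    put("library.smi", function(p) {
      writeCompounds(study$set[compoundGroups(study$set) == "library"], p,
                     format = "smi")
    })
    put("catalog.csv", function(p) writeCatalog(study$catalog, p,
                                                header_comment = stamp))
    if (!is.null(fx$assayTruth)) {
      put("assay.csv", function(p) {
        writeTableCsv(generateAssayTable(fx), p, header_comment = stamp)
      })
    }
  }

  if ("curate" %in% stages) {
    mds_path <- .needInput(config, outDir, "mds", "mds.csv", "curate")
    raw <- readCompounds(mds_path, column_map = config$column_map)
    dd <- deduplicate(raw)
    put("curated_mds.csv", function(p) writeCompounds(dd$set, p,
                                                      header_comment = stamp))
    put("dedup_report.csv", function(p) writeTableCsv(dd$report, p,
                                                      header_comment = stamp))
    put("parse_failures.csv", function(p) {
      writeTableCsv(attr(raw, "failures"), p, header_comment = stamp)
    })
  }

  load_mds <- function(stage) {
    p <- .needInput(config, outDir, "mds_curated", "curated_mds.csv", stage)
    readCompounds(p, column_map = list(smiles = "smiles_canonical",
                                       id = "compound_id", name = "name",
                                       group = "group", targets = "targets",
                                       source_ref = "source_ref"))
  }
  load_catalog <- function(stage) {
    readCatalog(.needInput(config, outDir, "catalog", "catalog.csv", stage))
  }

  if ("analyze" %in% stages) {
    tab <- collectivePatternAnalysis(load_catalog("analyze"),
                                     load_mds("analyze"))
    put("occurrence.csv", function(p) writeTableCsv(tab, p,
                                                    header_comment = stamp))
  }

  load_occurrence <- function(stage) {
    p <- .needInput(config, outDir, "occurrence", "occurrence.csv", stage)
    utils::read.csv(p, stringsAsFactors = FALSE, comment.char = "#",
                    colClasses = c(pattern_id = "character"))
  }

  if ("fingerprint" %in% stages) {
    fp <- extractFingerprint(load_occurrence("fingerprint"),
                             load_catalog("fingerprint"),
                             primaryPct = rules$primary_pct,
                             fourAtomPct = rules$four_atom_pct,
                             minAtoms = rules$min_atoms,
                             minElements = rules$min_elements,
                             secondaryMinCount = rules$secondary_min_count)
    put("fingerprint.json", function(p) writeFingerprint(fp, p))
  }

  load_fingerprint <- function(stage) {
    readFingerprint(.needInput(config, outDir, "fingerprint",
                               "fingerprint.json", stage))
  }
  load_library <- function(stage) {
    readCompounds(.needInput(config, outDir, "library", "library.smi", stage))
  }

  if ("screen" %in% stages) {
    fp <- load_fingerprint("screen")
    hits <- conjunctiveFilter(load_library("screen"), load_catalog("screen"),
                              requiredIds = primaryIds(fp),
                              excludedIds = config$exclusions)
    put("filtered_library.smi", function(p) writeCompounds(hits, p,
                                                           format = "smi"))
  }

  load_filtered <- function(stage) {
    readCompounds(.needInput(config, outDir, "filtered",
                             "filtered_library.smi", stage),
                  format = "smi", allowEmpty = TRUE)
  }

  if ("score" %in% stages) {
    bm <- buildBinaryMatrix(load_filtered("score"), load_fingerprint("score"),
                            load_catalog("score"))
    put("binary_matrix.csv", function(p) writeBinaryMatrix(bm, p,
                                                           header_comment = stamp))
    put("ranking.csv", function(p) writeTableCsv(rankCandidates(bm), p,
                                                 header_comment = stamp))
  }

  if ("select" %in% stages) {
    fp <- load_fingerprint("select")
    bm_path <- .needInput(config, outDir, "binary_matrix",
                          "binary_matrix.csv", "select")
    bmd <- utils::read.csv(bm_path, stringsAsFactors = FALSE,
                           comment.char = "#", check.names = FALSE)
    bits <- as.matrix(bmd[, -(1:2), drop = FALSE])
    storage.mode(bits) <- "integer"
    rownames(bits) <- bmd$compound_id
    bm <- new("BinaryPatternMatrix", bits = bits,
              fourAtomIds = fourAtomIds(fp),
              basicScaffoldIds = setdiff(basicScaffoldIds(fp),
                                         fourAtomIds(fp)),
              scores = stats::setNames(as.integer(bmd$score),
                                       bmd$compound_id))
    defs <- if (!is.null(config$paths$class_defs)) {
      defaultScaffoldClasses(config$paths$class_defs)
    } else defaultScaffoldClasses()
    sel <- classSelect(bm, load_filtered("select"), defs)
    for (nm in names(sel)) {
      local({
        nm_ <- nm
        put(sprintf("selection_%s.csv", nm_), function(p) {
          writeTableCsv(sel[[nm_]], p, header_comment = stamp)
        })
      })
    }
    put("selection_summary.csv", function(p) {
      writeTableCsv(summarizeSelection(sel), p, header_comment = stamp)
    })
  }

  if ("physchem" %in% stages) {
    mds <- load_mds("physchem")
    desc <- computeDescriptors(mds)
    put("descriptors.csv", function(p) writeTableCsv(desc, p,
                                                     header_comment = stamp))
    put("group_stats.csv", function(p) {
      writeTableCsv(groupStatistics(mds, desc), p, header_comment = stamp)
    })
  }

  if ("bioval" %in% stages) {
    assay <- readAssayTable(.needInput(config, outDir, "assay", "assay.csv",
                                       "bioval"))
    flags <- callHits(assay, thresholdPct = rules$hit_threshold_pct,
                      rule = rules$hit_rule)
    concs <- sort(unique(assay$concentration_uM))
    if (length(concs) != 2L) {
      stop("two-point IC50 estimation needs exactly two concentrations")
    }
    wide <- merge(
      assay[assay$concentration_uM == concs[1],
            c("compound_id", "inhibition_pct")],
      assay[assay$concentration_uM == concs[2],
            c("compound_id", "inhibition_pct")],
      by = "compound_id", suffixes = c("_low", "_high")
    )
    est <- estimateIC50TwoPoint(wide$inhibition_pct_low,
                                wide$inhibition_pct_high,
                                xLow = concs[1], xHigh = concs[2])
    est <- cbind(compound_id = wide$compound_id, est)
    out <- merge(flags, est, by = "compound_id", sort = TRUE)
    put("bioval.csv", function(p) writeTableCsv(out, p,
                                                header_comment = stamp))
    put("bioval_summary.json", function(p) {
      jsonlite::write_json(
        list(hit_rates_pct = as.list(hitRate(flags)),
             potent_fraction_pct = potencySummary(est,
                                                  rules$potency_cutoff_uM)),
        p, auto_unbox = TRUE, pretty = TRUE)
    })
  }

  invisible(made)
}
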
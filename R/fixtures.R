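# Deterministic synthetic fixtures with known ground truth. Molecules are
# assembled from an alkane backbone plus attachable fragments so that the
# realized per-group pattern frequencies equal the requested counts exactly
# (deterministic assignment, not sampling); the incidence map records which
# fragment every molecule carries by construction.

#' Fragment panel for synthetic compound sets
#'
#' Each row pairs a catalog pattern with an attachable substituent form.
#' The panel is built from heteroatom-bearing fragments so that the
#' all-carbon backbone of generated molecules can never create an
#' accidental match, and fragments are chosen pairwise non-matching (the
#' generator verifies this for the fragments actually planted).
#'
#' @return data.frame with \code{frag_id}, \code{name},
#'   \code{pattern_smiles} (catalog form, may carry \code{[H]}/\code{[R]}),
#'   \code{attach_smiles} (substituent form) and \code{heteroaromatic}.
#' @export
fixtureFragments <- function() {
  read_frag <- function(...) {
    m <- matrix(c(...), ncol = 4, byrow = TRUE)
    data.frame(frag_id = m[, 1], name = m[, 2], pattern_smiles = m[, 3],
               attach_smiles = m[, 4], stringsAsFactors = FALSE)
  }
  d <- read_frag(
    "pyridine",   "pyridin-4-yl",        "c1ccncc1",      "c1ccncc1",
    "furan",      "furan-2-yl",          "c1ccoc1",       "c1ccco1",
    "thiophene",  "thiophen-2-yl",       "c1ccsc1",       "c1cccs1",
    "pyrimidine", "pyrimidin-2-yl",      "c1cncnc1",      "c1ncccn1",
    "oxazole",    "1,3-oxazol-2-yl",     "c1ocnc1",       "c1ncco1",
    "thiazole",   "1,3-thiazol-2-yl",    "c1scnc1",       "c1nccs1",
    "isoxazole",  "isoxazol-3-yl",       "c1ccon1",       "c1ccon1",
    "pyrazole",   "1H-pyrazol-3-yl",     "c1cc[nH]n1",    "c1cc[nH]n1",
    "amide",      "carboxamide",         "C(=O)N",        "C(N)=O",
    "sulfonamide","sulfonamide",         "S(=O)(=O)N",    "S(N)(=O)=O",
    "carboxyl",   "carboxylic acid (defined H)", "C(=O)O[H]", "C(O)=O",
    "nitrile",    "nitrile",             "C#N",           "C#N",
    "cf3",        "trifluoromethyl",     "C(F)(F)F",      "C(F)(F)F"
  )
  d$heteroaromatic <- vapply(d$pattern_smiles, function(s) {
    .patternStats(.parseSmilesGraph(s))$is_heteroaromatic_scaffold
  }, FALSE, USE.NAMES = FALSE)
  d
}

# decoy patterns never planted by the generator (and verified absent)
.FIXTURE_DECOYS <- data.frame(
  frag_id = c("quinoline_d", "alkyne_d", "nitro_d", "bromo_d"),
  name = c("quinoline (decoy)", "terminal alkyne (decoy)",
           "nitro (decoy)", "aryl bromide (decoy)"),
  pattern_smiles = c("c1ccc2c(c1)cccn2", "C#C[H]", "[R]N(=O)=O",
                     "Brc1ccccc1"),
  stringsAsFactors = FALSE
)

#' Specify a synthetic fixture study
#'
#' @param seed integer RNG seed; same seed, same fixtures, byte-identical.
#' @param nDirect,nInconclusive,nLibrary group sizes.
#' @param planted data.frame with \code{frag_id} (from
#'   \code{\link{fixtureFragments}}) and either exact counts
#'   (\code{n_direct}, \code{n_inconclusive}, \code{n_library}) or
#'   frequencies (\code{freq_direct}, ...) that must be integer-feasible for
#'   the group sizes.
#' @param decoys decoy pattern ids to append to the catalog (default: all
#'   built-in decoys).
#' @param assayTruth optional data.frame (\code{compound_id}, \code{ic50},
#'   \code{hill}); \code{NA} ic50 means no inhibition.
#' @param noiseSd,nRep assay noise SD (percent inhibition) and replicate
#'   count.
#' @return a \code{FixtureSpec} list.
#' @export
fixtureSpec <- function(seed = 1L, nDirect = 0L, nInconclusive = 0L,
                        nLibrary = 0L, planted = NULL,
                        decoys = .FIXTURE_DECOYS$frag_id,
                        assayTruth = NULL, noiseSd = 2, nRep = 3L) {
  panel <- fixtureFragments()
  if (!is.null(planted)) {
    bad <- setdiff(planted$frag_id, panel$frag_id)
    if (length(bad) > 0L) {
      stop(sprintf("unknown fragment id(s): %s", paste(bad, collapse = ", ")))
    }
    sizes <- c(direct = nDirect, inconclusive = nInconclusive,
               library = nLibrary)
    for (g in names(sizes)) {
      ncol_ <- paste0("n_", g); fcol <- paste0("freq_", g)
      if (is.null(planted[[ncol_]])) {
        if (!is.null(planted[[fcol]])) {
          cnt <- planted[[fcol]] * sizes[[g]]
          if (any(abs(cnt - round(cnt)) > 1e-9)) {
            stop(sprintf(
              "frequency for group '%s' is not integer-feasible for n=%d",
              g, sizes[[g]]))
          }
          planted[[ncol_]] <- as.integer(round(cnt))
        } else {
          planted[[ncol_]] <- 0L
        }
      }
      if (any(planted[[ncol_]] > sizes[[g]])) {
        stop(sprintf("planted count exceeds group size for '%s'", g))
      }
    }
  }
  structure(list(seed = as.integer(seed), nDirect = as.integer(nDirect),
                 nInconclusive = as.integer(nInconclusive),
                 nLibrary = as.integer(nLibrary), planted = planted,
                 decoys = decoys, assayTruth = assayTruth,
                 noiseSd = noiseSd, nRep = as.integer(nRep)),
            class = "FixtureSpec")
}

# index -> unique all-carbon backbone: "C" + binary methyl-branch encoding
.backboneSmiles <- function(index) {
  bits <- integer(0)
  i <- index
  while (i > 0L) { bits <- c(bits, i %% 2L); i <- i %/% 2L }
  units <- vapply(bits, function(b) if (b == 1L) "C(C)" else "C", "")
  paste0("C", paste(units, collapse = ""), "C")
}

#' Generate a synthetic compound set with known incidence
#'
#' Builds \code{nDirect + nInconclusive + nLibrary} molecules; each planted
#' fragment is attached to a seeded random subset of each group of exactly
#' the requested size, so realized occurrence counts equal the targets. The
#' returned catalog holds the planted patterns plus never-planted decoys.
#' Planted fragments are verified pairwise non-cross-matching so the
#' incidence map is exact ground truth.
#'
#' @param spec a \code{\link{fixtureSpec}}.
#' @return list with \code{$set} (\linkS4class{CompoundSet}),
#'   \code{$catalog} (\linkS4class{SubstructureCatalog}, planted + decoys),
#'   \code{$incidence} (logical ground-truth matrix, compounds x catalog
#'   patterns) and \code{$spec}.
#' @export
generateCompoundSet <- function(spec) {
  panel <- fixtureFragments()
  n_total <- spec$nDirect + spec$nInconclusive + spec$nLibrary
  groups <- rep(c("direct", "inconclusive", "library"),
                c(spec$nDirect, spec$nInconclusive, spec$nLibrary))
  ids <- sprintf("FIX_%04d", seq_len(n_total))

  planted <- spec$planted
  frag_ids <- if (is.null(planted)) character(0) else planted$frag_id

  # cross-match guard: no planted pattern may hit another fragment alone
  if (length(frag_ids) > 1L) {
    probes <- .obCanonical(paste0("C(", vapply(frag_ids, function(f) {
      panel$attach_smiles[panel$frag_id == f]
    }, ""), ")C"))
    pats <- lapply(frag_ids, function(f) {
      parsePattern(f, f, panel$pattern_smiles[panel$frag_id == f])
    })
    for (i in seq_along(frag_ids)) {
      for (j in seq_along(frag_ids)) {
        if (i == j) next
        if (unname(matchesPattern(probes[j], pats[[i]]))) {
          stop(sprintf(
            "fragments '%s' and '%s' cross-match; pick a disjoint panel",
            frag_ids[i], frag_ids[j]))
        }
      }
    }
  }

  assign_mat <- matrix(FALSE, nrow = n_total, ncol = length(frag_ids),
                       dimnames = list(ids, frag_ids))
  if (length(frag_ids) > 0L) {
    set.seed(spec$seed)
    for (g in c("direct", "inconclusive", "library")) {
      rows <- which(groups == g)
      for (k in seq_along(frag_ids)) {
        cnt <- planted[[paste0("n_", g)]][k]
        if (cnt > 0L) {
          assign_mat[sample(rows, cnt), k] <- TRUE
        }
      }
    }
  }

  smiles <- vapply(seq_len(n_total), function(i) {
    frs <- frag_ids[assign_mat[i, ]]
    att <- vapply(frs, function(f) {
      paste0("C(", panel$attach_smiles[panel$frag_id == f], ")")
    }, "")
    paste0("C", paste(att, collapse = ""), .backboneSmiles(i))
  }, "")

  set <- makeCompoundSet(smiles, compound_id = ids, group = groups,
                         label = sprintf("fixture (seed %d)", spec$seed))
  stopifnot(nrow(attr(set, "failures")) == 0L)

  decoy_rows <- .FIXTURE_DECOYS[.FIXTURE_DECOYS$frag_id %in% spec$decoys, ]
  cat_ids <- c(frag_ids, decoy_rows$frag_id)
  cat_names <- c(panel$name[match(frag_ids, panel$frag_id)], decoy_rows$name)
  cat_smiles <- c(panel$pattern_smiles[match(frag_ids, panel$frag_id)],
                  decoy_rows$pattern_smiles)
  catalog <- makeCatalog(cat_ids, cat_names, cat_smiles,
                         provenance = sprintf("fixture (seed %d)", spec$seed))

  incidence <- cbind(
    assign_mat,
    matrix(FALSE, nrow = n_total, ncol = nrow(decoy_rows),
           dimnames = list(ids, decoy_rows$frag_id))
  )
  list(set = set, catalog = catalog, incidence = incidence, spec = spec)
}

#' Generate a synthetic two-concentration assay table
#'
#' Simulates replicate percent-inhibition measurements from each compound's
#' true three-parameter-logistic curve plus seeded Gaussian noise; reported
#' rows carry the replicate mean and SEM = SD/sqrt(n). Compounds with
#' \code{NA} ic50 are generated as no-inhibition (true response 0 at every
#' concentration).
#'
#' @param spec a \code{\link{fixtureSpec}} with \code{assayTruth}.
#' @param concentrations test concentrations in uM.
#' @return data.frame in \code{\link{readAssayTable}} layout.
#' @export
generateAssayTable <- function(spec, concentrations = c(10, 50)) {
  truth <- spec$assayTruth
  if (is.null(truth)) stop("fixture spec has no assayTruth")
  set.seed(spec$seed + 1L)
  rows <- list()
  for (i in seq_len(nrow(truth))) {
    for (x in concentrations) {
      y_true <- if (is.na(truth$ic50[i])) 0 else {
        logistic3pl(x, truth$ic50[i], truth$hill[i])
      }
      reps <- y_true + stats::rnorm(spec$nRep, 0, spec$noiseSd)
      rows[[length(rows) + 1L]] <- data.frame(
        compound_id = truth$compound_id[i],
        concentration_uM = x,
        inhibition_pct = mean(reps),
        sem_pct = if (spec$noiseSd == 0) 0 else stats::sd(reps) / sqrt(spec$nRep),
        n = spec$nRep,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
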
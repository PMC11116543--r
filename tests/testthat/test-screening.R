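test_that("conjunctive filter keeps only molecules bearing every required pattern", {
  lib <- makeCompoundSet(c("c1ccccc1", "c1ccncc1", "CCCCCC"),
                         compound_id = c("benzene", "pyridine", "hexane"),
                         group = "library")
  catalog <- makeCatalog(c("bz", "py"),
                         smiles_pattern = c("c1ccccc1", "c1ccncc1"))
  out <- conjunctiveFilter(lib, catalog, requiredIds = "bz")
  expect_equal(compoundIds(out), "benzene")
  # requiring nothing is a configuration error
  expect_error(conjunctiveFilter(lib, catalog, requiredIds = "bz",
                                 excludedIds = "bz"), "no required")
  expect_error(conjunctiveFilter(lib, catalog, requiredIds = "nope"),
               "not in catalog")
})

test_that("filter is monotone in the required set", {
  planted <- data.frame(
    frag_id = c("pyridine", "furan", "amide"),
    n_direct = c(0L, 0L, 0L), n_inconclusive = c(0L, 0L, 0L),
    n_library = c(60L, 40L, 30L))
  study <- generateCompoundSet(fixtureSpec(seed = 3L, nLibrary = 100L,
                                           planted = planted))
  lib <- study$set
  f1 <- conjunctiveFilter(lib, study$catalog, c("pyridine"))
  f2 <- conjunctiveFilter(lib, study$catalog, c("pyridine", "furan"))
  f3 <- conjunctiveFilter(lib, study$catalog, c("pyridine", "furan", "amide"))
  # adding a requirement never enlarges the set
  expect_true(all(compoundIds(f2) %in% compoundIds(f1)))
  expect_true(all(compoundIds(f3) %in% compoundIds(f2)))
  # excluding a pattern from the requirement yields a superset
  relaxed <- conjunctiveFilter(lib, study$catalog,
                               c("pyridine", "furan", "amide"),
                               excludedIds = "amide")
  expect_true(all(compoundIds(f3) %in% compoundIds(relaxed)))
  expect_identical(compoundIds(relaxed), compoundIds(f2))
  # realized sizes equal the ground-truth intersections
  inc <- study$incidence
  expect_equal(length(f2), sum(inc[, "pyridine"] & inc[, "furan"]))
})

test_that("binary matrix equals the fixtures' ground-truth incidence", {
  planted <- data.frame(
    frag_id = c("pyridine", "furan", "thiophene", "oxazole", "amide",
                "sulfonamide"),
    n_direct = 0L, n_inconclusive = 0L,
    n_library = c(3L, 2L, 4L, 1L, 3L, 2L))
  study <- generateCompoundSet(fixtureSpec(seed = 5L, nLibrary = 5L,
                                           planted = planted))
  fp <- new("FocusedFingerprint",
            primary = character(0),
            fourAtom = c("pyridine", "furan", "amide", "sulfonamide"),
            basicScaffold = c("thiophene", "oxazole"))
  bm <- buildBinaryMatrix(study$set, fp, study$catalog)
  truth <- study$incidence[rownames(patternBits(bm)),
                           colnames(patternBits(bm))]
  expect_identical(patternBits(bm), matrix(as.integer(truth),
                                           nrow = nrow(truth),
                                           dimnames = dimnames(truth)))
  # score identity: row sums restricted to 4-Atom columns
  expect_equal(unname(patternScores(bm)),
               unname(as.integer(rowSums(truth[, fourAtomIds(fp)]))))
  # a compound matching nothing scores zero; full match scores |four_atom|
  expect_true(all(patternScores(bm) >= 0 &
                    patternScores(bm) <= length(fourAtomIds(fp))))
})

test_that("ranking is score-descending with deterministic tie-breaks", {
  bits <- matrix(c(1L, 1L, 1L, 0L, 1L,
                   1L, 1L, 1L, 1L, 1L,
                   1L, 1L, 1L, 0L, 1L),
                 nrow = 3, byrow = TRUE,
                 dimnames = list(c("A", "B", "C"),
                                 c("f1", "f2", "f3", "f4", "f5")))
  scores <- setNames(as.integer(rowSums(bits[, c("f1", "f2", "f3", "f4")])),
                     rownames(bits))
  ord <- order(-scores, names(scores))
  bm <- new("BinaryPatternMatrix", bits = bits[ord, ],
            fourAtomIds = c("f1", "f2", "f3", "f4"), basicScaffoldIds = "f5",
            scores = scores[ord])
  r <- rankCandidates(bm)
  expect_equal(r$compound_id, c("B", "A", "C"))   # scores 4,3,3: B first, tie A<C
  expect_equal(r$score, c(4L, 3L, 3L))
})

test_that("row sums recomputed independently agree on a larger fixture", {
  planted <- data.frame(
    frag_id = c("pyridine", "furan", "thiophene", "amide"),
    n_direct = 0L, n_inconclusive = 0L,
    n_library = c(55L, 40L, 25L, 70L))
  study <- generateCompoundSet(fixtureSpec(seed = 9L, nLibrary = 100L,
                                           planted = planted))
  fp <- new("FocusedFingerprint", fourAtom = c("pyridine", "furan", "amide"),
            basicScaffold = "thiophene")
  bm <- buildBinaryMatrix(study$set, fp, study$catalog,
                          incidence = study$incidence)
  indep <- rowSums(study$incidence[rownames(patternBits(bm)),
                                   c("pyridine", "furan", "amide")])
  expect_equal(unname(patternScores(bm)), unname(as.integer(indep)))
})

test_that("class selection honors include/exclude queries and windows", {
  mols <- c(pyr = "Cc1cc[nH]c1", ind = "c1ccc2c(c1)cc[nH]2",
            pyd = "Cc1ccncc1", qui = "c1ccc2ncccc2c1",
            iso = "c1cc2ccncc2cc1", hex = "CCCCCC")
  lib <- makeCompoundSet(unname(mols), compound_id = names(mols),
                         group = "library")
  catalog <- makeCatalog(c("f1", "f2"), smiles_pattern = c("c1ccccc1", "C"))
  fp <- new("FocusedFingerprint", fourAtom = c("f1", "f2"),
            basicScaffold = "f1")
  bm <- buildBinaryMatrix(lib, fp, catalog)
  defs <- list(
    list(class_name = "pyrrole", include_pattern = "n1cccc1",
         exclude_patterns = list("c1ccc2c(c1)ccn2"), score_window = NULL,
         top_n = NULL),
    list(class_name = "indole", include_pattern = "c1ccc2c(c1)ccn2",
         exclude_patterns = list(), score_window = NULL, top_n = NULL),
    list(class_name = "pyridine", include_pattern = "c1ccncc1",
         exclude_patterns = list("c1ccc2c(c1)cccn2"), score_window = NULL,
         top_n = NULL))
  sel <- classSelect(bm, lib, defs)
  # indole bears a pyrrole ring but is excluded from the pyrrole class
  expect_equal(sel$pyrrole$compound_id, "pyr")
  expect_equal(sel$indole$compound_id, "ind")
  # quinoline excluded from pyridines, isoquinoline kept
  expect_setequal(sel$pyridine$compound_id, c("pyd", "iso"))
  expect_false("qui" %in% sel$pyridine$compound_id)
})

test_that("selection matches hand enumeration on a known fixture", {
  planted <- data.frame(
    frag_id = c("pyridine", "furan", "amide", "sulfonamide"),
    n_direct = 0L, n_inconclusive = 0L,
    n_library = c(10L, 8L, 12L, 6L))
  study <- generateCompoundSet(fixtureSpec(seed = 13L, nLibrary = 20L,
                                           planted = planted))
  fp <- new("FocusedFingerprint",
            fourAtom = c("pyridine", "furan", "amide", "sulfonamide"),
            basicScaffold = "pyridine")
  bm <- buildBinaryMatrix(study$set, fp, study$catalog,
                          incidence = study$incidence)
  defs <- list(
    list(class_name = "top", include_pattern = NA_character_,
         exclude_patterns = character(0), score_window = c(3L, 4L),
         top_n = NULL),
    list(class_name = "pyridines", include_pattern = "c1ccncc1",
         exclude_patterns = character(0), score_window = c(2L, 4L),
         top_n = NULL))
  sel <- classSelect(bm, study$set, defs)
  inc <- study$incidence
  sc <- rowSums(inc[, c("pyridine", "furan", "amide", "sulfonamide")])
  # brute-force evaluation per molecule
  expect_setequal(sel$top$compound_id, names(sc)[sc >= 3 & sc <= 4])
  expect_setequal(sel$pyridines$compound_id,
                  names(sc)[inc[, "pyridine"] & sc >= 2 & sc <= 4])
  # summary agrees with independent arithmetic
  smry <- summarizeSelection(sel)
  expect_equal(smry$n, vapply(sel, nrow, 0L), ignore_attr = TRUE)
  expect_equal(smry$score_mean[smry$class_name == "top"],
               round(mean(sc[sc >= 3 & sc <= 4]), 1))
})

test_that("selection summaries handle singleton and empty classes", {
  sel <- list(single = data.frame(compound_id = "A", score = 7L),
              empty = data.frame(compound_id = character(0),
                                 score = integer(0)))
  smry <- summarizeSelection(sel)
  expect_equal(smry$score_mean[1], 7.0)
  expect_equal(smry$n[2], 0L)
  expect_true(is.na(smry$score_mean[2]))
})

test_that("unparseable class queries raise errors naming the class", {
  bits <- matrix(1L, 1, 1, dimnames = list("A", "f1"))
  bm <- new("BinaryPatternMatrix", bits = bits, fourAtomIds = "f1",
            basicScaffoldIds = character(0),
            scores = c(A = 1L))
  lib <- makeCompoundSet("CCO", compound_id = "A")
  defs <- list(list(class_name = "broken", include_pattern = "C1CC",
                    exclude_patterns = character(0), score_window = NULL,
                    top_n = NULL))
  expect_error(classSelect(bm, lib, defs), "broken")
})
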
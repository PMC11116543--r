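test_that("occurrence percentages follow the group-quotient rule", {
  set <- makeCompoundSet(c("CCO", "CC(=O)O", "CCC"),
                         compound_id = c("A", "B", "C"), group = "direct")
  catalog <- makeCatalog(c("co", "acid"),
                         name = c("C-O single bond", "carboxylic acid"),
                         smiles_pattern = c("CO", "C(=O)O"))
  tab <- collectivePatternAnalysis(catalog, set)
  co <- tab[tab$pattern_id == "co", ]
  acid <- tab[tab$pattern_id == "acid", ]
  expect_equal(co$count_all, 2L)            # ethanol + the acid's C-OH
  expect_equal(co$pct_all, 100 * 2 / 3, tolerance = 1e-12)
  expect_equal(acid$count_all, 1L)
  expect_equal(acid$pct_all, 100 * 1 / 3, tolerance = 1e-12)
  # ordering: count_all descending
  expect_equal(tab$pattern_id, c("co", "acid"))
})

test_that("all-present and all-absent patterns hit the percentage bounds", {
  set <- makeCompoundSet(c("CCO", "CCCO", "OCCN"), group = "direct")
  catalog <- makeCatalog(c("oh", "ni"), smiles_pattern = c("O[H]", "C#N"))
  tab <- collectivePatternAnalysis(catalog, set)
  expect_equal(tab$pct_all[tab$pattern_id == "oh"], 100)
  expect_equal(tab$count_all[tab$pattern_id == "ni"], 0L)
  expect_false(tab$active[tab$pattern_id == "ni"])
  # empty catalog -> empty table
  empty <- collectivePatternAnalysis(
    new("SubstructureCatalog"), set)
  expect_equal(nrow(empty), 0L)
})

test_that("counts add over a direct/inconclusive partition", {
  study <- boundaryStudy()
  tab <- collectivePatternAnalysis(study$catalog, study$set,
                                   incidence = study$incidence)
  expect_equal(tab$count_all, tab$count_direct + tab$count_inconclusive)
})

test_that("active/inactive classification recovers the planted split", {
  study <- boundaryStudy()
  tab <- collectivePatternAnalysis(study$catalog, study$set)
  cls <- classifyActive(tab)
  # 7 planted fragments present, 4 decoys absent
  expect_setequal(cls$active, c("pyridine", "furan", "thiophene", "oxazole",
                                "nitrile", "sulfonamide", "amide"))
  expect_setequal(cls$inactive, c("quinoline_d", "alkyne_d", "nitro_d",
                                  "bromo_d"))
})

test_that("primary extraction includes the boundary and sorts by percentage", {
  tab <- data.frame(pattern_id = c("p1", "p2", "p3"),
                    name = c("a", "b", "c"),
                    count_all = c(5L, 4L, 4L), count_direct = c(5L, 4L, 4L),
                    count_inconclusive = c(0L, 0L, 0L),
                    pct_all = c(50, 40, 39.9), pct_direct = c(50, 40, 39.9),
                    pct_inconclusive = c(0, 0, 0),
                    active = TRUE, stringsAsFactors = FALSE)
  expect_equal(extractPrimary(tab, thresholdPct = 40), c("p1", "p2"))
  expect_equal(extractPrimary(tab[0, ], thresholdPct = 40), character(0))
})

test_that("threshold monotonicity: raising a threshold never adds patterns", {
  study <- boundaryStudy()
  tab <- collectivePatternAnalysis(study$catalog, study$set)
  thresholds <- c(10, 20, 30, 40, 50, 60)
  prev_p <- prev_f <- NULL
  for (th in thresholds) {
    p <- extractPrimary(tab, thresholdPct = th)
    f <- extractFourAtom(tab, study$catalog, thresholdPct = th)
    if (!is.null(prev_p)) {
      expect_true(all(p %in% prev_p))
      expect_true(all(f %in% prev_f))
    }
    prev_p <- p; prev_f <- f
  }
})

test_that("the 4-atom scheme enforces size and element diversity", {
  set <- makeCompoundSet(c("Oc1ccccc1", "OCCN", "CCCCO"), group = "direct")
  catalog <- makeCatalog(c("oh", "propyl", "ethanolamine"),
                         smiles_pattern = c("O[H]", "CCC", "OCCN"))
  tab <- collectivePatternAnalysis(catalog, set)
  fa <- extractFourAtom(tab, catalog, thresholdPct = 20)
  # O[H]: 100% occurrence but 2 counted atoms -> out
  expect_false("oh" %in% fa)
  # CCC: one element -> out
  expect_false("propyl" %in% fa)
  # OCCN: 4 atoms, 3 elements, 1/3 occurrence -> in
  expect_true("ethanolamine" %in% fa)
})

test_that("basic scaffold extraction ignores occurrence entirely", {
  study <- boundaryStudy()
  scaffolds <- extractBasicScaffolds(study$catalog)
  # heteroaromatic planted fragments and the never-present quinoline decoy
  expect_setequal(scaffolds,
                  c("pyridine", "furan", "thiophene", "oxazole",
                    "quinoline_d"))
  # zero-occurrence decoy is retained: frequency is not consulted
  expect_true("quinoline_d" %in% scaffolds)
})

test_that("boundary fixture recovers the planted fingerprint exactly", {
  study <- boundaryStudy()
  tab <- collectivePatternAnalysis(study$catalog, study$set)
  want <- boundaryExpectations()
  fp <- extractFingerprint(tab, study$catalog)
  expect_equal(primaryIds(fp), want$primary)
  expect_setequal(fourAtomIds(fp), want$four_atom)
  expect_equal(secondaryIds(fp), want$secondary)
  expect_false(any(want$not_primary %in% primaryIds(fp)))
  expect_false(any(want$not_four_atom %in% fourAtomIds(fp)))
  expect_false(any(want$not_secondary %in% secondaryIds(fp)))
  # secondary stays disjoint from the other three components
  expect_length(intersect(secondaryIds(fp),
                          c(primaryIds(fp), fourAtomIds(fp),
                            basicScaffoldIds(fp))), 0)
})

test_that("fingerprint JSON round-trips", {
  study <- boundaryStudy()
  tab <- collectivePatternAnalysis(study$catalog, study$set)
  fp <- extractFingerprint(tab, study$catalog)
  path <- withr::local_tempfile(fileext = ".json")
  writeFingerprint(fp, path)
  back <- readFingerprint(path)
  expect_equal(primaryIds(back), primaryIds(fp))
  expect_equal(fourAtomIds(back), fourAtomIds(fp))
  expect_equal(basicScaffoldIds(back), basicScaffoldIds(fp))
  expect_equal(secondaryIds(back), secondaryIds(fp))
})
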
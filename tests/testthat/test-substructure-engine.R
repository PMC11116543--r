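test_that("pattern parsing applies the counting rule", {
  p <- parsePattern("0044", "hydroxy-H, defined (1H; OH)", "O[H]")
  expect_equal(p$counted_atoms, 2L)     # O + defined H
  expect_equal(p$defined_h, 1L)
  expect_equal(p$distinct_elements, 2L) # O and H

  p2 <- parsePattern("x1", "phenol-like", "[R]c1ccc(O[H])cc1")
  expect_equal(p2$counted_atoms, 8L)    # 6 aromatic C + O + H; [R] not counted
  expect_equal(p2$defined_h, 1L)
  expect_equal(p2$distinct_elements, 3L)

  p3 <- parsePattern("x2", "propyl", "CCC")
  expect_equal(p3$distinct_elements, 1L)
  expect_false(p3$is_heteroaromatic_scaffold)

  expect_true(parsePattern("x3", "pyridine", "c1ccncc1")$is_heteroaromatic_scaffold)
  expect_false(parsePattern("x4", "benzene", "c1ccccc1")$is_heteroaromatic_scaffold)
  # cached statistics are recomputable: reparsing reproduces them
  p2b <- parsePattern("x1", "phenol-like", p2$smiles_pattern)
  expect_equal(p2b[c("counted_atoms", "defined_h", "distinct_elements")],
               p2[c("counted_atoms", "defined_h", "distinct_elements")])
})

test_that("invalid patterns raise errors naming the pattern", {
  expect_error(parsePattern("bad1", "x", "C1CC"), "bad1")
  expect_error(parsePattern("bad2", "x", ""), "empty")
  expect_error(parsePattern("bad3", "x", "C(C"), "bad3")
  # non-terminal attachment points are rejected
  expect_error(parsePattern("bad4", "x", "C[R]C"), "terminal")
})

test_that("defined-H and attachment-point semantics drive presence calls", {
  cat44 <- makeCatalog("0044", "hydroxy-H", "O[H]")
  m <- matchesPattern(c(toluene = "Cc1ccccc1", phenol = "Oc1ccccc1",
                        anisole = "COc1ccccc1"), cat44@data)
  expect_equal(unname(m), c(FALSE, TRUE, FALSE))
  # [R] may be unsubstituted under the permissive default ...
  perm <- parsePattern("p", "p", "[R]c1ccc(O[H])cc1", rMatchesH = TRUE)
  expect_true(unname(matchesPattern("Oc1ccccc1", perm)))
  # ... but requires a heavy substituent para to the hydroxy when strict
  strict <- parsePattern("p", "p", "[R]c1ccc(O[H])cc1", rMatchesH = FALSE)
  expect_false(unname(matchesPattern("Oc1ccccc1", strict)))
  expect_true(unname(matchesPattern("Cc1ccc(O)cc1", strict)))
})

test_that("matching is stereo-blind, quantity-blind and notation-invariant", {
  pats <- makeCatalog(c("a", "b"), smiles_pattern = c("O[H]", "OCC(O)C=O"))
  r <- matchMatrix(c(R = "OC[C@@H](O)C=O", S = "OC[C@H](O)C=O"), pats)
  expect_equal(r["R", ], r["S", ])  # stereoisomers give identical rows
  # one occurrence vs two occurrences: same boolean
  one <- matchesPattern("Oc1ccccc1", pats@data[1, ])
  two <- matchesPattern("Oc1ccccc1O", pats@data[1, ])
  expect_equal(unname(one), unname(two))
  # kekule vs aromatic input molecule
  benz <- makeCatalog("bz", smiles_pattern = "c1ccccc1")
  expect_equal(unname(matchesPattern("C1=CC=CC=C1", benz@data)),
               unname(matchesPattern("c1ccccc1", benz@data)))
})

test_that("matcher agrees with the brute-force oracle over the panel", {
  mols <- panelMolecules()
  pats <- panelPatterns()
  catalog <- makeCatalog(names(pats), smiles_pattern = unname(pats))
  got <- matchMatrix(mols, catalog)
  want <- oracleMatrix(mols, pats)
  expect_identical(unname(got), unname(want))
})

test_that("substructure nesting is monotone across the molecule panel", {
  # (sub, super) pattern pairs: any molecule containing the super-pattern
  # must contain the sub-pattern
  pairs <- list(c("c1ccccc1", "c1ccc2ncccc2c1"),
                c("c1ccncc1", "c1ccc2ncccc2c1"),
                c("c1ccoc1", "c1ccc2c(c1)cco2"),
                c("O[H]", "C(=O)O[H]"))
  mols <- panelMolecules()
  for (pr in pairs) {
    sub <- parsePattern("sub", "sub", pr[1])
    super <- parsePattern("sup", "sup", pr[2])
    m_sub <- matchesPattern(mols, sub)
    m_super <- matchesPattern(mols, super)
    expect_true(all(m_sub[m_super]),
                info = sprintf("%s should imply %s", pr[2], pr[1]))
  }
})

test_that("heavy-atom substitution enumerates distinct valid derivatives", {
  aza <- substitutionScheme(list(c("c", "n")), maxSubstitutions = 1)
  e1 <- enumerateSubstitutions("c1ccccc1", aza)
  expect_equal(nrow(e1), 2L)  # benzene + the single distinct mono-aza form
  expect_setequal(e1$normal_form,
                  capscore:::.obCanonical(c("c1ccccc1", "c1ccncc1")))

  os <- substitutionScheme(list(c("O", "S")), maxSubstitutions = 1)
  e2 <- enumerateSubstitutions("c1ccoc1", os)
  expect_setequal(e2$normal_form,
                  capscore:::.obCanonical(c("c1ccoc1", "c1ccsc1")))

  # two substitutions: benzene -> {benzene, pyridine, 3 diazines}
  aza2 <- substitutionScheme(list(c("c", "n")), maxSubstitutions = 2)
  e3 <- enumerateSubstitutions("c1ccccc1", aza2)
  expect_equal(nrow(e3), 5L)
  expect_setequal(
    e3$normal_form,
    capscore:::.obCanonical(c("c1ccccc1", "c1ccncc1", "c1ccnnc1",
                              "c1cncnc1", "c1cnccn1")))
  # every product parses and survives canonicalization
  expect_false(anyNA(capscore:::.obCanonical(e3$smiles_pattern)))

  # empty scheme returns the input alone
  e4 <- enumerateSubstitutions("c1ccccc1",
                               substitutionScheme(list(), maxSubstitutions = 1))
  expect_equal(nrow(e4), 1L)
})

test_that("catalog dedup keys on normalized patterns, earlier id wins", {
  cat1 <- makeCatalog(c("0001", "0002"), smiles_pattern = c("c1ccccc1", "c1ccccc1"))
  dd <- deduplicate(cat1)
  expect_equal(patternIds(dd$catalog), "0001")
  expect_equal(dd$report$removed_id, "0002")

  disjoint <- makeCatalog(c("a", "b", "c"),
                          smiles_pattern = c("c1ccccc1", "c1ccncc1", "CCO"))
  expect_equal(length(deduplicate(disjoint)$catalog), 3L)

  # merged 10 + 10 with 3 overlaps (as rewritings) -> 17
  s1 <- c("c1ccccc1", "c1ccncc1", "c1ccoc1", "c1ccsc1", "CCO",
          "CC(=O)O", "C(=O)N", "C#N", "c1cncnc1", "c1cc[nH]c1")
  s2 <- c("C1=CC=CC=C1", "n1ccccc1", "OCC",            # overlaps with s1
          "c1ccc2ncccc2c1", "c1ccc2c(c1)cco2", "S(=O)(=O)N",
          "C(F)(F)F", "c1scnc1", "CCCC", "N")
  merged <- catalogDedup(
    makeCatalog(sprintf("A%02d", 1:10), smiles_pattern = s1),
    makeCatalog(sprintf("B%02d", 1:10), smiles_pattern = s2))
  expect_equal(length(merged), 17L)
  # pairwise-comparison oracle on normal forms
  nf <- c(makeCatalog(sprintf("A%02d", 1:10), smiles_pattern = s1)@data$normal_form,
          makeCatalog(sprintf("B%02d", 1:10), smiles_pattern = s2)@data$normal_form)
  expect_equal(length(merged), length(unique(nf)))
  # earlier nomenclature wins
  expect_true(all(grepl("^A", patternIds(merged)[1:10])))
})
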
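# shared molecule/pattern panels and fixture studies used across tests

# diverse drug-like molecules, all <= 30 heavy atoms
panelMolecules <- function() {
  c(benzene = "c1ccccc1",
    toluene = "Cc1ccccc1",
    phenol = "Oc1ccccc1",
    anisole = "COc1ccccc1",
    catechol = "Oc1ccccc1O",
    pyridine = "c1ccncc1",
    quinoline = "c1ccc2ncccc2c1",
    isoquinoline = "c1cc2ccncc2cc1",
    indole = "c1ccc2c(c1)cc[nH]2",
    n_methylindole = "Cn1ccc2ccccc21",
    furan = "c1ccoc1",
    benzofuran = "c1ccc2c(c1)cco2",
    thiophene = "c1ccsc1",
    thiazole = "c1cscn1",
    pyrimidine = "c1cncnc1",
    naphthalene = "c1ccc2ccccc2c1",
    biphenyl = "c1ccccc1-c1ccccc1",
    hexane = "CCCCCC",
    ethanol = "CCO",
    acetic_acid = "CC(=O)O",
    acetamide = "CC(N)=O",
    benzamide = "NC(=O)c1ccccc1",
    methyl_benzoate = "COC(=O)c1ccccc1",
    glyceraldehyde_R = "OC[C@@H](O)C=O",
    glyceraldehyde_S = "OC[C@H](O)C=O",
    sulfanilamide = "Nc1ccc(cc1)S(N)(=O)=O",
    benzonitrile = "N#Cc1ccccc1",
    trifluorotoluene = "FC(F)(F)c1ccccc1",
    aspirin = "CC(=O)Oc1ccccc1C(=O)O",
    nicotinamide = "NC(=O)c1cccnc1")
}

# catalog-style patterns, all <= 12 counted atoms, mixing plain fragments,
# defined hydrogens and attachment points
panelPatterns <- function() {
  c(hydroxy_h = "O[H]",
    phenol_r = "[R]c1ccc(O[H])cc1",
    benzene = "c1ccccc1",
    pyridine = "c1ccncc1",
    pyrrole_core = "n1cccc1",
    pyrrole_nh = "c1cc[nH]c1",
    furan = "c1ccoc1",
    thiophene = "c1ccsc1",
    amide = "C(=O)N",
    carboxyl_h = "C(=O)O[H]",
    ester = "C(=O)OC",
    sulfonamide = "S(=O)(=O)N",
    nitrile = "C#N",
    cf3 = "C(F)(F)F",
    biphenyl_single = "c1ccccc1-c1ccccc1",
    quinoline = "c1ccc2ncccc2c1")
}

# boundary-study fixture: group sizes chosen so every rule threshold is
# integer-exact (40% of 40 direct = 16; 20% of 50 total = 10; 5 of 10
# inconclusive)
boundaryStudy <- function(seed = 11L) {
  planted <- data.frame(
    frag_id = c("pyridine", "furan", "thiophene", "oxazole", "nitrile",
                "sulfonamide", "amide"),
    n_direct       = c(16L, 15L,  8L,  9L, 20L, 0L, 0L),
    n_inconclusive = c(0L,   0L,  2L,  0L,  5L, 5L, 4L),
    n_library      = c(0L,   0L,  0L,  0L,  0L, 0L, 0L),
    stringsAsFactors = FALSE
  )
  spec <- fixtureSpec(seed = seed, nDirect = 40L, nInconclusive = 10L,
                      nLibrary = 0L, planted = planted)
  generateCompoundSet(spec)
}

# expected fingerprint for boundaryStudy under default thresholds:
#   primary:      nitrile (50%) and pyridine (16/40 = 40%, inclusive
#                 boundary); furan one-below (37.5%); no size rule applies
#   four-atom:    pyridine 32%, furan 30%, thiophene 20% (boundary);
#                 oxazole 18% (one-below), nitrile 50% but 2 atoms,
#                 sulfonamide/amide < 20%
#   secondary:    sulfonamide (5/10, 4-atom scheme, not elsewhere);
#                 amide one-below (4/10); nitrile fails the atom rule
boundaryExpectations <- function() {
  list(primary = c("nitrile", "pyridine"),
       four_atom = c("pyridine", "furan", "thiophene"),
       secondary = "sulfonamide",
       not_primary = "furan",
       not_four_atom = c("oxazole", "nitrile", "sulfonamide", "amide"),
       not_secondary = c("amide", "nitrile"))
}
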
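# Thin wrappers around ChemmineOB (Open Babel). All molecule-level chemistry
# (SMILES parsing, canonicalization, SMARTS matching, descriptor primitives)
# is delegated here; one aromaticity/valence model therefore applies to both
# the screened molecules and the catalog patterns.

.OB_NOOPT <- data.frame(names = character(0), args = character(0))

# Canonical isomeric SMILES, or NA_character_ for unparseable input.
# Open Babel truncates batch conversion at the first bad record, so each
# string is converted on its own.
.obCanonical <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    out <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", paste0(s, "\n"),
                                                 options = .OB_NOOPT)),
      error = function(e) ""
    )
    out <- sub("[ \t\r\n]+$", "", out)
    if (!nzchar(out)) NA_character_ else out
  }, character(1), USE.NAMES = FALSE)
}

# Open Babel molecule handle for repeated SMARTS queries on one molecule.
.obMol <- function(smiles) {
  ChemmineOB::forEachMol("SMILES", smiles, identity)
}

.obMatches <- function(mol, smarts) {
  ChemmineOB::smartsSearch_OB(mol, smarts, uniqueMatches = TRUE) > 0
}

.obMatchCount <- function(mol, smarts) {
  ChemmineOB::smartsSearch_OB(mol, smarts, uniqueMatches = TRUE)
}

.obProps <- function(mol) {
  ChemmineOB::prop_OB(mol)
}
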
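# Brute-force subgraph-matching oracle, independent of the SMARTS route used
# by matchesPattern(): molecules are canonicalized, parsed into atom/bond
# graphs, and pattern embedding is decided by exhaustive backtracking over
# injective atom maps. Used to cross-check the production matcher.

.oracleGraph <- function(smiles) {
  g <- capscore:::.parseSmilesGraph(capscore::canonicalizeSmiles(smiles))
  g$h <- capscore:::.implicitHydrogens(g)
  g
}

.oraclePatternGraph <- function(pattern_smiles) {
  capscore:::.parseSmilesGraph(pattern_smiles)
}

# bond compatibility mirroring the declared match semantics:
# aromatic -> aromatic; double/triple -> equal order; single between two
# aromatic-written atoms -> strictly single; other singles -> single or
# aromatic (the aromatic case is only reachable for unconstrained atoms)
.bondCompatible <- function(pb_arom, pb_order, p_arom1, p_arom2,
                            mb_arom, mb_order) {
  if (pb_arom) return(mb_arom)
  if (pb_order == 2L) return(!mb_arom && mb_order == 2L)
  if (pb_order == 3L) return(!mb_arom && mb_order == 3L)
  if (p_arom1 && p_arom2) return(!mb_arom && mb_order == 1L)
  mb_arom || mb_order == 1L
}

oracleMatches <- function(mol_smiles, pattern_smiles, rMatchesH = TRUE) {
  mol <- .oracleGraph(mol_smiles)
  pat <- .oraclePatternGraph(pattern_smiles)
  pA <- pat$atoms; mA <- mol$atoms
  keep <- if (rMatchesH) which(!pA$isR) else seq_len(nrow(pA))
  np <- length(keep); nm <- nrow(mA)
  if (np == 0L) return(TRUE)
  if (np > nm) return(FALSE)

  # adjacency lookup for molecule bonds
  mB <- mol$bonds
  mbond <- function(i, j) {
    k <- which((mB$a1 == i & mB$a2 == j) | (mB$a1 == j & mB$a2 == i))
    if (length(k) == 0L) NULL else mB[k[1L], ]
  }
  pB <- pat$bonds

  atom_ok <- function(pi, mi) {
    if (pA$isR[pi]) return(TRUE)  # strict mode: any heavy atom
    if (pA$element[pi] != mA$element[mi]) return(FALSE)
    if (pA$aromatic[pi] != mA$aromatic[mi]) return(FALSE)
    if (pA$charge[pi] != 0L && pA$charge[pi] != mA$charge[mi]) return(FALSE)
    mol$h[mi] >= pA$hdef[pi]
  }

  # visit pattern atoms in a connectivity order so each new atom has at
  # least one already-mapped neighbour (except the first)
  order_visit <- keep[1L]
  remaining <- setdiff(keep, order_visit)
  while (length(remaining) > 0L) {
    nxt <- NA_integer_
    for (cand in remaining) {
      nb <- c(pB$a2[pB$a1 == cand], pB$a1[pB$a2 == cand])
      if (any(nb %in% order_visit)) { nxt <- cand; break }
    }
    if (is.na(nxt)) nxt <- remaining[1L]
    order_visit <- c(order_visit, nxt)
    remaining <- setdiff(remaining, nxt)
  }

  mapping <- rep(NA_integer_, nrow(pA))
  found <- FALSE
  bt <- function(step) {
    if (found) return()
    if (step > length(order_visit)) { found <<- TRUE; return() }
    pi <- order_visit[step]
    for (mi in seq_len(nm)) {
      if (found) return()
      if (mi %in% mapping) next
      if (!atom_ok(pi, mi)) next
      ok <- TRUE
      for (k in seq_len(nrow(pB))) {
        other <- if (pB$a1[k] == pi) pB$a2[k]
                 else if (pB$a2[k] == pi) pB$a1[k] else next
        mo <- mapping[other]
        if (is.na(mo)) next
        if (rMatchesH && pA$isR[other]) next
        mb <- mbond(mi, mo)
        if (is.null(mb) ||
            !.bondCompatible(pB$aromatic[k], pB$order[k],
                             pA$aromatic[pB$a1[k]] && !pA$isR[pB$a1[k]],
                             pA$aromatic[pB$a2[k]] && !pA$isR[pB$a2[k]],
                             mb$aromatic, mb$order)) { ok <- FALSE; break }
      }
      if (!ok) next
      mapping[pi] <<- mi
      bt(step + 1L)
      mapping[pi] <<- NA_integer_
    }
  }
  bt(1L)
  found
}

# oracle incidence matrix over molecule/pattern panels
oracleMatrix <- function(mol_smiles, pattern_smiles) {
  out <- matrix(FALSE, length(mol_smiles), length(pattern_smiles),
                dimnames = list(names(mol_smiles), names(pattern_smiles)))
  for (i in seq_along(mol_smiles)) {
    for (j in seq_along(pattern_smiles)) {
      out[i, j] <- oracleMatches(mol_smiles[[i]], pattern_smiles[[j]])
    }
  }
  out
}
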
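# Internal SMILES-dialect parser and writers for substructure patterns.
#
# Catalog patterns are SMILES-like strings that may carry two extra tokens:
#   [R] -- an attachment point (any substituent; does not count as an atom)
#   [H] -- a defined (= irreplaceable) hydrogen at the preceding position
# Atom counting rule: heavy atoms + defined hydrogens count, [R] does not;
# distinct elements are counted over the counted atoms (H included).

.ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.AROMATIC_ORGANIC <- c("b", "c", "n", "o", "p", "s")

# default valences used for implicit-hydrogen assignment (lowest listed
# valence >= bond-order sum wins, as in the SMILES organic-subset rule)
.DEFAULT_VALENCE <- list(
  B = 3, C = 4, N = 3, O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1
)

.pattern_error <- function(msg, id = NULL) {
  stop(structure(
    class = c("capscore_pattern_error", "error", "condition"),
    list(message = if (is.null(id)) msg else sprintf("pattern '%s': %s", id, msg),
         call = sys.call(-1))
  ))
}

# Parse one bracket atom body (text between '[' and ']').
# Returns list(element, aromatic, charge, hcount) or isR/isH markers.
.parseBracketAtom <- function(body, full, id) {
  s <- body
  # isotope prefix (ignored for matching purposes)
  s <- sub("^[0-9]+", "", s)
  if (s == "R" || grepl("^R[0-9]*$", s)) {
    return(list(isR = TRUE))
  }
  m <- regmatches(s, regexpr("^([A-Z][a-z]?|[bcnops]|se|as)", s))
  if (length(m) == 0L) {
    .pattern_error(sprintf("cannot read bracket atom '[%s]'", body), id)
  }
  elem_raw <- m
  s <- substring(s, nchar(elem_raw) + 1L)
  aromatic <- elem_raw %in% c(.AROMATIC_ORGANIC, "se", "as")
  element <- if (aromatic) {
    paste0(toupper(substring(elem_raw, 1, 1)), substring(elem_raw, 2))
  } else {
    elem_raw
  }
  if (element == "H" && !aromatic) {
    # explicit hydrogen atom token: fold into neighbour later
    return(list(isH = TRUE))
  }
  # chirality (stereo is ignored throughout pattern matching)
  s <- sub("^@@?(TH[12]|AL[12]|SP[1-3])?", "", s)
  hcount <- 0L
  hm <- regmatches(s, regexpr("^H[0-9]*", s))
  if (length(hm) == 1L) {
    hcount <- if (hm == "H") 1L else as.integer(substring(hm, 2))
    s <- substring(s, nchar(hm) + 1L)
  }
  charge <- 0L
  cm <- regmatches(s, regexpr("^(\\+{1,3}|-{1,3}|\\+[0-9]|-[0-9])", s))
  if (length(cm) == 1L) {
    charge <- if (grepl("[0-9]", cm)) {
      as.integer(cm)
    } else {
      (nchar(cm)) * (if (substring(cm, 1, 1) == "+") 1L else -1L)
    }
    s <- substring(s, nchar(cm) + 1L)
  }
  s <- sub("^:[0-9]+$", "", s)
  if (nzchar(s)) {
    .pattern_error(sprintf("unsupported token '%s' in bracket atom '[%s]'", s, body), id)
  }
  list(element = element, aromatic = aromatic, charge = charge,
       hcount = hcount, isR = FALSE, isH = FALSE)
}

# Parse a pattern (or plain SMILES) string into an atom/bond graph.
#
# Returns list(atoms, bonds):
#   atoms: data.frame(element, aromatic, charge, hdef, hcount, isR, bracket)
#     hdef   = defined hydrogens ([H] neighbours + bracket H count)
#     hcount = bracket H count or NA when unspecified (organic subset)
#   bonds: data.frame(a1, a2, order, aromatic, explicit_single)
.parseSmilesGraph <- function(smiles, id = NULL) {
  if (is.na(smiles) || !nzchar(smiles)) .pattern_error("empty pattern string", id)
  chars <- strsplit(smiles, "")[[1]]
  n <- length(chars)

  atoms <- list()
  bonds <- list()
  h_pend <- list()   # (atom, count) pairs from explicit [H] tokens
  prev <- NA_integer_
  stack <- integer(0)
  pending_bond <- NULL  # NULL = implicit; else list(order, aromatic, explicit)
  ring_open <- list()   # digit -> list(atom, bond)
  i <- 1L

  add_atom <- function(a) {
    atoms[[length(atoms) + 1L]] <<- a
    length(atoms)
  }
  connect <- function(a1, a2, bond) {
    if (is.null(bond)) {
      bonds[[length(bonds) + 1L]] <<- list(a1 = a1, a2 = a2, order = 1L,
                                           aromatic = NA, explicit_single = FALSE)
    } else {
      bonds[[length(bonds) + 1L]] <<- list(a1 = a1, a2 = a2, order = bond$order,
                                           aromatic = bond$aromatic,
                                           explicit_single = bond$explicit)
    }
  }
  place_atom <- function(a) {
    idx <- add_atom(a)
    if (!is.na(prev)) connect(prev, idx, pending_bond)
    pending_bond <<- NULL
    prev <<- idx
    idx
  }

  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) .pattern_error("unclosed bracket atom", id)
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      at <- .parseBracketAtom(body, smiles, id)
      if (isTRUE(at$isH)) {
        if (is.na(prev)) .pattern_error("[H] token with no preceding atom", id)
        h_pend[[length(h_pend) + 1L]] <- prev
        pending_bond <- NULL
      } else if (isTRUE(at$isR)) {
        place_atom(list(element = "R", aromatic = FALSE, charge = 0L,
                        hdef = 0L, hcount = 0L, isR = TRUE, bracket = TRUE))
      } else {
        place_atom(list(element = at$element, aromatic = at$aromatic,
                        charge = at$charge, hdef = at$hcount,
                        hcount = at$hcount, isR = FALSE, bracket = TRUE))
      }
      i <- j + 1L
    } else if (ch %in% c("C", "B") && i < n && chars[i + 1L] %in% c("l", "r") &&
               paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      place_atom(list(element = paste0(ch, chars[i + 1L]), aromatic = FALSE,
                      charge = 0L, hdef = 0L, hcount = NA_integer_,
                      isR = FALSE, bracket = FALSE))
      i <- i + 2L
    } else if (ch %in% .ORGANIC_SUBSET) {
      place_atom(list(element = ch, aromatic = FALSE, charge = 0L, hdef = 0L,
                      hcount = NA_integer_, isR = FALSE, bracket = FALSE))
      i <- i + 1L
    } else if (ch %in% .AROMATIC_ORGANIC) {
      place_atom(list(element = toupper(ch), aromatic = TRUE, charge = 0L,
                      hdef = 0L, hcount = NA_integer_, isR = FALSE,
                      bracket = FALSE))
      i <- i + 1L
    } else if (ch == "(") {
      if (is.na(prev)) .pattern_error("branch with no preceding atom", id)
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) .pattern_error("unbalanced ')'", id)
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch %in% c("-", "/", "\\")) {
      pending_bond <- list(order = 1L, aromatic = FALSE, explicit = TRUE)
      i <- i + 1L
    } else if (ch == "=") {
      pending_bond <- list(order = 2L, aromatic = FALSE, explicit = TRUE)
      i <- i + 1L
    } else if (ch == "#") {
      pending_bond <- list(order = 3L, aromatic = FALSE, explicit = TRUE)
      i <- i + 1L
    } else if (ch == ":") {
      pending_bond <- list(order = 1L, aromatic = TRUE, explicit = TRUE)
      i <- i + 1L
    } else if (grepl("[0-9]", ch) || ch == "%") {
      if (ch == "%") {
        if (i + 2L > n) .pattern_error("truncated %nn ring closure", id)
        num <- paste(chars[(i + 1L):(i + 2L)], collapse = "")
        i <- i + 3L
      } else {
        num <- ch
        i <- i + 1L
      }
      if (is.na(prev)) .pattern_error("ring closure with no preceding atom", id)
      if (!is.null(ring_open[[num]])) {
        op <- ring_open[[num]]
        bond <- if (!is.null(pending_bond)) pending_bond else op$bond
        connect(op$atom, prev, bond)
        pending_bond <- NULL
        ring_open[[num]] <- NULL
      } else {
        ring_open[[num]] <- list(atom = prev, bond = pending_bond)
        pending_bond <- NULL
      }
    } else if (ch == ".") {
      .pattern_error("disconnected (multi-fragment) patterns are not supported", id)
    } else if (ch %in% c("@", "+")) {
      .pattern_error(sprintf("unexpected character '%s' outside brackets", ch), id)
    } else {
      .pattern_error(sprintf("unrecognized character '%s'", ch), id)
    }
  }
  if (length(ring_open) > 0L) .pattern_error("unclosed ring bond", id)
  if (length(stack) > 0L) .pattern_error("unbalanced '('", id)
  if (length(atoms) == 0L) .pattern_error("no atoms in pattern", id)

  A <- data.frame(
    element = vapply(atoms, `[[`, "", "element"),
    aromatic = vapply(atoms, `[[`, FALSE, "aromatic"),
    charge = vapply(atoms, function(a) as.integer(a$charge), 0L),
    hdef = vapply(atoms, function(a) as.integer(a$hdef), 0L),
    hcount = vapply(atoms, function(a) as.integer(a$hcount), 0L),
    isR = vapply(atoms, `[[`, FALSE, "isR"),
    bracket = vapply(atoms, `[[`, FALSE, "bracket"),
    stringsAsFactors = FALSE
  )
  # fold explicit [H] tokens into their neighbour's defined-H count
  for (at in h_pend) A$hdef[at] <- A$hdef[at] + 1L

  if (length(bonds) > 0L) {
    B <- data.frame(
      a1 = vapply(bonds, function(b) as.integer(b$a1), 0L),
      a2 = vapply(bonds, function(b) as.integer(b$a2), 0L),
      order = vapply(bonds, function(b) as.integer(b$order), 0L),
      aromatic = vapply(bonds, function(b) as.logical(b$aromatic), NA),
      explicit_single = vapply(bonds, `[[`, FALSE, "explicit_single"),
      stringsAsFactors = FALSE
    )
  } else {
    B <- data.frame(a1 = integer(0), a2 = integer(0), order = integer(0),
                    aromatic = logical(0), explicit_single = logical(0))
  }

  # [R] must be a terminal attachment
  if (any(A$isR)) {
    for (r in which(A$isR)) {
      deg <- sum(B$a1 == r | B$a2 == r)
      if (deg != 1L) {
        .pattern_error("[R] attachment points must be terminal (exactly one bond)", id)
      }
    }
    if (sum(!A$isR) == 0L) .pattern_error("pattern consists only of [R] tokens", id)
  }

  g <- list(atoms = A, bonds = B)
  g$bonds <- .resolveAromaticBonds(g)
  g
}

# A bond is in a ring iff its endpoints stay connected after its removal.
.ringBondFlags <- function(atoms, bonds) {
  nb <- nrow(bonds)
  if (nb == 0L) return(logical(0))
  n <- nrow(atoms)
  flags <- logical(nb)
  for (k in seq_len(nb)) {
    # BFS from a1 to a2 avoiding bond k
    src <- bonds$a1[k]; dst <- bonds$a2[k]
    seen <- rep(FALSE, n)
    seen[src] <- TRUE
    queue <- src
    while (length(queue) > 0L && !seen[dst]) {
      cur <- queue[1L]; queue <- queue[-1L]
      idx <- which((bonds$a1 == cur | bonds$a2 == cur) & seq_len(nb) != k)
      for (b in idx) {
        other <- if (bonds$a1[b] == cur) bonds$a2[b] else bonds$a1[b]
        if (!seen[other]) { seen[other] <- TRUE; queue <- c(queue, other) }
      }
    }
    flags[k] <- seen[dst]
  }
  flags
}

# Implicit bonds between two aromatic atoms are aromatic when they lie in a
# ring (biphenyl-type inter-ring bonds stay single). Explicit '-' stays single.
.resolveAromaticBonds <- function(g) {
  B <- g$bonds
  if (nrow(B) == 0L) return(B)
  ring <- .ringBondFlags(g$atoms, B)
  B$in_ring <- ring
  implicit <- is.na(B$aromatic)
  both_arom <- g$atoms$aromatic[B$a1] & g$atoms$aromatic[B$a2]
  B$aromatic[implicit] <- both_arom[implicit] & ring[implicit]
  B$aromatic[!implicit & B$explicit_single] <- FALSE
  B$aromatic[is.na(B$aromatic)] <- FALSE
  B
}

# Implicit hydrogen count per atom under organic-subset valence rules.
# Aromatic bonds contribute 1.5 to the bond-order sum (ceiling applied).
.implicitHydrogens <- function(g) {
  A <- g$atoms; B <- g$bonds
  n <- nrow(A)
  h <- integer(n)
  bsum <- numeric(n)
  if (nrow(B) > 0L) {
    contrib <- ifelse(B$aromatic, 1.5, B$order)
    for (k in seq_len(nrow(B))) {
      bsum[B$a1[k]] <- bsum[B$a1[k]] + contrib[k]
      bsum[B$a2[k]] <- bsum[B$a2[k]] + contrib[k]
    }
  }
  for (i in seq_len(n)) {
    if (A$isR[i]) { h[i] <- 0L; next }
    if (A$bracket[i]) { h[i] <- A$hcount[i]; next }  # bracket: H as written
    vals <- .DEFAULT_VALENCE[[A$element[i]]]
    if (is.null(vals)) { h[i] <- 0L; next }
    # charge shifts the target valence (N+ -> 4, O- -> 1, ...)
    vals <- vals + A$charge[i]
    need <- ceiling(bsum[i])
    ok <- vals[vals >= need]
    h[i] <- if (length(ok) == 0L) 0L else as.integer(min(ok) - need)
  }
  h
}

# --- SMARTS emission ---------------------------------------------------------

.smartsAtomExpr <- function(A, i) {
  sym <- A$element[i]
  sym <- if (A$aromatic[i]) tolower(sym) else sym
  parts <- sym
  if (A$charge[i] != 0L) {
    ch <- A$charge[i]
    parts <- c(parts, if (ch == 1L) "+" else if (ch == -1L) "-"
               else sprintf("%+d", ch))
  }
  if (A$hdef[i] > 0L) {
    # defined hydrogens are a minimum requirement at the mapped position
    parts <- c(parts, paste0("!H", seq_len(A$hdef[i]) - 1L))
  }
  paste0("[", paste(parts, collapse = ";"), "]")
}

.smartsBondExpr <- function(A, B, k) {
  if (B$aromatic[k]) return(":")
  if (B$order[k] == 2L) return("=")
  if (B$order[k] == 3L) return("#")
  # single bond between two aromatic atoms must not match a fused
  # aromatic bond, so it is written explicitly
  if (A$aromatic[B$a1[k]] && A$aromatic[B$a2[k]]) return("-")
  ""
}

# Depth-first writer shared by the SMARTS and SMILES emitters.
# atom_expr(i) and bond_expr(k) produce the token text; skip marks atoms to
# omit entirely (terminal attachment points in permissive mode).
.writeGraph <- function(g, atom_expr, bond_expr, skip = rep(FALSE, nrow(g$atoms))) {
  A <- g$atoms; B <- g$bonds
  n <- nrow(A)
  keep <- which(!skip)
  if (length(keep) == 0L) .pattern_error("nothing to write after dropping attachment points")
  adj <- vector("list", n)
  for (k in seq_len(nrow(B))) {
    if (skip[B$a1[k]] || skip[B$a2[k]]) next
    adj[[B$a1[k]]] <- c(adj[[B$a1[k]]], k)
    adj[[B$a2[k]]] <- c(adj[[B$a2[k]]], k)
  }
  visited <- rep(FALSE, n)
  used_bond <- rep(FALSE, nrow(B))
  ring_num <- 0L
  ring_label <- list()  # bond index -> digit label
  # first pass: identify back edges via DFS
  order_visit <- integer(0)
  stack <- list(list(atom = keep[1L], from = NA_integer_))
  visited[keep[1L]] <- TRUE
  tree_children <- vector("list", n)
  back_edges <- vector("list", n)  # atom -> bond indices opening a ring there
  dfs <- function(a) {
    for (k in adj[[a]]) {
      if (used_bond[k]) next
      other <- if (B$a1[k] == a) B$a2[k] else B$a1[k]
      if (!visited[other]) {
        used_bond[k] <<- TRUE
        visited[other] <<- TRUE
        tree_children[[a]] <<- c(tree_children[[a]], list(list(bond = k, atom = other)))
        dfs(other)
      } else if (!used_bond[k]) {
        used_bond[k] <<- TRUE
        ring_num <<- ring_num + 1L
        lbl <- if (ring_num < 10L) as.character(ring_num) else paste0("%", ring_num)
        ring_label[[as.character(k)]] <<- lbl
        back_edges[[a]] <<- c(back_edges[[a]], k)
        back_edges[[other]] <<- c(back_edges[[other]], k)
      }
    }
  }
  dfs(keep[1L])
  if (!all(visited[keep])) {
    .pattern_error("pattern graph is disconnected after dropping attachment points")
  }
  emitted_ring <- rep(FALSE, nrow(B))
  emit <- function(a) {
    out <- atom_expr(a)
    for (k in back_edges[[a]]) {
      lbl <- ring_label[[as.character(k)]]
      # the bond symbol goes on the first (opening) occurrence
      pre <- if (!emitted_ring[k]) bond_expr(k) else ""
      emitted_ring[k] <<- TRUE
      out <- paste0(out, pre, lbl)
    }
    kids <- tree_children[[a]]
    if (length(kids) > 0L) {
      for (j in seq_along(kids)) {
        sub <- paste0(bond_expr(kids[[j]]$bond), emit(kids[[j]]$atom))
        out <- if (j < length(kids)) paste0(out, "(", sub, ")") else paste0(out, sub)
      }
    }
    out
  }
  emit(keep[1L])
}

# Translate a parsed pattern graph into a SMARTS expression implementing the
# match semantics: presence-only, stereo-blind, defined-H enforced as a
# minimum, attachment points unconstrained (permissive) or heavy-atom-only.
.graphToSmarts <- function(g, rMatchesH = TRUE) {
  A <- g$atoms
  skip <- A$isR & rMatchesH
  atom_expr <- function(i) if (A$isR[i]) "[!#1]" else .smartsAtomExpr(A, i)
  bond_expr <- function(k) .smartsBondExpr(A, g$bonds, k)
  .writeGraph(g, atom_expr, bond_expr, skip = skip)
}

# Normal form used as the dedup key for catalog entries: attachment points
# become [U] placeholders, defined hydrogens become [At] placeholders, and
# Open Babel canonicalization makes the key independent of atom ordering.
.patternNormalForm <- function(g) {
  A <- g$atoms
  atom_expr <- function(i) {
    if (A$isR[i]) return("[U]")
    sym <- if (A$aromatic[i]) tolower(A$element[i]) else A$element[i]
    core <- if (A$charge[i] != 0L) {
      paste0("[", sym, if (A$charge[i] > 0) strrep("+", A$charge[i])
             else strrep("-", -A$charge[i]), "]")
    } else if (A$bracket[i] && !(A$element[i] %in% .ORGANIC_SUBSET)) {
      paste0("[", sym, "]")
    } else sym
    if (A$hdef[i] > 0L) {
      core <- paste0(core, strrep("([At])", A$hdef[i]))
    }
    core
  }
  bond_expr <- function(k) {
    B <- g$bonds
    if (B$aromatic[k]) return("")
    if (B$order[k] == 2L) return("=")
    if (B$order[k] == 3L) return("#")
    if (A$aromatic[B$a1[k]] && A$aromatic[B$a2[k]]) return("-")
    ""
  }
  raw <- .writeGraph(g, atom_expr, bond_expr)
  can <- .obCanonical(raw)
  if (is.na(can)) raw else can
}

# Plain-SMILES emitter for substitution products (no [R]/[H] decoration).
.graphToSmiles <- function(g) {
  A <- g$atoms
  atom_expr <- function(i) {
    sym <- if (A$aromatic[i]) tolower(A$element[i]) else A$element[i]
    hc <- if (is.na(A$hcount[i])) 0L else A$hcount[i]
    needs_bracket <- A$charge[i] != 0L || hc > 0L ||
      (A$bracket[i] && !(A$element[i] %in% .ORGANIC_SUBSET)) ||
      (A$aromatic[i] && !(tolower(A$element[i]) %in% .AROMATIC_ORGANIC))
    if (!needs_bracket) return(sym)
    h <- if (hc > 0L) paste0("H", if (hc > 1L) hc else "") else ""
    ch <- if (A$charge[i] > 0L) strrep("+", A$charge[i])
          else if (A$charge[i] < 0L) strrep("-", -A$charge[i]) else ""
    paste0("[", sym, h, ch, "]")
  }
  bond_expr <- function(k) {
    B <- g$bonds
    if (B$aromatic[k]) return("")
    if (B$order[k] == 2L) return("=")
    if (B$order[k] == 3L) return("#")
    if (A$aromatic[B$a1[k]] && A$aromatic[B$a2[k]]) return("-")
    ""
  }
  .writeGraph(g, atom_expr, bond_expr)
}

# Counted-atom statistics per the catalog counting rule.
.patternStats <- function(g) {
  A <- g$atoms
  heavy <- !A$isR
  defined_h <- sum(A$hdef[heavy])
  counted <- sum(heavy) + defined_h
  elems <- unique(A$element[heavy])
  if (defined_h > 0L) elems <- union(elems, "H")
  # an aromatic heteroatom is by construction part of a heteroaromatic ring
  heteroarom <- any(A$aromatic & A$element != "C" & !A$isR)
  list(
    counted_atoms = as.integer(counted),
    defined_h = as.integer(defined_h),
    distinct_elements = length(elems),
    is_heteroaromatic_scaffold = isTRUE(heteroarom)
  )
}
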
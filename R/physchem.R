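# rotatable bond: single, acyclic, both ends non-terminal, neither end a
# triple-bonded atom (classic definition; unique SMARTS matching counts
# each bond once)
.ROTATABLE_SMARTS <- "[!$(*#*)&!D1]-&!@[!$(*#*)&!D1]"

#' Compute molecular descriptors
#'
#' Computes the eight-descriptor vector per compound: calculated
#' octanol-water partition coefficient (CLogP), molecular weight (MW,
#' g/mol), molar refractivity (MR), topological polar surface area (TPSA,
#' A^2), hydrogen-bond donors and acceptors, rotatable bonds, and heavy
#' atoms. CLogP, MR and TPSA come from Open Babel's published
#' atom-contribution models; absolute parity with commercial estimators is
#' not expected for CLogP, whereas MW and the count descriptors are
#' implementation-independent. HBD and HBA follow the Lipinski conventions
#' (HBD = number of O-H and N-H hydrogens, HBA = number of N and O atoms).
#'
#' @param compounds a \linkS4class{CompoundSet} or character vector of
#'   SMILES.
#' @return data.frame keyed by \code{compound_id} with columns
#'   \code{clogp}, \code{mw}, \code{mr}, \code{tpsa}, \code{hbd},
#'   \code{hba}, \code{rotatable_bonds}, \code{heavy_atoms}.
#' @examples
#' computeDescriptors("CCO")   # ethanol: hbd = 1, hba = 1, mw ~ 46.07
#' @export
computeDescriptors <- function(compounds) {
  smiles <- if (is(compounds, "CompoundSet")) {
    canonicalSmiles(compounds)
  } else {
    stats::setNames(as.character(compounds),
                    names(compounds) %||% as.character(compounds))
  }
  rows <- lapply(seq_along(smiles), function(i) {
    mol <- .obMol(smiles[[i]])
    p <- .obProps(mol)
    hbd <- sum(vapply(1:4, function(k) {
      k * .obMatchCount(mol, sprintf("[#7H%d,#8H%d]", k, k))
    }, numeric(1)))
    hba <- .obMatchCount(mol, "[#7,#8]")
    rot <- .obMatchCount(mol, .ROTATABLE_SMARTS)  # unique matches: 1 per bond
    heavy <- .obMatchCount(mol, "[!#1]")
    data.frame(compound_id = names(smiles)[i],
               clogp = p$logP, mw = p$MW, mr = p$MR, tpsa = p$TPSA,
               hbd = as.integer(hbd), hba = as.integer(hba),
               rotatable_bonds = as.integer(rot),
               heavy_atoms = as.integer(heavy),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-group descriptor statistics and drug-likeness fractions
#'
#' Median and mean of each descriptor per compound group, plus the
#' rule-of-five fractions with inclusive thresholds: CLogP <= 5, MW <= 500,
#' HBD <= 5, HBA <= 10. The \code{all} group spans the whole set. Empty
#' groups report NA rather than erroring.
#'
#' @param set a \linkS4class{CompoundSet}.
#' @param descriptors optional precomputed \code{\link{computeDescriptors}}
#'   table.
#' @param groups group labels to report, in addition to \code{"all"}.
#' @return data.frame with one row per group: \code{n}, per-descriptor
#'   \code{<desc>_median} / \code{<desc>_mean}, and the four percentage
#'   columns \code{pct_clogp_le5}, \code{pct_mw_le500}, \code{pct_hbd_le5},
#'   \code{pct_hba_le10}.
#' @export
groupStatistics <- function(set, descriptors = NULL,
                            groups = c("direct", "inconclusive")) {
  if (is.null(descriptors)) descriptors <- computeDescriptors(set)
  grp <- compoundGroups(set)
  stopifnot(all(descriptors$compound_id == names(grp)))
  desc_cols <- c("clogp", "mw", "mr", "tpsa", "hbd", "hba",
                 "rotatable_bonds", "heavy_atoms")
  one <- function(label, rows) {
    d <- descriptors[rows, , drop = FALSE]
    out <- data.frame(group = label, n = nrow(d), stringsAsFactors = FALSE)
    for (col in desc_cols) {
      v <- d[[col]]
      out[[paste0(col, "_median")]] <- if (nrow(d) == 0L) NA_real_ else stats::median(v)
      out[[paste0(col, "_mean")]] <- if (nrow(d) == 0L) NA_real_ else mean(v)
    }
    frac <- function(x) if (nrow(d) == 0L) NA_real_ else 100 * mean(x)
    out$pct_clogp_le5 <- frac(d$clogp <= 5)
    out$pct_mw_le500 <- frac(d$mw <= 500)
    out$pct_hbd_le5 <- frac(d$hbd <= 5)
    out$pct_hba_le10 <- frac(d$hba <= 10)
    out
  }
  res <- list(one("all", rep(TRUE, length(grp))))
  for (g in groups) res[[length(res) + 1L]] <- one(g, grp == g)
  do.call(rbind, res)
}

#' Histogram export for a descriptor
#'
#' Fixed-width binning of one descriptor over a compound group; bin counts
#' always sum to the group size (values outside the given range are clamped
#' into the edge bins so nothing is dropped).
#'
#' @param set a \linkS4class{CompoundSet} or a descriptor table.
#' @param descriptor descriptor column name.
#' @param binWidth positive bin width.
#' @param origin left edge of the first bin (default: floor of the minimum).
#' @return data.frame with \code{bin_low}, \code{bin_high}, \code{count}.
#' @export
histogramExport <- function(set, descriptor = "mw", binWidth = 50,
                            origin = NULL) {
  if (binWidth <= 0) stop("binWidth must be positive")
  d <- if (is(set, "CompoundSet")) computeDescriptors(set) else set
  v <- d[[descriptor]]
  if (is.null(v)) stop(sprintf("unknown descriptor '%s'", descriptor))
  if (length(v) == 0L) {
    return(data.frame(bin_low = numeric(0), bin_high = numeric(0),
                      count = integer(0)))
  }
  if (is.null(origin)) origin <- floor(min(v) / binWidth) * binWidth
  idx <- pmax(0L, floor((v - origin) / binWidth))
  nbin <- max(idx) + 1L
  counts <- tabulate(idx + 1L, nbins = nbin)
  data.frame(bin_low = origin + (seq_len(nbin) - 1L) * binWidth,
             bin_high = origin + seq_len(nbin) * binWidth,
             count = counts)
}
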
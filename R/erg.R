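# Reduced-graph pharmacophoric fingerprint in the ErG style: molecules
# are abstracted to six property-point types (donor, acceptor, positive,
# negative, hydrophobe, aromatic system), pairwise topological distances
# between points are histogrammed per type pair with fuzzy +/-1-bin
# increments, and similarity is the modified Tanimoto for non-binary
# vectors. The property typing here is deliberately independent of the
# pinned 8-family definitions used for the conditioning fingerprints, so
# that pharmacophoric similarity scoring does not share patterns with
# the condition channel it evaluates.

ERG_TYPES <- c("D", "A", "P", "M", "Hf", "Ar")
ERG_MAX_DIST <- 15L
ERG_FUZZ <- 0.3

erg_atom_smarts <- list(
  D = c("[O,S;H1;+0]", "[#7;!H0;+0,+1]"),
  A = c("[OX1]", "[OX2;+0]", "[O-]", "[nX2;+0]", "[NX1]",
        "[NX2;$(N=C);+0]", "[NX3;+0;!$(N=*);!$(N-a);!$(NC=[O,N,S])]"),
  P = c("[+;!$([+]~[-])]"),
  M = c("[-;!$([-]~[+])]", "[OX2H1;$(OC=O)]"),
  Hf = c("[C;!R;!$(C~[!#6;!#1])]", "[Cl,Br,I;X1]")
)

# Property points of one molecule: list of (type, atoms). Aromatic ring
# systems and saturated carbocyclic systems are single lumped points.
erg_points <- function(md) {
  pts <- list()
  for (ty in names(erg_atom_smarts)) {
    for (pat in erg_atom_smarts[[ty]]) {
      for (hit in ob_smarts_match(md$mol, pat)) {
        pts[[length(pts) + 1L]] <- list(type = ty,
                                        atoms = sort(as.integer(hit)))
      }
    }
  }
  # ring systems from connected components of the ring-bond subgraph
  rb <- md$bonds[md$bonds$in_ring, , drop = FALSE]
  if (nrow(rb)) {
    rg <- igraph::graph_from_data_frame(
      data.frame(from = rb$begin, to = rb$end), directed = FALSE)
    comp <- igraph::components(rg)$membership
    for (cid in unique(comp)) {
      atoms <- sort(as.integer(names(comp)[comp == cid]))
      arom <- md$atoms$aromatic[match(atoms, md$atoms$idx)]
      elem <- md$atoms$atomic_num[match(atoms, md$atoms$idx)]
      ty <- if (any(arom)) "Ar" else if (all(elem == 6L)) "Hf" else NA
      if (!is.na(ty)) {
        pts[[length(pts) + 1L]] <- list(type = ty, atoms = atoms)
      }
    }
  }
  if (!length(pts)) return(pts)
  key <- vapply(pts, function(p) paste(p$type,
                                       paste(p$atoms, collapse = ",")),
                character(1))
  pts[!duplicated(key)]
}

#' ErG-style reduced-graph fingerprint
#'
#' Encodes a molecule as a fuzzy histogram of topological distances
#' between pharmacophoric property points (donor, acceptor, positive,
#' negative, hydrophobe, aromatic system): 21 type pairs x distances
#' 1-15, each realised distance incrementing its bin by 1 and the
#' adjacent bins by 0.3.
#'
#' @param smiles A single SMILES string.
#' @return A numeric vector of length 315.
#' @examples
#' sum(erg_fingerprint("c1ccccc1O") > 0)
#' @export
erg_fingerprint <- function(smiles) {
  md <- mol_data(smiles)
  pts <- erg_points(md)
  npair <- length(ERG_TYPES) * (length(ERG_TYPES) + 1L) / 2L
  out <- numeric(npair * ERG_MAX_DIST)
  n <- length(pts)
  if (n < 2) return(out)
  ad <- atom_distances(md)
  pair_idx <- matrix(NA_integer_, 6, 6)
  k <- 0L
  for (i in 1:6) for (j in i:6) {
    k <- k + 1L
    pair_idx[i, j] <- pair_idx[j, i] <- k
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- min(ad[pts[[i]]$atoms, pts[[j]]$atoms])
    if (!is.finite(d)) next
    d <- max(1L, min(ERG_MAX_DIST, as.integer(d)))
    ti <- match(pts[[i]]$type, ERG_TYPES)
    tj <- match(pts[[j]]$type, ERG_TYPES)
    base <- (pair_idx[ti, tj] - 1L) * ERG_MAX_DIST
    out[base + d] <- out[base + d] + 1
    if (d > 1L) out[base + d - 1L] <- out[base + d - 1L] + ERG_FUZZ
    if (d < ERG_MAX_DIST) out[base + d + 1L] <- out[base + d + 1L] + ERG_FUZZ
  }
  out
}

# modified Tanimoto for non-negative real vectors
erg_tanimoto <- function(a, b) {
  ab <- sum(a * b)
  den <- sum(a * a) + sum(b * b) - ab
  if (den <= 0) {
    # both featureless: identical by convention
    return(if (sum(a) == 0 && sum(b) == 0) 1 else 0)
  }
  ab / den
}
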
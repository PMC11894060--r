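# Molecule-level utilities shared by the fingerprint, generation, metrics
# and screening modules: validity, canonicalization, bond-graph distances
# and substructure extraction.

#' Validate and canonicalize SMILES strings
#'
#' `valid_smiles()` reports which strings parse as molecules;
#' `canonical_smiles()` returns the canonical form (`NA` for unparseable
#' input).
#'
#' @param smiles Character vector of SMILES strings.
#' @return A logical vector (`valid_smiles`) or character vector
#'   (`canonical_smiles`) of the same length as `smiles`.
#' @examples
#' canonical_smiles(c("OCC", "CCO"))
#' @export
valid_smiles <- function(smiles) {
  vapply(smiles, function(s) !is.null(ob_parse(s)), logical(1),
         USE.NAMES = FALSE)
}

#' @rdname valid_smiles
#' @export
canonical_smiles <- function(smiles) {
  vapply(smiles, ob_canonical, character(1), USE.NAMES = FALSE)
}

assert_smiles <- function(smiles, arg = "smiles") {
  mol <- ob_parse(smiles)
  if (is.null(mol)) stop("invalid SMILES in `", arg, "`: ", smiles,
                         call. = FALSE)
  mol
}

# Parsed molecule bundle: OBMol handle, atom/bond tibbles and the bond
# graph as an igraph object (vertices = atoms, unweighted edges = bonds).
mol_data <- function(smiles) {
  mol <- assert_smiles(smiles)
  g <- ob_graph(mol)
  ig <- igraph::graph_from_data_frame(
    d = data.frame(from = g$bonds$begin, to = g$bonds$end),
    directed = FALSE,
    vertices = data.frame(name = g$atoms$idx)
  )
  list(smiles = smiles, mol = mol, atoms = g$atoms, bonds = g$bonds,
       graph = ig)
}

# Bond-count shortest-path matrix between all heavy atoms; Inf across
# disconnected components.
atom_distances <- function(md) {
  d <- igraph::distances(md$graph)
  ord <- match(as.character(md$atoms$idx), rownames(d))
  d[ord, ord, drop = FALSE]
}

# Extract the sub-molecule induced by `keep` (1-based atom indices).
# Severed bonds are healed with implicit hydrogens so valence is preserved.
# Returns the new OBMol plus the position of each kept atom in the new
# numbering.
mol_extract <- function(md, keep) {
  keep <- sort(unique(as.integer(keep)))
  drop <- setdiff(md$atoms$idx, keep)
  sub <- ob_mol_copy(md$mol)
  if (length(drop)) {
    b <- md$bonds
    severed <- b[(b$begin %in% keep & b$end %in% drop) |
                   (b$end %in% keep & b$begin %in% drop), , drop = FALSE]
    add_h <- stats::aggregate(
      order ~ atom,
      data = data.frame(
        atom = ifelse(severed$begin %in% keep, severed$begin, severed$end),
        order = severed$order
      ),
      FUN = sum
    )
    ob_delete_atoms(sub, drop)
    if (nrow(add_h)) {
      new_idx <- match(add_h$atom, keep)
      old_h <- md$atoms$n_h[match(add_h$atom, md$atoms$idx)]
      for (k in seq_len(nrow(add_h))) {
        ob_set_implicit_h(sub, new_idx[k], old_h[k] + add_h$order[k])
      }
    }
  }
  list(mol = sub, new_index = stats::setNames(seq_along(keep), keep))
}
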
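# Thin shim over the OpenBabel SWIG bindings shipped inside ChemmineOB.
#
# ChemmineOB's exported surface (smartsSearch_OB, fingerprint_OB, prop_OB,
# convertFormat) covers counts and whole-molecule conversions only; the
# operations here additionally need SMARTS match *atom indices*, atom/bond
# accessors, molecule editing and rooted SMILES output, all of which exist
# in the bundled SWIG layer. They are fetched once from the package
# namespace and cached. Atom indices are 1-based throughout (OpenBabel
# convention).

.ob <- new.env(parent = emptyenv())

ob_sym <- function(name) {
  if (is.null(.ob$ns)) {
    .ob$ns <- getNamespace("ChemmineOB")
    # OpenBabel logs parse warnings to stderr; keep the console quiet.
    try(.ob$ns$OBMessageHandler_SetOutputLevel(.ob$ns$obErrorLog_get(), 0L),
        silent = TRUE)
  }
  get(name, envir = .ob$ns)
}

ob_new_conversion <- function(infmt, outfmt) {
  conv <- ob_sym("OBConversion")()
  ob_sym("OBConversion_SetInAndOutFormats")(conv, infmt, outfmt)
  conv
}

#' @noRd
ob_parse <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (is.na(smiles) || !nzchar(smiles)) return(NULL)
  conv <- ob_new_conversion("smi", "smi")
  mol <- ob_sym("OBMol")()
  ok <- isTRUE(ob_sym("OBConversion_ReadString")(conv, mol, smiles))
  if (!ok || ob_sym("OBMol_NumAtoms")(mol) == 0L) return(NULL)
  mol
}

ob_mol_copy <- function(mol) ob_sym("OBMol__SWIG_1")(mol)

# Write a molecule as SMILES. canonical selects the canonical writer;
# root_last leaves atom `root_last` syntactically open at the end of the
# string (output option "l": what an elaboration core needs), root_first
# writes atom `root_first` first (output option "f": what a continuation
# fragment needs).
ob_write_smiles <- function(mol, canonical = TRUE, root_last = NULL,
                            root_first = NULL) {
  conv <- ob_new_conversion("smi", if (canonical) "can" else "smi")
  outopt <- ob_sym("OBConversion_OUTOPTIONS_get")()
  if (!is.null(root_last)) {
    ob_sym("OBConversion_AddOption__SWIG_0")(conv, "l", outopt,
                                             as.character(root_last))
  }
  if (!is.null(root_first)) {
    ob_sym("OBConversion_AddOption__SWIG_0")(conv, "f", outopt,
                                             as.character(root_first))
  }
  out <- ob_sym("OBConversion_WriteString")(conv, mol)
  sub("[ \t\r\n].*$", "", out)
}

#' @noRd
ob_canonical <- function(smiles) {
  mol <- ob_parse(smiles)
  if (is.null(mol)) return(NA_character_)
  ob_write_smiles(mol, canonical = TRUE)
}

# Atom and bond tables of a parsed molecule.
ob_graph <- function(mol) {
  n <- ob_sym("OBMol_NumAtoms")(mol)
  nb <- ob_sym("OBMol_NumBonds")(mol)
  get_atom <- ob_sym("OBMol_GetAtom")
  anum <- integer(n); chg <- integer(n); hcnt <- integer(n)
  arom <- logical(n); ring <- logical(n)
  for (i in seq_len(n)) {
    a <- get_atom(mol, i)
    anum[i] <- ob_sym("OBAtom_GetAtomicNum")(a)
    chg[i] <- ob_sym("OBAtom_GetFormalCharge")(a)
    hcnt[i] <- ob_sym("OBAtom_GetImplicitHCount")(a) +
      ob_sym("OBAtom_ExplicitHydrogenCount__SWIG_1")(a)
    arom[i] <- ob_sym("OBAtom_IsAromatic")(a)
    ring[i] <- ob_sym("OBAtom_IsInRing")(a)
  }
  get_bond <- ob_sym("OBMol_GetBond__SWIG_0")
  b1 <- integer(nb); b2 <- integer(nb); ord <- integer(nb)
  barom <- logical(nb); bring <- logical(nb)
  for (j in seq_len(nb)) {
    b <- get_bond(mol, j - 1L)
    b1[j] <- ob_sym("OBBond_GetBeginAtomIdx")(b)
    b2[j] <- ob_sym("OBBond_GetEndAtomIdx")(b)
    ord[j] <- ob_sym("OBBond_GetBondOrder")(b)
    barom[j] <- ob_sym("OBBond_IsAromatic")(b)
    bring[j] <- ob_sym("OBBond_IsInRing")(b)
  }
  list(
    atoms = tibble::tibble(idx = seq_len(n), atomic_num = anum,
                           charge = chg, n_h = hcnt,
                           aromatic = arom, in_ring = ring),
    bonds = tibble::tibble(begin = b1, end = b2, order = ord,
                           aromatic = barom, in_ring = bring)
  )
}

# All unique SMARTS matches as a list of integer atom-index vectors.
ob_smarts_match <- function(mol, pattern) {
  sp <- ob_sym("OBSmartsPattern")()
  if (!isTRUE(ob_sym("OBSmartsPattern_Init")(sp, pattern))) {
    stop("invalid SMARTS pattern: ", pattern)
  }
  if (!isTRUE(ob_sym("OBSmartsPattern_Match__SWIG_1")(sp, mol))) return(list())
  ob_sym("OBSmartsPattern_GetUMapList")(sp)
}

ob_set_formal_charge <- function(mol, idx, charge) {
  a <- ob_sym("OBMol_GetAtom")(mol, idx)
  ob_sym("OBAtom_SetFormalCharge")(a, as.integer(charge))
  invisible(mol)
}

ob_set_implicit_h <- function(mol, idx, nh) {
  a <- ob_sym("OBMol_GetAtom")(mol, idx)
  ob_sym("OBAtom_SetImplicitHCount")(a, as.integer(nh))
  invisible(mol)
}

# Delete atoms (1-based indices) from a copy-safe molecule in place.
# Deletion renumbers, so indices are removed in descending order.
ob_delete_atoms <- function(mol, idx) {
  for (i in sort(unique(as.integer(idx)), decreasing = TRUE)) {
    a <- ob_sym("OBMol_GetAtom")(mol, i)
    ob_sym("OBMol_DeleteAtom__SWIG_1")(mol, a)
  }
  invisible(mol)
}

ob_mol_props <- function(mol) ChemmineOB::prop_OB(mol)

# OpenBabel extended-connectivity fingerprints (ECFP4 = circular, radius 2),
# folded from the native 4096 bits to `fold` bits.
ob_ecfp <- function(smiles, fold = 2048L) {
  mols <- lapply(smiles, ob_parse)
  bad <- vapply(mols, is.null, logical(1))
  if (any(bad)) stop("invalid SMILES: ", paste(smiles[bad], collapse = ", "))
  fp <- ChemmineOB::fingerprint_OB(mols, "ECFP4")
  fp <- matrix(as.integer(fp != 0), nrow = length(mols))
  nb <- ncol(fp)
  if (nb %% fold != 0) stop("cannot fold ", nb, " bits to ", fold)
  folded <- matrix(0L, nrow = nrow(fp), ncol = fold)
  for (k in seq_len(nb / fold)) {
    block <- fp[, ((k - 1L) * fold + 1L):(k * fold), drop = FALSE]
    folded <- pmax(folded, block)
  }
  rownames(folded) <- names(smiles)
  folded
}
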
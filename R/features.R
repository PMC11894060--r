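# Pharmacophore feature detection and the topological feature graph.
#
# A molecule is abstracted into instances of eight feature families
# (hydrogen-bond acceptor/donor, aromatic ring, positive/negative
# ionizability, chain hydrophobe, lumped ring hydrophobe, zinc binder),
# each instance being the set of atoms matched by a pinned SMARTS pattern.
# Pairwise feature distances are bond-count shortest paths between the
# closest member atoms.

FAMILY_NAMES <- c("acceptor", "donor", "aromatic", "pos_ionizable",
                  "neg_ionizable", "hydrophobe", "lumped_hydrophobe",
                  "zn_binder")

.families_cache <- new.env(parent = emptyenv())

#' Pharmacophore feature family definitions
#'
#' Reads the pinned SMARTS definition file shipped with the package (or a
#' user-supplied file in the same two-column tab-separated format). The
#' eight families have fixed ids 0-7 in the order acceptor, donor,
#' aromatic, pos_ionizable, neg_ionizable, hydrophobe, lumped_hydrophobe,
#' zn_binder; this order defines the fingerprint bit layout.
#'
#' @param path Path to a feature definition file; `NULL` uses the pinned
#'   file shipped in `extdata/feature_families.smarts`.
#' @return A tibble with columns `family_id` (0-based), `family` and
#'   `smarts` (one row per pattern; families repeat).
#' @examples
#' feature_families()
#' @export
feature_families <- function(path = NULL) {
  default <- is.null(path)
  if (default && !is.null(.families_cache$default)) {
    return(.families_cache$default)
  }
  if (default) {
    path <- system.file("extdata", "feature_families.smarts",
                        package = "phoregen", mustWork = TRUE)
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  fam <- vapply(parts, `[`, character(1), 1L)
  pat <- vapply(parts, `[`, character(1), 2L)
  if (!setequal(unique(fam), FAMILY_NAMES)) {
    stop("feature definition file must define exactly these 8 families: ",
         paste(FAMILY_NAMES, collapse = ", "))
  }
  out <- tibble::tibble(
    family_id = match(fam, FAMILY_NAMES) - 1L,
    family = factor(fam, levels = FAMILY_NAMES),
    smarts = pat
  )
  out <- out[order(out$family_id), ]
  if (default) .families_cache$default <- out
  out
}

#' Detect pharmacophore features of a molecule
#'
#' Matches every SMARTS pattern of every feature family against the
#' molecule. Matches identical in (family, member atoms) are collapsed to
#' one feature instance.
#'
#' @param smiles A single SMILES string.
#' @param families Feature definition table from [feature_families()].
#' @return A tibble with columns `family_id`, `family` and `atoms` (a
#'   list-column of sorted 1-based atom indices), one row per feature
#'   instance.
#' @examples
#' detect_features("CCO")
#' @export
detect_features <- function(smiles, families = feature_families()) {
  md <- mol_data(smiles)
  detect_features_md(md, families)
}

detect_features_md <- function(md, families = feature_families()) {
  rows <- list()
  for (k in seq_len(nrow(families))) {
    hits <- ob_smarts_match(md$mol, families$smarts[k])
    for (h in hits) {
      rows[[length(rows) + 1L]] <- list(
        family_id = families$family_id[k],
        atoms = sort(unique(as.integer(h)))
      )
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(family_id = integer(),
                          family = factor(character(), levels = FAMILY_NAMES),
                          atoms = list()))
  }
  fid <- vapply(rows, `[[`, integer(1), "family_id")
  atoms <- lapply(rows, `[[`, "atoms")
  key <- paste(fid, vapply(atoms, paste, character(1), collapse = ","))
  keep <- !duplicated(key)
  ordidx <- order(fid[keep], key[keep])
  tibble::tibble(
    family_id = fid[keep][ordidx],
    family = factor(FAMILY_NAMES[fid[keep][ordidx] + 1L],
                    levels = FAMILY_NAMES),
    atoms = atoms[keep][ordidx]
  )
}

#' Build the pharmacophoric topology graph
#'
#' Computes the matrix of shortest topological (bond-count) distances
#' between every pair of detected feature instances. The distance between
#' two features is the minimum over pairs of member atoms of the
#' bond-graph shortest-path length (closest-atom convention), so features
#' sharing an atom are at distance 0. Features in different connected
#' components of a disconnected molecule are at infinite distance, which
#' downstream encoders treat as a null signal.
#'
#' @inheritParams detect_features
#' @param features Optional precomputed feature table for the same
#'   molecule (from [detect_features()]).
#' @return An object of class `phore_graph`: a list with `smiles`,
#'   `features` (tibble) and `dist` (symmetric numeric matrix, zero
#'   diagonal).
#' @examples
#' phore_graph("OCCCO")
#' @export
phore_graph <- function(smiles, features = NULL,
                        families = feature_families()) {
  md <- mol_data(smiles)
  if (is.null(features)) features <- detect_features_md(md, families)
  n <- nrow(features)
  dist <- matrix(0, n, n)
  if (n > 1) {
    ad <- atom_distances(md)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        dij <- min(ad[features$atoms[[i]], features$atoms[[j]]])
        dist[i, j] <- dij
        dist[j, i] <- dij
      }
    }
  }
  structure(list(smiles = smiles, features = features, dist = dist),
            class = "phore_graph")
}

#' @export
print.phore_graph <- function(x, ...) {
  cat("<phore_graph> ", x$smiles, ": ", nrow(x$features),
      " feature(s)\n", sep = "")
  if (nrow(x$features)) {
    print(tibble::as_tibble(x$features))
  }
  invisible(x)
}

#' Per-family pharmacophore feature counts
#'
#' Counts detected feature instances per family; the condition vector of
#' the count-conditioned decoder and the n_j of the feature-count
#' deviation metric.
#'
#' @param data A data frame with a SMILES column, or a character vector of
#'   SMILES strings.
#' @param smiles_col Column holding SMILES strings (tidy-eval, default
#'   `smiles`).
#' @inheritParams detect_features
#' @return The input as a tibble with eight added integer columns
#'   `n_acceptor`, `n_donor`, `n_aromatic`, `n_pos_ionizable`,
#'   `n_neg_ionizable`, `n_hydrophobe`, `n_lumped_hydrophobe`,
#'   `n_zn_binder`.
#' @examples
#' feature_counts(c("C", "CCO"))
#' @export
feature_counts <- function(data, smiles_col = smiles,
                           families = feature_families()) {
  data <- as_smiles_tibble(data)
  smi <- dplyr::pull(data, {{ smiles_col }})
  counts <- t(vapply(smi, count_vector, integer(8), families = families))
  colnames(counts) <- paste0("n_", FAMILY_NAMES)
  dplyr::bind_cols(data, tibble::as_tibble(counts))
}

# Length-8 named integer count vector for one molecule.
count_vector <- function(smiles, families = feature_families()) {
  feats <- detect_features(smiles, families)
  out <- integer(8)
  if (nrow(feats)) {
    tab <- table(factor(feats$family_id, levels = 0:7))
    out <- as.integer(tab)
  }
  names(out) <- FAMILY_NAMES
  out
}

as_smiles_tibble <- function(data) {
  if (is.character(data)) return(tibble::tibble(smiles = data))
  tibble::as_tibble(data)
}
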
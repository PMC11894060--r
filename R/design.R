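# Case-study procedures: Bemis-Murcko scaffolds, Butina sphere-exclusion
# clustering, the scaffold-clustered active/heldout split, and the
# post-generation virtual-screening triage over externally supplied
# docking results.

#' Bemis-Murcko scaffold of a molecule
#'
#' Ring systems plus linkers, with side chains removed; atoms
#' multiply-bonded directly to the retained framework (e.g. carbonyl
#' oxygens on rings or linkers) are kept. Acyclic molecules yield the
#' empty scaffold `""`.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical scaffold SMILES (`""` for
#'   acyclic molecules).
#' @examples
#' bemis_murcko("Cc1ccccc1")
#' @export
bemis_murcko <- function(smiles) {
  vapply(smiles, bemis_murcko1, character(1), USE.NAMES = FALSE)
}

bemis_murcko1 <- function(smiles) {
  md <- mol_data(smiles)
  at <- md$atoms
  if (!any(at$in_ring)) return("")
  # iteratively prune non-ring terminal atoms
  g <- md$graph
  repeat {
    deg <- igraph::degree(g)
    names_keep <- as.integer(igraph::V(g)$name)
    prune <- names_keep[deg <= 1 & !at$in_ring[match(names_keep, at$idx)]]
    if (!length(prune)) break
    g <- igraph::delete_vertices(g, as.character(prune))
  }
  frame <- as.integer(igraph::V(g)$name)
  # re-attach atoms multiply bonded to the framework
  b <- md$bonds
  extra <- unique(c(
    b$end[b$order >= 2L & b$begin %in% frame & !(b$end %in% frame)],
    b$begin[b$order >= 2L & b$end %in% frame & !(b$begin %in% frame)]))
  keep <- sort(unique(c(frame, extra)))
  ex <- mol_extract(md, keep)
  ob_write_smiles(ex$mol, canonical = TRUE)
}

#' Butina sphere-exclusion clustering
#'
#' Clusters items by Tanimoto distance on binary fingerprints:
#' candidate centroids are ranked by descending neighbour count (ties
#' by item order), each unassigned candidate seeds a cluster absorbing
#' its unassigned neighbours within `distance_threshold`, and leftovers
#' become singletons. Clusters are disjoint and exhaustive.
#'
#' @param fps Binary matrix, one fingerprint per row (e.g. from
#'   structural fingerprints of scaffolds).
#' @param distance_threshold Tanimoto distance radius (paper settings:
#'   0.4 for the active split, 0.1 for triage clustering).
#' @return Integer vector of cluster ids (1-based, in decreasing
#'   cluster-size order) per row of `fps`.
#' @export
butina_cluster <- function(fps, distance_threshold = 0.4) {
  n <- nrow(fps)
  if (is.null(n) || n == 0) stop("empty input")
  sims <- tcrossprod(fps) # bit intersections
  ones <- rowSums(fps)
  uni <- outer(ones, ones, `+`) - sims
  tan <- ifelse(uni == 0, 1, sims / uni)
  nbr <- (1 - tan) <= distance_threshold
  diag(nbr) <- FALSE
  counts <- rowSums(nbr)
  order_cand <- order(-counts, seq_len(n))
  cluster <- integer(n)
  cid <- 0L
  for (i in order_cand) {
    if (cluster[i] != 0L) next
    cid <- cid + 1L
    members <- c(i, which(nbr[i, ] & cluster == 0L))
    cluster[members] <- cid
  }
  # relabel by decreasing size, ties by first appearance
  sz <- table(cluster)
  ord <- order(-as.integer(sz), as.integer(names(sz)))
  relabel <- integer(length(sz))
  relabel[as.integer(names(sz))[ord]] <- seq_along(ord)
  relabel[cluster]
}

#' Scaffold-clustered split of active ligands
#'
#' Extracts Bemis-Murcko scaffolds, groups identical scaffolds,
#' clusters the distinct scaffolds with Butina on 2048-bit circular
#' fingerprints, sorts clusters by ligand count in descending order
#' (ties by the lexicographically smallest scaffold in the cluster),
#' and assigns ligands of 1-based odd-ranked clusters to the training
#' side and even-ranked clusters to the heldout side. The resulting
#' partition is scaffold-disjoint, exhaustive and deterministic.
#' Acyclic molecules (empty scaffold) form their own scaffold group.
#'
#' @param data Data frame with a SMILES column, or character vector.
#' @param smiles_col Column holding SMILES strings.
#' @param distance_threshold Butina distance threshold (default 0.4).
#' @return The input as a tibble with added columns `scaffold`,
#'   `cluster` (size rank, 1 = largest) and `split`
#'   (`"train"`/`"heldout"`).
#' @export
drd2_split <- function(data, smiles_col = smiles,
                       distance_threshold = 0.4) {
  data <- as_smiles_tibble(data)
  smi <- dplyr::pull(data, {{ smiles_col }})
  scaff <- bemis_murcko(smi)
  uniq <- sort(unique(scaff))
  scl <- integer(length(uniq))
  ringed <- uniq[nzchar(uniq)]
  if (length(ringed) >= 1) {
    fps <- ob_ecfp(ringed)
    scl[match(ringed, uniq)] <- butina_cluster(fps, distance_threshold)
  }
  if (any(!nzchar(uniq))) {
    scl[!nzchar(uniq)] <- max(scl) + 1L # acyclic group
  }
  mol_cluster <- scl[match(scaff, uniq)]
  sizes <- table(mol_cluster)
  smallest_scaffold <- vapply(names(sizes), function(cid) {
    min(scaff[mol_cluster == as.integer(cid)])
  }, character(1))
  ord <- order(-as.integer(sizes), smallest_scaffold)
  rank_of <- integer(length(sizes))
  rank_of[as.integer(names(sizes))[ord]] <- seq_along(ord)
  if (max(rank_of) < 2) stop("need at least 2 scaffold clusters to split")
  ranks <- rank_of[mol_cluster]
  data$scaffold <- scaff
  data$cluster <- ranks
  data$split <- ifelse(ranks %% 2L == 1L, "train", "heldout")
  data
}

#' Triage configuration
#'
#' Thresholds of the post-generation screening pipeline. Defaults are
#' the case-study settings: pharmacophoric similarity floor 0.85,
#' maximum molecular weight 1000 Da, docking-score cutoff -9.0 kcal/mol
#' ("better" = more negative), hinge residue Cys133 requisite among at
#' least 2 polar contacts, scaffold Butina threshold 0.1, and 2300 kept
#' compounds. The default novelty filter removes molecules matching the
#' fused bicyclic core pattern of the reference chemotype.
#'
#' @param pharma_min,mw_max,score_max,min_polar_contacts,required_residue
#'   Stage thresholds.
#' @param novelty_smarts Character vector of SMARTS; matching molecules
#'   are discarded as insufficiently novel.
#' @param butina_threshold,keep_n Clustering/ranking settings.
#' @param alerts_file Structural-alert SMARTS file (name TAB pattern).
#' @return A list of class `triage_config`.
#' @export
triage_config <- function(pharma_min = 0.85, mw_max = 1000,
                          novelty_smarts =
                            "c12ncncc1-CC-[n,c]3:[n,c]:[n,c]:[n,c]:[n,c]32",
                          score_max = -9.0,
                          required_residue = "Cys133",
                          min_polar_contacts = 2L,
                          butina_threshold = 0.1, keep_n = 2300L,
                          alerts_file = NULL) {
  if (is.null(alerts_file)) {
    alerts_file <- system.file("extdata", "structural_alerts.smarts",
                               package = "phoregen", mustWork = TRUE)
  }
  structure(list(pharma_min = pharma_min, mw_max = mw_max,
                 novelty_smarts = novelty_smarts, score_max = score_max,
                 required_residue = required_residue,
                 min_polar_contacts = as.integer(min_polar_contacts),
                 butina_threshold = butina_threshold,
                 keep_n = as.integer(keep_n),
                 alerts_file = alerts_file),
            class = "triage_config")
}

read_alerts <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(vapply(parts, `[`, character(1), 2L),
                  vapply(parts, `[`, character(1), 1L))
}

matches_any_smarts <- function(smiles, patterns) {
  md <- mol_data(smiles)
  for (p in patterns) {
    if (length(ob_smarts_match(md$mol, p))) return(TRUE)
  }
  FALSE
}

# modified rule of five: hard MW cap, at most one violation among
# logP > 5, H-bond donors > 5, H-bond acceptors > 10
passes_druglikeness <- function(smiles, mw_max) {
  md <- mol_data(smiles)
  pr <- ob_mol_props(md$mol)
  if (pr$MW > mw_max) return(FALSE)
  violations <- sum(pr$logP > 5, pr$HBD > 5, pr$HBA1 > 10)
  violations <= 1
}

#' Virtual-screening triage of generated molecules
#'
#' Applies, in order: (1) pharmacophoric similarity to the reference at
#' or above `pharma_min`; (2) modified rule of five (MW cap) plus
#' structural-alert filters; (3) novelty filter discarding matches to
#' the novelty SMARTS; (4) docking score at or below `score_max` with
#' at least `min_polar_contacts` key-residue polar contacts including
#' the requisite hinge residue; (5) grouping of identical Bemis-Murcko
#' scaffolds and Butina clustering of the scaffolds; (6) best member
#' per cluster by docking score then ligand efficiency (docking score
#' divided by molecular weight, as the case study defines it); (7) the
#' top `keep_n` survivors ranked by docking score then ligand
#' efficiency. Records with a missing docking score are skipped with a
#' warning. Every stage only removes records.
#'
#' @param records Data frame with columns `smiles`, `docking_score`
#'   (kcal/mol) and `interactions` (semicolon-separated residue tags,
#'   e.g. `"Cys133;Lys82"`); optional `s_pharma_to_ref` (computed from
#'   `reference` when absent) and `mol_weight` (computed when absent).
#' @param config A [triage_config()].
#' @param reference Reference SMILES used to compute
#'   `s_pharma_to_ref` when the column is absent.
#' @return A tibble of surviving records ranked best-first, with added
#'   columns `scaffold`, `scaffold_cluster`, `ligand_efficiency` and
#'   `rank`; per-stage record counts in `attr(, "stage_counts")`.
#' @export
triage <- function(records, config = triage_config(), reference = NULL) {
  records <- tibble::as_tibble(records)
  stopifnot(all(c("smiles", "docking_score", "interactions") %in%
                  names(records)))
  missing_score <- !is.finite(records$docking_score)
  if (any(missing_score)) {
    warning(sum(missing_score), " record(s) without docking score skipped")
    records <- records[!missing_score, ]
  }
  counts <- c(input = nrow(records))
  if (!"s_pharma_to_ref" %in% names(records)) {
    if (is.null(reference)) {
      stop("records lack `s_pharma_to_ref` and no `reference` was given")
    }
    records$s_pharma_to_ref <- s_pharma(records$smiles, reference)
  }
  if (!"mol_weight" %in% names(records)) {
    records$mol_weight <- vapply(records$smiles, function(s) {
      ob_mol_props(mol_data(s)$mol)$MW
    }, numeric(1))
  }
  # stage 1: pharmacophoric similarity
  records <- records[records$s_pharma_to_ref >= config$pharma_min, ]
  counts["pharma"] <- nrow(records)
  # stage 2: drug-likeness + structural alerts
  alerts <- read_alerts(config$alerts_file)
  ok2 <- vapply(records$smiles, function(s) {
    passes_druglikeness(s, config$mw_max) && !matches_any_smarts(s, alerts)
  }, logical(1))
  records <- records[ok2, ]
  counts["druglike"] <- nrow(records)
  # stage 3: novelty
  ok3 <- !vapply(records$smiles, matches_any_smarts, logical(1),
                 patterns = config$novelty_smarts)
  records <- records[ok3, ]
  counts["novelty"] <- nrow(records)
  # stage 4: docking score + key polar contacts
  inter <- strsplit(as.character(records$interactions), ";", fixed = TRUE)
  inter <- lapply(inter, function(x) trimws(x[nzchar(trimws(x))]))
  ok4 <- records$docking_score <= config$score_max &
    vapply(inter, length, integer(1)) >= config$min_polar_contacts &
    vapply(inter, function(x) config$required_residue %in% x, logical(1))
  records <- records[ok4, ]
  counts["docking"] <- nrow(records)
  if (!nrow(records)) {
    records$scaffold <- character(0)
    records$scaffold_cluster <- integer(0)
    records$ligand_efficiency <- numeric(0)
    records$rank <- integer(0)
    attr(records, "stage_counts") <- counts
    return(records)
  }
  # stages 5-6: scaffold grouping, Butina on scaffolds, best per cluster
  records$scaffold <- bemis_murcko(records$smiles)
  records$ligand_efficiency <- records$docking_score / records$mol_weight
  uniq <- sort(unique(records$scaffold))
  scl <- integer(length(uniq))
  ringed <- uniq[nzchar(uniq)]
  if (length(ringed)) {
    scl[match(ringed, uniq)] <- butina_cluster(ob_ecfp(ringed),
                                               config$butina_threshold)
  }
  if (any(!nzchar(uniq))) scl[!nzchar(uniq)] <- max(scl) + 1L
  records$scaffold_cluster <- scl[match(records$scaffold, uniq)]
  records <- dplyr::arrange(records, .data$docking_score,
                            .data$ligand_efficiency, .data$smiles)
  best <- !duplicated(records$scaffold_cluster)
  records <- records[best, ]
  counts["cluster_best"] <- nrow(records)
  # stage 7: final ranking and cap
  records <- utils::head(records, config$keep_n)
  records$rank <- seq_len(nrow(records))
  counts["kept"] <- nrow(records)
  attr(records, "stage_counts") <- counts
  records
}

#' Funnel plot of triage stage counts
#'
#' @param x A result of [triage()].
#' @param ... Unused.
#' @return A ggplot bar chart of record counts per stage.
#' @export
plot_triage_funnel <- function(x, ...) {
  counts <- attr(x, "stage_counts")
  df <- tibble::tibble(stage = factor(names(counts),
                                      levels = names(counts)),
                       n = as.integer(counts))
  ggplot2::ggplot(df, ggplot2::aes(.data$stage, .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "records remaining",
                  title = "screening triage funnel") +
    ggplot2::theme_minimal()
}
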
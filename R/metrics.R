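# Evaluation metrics for pharmacophore-constrained generation: charge
# neutralization, structural and pharmacophoric similarity, feature-count
# deviation, recall and apparent precision.

#' Neutralize charged molecules
#'
#' Returns protonatable/deprotonatable centres to neutral form where
#' valence allows, atom by atom: a positively charged atom carrying a
#' hydrogen loses one proton; a negatively charged N/O/S/C gains one.
#' Atoms participating in adjacent +/- pairs (e.g. nitro, N-oxides) and
#' quaternary ammonium centres (no H to remove) are left unchanged.
#' Idempotent; applied before all similarity scoring.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical neutralized SMILES.
#' @examples
#' neutralize_smiles("[NH3+]CC")
#' @export
neutralize_smiles <- function(smiles) {
  vapply(smiles, neutralize1, character(1), USE.NAMES = FALSE)
}

neutralize1 <- function(smiles) {
  md <- mol_data(smiles)
  at <- md$atoms
  mol <- ob_mol_copy(md$mol)
  nbr_charge <- function(i) {
    nb <- c(md$bonds$end[md$bonds$begin == i],
            md$bonds$begin[md$bonds$end == i])
    if (!length(nb)) 0L else at$charge[match(nb, at$idx)]
  }
  changed <- FALSE
  for (i in at$idx) {
    chg <- at$charge[at$idx == i]
    if (chg > 0L && at$n_h[at$idx == i] > 0L && !any(nbr_charge(i) < 0L)) {
      ob_set_formal_charge(mol, i, chg - 1L)
      ob_set_implicit_h(mol, i, at$n_h[at$idx == i] - 1L)
      changed <- TRUE
    } else if (chg < 0L &&
                 at$atomic_num[at$idx == i] %in% c(6L, 7L, 8L, 16L) &&
                 !any(nbr_charge(i) > 0L)) {
      ob_set_formal_charge(mol, i, chg + 1L)
      ob_set_implicit_h(mol, i, at$n_h[at$idx == i] + 1L)
      changed <- TRUE
    }
  }
  out <- ob_write_smiles(mol, canonical = TRUE)
  # repeat until fixed point (multiply charged centres)
  if (changed) return(neutralize1(out))
  out
}

tanimoto_bits <- function(a, b) {
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0) 1 else inter / uni
}

#' Structural and pharmacophoric similarity
#'
#' `s_struct()` is the Tanimoto coefficient of 2048-bit circular
#' (Morgan, radius 2) fingerprints; `s_pharma()` the modified Tanimoto
#' of ErG-style reduced-graph fingerprints ([erg_fingerprint()]). Both
#' neutralize charges first, are symmetric, lie in [0, 1] and give 1
#' for identical molecules.
#'
#' @param a,b Character vectors of SMILES strings (recycled to common
#'   length).
#' @return Numeric vector of similarity scores.
#' @examples
#' s_struct("CCO", "CCO")
#' @export
s_struct <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(neutralize_smiles(a), n)
  b <- rep_len(neutralize_smiles(b), n)
  fpa <- ob_ecfp(a)
  fpb <- ob_ecfp(b)
  vapply(seq_len(n), function(i) tanimoto_bits(fpa[i, ], fpb[i, ]),
         numeric(1))
}

#' @rdname s_struct
#' @export
s_pharma <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(neutralize_smiles(a), n)
  b <- rep_len(neutralize_smiles(b), n)
  vapply(seq_len(n), function(i) {
    erg_tanimoto(erg_fingerprint(a[i]), erg_fingerprint(b[i]))
  }, numeric(1))
}

#' Pharmacophore feature-count deviation
#'
#' Mean, over generated molecules, of the L1 distance between the
#' per-family feature-count vector of each generated molecule and that
#' of the reference (8 families).
#'
#' @param generated Character vector of generated SMILES (non-empty).
#' @param reference A single reference SMILES.
#' @param families Feature definitions, see [feature_families()].
#' @return A single non-negative number.
#' @examples
#' d_count(c("CCO"), "CCO")
#' @export
d_count <- function(generated, reference, families = feature_families()) {
  if (!length(generated)) stop("empty generated set")
  ref <- count_vector(reference, families)
  devs <- vapply(generated, function(s) {
    sum(abs(count_vector(s, families) - ref))
  }, numeric(1))
  mean(devs)
}

#' Recall of reserved actives in a generated set
#'
#' Exact mode counts membership by canonical SMILES after
#' neutralization. Relaxed mode additionally counts a reserved active
#' as recalled when any generated molecule has structural similarity
#' [s_struct()] at or above `relaxed_threshold` to it.
#'
#' @param generated Character vector of generated SMILES.
#' @param reserved Character vector of reserved active SMILES
#'   (non-empty).
#' @param relaxed_threshold Optional similarity threshold (e.g. 0.8);
#'   `NULL` for exact recall only.
#' @return A tibble with `recall`, `n_recalled`, `n_reserved` and
#'   `relaxed_threshold`.
#' @examples
#' recall_rate(c("CCO"), c("CCO", "CCN"))
#' @export
recall_rate <- function(generated, reserved, relaxed_threshold = NULL) {
  if (!length(reserved)) stop("empty reserved set")
  res_canon <- canonical_smiles(neutralize_smiles(reserved))
  gen_canon <- if (length(generated)) {
    canonical_smiles(neutralize_smiles(generated))
  } else character(0)
  hit <- res_canon %in% gen_canon
  if (!is.null(relaxed_threshold) && length(gen_canon)) {
    miss <- which(!hit)
    if (length(miss)) {
      gen_fp <- ob_ecfp(gen_canon)
      res_fp <- ob_ecfp(res_canon[miss])
      for (k in seq_along(miss)) {
        sims <- apply(gen_fp, 1, tanimoto_bits, b = res_fp[k, ])
        if (any(sims >= relaxed_threshold)) hit[miss[k]] <- TRUE
      }
    }
  }
  tibble::tibble(recall = mean(hit), n_recalled = sum(hit),
                 n_reserved = length(reserved),
                 relaxed_threshold = relaxed_threshold %||% NA_real_)
}

#' Apparent precision over a high-confidence generated set
#'
#' Builds the high-confidence set from the raw generation stream:
#' molecules sampled more than once join the set in the order of their
#' first repetition until `budget` molecules are collected. Counts how
#' many reserved actives are matched by that set, exactly (canonical
#' SMILES after neutralization) or at structural similarity >=
#' `threshold`.
#'
#' @param stream Character vector of raw generated SMILES with
#'   multiplicity, in generation order.
#' @param reserved Character vector of reserved active SMILES.
#' @param budget Size cap of the high-confidence set (4000 in the
#'   benchmark protocol).
#' @param threshold Similarity threshold for relaxed matching; `NULL`
#'   for exact only.
#' @return Integer count of reserved actives found.
#' @examples
#' apparent_precision(c("CCO", "OCC", "CCN"), reserved = "CCO")
#' @export
apparent_precision <- function(stream, reserved, budget = 4000L,
                               threshold = 0.8) {
  if (budget <= 0) stop("budget must be positive")
  if (!length(reserved)) stop("empty reserved set")
  canon <- canonical_smiles(stream)
  canon <- canon[!is.na(canon)]
  second_seen <- canon[duplicated(canon)]
  high_conf <- unique(second_seen)
  if (length(high_conf) > budget) high_conf <- high_conf[seq_len(budget)]
  if (!length(high_conf)) return(0L)
  res <- recall_rate(high_conf, reserved, relaxed_threshold = threshold)
  as.integer(res$n_recalled)
}

#' Evaluate a generated set against its conditioning reference
#'
#' Per-molecule structural similarity, pharmacophoric similarity and
#' feature-count deviation with respect to the reference compound, as a
#' tidy report; `glance()` gives the aggregate means and standard
#' deviations.
#'
#' @param data A data frame with a SMILES column, or a character vector
#'   of generated SMILES.
#' @param reference A single reference SMILES.
#' @param smiles_col Column holding SMILES strings.
#' @param families Feature definitions.
#' @return A tibble of class `metric_report` with columns `smiles`,
#'   `s_struct`, `s_pharma`, `count_deviation`.
#' @export
evaluate_generation <- function(data, reference, smiles_col = smiles,
                                families = feature_families()) {
  data <- as_smiles_tibble(data)
  smi <- dplyr::pull(data, {{ smiles_col }})
  if (!length(smi)) stop("empty generated set")
  ref_counts <- count_vector(reference, families)
  out <- tibble::tibble(
    smiles = smi,
    s_struct = s_struct(smi, reference),
    s_pharma = s_pharma(smi, reference),
    count_deviation = vapply(smi, function(s) {
      sum(abs(count_vector(s, families) - ref_counts))
    }, numeric(1), USE.NAMES = FALSE))
  attr(out, "reference") <- reference
  class(out) <- c("metric_report", class(out))
  out
}

#' @exportS3Method generics::glance
glance.metric_report <- function(x, ...) {
  tibble::tibble(
    n = nrow(x),
    d_count_mean = mean(x$count_deviation),
    d_count_sd = stats::sd(x$count_deviation),
    s_pharma_mean = mean(x$s_pharma),
    s_pharma_sd = stats::sd(x$s_pharma),
    s_struct_mean = mean(x$s_struct),
    s_struct_sd = stats::sd(x$s_struct))
}

#' @exportS3Method ggplot2::autoplot
autoplot.metric_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$s_struct, .data$s_pharma)) +
    ggplot2::geom_point(alpha = 0.6, colour = "steelblue") +
    ggplot2::lims(x = c(0, 1), y = c(0, 1)) +
    ggplot2::labs(
      x = "structural similarity to reference",
      y = "pharmacophoric similarity to reference",
      title = "exploration mode of the generated set") +
    ggplot2::theme_minimal()
}
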
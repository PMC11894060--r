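# Autoregressive sampling under pharmacophore conditions: de novo
# generation, scaffold elaboration with the bond-breaking fragmentation
# protocol, temperature control and post-processing.

#' Sample SMILES strings from a trained decoder
#'
#' Draws tokens one at a time from `softmax(logits / temperature)`,
#' starting after the condition prefix (and optional forced token
#' prefix), stopping at the pad/end token or `max_length` tokens.
#' Returns exactly `n_samples` raw strings; validity is not guaranteed
#' and unterminated strings are returned as-is. Deterministic given
#' `seed`.
#'
#' @param model A trained [train_decoder()] object.
#' @param condition Condition vector matching the model's
#'   `condition_kind` (`NULL` for unconditional models).
#' @param n_samples Number of strings to draw.
#' @param temperature Sampling temperature (> 0); lower values
#'   concentrate probability on top-ranked tokens. Default 0.7.
#' @param max_length Maximum number of generated SMILES tokens.
#' @param seed Integer seed.
#' @param prefix Optional character vector of vocabulary tokens forced
#'   as the start of every sample (scaffold-elaboration core).
#' @param greedy If `TRUE`, take the argmax token instead of sampling
#'   (the temperature-to-zero limit).
#' @param vocab Vocabulary the model was trained with.
#' @return A tibble with columns `smiles` (raw generated strings) and
#'   `terminated` (whether the end token was produced).
#' @export
sample_molecules <- function(model, condition = NULL, n_samples = 10L,
                             temperature = 0.7, max_length = 80L,
                             seed = 1L, prefix = NULL, greedy = FALSE,
                             vocab = smiles_vocabulary()) {
  stopifnot(inherits(model, "phore_decoder"), n_samples >= 1)
  if (temperature <= 0) stop("temperature must be > 0")
  cl <- condition_length(model$config)
  cond <- if (cl > 0L) {
    if (is.null(condition)) stop("model expects a condition vector")
    if (length(condition) != cl) stop("condition length must be ", cl)
    as.integer(condition)
  } else integer(0)
  start_ids <- encode_tokens(prefix %||% character(0), vocab)
  if (cl + length(start_ids) + max_length > model$config$max_seq_len) {
    stop("prefix plus max_length exceeds the model's max_seq_len")
  }
  pad_id <- unname(vocab$ids[vocab$pad])
  n_prefix <- length(start_ids)
  seqs <- rep(list(start_ids), n_samples)
  done <- logical(n_samples)
  withr::with_seed(seed, {
    for (step in seq_len(max_length)) {
      active <- which(!done)
      if (!length(active)) break
      probs <- decoder_next_probs(
        model, rep(list(cond), length(active)), seqs[active],
        temperature = temperature)
      for (k in seq_along(active)) {
        i <- active[k]
        nxt <- if (greedy) which.max(probs[k, ]) else
          sample.int(ncol(probs), 1L, prob = probs[k, ])
        if (nxt == pad_id) {
          done[i] <- TRUE
        } else {
          seqs[[i]] <- c(seqs[[i]], nxt)
        }
      }
    }
  })
  smiles <- vapply(seqs, decode_ids, character(1), vocab = vocab)
  tibble::tibble(smiles = smiles, terminated = done)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fragment a molecule by breaking one acyclic single bond
#'
#' Chooses uniformly at random (seeded) among eligible bonds - single,
#' acyclic, both ends heavy atoms - breaks it, and emits the two
#' fragments as SMILES rooted at the broken-bond atoms: the core with
#' its attachment atom written last and syntactically open, the
#' reference with its attachment atom written first, so that
#' `paste0(core, reference)` is a valid SMILES of the parent molecule.
#' One fragment is designated the core (starting point for
#' elaboration), the other the reference elaboration; the assignment is
#' randomized.
#'
#' @param smiles A single SMILES string.
#' @param seed Integer seed for the bond and assignment draw.
#' @return A list of class `fragment_pair` with elements `core`,
#'   `reference` (fragment SMILES), `broken_bond` (atom index pair in
#'   the parent) and `parent`.
#' @examples
#' fragment_molecule("CCOC", seed = 1)
#' @export
fragment_molecule <- function(smiles, seed = 1L) {
  md <- mol_data(smiles)
  b <- md$bonds
  heavy <- md$atoms$atomic_num > 1L
  eligible <- which(b$order == 1L & !b$in_ring &
                      heavy[b$begin] & heavy[b$end])
  if (!length(eligible)) {
    cnd <- structure(
      class = c("phoregen_nocut", "error", "condition"),
      list(message = paste0("no eligible acyclic single bond between ",
                            "heavy atoms in ", smiles), call = NULL))
    stop(cnd)
  }
  withr::with_seed(seed, {
    pick <- eligible[sample.int(length(eligible), 1L)]
    swap <- stats::runif(1) < 0.5
  })
  a1 <- b$begin[pick]
  a2 <- b$end[pick]
  g2 <- igraph::delete_edges(md$graph, igraph::get_edge_ids(md$graph,
                                                            c(a1, a2)))
  comp <- igraph::components(g2)$membership
  comp <- comp[as.character(md$atoms$idx)]
  side1 <- md$atoms$idx[comp == comp[[as.character(a1)]]]
  side2 <- md$atoms$idx[comp == comp[[as.character(a2)]]]
  frag_smiles <- function(keep, attach, role) {
    ex <- mol_extract(md, keep)
    new_idx <- ex$new_index[[as.character(attach)]]
    if (role == "core") {
      # attachment atom written last and left syntactically open
      ob_write_smiles(ex$mol, canonical = FALSE, root_last = new_idx)
    } else {
      # attachment atom written first so core + reference reads as one
      # SMILES with the broken bond restored
      ob_write_smiles(ex$mol, canonical = FALSE, root_first = new_idx)
    }
  }
  if (swap) {
    core <- frag_smiles(side2, a2, "core")
    ref <- frag_smiles(side1, a1, "reference")
  } else {
    core <- frag_smiles(side1, a1, "core")
    ref <- frag_smiles(side2, a2, "reference")
  }
  structure(list(core = core, reference = ref,
                 broken_bond = c(a1, a2), parent = smiles),
            class = "fragment_pair")
}

#' @export
print.fragment_pair <- function(x, ...) {
  cat("<fragment_pair> parent ", x$parent, "\n  core:      ", x$core,
      "\n  reference: ", x$reference, "\n  broken bond: ",
      x$broken_bond[1], "-", x$broken_bond[2], "\n", sep = "")
  invisible(x)
}

#' Scaffold elaboration from a core fragment
#'
#' Samples completions with the core's token sequence forced as prefix,
#' conditioned on pharmacophoric information of the reference
#' elaboration (typically the reference fragment's fingerprint). Every
#' returned string begins with the core prefix verbatim.
#'
#' @inheritParams sample_molecules
#' @param core_smiles Core fragment SMILES (rooted so its attachment
#'   atom is syntactically open; see [fragment_molecule()]).
#' @return A tibble as in [sample_molecules()].
#' @export
elaborate <- function(model, core_smiles, condition = NULL,
                      n_samples = 10L, temperature = 0.7,
                      max_length = 80L, seed = 1L, greedy = FALSE,
                      vocab = smiles_vocabulary()) {
  prefix <- tokenize_smiles(core_smiles, vocab)
  sample_molecules(model, condition = condition, n_samples = n_samples,
                   temperature = temperature, max_length = max_length,
                   seed = seed, prefix = prefix, greedy = greedy,
                   vocab = vocab)
}

#' Filter raw generated strings to unique valid canonical molecules
#'
#' Removes strings that fail parsing, canonicalizes the survivors and
#' collapses duplicates by canonical form, preserving order of first
#' occurrence.
#'
#' @param data A data frame with a SMILES column (e.g. from
#'   [sample_molecules()]) or a character vector of raw SMILES.
#' @param smiles_col Column holding SMILES strings.
#' @return A tibble with columns `smiles` (canonical) and `n_seen`
#'   (multiplicity of that canonical form in the input).
#' @examples
#' postprocess_smiles(c("OCC", "CCO", "not_a_smiles"))
#' @export
postprocess_smiles <- function(data, smiles_col = smiles) {
  data <- as_smiles_tibble(data)
  raw <- dplyr::pull(data, {{ smiles_col }})
  if (!length(raw)) {
    return(tibble::tibble(smiles = character(), n_seen = integer()))
  }
  canon <- canonical_smiles(raw)
  canon <- canon[!is.na(canon)]
  if (!length(canon)) {
    return(tibble::tibble(smiles = character(), n_seen = integer()))
  }
  out <- dplyr::count(tibble::tibble(smiles = canon), .data$smiles,
                      name = "n_seen")
  out[match(unique(canon), out$smiles), ]
}
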
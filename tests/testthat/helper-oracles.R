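# Shared test helpers.

# Run a short python snippet against the RDKit toolkit (used only as an
# independent oracle on tiny fixtures) and return its stdout lines.
run_rdkit <- function(code) {
  out <- suppressWarnings(system2("python", "-", input = code,
                                  stdout = TRUE, stderr = FALSE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("python oracle failed with status ", status)
  }
  out
}

# Independent SMARTS match oracle: atoms matched by a pattern, as a
# sorted unique set of 1-based indices per match.
rdkit_smarts_atoms <- function(smiles, smarts) {
  code <- sprintf(
    "from rdkit import Chem
m = Chem.MolFromSmiles(%s)
p = Chem.MolFromSmarts(%s)
for match in m.GetSubstructMatches(p, uniquify=True):
    print(','.join(str(i + 1) for i in sorted(set(match))))",
    deparse(smiles), deparse(smarts))
  lines <- run_rdkit(code)
  lapply(lines, function(l) as.integer(strsplit(l, ",")[[1]]))
}

# Minimal two-column family table for layout-isolation tests.
mini_families <- function(acceptor, donor) {
  tibble::tibble(
    family_id = c(0L, 1L),
    family = factor(c("acceptor", "donor"),
                    levels = levels(feature_families()$family)),
    smarts = c(acceptor, donor))
}

# Small deterministic training corpus shared by model/generation tests.
tiny_corpus <- function(n = 40, seed = 3) toy_corpus(n, seed = seed)

tiny_config <- function(kind = "fingerprint_72", seed = 11) {
  decoder_config(condition_kind = kind, n_layers = 2L, n_heads = 4L,
                 embed_dim = 64L, feedforward_dim = 128L,
                 max_seq_len = 160L, seed = seed)
}

# Independent brute-force sphere-exclusion clustering (oracle for the
# Butina implementation), written against the same tie-break convention
# but via per-pair similarity recomputation.
brute_butina <- function(fps, thr) {
  n <- nrow(fps)
  tanimoto <- function(i, j) {
    inter <- sum(fps[i, ] & fps[j, ])
    uni <- sum(fps[i, ] | fps[j, ])
    if (uni == 0) 1 else inter / uni
  }
  nbrs <- lapply(seq_len(n), function(i) {
    setdiff(which(vapply(seq_len(n), function(j) {
      1 - tanimoto(i, j) <= thr
    }, logical(1))), i)
  })
  counts <- lengths(nbrs)
  assigned <- rep(NA_integer_, n)
  cid <- 0L
  for (i in order(-counts, seq_len(n))) {
    if (!is.na(assigned[i])) next
    cid <- cid + 1L
    members <- c(i, nbrs[[i]][is.na(assigned[nbrs[[i]]])])
    assigned[members] <- cid
  }
  sz <- table(assigned)
  ord <- order(-as.integer(sz), as.integer(names(sz)))
  relabel <- integer(length(sz))
  relabel[as.integer(names(sz))[ord]] <- seq_along(ord)
  relabel[assigned]
}

# cache of trained tiny models within one test file run
.test_models <- new.env(parent = emptyenv())
tiny_model <- function(kind = "fingerprint_72", n = 40, epochs = 60,
                       seed = 11) {
  key <- paste(kind, n, epochs, seed)
  if (is.null(.test_models[[key]])) {
    .test_models[[key]] <- train_decoder(
      tiny_corpus(n), tiny_config(kind, seed), epochs = epochs,
      batch_size = 20L, lr = 2e-3)
  }
  .test_models[[key]]
}
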
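# Sampling, fragmentation, scaffold elaboration and post-processing.

test_that("sampling returns exactly n raw strings, reproducibly", {
  model <- tiny_model("none", n = 20, epochs = 30)
  g1 <- sample_molecules(model, n_samples = 7, seed = 42, max_length = 30)
  expect_equal(nrow(g1), 7L)
  g2 <- sample_molecules(model, n_samples = 7, seed = 42, max_length = 30)
  expect_identical(g1, g2)
  g3 <- sample_molecules(model, n_samples = 7, seed = 43, max_length = 30)
  expect_false(identical(g1$smiles, g3$smiles))
  expect_error(sample_molecules(model, n_samples = 3, temperature = 0),
               "temperature")
})

test_that("greedy decoding is the temperature-to-zero limit: all samples identical", {
  model <- tiny_model("none", n = 20, epochs = 30)
  g <- sample_molecules(model, n_samples = 5, greedy = TRUE, seed = 1,
                        max_length = 30)
  expect_equal(length(unique(g$smiles)), 1L)
})

test_that("an overfit conditional model reproduces a training molecule greedily", {
  corp <- tiny_corpus(20, seed = 3)
  fpkey <- vapply(corp$condition, paste, character(1), collapse = "")
  uniq <- which(!(duplicated(fpkey) | duplicated(fpkey, fromLast = TRUE)))
  model <- tiny_model("fingerprint_72", n = 20, epochs = 150)
  hits <- 0L
  for (k in uniq[1:3]) {
    g <- sample_molecules(model, condition = as.integer(corp$condition[[k]]),
                          n_samples = 1, greedy = TRUE, seed = 1,
                          max_length = 30)
    if (identical(canonical_smiles(g$smiles[1]),
                  canonical_smiles(corp$smiles[k]))) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 2L)
})

test_that("fragmentation breaks one eligible acyclic single bond", {
  fp <- fragment_molecule("CC", seed = 1)
  expect_setequal(c(fp$core, fp$reference), c("C", "C"))
  expect_error(fragment_molecule("c1ccccc1", seed = 1), "no eligible")
  expect_error(fragment_molecule(worked_molecules()[["no_cut_ring"]]),
               "no eligible")

  heavy_atoms <- function(s) {
    sum(phoregen:::mol_data(s)$atoms$atomic_num > 1)
  }
  for (smi in c("CCOC", "CC(=O)Oc1ccccc1C(=O)O", "NCCc1ccc(O)cc1",
                "CCCCCC")) {
    for (seed in 1:5) {
      fp <- fragment_molecule(smi, seed = seed)
      expect_equal(heavy_atoms(fp$core) + heavy_atoms(fp$reference),
                   heavy_atoms(smi), label = paste(smi, seed))
      # the broken bond is acyclic: both fragments parse independently
      expect_true(all(valid_smiles(c(fp$core, fp$reference))))
    }
  }
})

test_that("fragmentation never selects ring bonds", {
  md <- phoregen:::mol_data("CC1CC1c1ccccc1")
  ring_pairs <- with(md$bonds[md$bonds$in_ring, ],
                     paste(pmin(begin, end), pmax(begin, end)))
  for (seed in 1:20) {
    fp <- fragment_molecule("CC1CC1c1ccccc1", seed = seed)
    got <- paste(min(fp$broken_bond), max(fp$broken_bond))
    expect_false(got %in% ring_pairs)
  }
})

test_that("elaboration forces the core prefix verbatim", {
  model <- tiny_model("none", n = 20, epochs = 30)
  out <- elaborate(model, core_smiles = "CCC", n_samples = 6, seed = 2,
                   max_length = 25)
  expect_equal(nrow(out), 6L)
  expect_true(all(startsWith(out$smiles, "CCC")))
  expect_error(elaborate(model, core_smiles = strrep("C", 200)),
               "max_seq_len")
})

test_that("an overfit model completes a core to its parent molecule", {
  # emulate elaboration fine-tuning: pair each parent, written in the
  # core-rooted form, with the fingerprint of its reference fragment
  parents <- c("NCCCO", "OCCCCN", "NCCc1ccccc1", "OC(=O)CCN",
               "CCOC(=O)C", "NCCCCO")
  frags <- lapply(parents, fragment_molecule, seed = 4)
  rooted <- vapply(seq_along(parents), function(i) {
    paste0(frags[[i]]$core, frags[[i]]$reference)
  }, character(1))
  # rooted core+reference concatenation is a valid rendering of the parent
  expect_identical(canonical_smiles(rooted), canonical_smiles(parents))
  corpus <- tibble::tibble(
    smiles = rooted,
    condition = lapply(frags, function(f) {
      phoregen:::fingerprint1(f$reference, "P72")
    }))
  cfg <- tiny_config("fingerprint_72", seed = 21)
  model <- train_decoder(corpus, cfg, epochs = 120, batch_size = 6,
                         lr = 2e-3)
  ok <- 0L
  for (i in seq_along(parents)) {
    out <- elaborate(model, core_smiles = frags[[i]]$core,
                     condition = as.integer(corpus$condition[[i]]),
                     n_samples = 1, greedy = TRUE, seed = 1,
                     max_length = 25)
    if (identical(canonical_smiles(out$smiles[1]),
                  canonical_smiles(parents[i]))) {
      ok <- ok + 1L
    }
  }
  expect_gte(ok, 4L)
})

test_that("postprocess removes invalid strings and canonical duplicates", {
  out <- postprocess_smiles(c("CCO", "not_a_smiles"))
  expect_equal(nrow(out), 1L)
  out2 <- postprocess_smiles(c("OCC", "CCO"))
  expect_equal(nrow(out2), 1L)
  expect_equal(out2$n_seen, 2L)
  expect_equal(nrow(postprocess_smiles(character(0))), 0L)
  # order of first occurrence is preserved
  out3 <- postprocess_smiles(c("CCN", "CCO", "OCC", "CCN"))
  expect_identical(out3$smiles, canonical_smiles(c("CCN", "CCO")))
})

test_that("higher temperature does not reduce sample diversity", {
  model <- tiny_model("none", n = 20, epochs = 30)
  n_unique <- function(t) {
    vapply(1:20, function(sd) {
      g <- sample_molecules(model, n_samples = 10, temperature = t,
                            seed = sd, max_length = 25)
      length(unique(g$smiles))
    }, numeric(1))
  }
  expect_gte(mean(n_unique(1.2)), mean(n_unique(0.7)))
})
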
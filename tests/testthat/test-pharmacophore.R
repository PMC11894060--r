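# Feature detection, the topological feature graph, and the
# 72/108/1032-bit encoders.

test_that("feature detection matches the pinned patterns on worked molecules", {
  wm <- worked_molecules()

  expect_equal(nrow(detect_features(wm[["methane"]])), 0L)

  eth <- detect_features(wm[["ethanol"]])
  don <- eth[eth$family == "donor", ]
  acc <- eth[eth$family == "acceptor", ]
  expect_gte(nrow(don), 1L)
  expect_gte(nrow(acc), 1L)
  # both features sit on the oxygen (atom 3 of CCO)
  expect_true(all(unlist(don$atoms) == 3L))
  expect_true(all(unlist(acc$atoms) == 3L))

  asp <- detect_features(wm[["aspirin"]])
  expect_gt(nrow(asp), 0L)
  expect_true("aromatic" %in% asp$family)
  expect_gte(sum(asp$family == "acceptor"), 2L)

  expect_error(detect_features("not_a_smiles"), "invalid SMILES")
})

test_that("detection agrees with an independent SMARTS matcher", {
  fams <- feature_families()
  for (smi in c("CCO", "CC(=O)Oc1ccccc1C(=O)O", "NC(=N)N")) {
    mine <- detect_features(smi, fams)
    for (fam in c("acceptor", "donor", "neg_ionizable")) {
      pats <- fams$smarts[fams$family == fam]
      oracle <- unique(unlist(lapply(pats, function(p) {
        lapply(rdkit_smarts_atoms(smi, p), paste, collapse = ",")
      })))
      oracle <- as.character(oracle)
      got <- vapply(mine$atoms[mine$family == fam], paste, character(1),
                    collapse = ",")
      expect_setequal(as.character(got), oracle)
    }
  }
})

test_that("feature distances are closest-atom bond-count shortest paths", {
  # single feature: 1x1 zero matrix
  g1 <- phore_graph("CC(C)=O")
  expect_true(nrow(g1$dist) >= 1)
  expect_true(all(diag(g1$dist) == 0))

  # donor and acceptor share the hydroxyl oxygen: distance 0
  g2 <- phore_graph("CCO")
  expect_equal(g2$dist[1, 2], 0)

  # two hydroxyls four bonds apart (hand BFS oracle: O-C-C-C-O)
  g3 <- phore_graph("OCCCO")
  accs <- which(g3$features$family == "acceptor")
  expect_equal(g3$dist[accs[1], accs[2]], 4)

  # disconnected components are infinitely far apart
  g4 <- phore_graph("CCO.NCC")
  don_o <- which(vapply(g4$features$atoms, function(a) 3L %in% a,
                        logical(1)))
  don_n <- which(vapply(g4$features$atoms, function(a) 4L %in% a,
                        logical(1)))
  expect_true(all(!is.finite(g4$dist[don_o, don_n])))

  # symmetric
  expect_identical(g3$dist, t(g3$dist))
})

test_that("duplicate (family, atoms) matches collapse to one instance", {
  feats <- detect_features("CCO")
  key <- paste(feats$family_id,
               vapply(feats$atoms, paste, character(1), collapse = ","))
  expect_false(any(duplicated(key)))
})

test_that("fingerprint lengths obey the combinatorial layout", {
  # 36 pair keys x 2 bins = 72; x 3 bins = 108;
  # 120 triples x 8 patterns + 72 = 1032
  expect_equal(36 * 2, 72)
  expect_equal(nrow(fp_layout("P72")), 72)
  expect_equal(nrow(fp_layout("P108")), 108)
  expect_equal(nrow(fp_layout("P1032")), 1032)
  for (smi in worked_molecules()) {
    expect_length(phoregen:::fingerprint1(smi, "P72"), 72)
    expect_length(phoregen:::fingerprint1(smi, "P108"), 108)
    expect_length(phoregen:::fingerprint1(smi, "P1032"), 1032)
  }
})

test_that("a single feature pair at distance 4 sets exactly the long acceptor-donor bit", {
  fams <- mini_families("[OX1;$(O=C)]", "[NX3;H2;!$(NC=O)]")
  g <- phore_graph("O=CCCN", families = fams)
  expect_equal(nrow(g$features), 2L)
  expect_equal(g$dist[1, 2], 4)
  fp <- encode_two_point(g, "two_bin")
  # pair key (acceptor, donor) = key index 1; long bin = bit 1*2+1+1 = 4
  expect_equal(sum(fp), 1L)
  expect_equal(which(as.integer(fp) == 1L), 4L)
  lay <- fp_layout("P72")
  expect_equal(lay$families[4], "acceptor+donor")
  expect_equal(lay$bins[4], "long")
})

test_that("null signals: distances at or beyond 8 bonds set no bit", {
  fams <- mini_families("[OX1;$(O=C)]", "[NX3;H2;!$(NC=O)]")
  g <- phore_graph(paste0("O=C", strrep("C", 8), "N"), families = fams)
  expect_gte(g$dist[1, 2], 8)
  expect_equal(sum(encode_two_point(g, "two_bin")), 0L)
  expect_equal(sum(encode_two_point(g, "three_bin")), 0L)
  expect_equal(sum(encode_three_point(g)), 0L)
})

test_that("the three-bin scheme excludes distance zero as printed", {
  sch <- bin_scheme("three_bin")
  expect_true(sch$lower_open[1])
  g <- phore_graph("CCO") # donor/acceptor at distance 0
  fp108 <- encode_two_point(g, "three_bin")
  expect_equal(sum(fp108), 0L)
  fp72 <- encode_two_point(g, "two_bin") # [0,3) includes 0
  expect_gte(sum(fp72), 1L)
})

test_that("the 1032-bit prefix equals the 72-bit fingerprint bit-for-bit", {
  for (smi in c("CCO", "CC(=O)Oc1ccccc1C(=O)O", "NCCCc1ccccc1O")) {
    expect_identical(as.integer(phoregen:::fingerprint1(smi, "P1032"))[1:72],
                     as.integer(phoregen:::fingerprint1(smi, "P72")))
  }
})

test_that("fingerprints are invariant to SMILES atom ordering", {
  pairs <- list(c("c1ccccc1C(=O)O", "OC(=O)c1ccccc1"),
                c("CCOC(=O)CN", "NCC(=O)OCC"),
                c("Oc1ccc(CCN)cc1", "NCCc1ccc(O)cc1"))
  for (p in pairs) {
    for (v in c("P72", "P108", "P1032")) {
      expect_identical(as.integer(phoregen:::fingerprint1(p[1], v)),
                       as.integer(phoregen:::fingerprint1(p[2], v)))
    }
  }
})

test_that("fingerprinting is deterministic and rejects invalid input", {
  a <- phoregen:::fingerprint1("CC(=O)Oc1ccccc1C(=O)O", "P1032")
  b <- phoregen:::fingerprint1("CC(=O)Oc1ccccc1C(=O)O", "P1032")
  expect_identical(as.integer(a), as.integer(b))
  expect_error(phore_fingerprint("???"), "invalid SMILES")
})

test_that("three-point encoding matches a brute-force triple enumerator", {
  # independent oracle: enumerate all feature triples directly from the
  # graph, classify each by sorted family multiset and the sorted-bin
  # convention, and set bits in a fresh vector
  brute_three_point <- function(g) {
    bin2 <- function(d) {
      if (!is.finite(d) || d >= 8) NA_integer_ else if (d < 3) 0L else 1L
    }
    fid <- g$features$family_id
    n <- length(fid)
    bits <- integer(960)
    if (n < 3) return(bits)
    keys <- list()
    for (g1 in 0:7) for (g2 in g1:7) for (g3 in g2:7) {
      keys[[length(keys) + 1L]] <- c(g1, g2, g3)
    }
    keystr <- vapply(keys, paste, character(1), collapse = "-")
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      trio <- c(i, j, k)
      dists <- c(g$dist[i, j], g$dist[i, k], g$dist[j, k])
      if (any(!is.finite(dists)) || any(dists >= 8)) next
      best <- NULL
      for (perm in list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                        c(3, 1, 2), c(3, 2, 1))) {
        t2 <- trio[perm]
        fams <- fid[t2]
        if (is.unsorted(fams)) next
        pat <- c(bin2(g$dist[t2[1], t2[2]]), bin2(g$dist[t2[1], t2[3]]),
                 bin2(g$dist[t2[2], t2[3]]))
        cand <- list(fams = fams, pat = pat)
        if (is.null(best) ||
            paste(pat, collapse = "") < paste(best$pat, collapse = "")) {
          best <- cand
        }
      }
      ki <- match(paste(best$fams, collapse = "-"), keystr) - 1L
      pi <- best$pat[1] * 4L + best$pat[2] * 2L + best$pat[3]
      bits[ki * 8L + pi + 1L] <- 1L
    }
    bits
  }
  for (smi in c("NCCCO", "OCCCO", "NCCCc1ccccc1", "OC(=O)CCCN",
                "SCCCN", "OCCCCCCCN")) {
    g <- phore_graph(smi)
    if (nrow(g$features) > 6) next
    mine <- as.integer(encode_three_point(g))[73:1032]
    expect_identical(mine, brute_three_point(g),
                     label = paste("three-point oracle on", smi))
  }
})

test_that("set-bit counts respect the combinatorial bound", {
  for (smi in c("CC(=O)Oc1ccccc1C(=O)O", "NCCCc1ccc(O)cc1")) {
    g <- phore_graph(smi)
    n_pairs <- choose(nrow(g$features), 2)
    expect_lte(sum(encode_two_point(g, "two_bin")), min(72, n_pairs))
    expect_lte(sum(encode_two_point(g, "three_bin")), min(108, n_pairs))
  }
})

test_that("feature counts sum to the number of detected features", {
  expect_identical(unname(phoregen:::count_vector("C")), rep(0L, 8))
  for (smi in c("CCO", "CC(=O)Oc1ccccc1C(=O)O", "NCCS")) {
    expect_equal(sum(phoregen:::count_vector(smi)), nrow(detect_features(smi)))
  }
  cc <- feature_counts(c("C", "CCO"))
  expect_equal(cc$n_donor, c(0L, 1L))
  expect_equal(cc$n_acceptor, c(0L, 1L))
})

test_that("the pinned definition file has exactly eight families", {
  fams <- feature_families()
  expect_equal(length(unique(fams$family_id)), 8L)
  expect_equal(sort(unique(as.character(fams$family))),
               sort(c("acceptor", "donor", "aromatic", "pos_ionizable",
                      "neg_ionizable", "hydrophobe", "lumped_hydrophobe",
                      "zn_binder")))
})
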
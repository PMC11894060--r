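# Binary topological pharmacophore fingerprints.
#
# Two-point encoding: every unordered pair of feature instances is keyed
# by its sorted family-id pair (36 keys) and its topological distance is
# discretized into 2 or 3 bins, giving 72- or 108-bit fingerprints.
# Three-point encoding: every triple of feature instances is keyed by the
# sorted family-id multiset (120 keys) and the pattern of its three
# pairwise distances under the 2-bin scheme (8 patterns), giving a
# 960-bit segment appended to the 72-bit two-point segment (1032 bits
# total). Distances of 8 bonds or more (and cross-component pairs) are
# null signals and set no bit. Fingerprints are binary: a bit records
# that at least one instance hit it, not how many.

#' Distance discretization schemes
#'
#' `two_bin` splits topological distances into short `[0, 3)` and long
#' `[3, 8)`; `three_bin` into short `(0, 2)` (distance 0 excluded),
#' medium `[2, 5)` and long `[5, 8)`. Distances at or beyond 8 fall in no
#' bin.
#'
#' @param name `"two_bin"` or `"three_bin"`.
#' @return A tibble with columns `bin` (0-based), `lower`, `upper` and
#'   `lower_open`.
#' @examples
#' bin_scheme("two_bin")
#' @export
bin_scheme <- function(name = c("two_bin", "three_bin")) {
  name <- match.arg(name)
  if (name == "two_bin") {
    tibble::tibble(bin = 0:1, lower = c(0, 3), upper = c(3, 8),
                   lower_open = c(FALSE, FALSE))
  } else {
    tibble::tibble(bin = 0:2, lower = c(0, 2, 5), upper = c(2, 5, 8),
                   lower_open = c(TRUE, FALSE, FALSE))
  }
}

# 0-based bin index for a distance, or NA for a null signal.
bin_of <- function(d, scheme) {
  if (!is.finite(d)) return(NA_integer_)
  for (k in seq_len(nrow(scheme))) {
    lo_ok <- if (scheme$lower_open[k]) d > scheme$lower[k] else
      d >= scheme$lower[k]
    if (lo_ok && d < scheme$upper[k]) return(scheme$bin[k])
  }
  NA_integer_
}

# Canonical pair keys: all (f1 <= f2) family-id pairs in lexicographic
# order; 36 keys.
pair_key_table <- function() {
  idx <- 0L
  out <- matrix(NA_integer_, 8, 8)
  for (f1 in 0:7) for (f2 in f1:7) {
    out[f1 + 1L, f2 + 1L] <- idx
    idx <- idx + 1L
  }
  out
}

# Canonical triple keys: all multisets (g1 <= g2 <= g3) of family ids in
# lexicographic order; 120 keys.
triple_key_table <- function() {
  keys <- list()
  for (g1 in 0:7) for (g2 in g1:7) for (g3 in g2:7) {
    keys[[length(keys) + 1L]] <- c(g1, g2, g3)
  }
  keys
}

.layout_cache <- new.env(parent = emptyenv())

#' Fingerprint bit layout
#'
#' Documents the meaning of every bit position of a fingerprint variant:
#' which family pair (or triple) and which distance bin (or bin pattern)
#' it encodes.
#'
#' @param variant `"P72"`, `"P108"` or `"P1032"`.
#' @return A tibble with columns `bit` (1-based position), `segment`
#'   (`two_point`/`three_point`), `families` (family names joined by
#'   `+`), and `bins` (bin labels joined by `-`; for three-point bits one
#'   label per pairwise distance in canonical order (1,2),(1,3),(2,3)).
#' @examples
#' fp_layout("P72")
#' @export
fp_layout <- function(variant = c("P72", "P108", "P1032")) {
  variant <- match.arg(variant)
  if (!is.null(.layout_cache[[variant]])) return(.layout_cache[[variant]])
  two_labels <- function(scheme_name) {
    sch <- bin_scheme(scheme_name)
    lab <- c("short", if (nrow(sch) == 3) "medium", "long")
    rows <- list()
    for (f1 in 0:7) for (f2 in f1:7) for (b in sch$bin) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        segment = "two_point",
        families = paste(FAMILY_NAMES[c(f1, f2) + 1L], collapse = "+"),
        bins = lab[b + 1L])
    }
    dplyr::bind_rows(rows)
  }
  out <- switch(variant,
    P72 = two_labels("two_bin"),
    P108 = two_labels("three_bin"),
    P1032 = {
      three <- list()
      lab <- c("short", "long")
      for (key in triple_key_table()) for (p in 0:7) {
        bits <- c(p %/% 4L, (p %/% 2L) %% 2L, p %% 2L)
        three[[length(three) + 1L]] <- tibble::tibble(
          segment = "three_point",
          families = paste(FAMILY_NAMES[key + 1L], collapse = "+"),
          bins = paste(lab[bits + 1L], collapse = "-"))
      }
      dplyr::bind_rows(two_labels("two_bin"), dplyr::bind_rows(three))
    })
  out <- dplyr::mutate(out, bit = dplyr::row_number(), .before = 1)
  .layout_cache[[variant]] <- out
  out
}

new_phore_fp <- function(bits, variant) {
  structure(as.integer(bits), variant = variant, class = "phore_fp")
}

#' @export
print.phore_fp <- function(x, ...) {
  cat("<phore_fp ", attr(x, "variant"), "> ", sum(x), "/", length(x),
      " bits set\n", sep = "")
  invisible(x)
}

#' Encode two-point pharmacophore fingerprints
#'
#' Sets one bit per (family pair, distance bin) realised by at least one
#' pair of distinct feature instances. `two_bin` yields 72 bits, and
#' `three_bin` 108 bits.
#'
#' @param graph A [phore_graph()].
#' @param scheme `"two_bin"` or `"three_bin"`.
#' @return A `phore_fp` binary vector with a `variant` attribute.
#' @examples
#' encode_two_point(phore_graph("CCO"))
#' @export
encode_two_point <- function(graph, scheme = c("two_bin", "three_bin")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(graph, "phore_graph"))
  sch <- bin_scheme(scheme)
  nbins <- nrow(sch)
  bits <- integer(36L * nbins)
  pk <- pair_key_table()
  fid <- graph$features$family_id
  n <- length(fid)
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      b <- bin_of(graph$dist[i, j], sch)
      if (is.na(b)) next
      fam <- sort(c(fid[i], fid[j]))
      key <- pk[fam[1] + 1L, fam[2] + 1L]
      bits[key * nbins + b + 1L] <- 1L
    }
  }
  new_phore_fp(bits, if (scheme == "two_bin") "P72" else "P108")
}

#' Encode the combined two- and three-point fingerprint
#'
#' Concatenates the 72-bit two-point segment (2-bin scheme) with a
#' 960-bit three-point segment: 120 canonical family triples times 8
#' patterns of the three pairwise distance bins, each bin in
#' \{short, long\} under the 2-bin scheme. A triple with any pairwise
#' distance outside the bins contributes nothing. Triple keys are
#' canonicalized by sorting family ids ascending; ties among equal
#' families are broken by choosing the atom assignment whose bin pattern
#' is lexicographically smallest, which makes the layout invariant to
#' feature enumeration order.
#'
#' @param graph A [phore_graph()].
#' @return A `phore_fp` binary vector of length 1032.
#' @examples
#' length(encode_three_point(phore_graph("CCO")))
#' @export
encode_three_point <- function(graph) {
  stopifnot(inherits(graph, "phore_graph"))
  two <- encode_two_point(graph, "two_bin")
  sch <- bin_scheme("two_bin")
  triples <- triple_key_table()
  tkey <- vapply(triples, paste, character(1), collapse = ",")
  bits3 <- integer(120L * 8L)
  fid <- graph$features$family_id
  n <- length(fid)
  if (n >= 3) {
    combs <- utils::combn(n, 3)
    perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                  c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
    for (cidx in seq_len(ncol(combs))) {
      trio <- combs[, cidx]
      b12 <- bin_of(graph$dist[trio[1], trio[2]], sch)
      b13 <- bin_of(graph$dist[trio[1], trio[3]], sch)
      b23 <- bin_of(graph$dist[trio[2], trio[3]], sch)
      if (anyNA(c(b12, b13, b23))) next
      fam_sorted <- sort(fid[trio])
      key_idx <- match(paste(fam_sorted, collapse = ","), tkey) - 1L
      binm <- matrix(NA_integer_, 3, 3)
      binm[1, 2] <- binm[2, 1] <- b12
      binm[1, 3] <- binm[3, 1] <- b13
      binm[2, 3] <- binm[3, 2] <- b23
      best <- NULL
      for (p in perms) {
        if (!identical(fid[trio][p], fam_sorted)) next
        pat <- c(binm[p[1], p[2]], binm[p[1], p[3]], binm[p[2], p[3]])
        if (is.null(best) ||
            pat[1] < best[1] ||
            (pat[1] == best[1] && pat[2] < best[2]) ||
            (pat[1] == best[1] && pat[2] == best[2] && pat[3] < best[3])) {
          best <- pat
        }
      }
      pat_idx <- best[1] * 4L + best[2] * 2L + best[3]
      bits3[key_idx * 8L + pat_idx + 1L] <- 1L
    }
  }
  new_phore_fp(c(unclass(two), bits3), "P1032")
}

#' Pharmacophore fingerprints for a table of molecules
#'
#' Data-frame-first wrapper composing feature detection, topology graph
#' construction and encoding. Deterministic: identical SMILES yield
#' bit-identical fingerprints.
#'
#' @inheritParams feature_counts
#' @param variant `"P72"` (two-point, 2-bin), `"P108"` (two-point,
#'   3-bin) or `"P1032"` (two- plus three-point, 2-bin).
#' @return The input as a tibble with list-column `fp` (each element a
#'   `phore_fp`) and integer column `n_bits_set`.
#' @examples
#' phore_fingerprint(c("CCO", "CC(=O)Oc1ccccc1C(=O)O"))
#' @export
phore_fingerprint <- function(data, smiles_col = smiles,
                              variant = c("P72", "P108", "P1032"),
                              families = feature_families()) {
  variant <- match.arg(variant)
  data <- as_smiles_tibble(data)
  smi <- dplyr::pull(data, {{ smiles_col }})
  fps <- lapply(smi, fingerprint1, variant = variant, families = families)
  data$fp <- fps
  data$n_bits_set <- vapply(fps, sum, integer(1))
  data
}

# Single-molecule fingerprint.
fingerprint1 <- function(smiles, variant = "P72",
                         families = feature_families()) {
  g <- phore_graph(smiles, families = families)
  switch(variant,
         P72 = encode_two_point(g, "two_bin"),
         P108 = encode_two_point(g, "three_bin"),
         P1032 = encode_three_point(g),
         stop("unknown variant: ", variant))
}

#' Plot which bits of a fingerprint are set
#'
#' @param object A `phore_fp`.
#' @param ... Unused.
#' @return A ggplot showing set bits by family pair and bin.
#' @exportS3Method ggplot2::autoplot
autoplot.phore_fp <- function(object, ...) {
  lay <- fp_layout(attr(object, "variant"))
  lay$set <- as.integer(object) == 1L
  ggplot2::ggplot(lay[lay$segment == "two_point", ],
                  ggplot2::aes(x = .data$bins, y = .data$families,
                               fill = .data$set)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "white",
                                          `TRUE` = "steelblue")) +
    ggplot2::labs(x = "distance bin", y = "family pair",
                  fill = "bit set",
                  title = paste0(attr(object, "variant"),
                                 " two-point segment")) +
    ggplot2::theme_minimal()
}
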
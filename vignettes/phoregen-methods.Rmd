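---
title: "Methods: topological pharmacophore fingerprints and conditioned SMILES generation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: topological pharmacophore fingerprints and conditioned SMILES generation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of the science it implements: the
fingerprint model, the conditional decoder, the evaluation metrics and
screening procedures, the choices made where the design was genuinely
open, and what the synthetic fixtures do and do not establish about real
data.

## The fingerprint model

A molecule is reduced to instances of eight pharmacophore feature
families — hydrogen-bond acceptor, donor, aromatic ring, positive and
negative ionizability, chain hydrophobe, lumped (ring) hydrophobe, and
zinc binder — detected by SMARTS patterns pinned in
`inst/extdata/feature_families.smarts`. Pinning a versioned file is
deliberate: feature perception differs between toolkits and versions,
and the fingerprints must not drift underneath trained models or frozen
regression values. The family split (chain vs. lumped hydrophobe) is
what brings the count to exactly eight; it mirrors the family structure
of the widespread ligand-pharmacophore definition files that inspired
this set.

Every pair of feature instances is characterised by the *topological*
distance between them — the bond count of the shortest path in the
molecular graph, no 3D geometry involved. For features spanning several
atoms (rings, carboxylate groups) the distance is the minimum over
member-atom pairs ("closest atom" convention). This keeps distance 0
meaningful: a hydroxyl oxygen is both donor and acceptor, and that
co-location is itself a signal under the 2-bin scheme.

Distances are discretized:

* `two_bin`: short `[0, 3)`, long `[3, 8)`;
* `three_bin`: short `(0, 2)`, medium `[2, 5)`, long `[5, 8)`.

Distances of 8 bonds or more give a *null signal* — no bit is set. The
`three_bin` scheme's open lower bound `(0, 2)` excludes distance 0; we
keep that exclusion exactly as specified rather than "repairing" it to
`[0, 2)`, and the test suite asserts the resulting behaviour (a
donor/acceptor pair sharing an atom sets a 2-bin bit but no 3-bin bit).

With 8 families there are 36 unordered family pairs, so two-point
fingerprints have 36 × 2 = 72 or 36 × 3 = 108 bits. The combined
two-plus-three-point variant appends, to the 72-bit segment, one bit
per (family multiset of size 3, pattern of the three pairwise 2-bin
distances): 120 multisets × 8 patterns = 960 bits, 1032 in total.
Triples are canonicalized by sorting the three family ids; ties between
equal families are resolved by choosing the assignment whose distance
bin pattern is lexicographically smallest, which makes the layout
invariant to feature enumeration order (verified against a brute-force
enumerator in the tests). Fingerprints are binary with OR semantics — a
bit says "at least one instance realised this arrangement" — and
feature instances identical in (family, member atoms) are deduplicated
before pairing.

## The conditional decoder

The generator is a small GPT-style causal transformer over SMILES
tokens. The condition channel — a fingerprint or an 8-vector of feature
counts — is injected as a prefix: each condition entry becomes one
position whose embedding is a learned value embedding (bit 0/1, or a
count clipped at 15) plus a learned per-channel embedding. A segment
embedding distinguishes condition positions (label 0) from SMILES
positions (label 1). Sequence order enters only through rotary
positional encoding (RoPE) applied to queries and keys: consecutive
dimension pairs are rotated by position-dependent angles so that
attention scores depend on relative offsets. The blocks themselves are
standard pre-layer-norm softmax attention plus GELU feed-forward
layers. Where the attention form was ambiguous (a linear-attention
notation with feature maps is one reading), we implement the softmax
default of GPT decoders; the RoPE relative-position property holds
either way and is asserted numerically at tolerance 1e-5.

Training minimises next-token cross-entropy on SMILES positions only;
condition positions are never prediction targets. The loss masking is
tested structurally: gradients are shown to never reach unused
condition-value embedding rows. Optimisation is Adam (β = 0.9/0.999,
ε = 1e-8) with an overridable learning rate that may be a per-epoch
vector (step decay). Everything is seeded — initialisation, batch
shuffling, dropout masks, sampling — and two runs with the same seed
produce bit-identical parameters.

Tokenization uses the fixed 108-token chemical-language vocabulary
shipped verbatim in `inst/extdata/vocab_full.txt`; pruning 14
infrequent bracket tokens gives the 94-token vocabulary used for
modelling. The begin token `<` is part of the printed vocabulary; the
vocabulary is silent on termination and padding, so the package
appends a single pad token `>` that doubles as end-of-sequence —
generation stops on it or at the length cap, and unterminated strings
are passed downstream as-is. The tokenizer is greedy longest-match
with a bracket fast path (`[` opens one token closed at the matching
`]`), making multi-character tokens (`Br`, `Cl`, `%10`-`%12`, bracket
atoms) atomic and the segmentation unambiguous and linear-time.

### Model sizes used in the test suite

The shipped default configuration is 2 layers, 4 heads, embedding 64,
feed-forward 256. The test suite and the conditioning-recovery
experiment use feed-forward 128 and corpora of 20–200 molecules with
80–150 epochs; these sizes were chosen once as the smallest at which
the decoder reliably memorises its corpus and exhibits clean
conditioning, and they keep the full suite comfortably within a desk
CPU budget. A full-scale configuration would raise depth/width and the
corpus by orders of magnitude; nothing in the architecture changes.

## Sampling and scaffold elaboration

Sampling draws tokens from `softmax(logits / t)`; the default
temperature 0.7 mirrors the low-temperature setting of the case
studies, and a greedy flag gives the `t → 0` argmax limit. For scaffold
elaboration a parent molecule is fragmented by breaking one randomly
chosen (seeded) eligible bond — single, acyclic, both ends heavy. The
core fragment is written as a rooted SMILES with the attachment atom
last and syntactically open; the reference fragment with its attachment
atom first, so `paste0(core, reference)` is a valid SMILES of the
parent. This rooted-SMILES priming is the package's documented choice
for a step the original description leaves unstated (attachment-token
alternatives exist); it keeps core + completion a single well-formed
string with no special tokens. Elaboration then forces the core's token
sequence as prefix and conditions on the reference fragment's
fingerprint.

## Metrics

* `s_struct`: Tanimoto of 2048-bit circular (Morgan radius-2
  equivalent) fingerprints, computed with OpenBabel's ECFP4 folded to
  2048 bits.
* `s_pharma`: modified Tanimoto of an ErG-style reduced-graph
  fingerprint implemented in the package (donor, acceptor, positive,
  negative, hydrophobe, aromatic-system property points; 21 type pairs
  × distances 1–15; fuzzy ±1-bin increments of 0.3). No installed R
  package provides ErG, so the package implements the descriptor class
  itself, with property typing deliberately independent of the pinned
  8-family condition definitions — a similarity score that shared
  patterns with the condition channel would flatter the generator.
  Ring systems are lumped as single property points (fused aromatics
  become one point); distances are clamped to a minimum of 1.
* `d_count`: mean L1 distance between per-family feature-count vectors
  of generated molecules and the reference.
* Recall: canonical-SMILES membership of reserved actives in the
  generated set after charge neutralization; the relaxed mode also
  accepts structural similarity ≥ 0.8. Apparent precision builds the
  high-confidence set from molecules sampled more than once, in order
  of first repetition, capped at 4000.

Charge neutralization precedes all similarity scoring: positively
charged atoms carrying a hydrogen lose one proton, negatively charged
N/O/S/C gain one, adjacent +/- pairs (nitro, N-oxide) and quaternary
nitrogens are untouched, applied to a fixed point. Whether exact-recall
matching happens before or after neutralization was an open choice; the
package matches after, so protomers of the same active count as
recalled.

## Screening procedures

The active/heldout split extracts Bemis-Murcko scaffolds (ring systems
plus linkers; atoms multiply-bonded to the framework are retained;
acyclic molecules yield an empty scaffold that forms its own group),
clusters the distinct scaffolds with Butina sphere exclusion (Tanimoto
distance 0.4 on the 2048-bit circular fingerprints), sorts clusters by
ligand count descending, and assigns 1-based odd ranks to training.
"Odd-indexed" was ambiguous; we fix 1-based indexing (the largest
cluster trains) and break size ties by the lexicographically smallest
scaffold so the split is deterministic.

The triage pipeline applies, in order: a pharmacophoric-similarity
floor (0.85) against the reference; a modified rule of five (hard
molecular-weight cap 1000 Da, at most one violation among logP > 5,
donors > 5, acceptors > 10) plus a pinned structural-alert SMARTS set;
a novelty filter discarding matches to a configurable SMARTS (default:
the fused bicyclic core pattern of the reference chemotype); the
docking gate (score ≤ −9.0 kcal/mol, "better" meaning more negative, at
least two key-residue polar contacts with the hinge residue Cys133
requisite); scaffold grouping plus Butina at distance 0.1; best member
per cluster; and a final ranking by docking score then ligand
efficiency, capped at 2300. Ligand efficiency here is docking score
divided by molecular weight — the case study's definition, kept verbatim
even though it differs from the conventional per-heavy-atom form. All
thresholds live in `triage_config()` and every stage only removes
records; docking scores and interaction flags are consumed from
external tools, never computed here.

## Synthetic fixtures, and what passing tests show

`toy_corpus()` assembles molecules from feature-tagged building blocks
(amines, hydroxyls, acids, amides, phenyl/pyridyl rings, nitriles)
joined by alkyl linkers of 1–6 carbons, so pairwise feature distances
sweep both bins of the 2-bin scheme. Its defaults (200 molecules,
seed 7) are the conditions of the conditioning-recovery experiment:
train a 2-layer conditional decoder and an unconditional twin on the
same corpus, verify that greedy decoding under a training molecule's
fingerprint reproduces that molecule, and that across 20 sampling seeds
the conditioned samples' mean pharmacophoric similarity to the
conditioning molecule exceeds the unconditional baseline's by at least
0.1.

The generator emulates controllable pharmacophore content, not drug
space: toy molecules are small, acyclic-linker-dominated, with limited
ring diversity, no stereochemistry, no charged species and none of the
long-range (≥ 8 bond) arrangements that produce null signals in real
ligands. Passing tests therefore establish correctness of the
machinery — encodings, conditioning, metrics, procedures — at desk
scale; they do not establish generative quality on pharmaceutical
corpora. The headline full-scale results that motivate these procedures
(recall percentages near 5%/0.9%/12%, similarity means near 0.6,
178,103 unique molecules from a million samples) require GPU-scale
training on ~1.27M molecules and external databases; they are recorded
in `benchmark_reference()` with `desk_reproducible = FALSE` and are
never asserted by the suite.

## Numerical choices and degenerate inputs

* Softmax rows are normalised in double precision; tests assert row
  sums within 1e-5 and RoPE isometry/shift invariance within 1e-5.
* Layer norm uses ε = 1e-5; cross-entropy clamps probabilities at
  1e-12.
* Feature-less molecules give all-zero fingerprints; the ErG-style
  similarity of two empty fingerprints is defined as 1 (identical
  featureless molecules), and 0 against a non-empty one.
* Disconnected molecules: cross-component feature distances are
  infinite and fall into no bin.
* Molecules with no eligible bond (all-ring, e.g. benzene) raise an
  explicit no-cut error from `fragment_molecule()`.
* Ties are broken lexicographically by canonical SMILES (triage
  ranking, split ordering) or by item order (Butina centroids), so
  every procedure is deterministic.

## Build-on-OpenBabel design

All standard chemistry — SMILES parsing and canonicalization, SMARTS
matching, molecular properties, circular fingerprints, molecule
editing — is delegated to OpenBabel through ChemmineOB. The package
reaches OpenBabel's bound API for atom-index match lists and rooted
SMILES output, which the high-level wrappers do not expose; the shim
is isolated in one file (`R/ob.R`). OpenBabel's aromaticity and
tautomer perception differ in places from other toolkits, so pinned
SMARTS were written against OpenBabel semantics and the independent
cross-checks in the tests run the same patterns through a second
toolkit on fixture molecules.

## Known limitations

* 2D only: topological pharmacophores cannot separate stereoisomers or
  conformer-dependent feature arrangements.
* The pinned family SMARTS are a pragmatic approximation of the
  ligand-pharmacophore definitions they mirror; absolute feature
  counts on exotic chemotypes will differ from other toolkits.
* The ErG-style similarity is this package's implementation of the
  descriptor class, not a bit-for-bit reproduction of any other
  toolkit's ErG; comparisons should stay within one implementation.
* The decoder is written in plain R matrix algebra for transparency
  and determinism; it is suitable for desk-scale corpora, not for
  million-molecule training.
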
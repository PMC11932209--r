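---
title: "Methods: relational geometric graph networks for RNA inverse design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: relational geometric graph networks for RNA inverse design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribodesign)
```

## Problem

Fixed-backbone RNA design (inverse folding) asks: given the 3D backbone of
an RNA — possibly observed in several conformations, as for a riboswitch —
which sequences are compatible with that geometry? `ribodesign` implements
a complete desk-scale pipeline for this problem: structure parsing, typed
graph construction, geometric featurization, a relational
geometric-vector-perceptron (GVP) message-passing encoder with
multi-conformation pooling, one-shot and autoregressive decoders, sampling,
evaluation metrics, cluster-aware data splitting, and deterministic
synthetic fixtures. Everything runs offline on a single CPU; the numerical
core (including reverse-mode differentiation) is written in base R.

## Structure representation

Each nucleotide is represented by three backbone atoms: the phosphate P,
the ribose C4' (which defines the node coordinate), and the glycosidic
nitrogen (N1 for pyrimidines, N9 for purines). `parse_structure()` reads
one chain from PDB or mmCIF text, keeping the first model, resolving
alternate locations to the highest-occupancy conformer, mapping modified
residues to the masked letter `N`, and flagging missing atoms per position.
Base-pair annotations (canonical and non-canonical) enter through
`read_basepairs()`, either as a plain two-column TSV of 1-based positions
or as the `pairs` block of DSSR-style JSON with Leontis–Westhof tags.
Several structures of one sequence form a `conformer_group()`.

## Typed graph

`build_graph()` attaches three mutually exclusive directed edge sets:

* **primary** — both directions of every backbone bond, `2(L-1)` edges;
* **secondary** — both directions of every annotated base pair, `2|BP|`;
* **spatial** — long-range proximity edges between *unpaired* nucleotides.

Spatial edges are found by clustering the C4' coordinates of unpaired
positions with DBSCAN (`eps` 20 Å, `min_samples` 5; implemented in-package
because the installed R stack ships no DBSCAN). Candidate pairs must lie in
one density cluster, be at least 500 nt apart in sequence, and have spatial
distance in [2, 40) Å. If the directed count would exceed `4L`, undirected
pairs are down-sampled uniformly under a fixed seed. Because no candidate
can exist for chains shorter than the 500 nt separation horizon, spatial
construction is skipped outright for `L < 500`.

## Featurization

Node scalars are the sines and cosines of three bond/trace angles and three
dihedrals around each position, followed by three distances
(|P−C4'|, |C4'−N|, |C4'−C4'(next)|) — 15 values; node vectors are four unit
displacement vectors anchored at C4'. Terms referencing a missing atom or
running past a terminus are zero-filled. Edge features are identical for
all three edge types: 16 Gaussian radial basis functions of the C4'–C4'
distance on [0, 40] Å plus the unit displacement vector. No positional
encodings are used anywhere, which keeps the representation usable across
chain lengths.

All scalar features are functions of distances and relative angles, so they
are invariant under rigid motions; the vector features rotate with the
input. Proper dihedral angles are signed, so mirror reflection of a
structure flips their sign — chirality is deliberately visible to the
model, as RNA is chiral.

## Relational GVP encoder

Vector features use a stacked `3n x channels` layout (rows `3i-2..3i` hold
node *i*'s xyz), so channel mixing is ordinary matrix multiplication and a
rotation acts block-wise on rows. A GVP maps scalar/vector inputs to
scalar/vector outputs: vectors enter the scalar pathway only through their
channel norms, and vector outputs are linear maps of input vectors scaled
by sigmoid gates computed from the scalars. This makes every layer exactly
O(3)-equivariant: scalars (and the final probabilities) are invariant,
vectors co-rotate — properties the test suite checks numerically.

One relational layer computes, per edge type, messages with a two-GVP
network applied to concatenated sender/receiver/edge features, sums them
per receiver, pools the per-type sums with learned scalar weights
(initialised at 1), and applies a residual update with layer normalisation
on scalars plus a feed-forward GVP. With a single populated edge type and
unit weight this reduces bit-for-bit to a plain (non-relational) GVP-GNN
layer, which the tests verify against an independent per-edge oracle.

## Multi-conformation pooling and decoding

For a conformer group of K structures the encoder runs on each structure
with shared parameters. The **one-shot** (non-autoregressive) decoder
averages the K final node embeddings, applies two GVPs and a linear 4-way
head, and emits all positions independently. The **autoregressive** decoder
conditions position *i* on the letters 5' of *i* through an exponentially
decaying causal context (decay 0.9 over an 8-dimensional previous-letter
embedding); its per-structure probability outputs are averaged, i.e. the
predictive distribution is the mean of the per-conformation predictive
distributions. Both pooling operations are means, so duplicating a
conformation K times collapses to the single-structure output and member
order is irrelevant — both properties are tested exactly.

Training minimises the masked cross-entropy of the native letters (`N`
masked out; teacher forcing for the autoregressive decoder) with Adam, one
step per conformer group per epoch. Gradients come from a small tape-based
reverse-mode automatic differentiation layer written for this package; its
correctness is established against central finite differences (worst
relative error observed in testing: order 1e-5 at step 1e-5, i.e. at the
finite-difference noise floor).

## Metrics

* `seq_perplexity()` — exponentiated mean negative log-likelihood of the
  native letters (uniform output gives exactly 4).
* `seq_accuracy()` — argmax match rate with a fixed A<C<G<U tie-break.
* `seq_recovery()` — mean per-position identity of sampled sequences.
* `sc_score()` — self-consistency: a secondary-structure predictor is run
  on each sampled sequence and its pair set compared to the template's by
  Matthews correlation over all unordered position pairs.
  `predict_pairs_nussinov()` (base-pair maximisation, minimum loop 3) is
  the built-in offline stand-in predictor; `predictor_rnafold()` adapts
  the ViennaRNA command-line tool when present. The stand-in is *not* a
  thermodynamic model, so absolute sc values are not comparable to
  published ones.

## Data splits

`cluster_by_identity()` implements greedy CD-HIT-style clustering at 90%
identity (global alignment via Biostrings); `read_clstr()` and
`read_cluster_tsv()` load labels computed by external tools instead.
`assign_splits()` assigns whole clusters to train/validation/test, ranking
clusters by mean intra-group superposition RMSD (`intra_group_rmsd()`,
Kabsch fit on C4' atoms) so that structurally flexible groups — the hard,
riboswitch-like cases — fill the held-out sets.

## Synthetic fixtures and why they are learnable

`make_helix()`, `make_hairpin()`, `make_two_state()` and `make_long_coil()`
generate deterministic idealised structures (A-form rise 2.8 Å, twist
32.7°, radius 9.4 Å). One deliberate design choice makes desk-scale
training demonstrations possible: the glycosidic nitrogen is placed at a
**base-dependent** distance from the C4' trace (A 3.0, C 3.4, G 3.8,
U 4.2 Å). Real RNA encodes sequence in geometry far more subtly; this
exaggerated, noise-free signal lets a small model overfit a handful of
fixtures in minutes on one CPU, which is what the training-related
acceptance checks need. Conclusions about real-data recovery cannot be
drawn from these fixtures.

The two-state fixture is a toy riboswitch: regions r1–linker–r2–linker–r3
with r3 = r1 and r2 their reverse complement; conformation one pairs r1:r2,
conformation two pairs r2:r3. Both members share one sequence but have
different coordinates and base-pair sets, exercising the K>1 pooling path.

## Scope and limitations

* Problem sizes are desk-scale by design: tested models use 2 layers and
  node widths of 12–32 scalar channels; published-scale training data,
  model widths, and benchmark numbers are out of scope.
* The autodiff layer is dense-matrix only and single-threaded.
* The built-in secondary-structure predictor maximises pair counts; it is
  a stand-in, not a free-energy model.
* Worked examples on real structure-database accessions require a one-time
  network fetch (`fetch_pdb()`); all other functionality is offline.

## Reproducing the numbers

```{r acceptance, eval = FALSE}
# from the package source directory, against the installed package:
#   Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The script regenerates every headline quantity (graph counts, equivariance
residuals, pooling residuals, metric oracles, overfit training accuracy,
design recovery and self-consistency) from synthetic fixtures and writes
them as JSON; see the README for a sample of actual output values.
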
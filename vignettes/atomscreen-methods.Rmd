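---
title: "Atom-level contrastive embeddings for virtual screening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atom-level contrastive embeddings for virtual screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The idea

Docking-based virtual screening spends seconds per compound; that rules out
billion-scale libraries. `atomscreen` follows a representation-learning
route instead: two graph neural networks (one for protein pockets, one for
small molecules) map every heavy atom to a point in a shared d-dimensional
embedding space, trained so that a protein atom and a ligand atom that sit
within 4 Å of one another in a resolved complex land near one another in
embedding space. Screening then reduces to nearest-neighbour search: a
pocket "asks" a compound library which atoms resemble the partners it has
been seen binding, and per-compound evidence is accumulated by summing
similarities.

The package implements the full loop at desk scale — graph construction,
twin encoders, contrastive training with typed negatives, similarity
calibration, sharded nearest-neighbour scoring, enrichment-factor
evaluation, and inverted (ligand→pocket, pocket→pocket) searches — plus a
synthetic complex generator with planted atomic complementarity that makes
every stage testable without external data.

# Graph construction

**Compounds.** Heavy atoms are nodes with two one-hot features: the atomic
species over a fixed vocabulary (C, N, O, S, P, F, Cl, Br, I, B, other) and
the attached-hydrogen count, clamped at 4. Edges join every pair of atoms
within three covalent bonds; the only edge feature is the one-hot hop class
(1, 2 or 3). Bond order and aromaticity are deliberately not featurised;
hop counting runs on the covalent bond list regardless of order. Atom order
follows the parser's canonical order, so construction is deterministic.
Training-complex ligands carry 3D coordinates, but the encoder never sees
them — coordinates only define interacting pairs.

**Pockets.** Given a protein structure and a pocket specification (a bound
ligand, or a centroid), the surface set S is every protein heavy atom
within the 4 Å cutoff of the ligand (or within a shell of the centroid;
shell radius default 8 Å). Edges come in three tiers: each surface atom
connects to its `x` nearest surface atoms (E1), to its `y` nearest protein
atoms of any kind (E2), and each of those tier-2 neighbours connects to its
`z` nearest protein atoms (E3). The graph is the union E1 ∪ E2 ∪ E3; the
node set is every atom touched by an edge; each edge stores its Euclidean
length in Å. Defaults `x = 8, y = 4, z = 4` balance long-range
surface-to-surface communication against locality; ties in the kNN lists
break by ascending atom index so the graph is reproducible. For randomized
pocket centering during training the centroid is displaced uniformly within
a ball (a declared stand-in for an unpublished procedure; radius is a
tunable).

# Encoders

Both encoders share one residual architecture. Node one-hots are lifted
linearly to the working width, then `n_blocks` blocks apply two multi-head
GATv2-style attention operations, a SiLU nonlinearity, and *append*
(concatenate, DenseNet-style) the result to the block input; dropout
(p = 0.1) follows during training only. No normalization layers are used. A
final linear layer projects to `embed_dim`. Concatenation was chosen over
addition because it is well-defined without width constraints and keeps the
lifted input visible to the output layer.

The compound encoder feeds the hop one-hot into each attention score. The
pocket encoder's sole edge feature is a learned nonnegative scalar: the
edge length passes through a 1 → `edge_mlp_dim` linear layer with ReLU and
a second linear layer with ReLU, and the resulting scalar multiplies each
attention-weighted message. Because only pairwise distances enter, pocket
embeddings are invariant to rigid motions of the structure; both encoders
are permutation-equivariant (both properties are tested). The output bias
of the edge-weight map is initialised at 1 rather than 0: a ReLU scalar
that starts at or below zero silences every pocket message *and* its own
gradient, so a zero start can leave the pocket encoder permanently dead —
we observed exactly this failure before adopting the positive
initialisation.

There is no automatic differentiation framework in this stack, so the
package carries a small reverse-mode tape (matrix-valued nodes; matmul,
broadcast add, gather/scatter, per-group softmax, the activations, dropout
and pairwise distance). Its gradients are validated against central
differences in the test suite.

# Training

Each training batch holds `b = 8` complexes. Every interacting pair
(pocket atom within 4 Å of a ligand atom, closed threshold) contributes an
anchor–positive pair, with the anchor role — pocket atom or ligand atom —
alternating between batches. Three negatives are drawn per positive:

* **random** — an interacting atom from a different complex in the batch;
  using *interacting* atoms prevents the model from keying on
  "non-interactingness";
* **self** — an atom of the positive molecule among the 25 % most distant
  (in complex 3D coordinates, ceiling(0.25 n), excluding the positive) from
  the anchor; this blocks representation collapse within a molecule.
  Geometric rather than embedding distance is used because the rule's
  purpose is spatial: atoms far from the contact belong to a different
  chemical neighbourhood;
* **hard** — an atom close to the anchor in embedding space that belongs to
  a molecule *not active* against the anchor's pocket, drawn uniformly from
  the candidates within a distance percentile that shrinks linearly from
  the 99th at epoch 0 to the 5th at epoch 50 (constant afterwards). An
  empty pool falls back to a random negative with a logged count.

The loss is the *positive-margin* hinge
\[
L = \operatorname{mean}\big[\max(0, D^+ - m) + \max(0, n - D^-)\big],
\]
with absolute margins `m = 1` (positives inside) and `n = 2` (negatives
outside); it is zero exactly when every positive sits within m and every
negative beyond n. The classical triplet loss
\(\max(0, D^+ - D^- + m)\) is provided as a reference: any configuration
with zero positive-margin loss and \(n - m \ge\) margin also zeroes the
classical loss, but not conversely — the classical loss tolerates pairs
that are merely *relatively* ordered while drifting far from the anchor,
which defeats absolute-distance retrieval. Optimisation is Adam with a
fixed learning rate (default 3 × 10⁻³; 10⁻³ converged too slowly within
desk-scale epoch budgets, judged on the training loss and on the separation
between interacting and non-interacting embedding distances). Losses are
averaged over triplets; per-triplet reduction and the 3D self-negative rule
were genuinely open choices and are recorded here as package decisions.

Because the objective is non-convex, occasional runs settle in a
poorly-separated basin that is recognisable *from the training loss alone*
(elevated final loss). `train_encoders(restarts = R)` therefore runs R
independent, seed-derived initialisations and keeps the run with the lowest
mean loss over its final two epochs. Selection never looks at screening
performance.

# Scoring and calibration

All compound-atom embeddings go into an exact-search index, optionally
sharded at fixed capacity (search is merged by summation, so with a
sufficiently large k the shard partition provably cannot change a score; a
property test covers this). For a query pocket, each surface-atom embedding
retrieves its k nearest compound atoms per shard. Distances become
similarities through a calibration fixed once per model:
D_max is the largest distance in a large sample of *non-interacting*
(pocket atom, ligand atom) pairs, raw similarity is s′ = D_max − dist, and
the noise threshold t is the 99th percentile of the non-interacting s′
distribution, so that 99 % of random atom matches score zero after the
clamp s = max(0, s′ − t). The per-compound score is the sum of s over all
retrieved pairs belonging to that compound; compounds never retrieved score
0. Inverted searches swap the roles — the database holds pocket atoms,
grouped by pocket id — and targets whose every retrieved pair clamps to
zero are reported unranked.

A consequence worth stating: the scoring window D_max − t is the 1st
percentile of the non-interacting *distance* distribution. When
non-interacting pairs frequently involve chemically compatible atoms (as in
a small synthetic type alphabet), that window sits *below* the positive
margin m, so only the closest tail of genuine matches contributes to
scores. Screening still works because actives accumulate more
tail events than decoys, but scores are sparse; this is intrinsic to the
99th-percentile design, not an implementation artifact.

# The synthetic world

The generator plants recoverable complementarity: T latent atom types with
a fixed compatibility permutation; each complex restricts its ligand to a
subset of the types (half of T by default); each ligand atom is placed
2.5–4 Å from a pocket partner atom of the compatible type on a
hemispherical shell (radius 6 Å), with filler shell atoms kept > 4 Å away;
latent types surface as designated elements, corrupted with probability ε
(feature noise), so the real parsers, featurisers and encoders run
unmodified. Ligand bond graphs are random trees plus occasional cycles, so
hop edges are nontrivial; hydrogen counts derive from degree. Screening
libraries pair actives (types drawn from the pocket's compatible subset)
with decoys (types drawn uniformly); compound ids are assigned by a random
permutation so that deterministic tie-breaking in the ranking can never
correlate with the label. Library compounds carry no coordinates, as in
real inference.

Because two complexes with overlapping type subsets are mutually active by
construction, the training-side activity map (`synthetic_active_map()`)
marks them as such; hard negatives are then drawn only from genuinely
incompatible molecules. Without this map the hard-negative schedule
actively unlearns the planted signal — the nearest embeddings to an anchor
are precisely the compatible-type atoms of other complexes.

What the world does *not* emulate: real chemistry's diversity of local
environments. With T = 4 types, atoms that the loss must separate are often
feature-identical, so the encoders lean on graph context, and generalisation
from 60 complexes is noisier than PDBBind-scale training. Passing the
end-to-end recovery test therefore demonstrates that the machinery learns
and transfers a planted signal under noise — not that it reproduces
benchmark enrichment on real proteins. For the recovery experiment we use a
deliberately small encoder (one block, 2 heads × 4 features, d = 16):
capacity matched to the data regime, since larger encoders memorise the 60
training complexes through molecule-level context and transfer less of the
composition signal.

# Numerical choices and degenerate inputs

* Interaction threshold closed at 4.0 Å; distances in Å throughout; atom
  indices are 0-based nowhere — all user-facing tables are 1-based.
* kNN ties break by ascending atom index; ranking ties break by ascending
  compound id; both documented so outputs are byte-stable under a seed.
* The pairwise-distance node adds 10⁻¹² under the square root to keep the
  derivative finite at coincident points.
* `calibrate()` rejects all-identical samples (D_max = 0) but accepts
  all-equal distances (every similarity 0) — a degenerate but valid
  calibration.
* Isolated compound atoms (methane) receive no messages; their embedding
  comes from the lifted node features alone.
* Quantiles use R's default type-7 interpolation.
* Single-molecule pockets and empty hard-negative pools have explicit
  fallbacks (error and random-negative substitution respectively).

# Problem sizes

The bundled tests train on complexes of ~40 protein atoms and 8–12 ligand
heavy atoms, 60 complexes for the recovery experiment (30 epochs, batch 8,
3 restarts, 3 seeds) and 4–12 complexes for smoke tests; screens use 200
compounds (20 actives / 180 decoys). These sizes were chosen so the entire
suite runs in minutes on one CPU while every mechanism — including the
hard-negative schedule crossing its lock-in epoch in longer runs — is
exercised.

# Known limitations

* No conformer generation, protonation enumeration or stereochemistry
  features; aromatic perception is delegated to the chemistry parser.
* The randomized-centering shell rule is a declared stand-in for an
  unpublished procedure.
* Exact search only by default; approximate backends are out of scope.
* Desk-scale training cannot and does not reproduce published benchmark
  enrichment factors; the acceptance machinery checks mechanism-level
  properties and in-text arithmetic instead.
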
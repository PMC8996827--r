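---
title: "Differential reaction fingerprints: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential reaction fingerprints: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drfp)
```

## The encoding

A reaction SMILES `REACTANTS>REAGENTS>PRODUCTS` is turned into a binary
vector in four steps:

1. **Merge.** Reagents are appended to the reactants. The fingerprint
   deliberately does not distinguish the two: which species is "only" a
   reagent is often ambiguous in real corpora, and any weighting scheme that
   depends on the distinction inherits that ambiguity.
2. **Shingle.** For every heavy atom of every molecule and every radius
   `0..r`, the circular substructure (all bonds within the given bond
   radius of the root, plus their atoms) is rendered as a canonical fragment
   SMILES; radius 0 is the bare atom. Every ring of the SSSR (smallest set
   of smallest rings; ring atoms and ring bonds only, no exocyclic
   substituents) is rendered as well. The fragments of one side form a set:
   multiplicity is erased, by construction.
3. **Difference.** The symmetric difference of the reactant-side and
   product-side fragment sets keeps exactly the substructures that changed.
   Anything untouched by the reaction cancels.
4. **Hash and fold.** Each surviving fragment string is hashed to an
   unsigned 32-bit integer, and bit `i` of the `d`-dimensional output is set
   iff some hash is congruent to `i` modulo `d`. Each set bit records which
   fragments produced it, so every feature of a downstream model maps back
   to substructures.

```{r example}
fp <- drfp_encode("CCO.CC(=O)O>[H+]>CCOC(=O)C", drfp_config(n_bits = 256))
summary(fp)
```

## Tunable parameters

* `radius` (default **3**, dimensionless bond count). Radii 2-4 are the
  useful range: 2 generalises better at small dimension or with little
  training data, 3 is the best all-rounder once `d` is a few hundred or
  more, and 4 adds little but collisions.
* `n_bits` / `d` (default **2048**). Powers of two from 16 to 2048 are all
  sensible; accuracy of downstream models typically saturates by a few
  hundred bits. Folding can only merge bits, so if `d1 | d2` the popcount at
  `d2` is at least that at `d1`.
* `include_rings` (default `TRUE`). Whole-ring fragments capture ring
  formation/cleavage even when every local atom environment is unchanged.

## Numerical and design choices

**Chemistry backend and canonical order.** Molecules are validated and
canonicalized through Open Babel (via ChemmineOB) on entry; the molecular
graph used for extraction is parsed from the backend's canonical SMILES.
Because every input rendering of a molecule maps to one canonical atom
order, the shingling is invariant to how the input SMILES was written — an
invariance the test suite checks with a randomized SMILES writer.

**Fragment rendering.** Fragments are rendered by an internal canonical
writer: atom ranks from iterative partition refinement over
(element, aromaticity, charge, isotope, hydrogen count, degree) with
deterministic symmetry tie-breaking, then a depth-first traversal that
visits neighbours in rank order. This makes the same substructure render to
the same string no matter which molecule it was extracted from — necessary
for cross-side cancellation. Aromaticity is inherited from the parent
perception (partial aromatic fragments such as `ccc` are legal fragment
strings and are kept aromatic rather than kekulized, because a kekulized
rendering would make chemically identical aromatic environments on the two
sides render differently and fail to cancel). Tetrahedral marks are kept
only when all neighbours of the stereocentre are inside the fragment, with
parity recomputed against the written neighbour order; cis/trans marks are
kept only while the defining marked bonds on both ends of the double bond
remain inside the fragment.

**SSSR determinism.** The ring basis is a minimum cycle basis computed from
shortest cycles through each bond, kept greedily under GF(2) independence
with a fixed candidate ordering (size, then lexicographic bond key). For
molecules where the SSSR is ambiguous (fused cage systems) the choice is
deterministic rather than canonical across all isomorphic renderings; the
canonicalization of the parent molecule makes it stable for any given
molecule.

**Hashing.** FNV-1a (32 bit) over the UTF-8 bytes of the fragment string:
process- and platform-independent (language-default string hashes are often
process-salted), cheap, and with collision probability far below any
desk-scale fragment count. The hash sits behind a single internal function,
so an alternative 32-bit hash is a one-line swap. 32-bit collisions ahead
of folding are not resolved; the colliding fragments simply share a
provenance entry, exactly as they share a bit after folding.

**Set semantics.** `A + A -> B` and `A -> B` encode identically, and a
fragment present on both sides in different copy numbers cancels. This is a
property of the set formulation, documented rather than patched.

**Degenerate inputs.** A reaction whose two sides contain the same molecule
set encodes to the zero vector; so does any molecule with no heavy atoms
(e.g. `[H+]`) on its own. Folding to any `d >= 1` is accepted; empty
shinglings fold to the zero vector of length `d`.

## Downstream harnesses

* **5-NN classification.** Exact search, Hamming distance (on binary
  vectors this ranks neighbours identically to squared Euclidean, so the
  metric choice is benign). Vote ties break by smaller summed distance,
  then first-seen order; distance ties break by training-row index — fully
  deterministic.
* **MLP classification.** One dense hidden layer (default width 1664) with
  tanh, softmax output, sparse categorical cross-entropy, Adam, 10 epochs,
  minibatch 64. The Adam learning rate is the optimizer's conventional
  default (0.001). Implemented in base R matrix algebra; all randomness
  (Glorot initialization, epoch shuffling) derives from the seed.
* **Gradient-boosting yield regression** (xgboost): `n_estimators` 999999,
  `learning_rate` 0.01, `max_depth` 15, `min_child_weight` 8,
  `colsample_bytree` 0.2125, `subsample` 1. A seeded random 10% of the
  training rows is held out, and boosting stops after 20 rounds without
  validation improvement; predictions use the best validation round. The
  parameters are fixed once and reused for every data set — the point of
  the protocol is that no per-task tuning is needed.

## What the synthetic generator emulates — and what it does not

Real benchmark corpora (template-classified patent reactions,
high-throughput yield panels) require large downloads, so the package ships
a generator instead. `generate_template_reactions()` instantiates up to six
reaction families (esterification, amide coupling, N-alkylation,
Suzuki-type coupling, ether formation, reductive amination) by splicing
substituents into string templates, sampling substituent pairs without
replacement (instances within a class are distinct) and validating every
instance through the strict parser. `generate_synthetic_yields()` draws an
additive structure-activity rule on fragments of the symmetric-difference
set — the set the fingerprint encodes; effects on substructures that cancel
between the two sides would be invisible to any model built on the
fingerprint, so they are excluded by construction. Defaults: base yield 50%,
eight effect fragments with magnitudes uniform in 10-25 percentage points,
Gaussian noise with SD 5, clipped to [0, 100]. The magnitudes are chosen so
the structural signal clearly dominates the noise (signal SD roughly 15-20
against noise SD 5); a generator whose noise ceiling sits at the evaluation
threshold would test nothing.

Passing on these fixtures demonstrates that the pipeline is wired
correctly, that the encoding separates structurally distinct reaction
families, and that the regressor can read an additive signal out of the
bits. It does **not** demonstrate performance on real reaction corpora:
the synthetic classes are far better separated than patent-derived template
classes, the yield rule is genuinely additive where real reactivity is not,
and the molecule diversity is tiny.

## Problem sizes

The test suite and the acceptance script use 5 classes x 100 reactions
(70/30 split) for the harnesses, 100 molecules/reactions per encoder
invariant, brute-force oracles on an exhaustive panel of <= 8-heavy-atom
molecules, and 50 random confusion matrices for the metric cross-checks.
These sizes give stable statistics while keeping a full run in the minutes
range on one CPU; they are generator parameters, not caps, and scale up by
argument.

## Known limitations

* A reaction and its reverse encode identically (the symmetric difference
  is symmetric). In practice direction is implied by which side the
  reagents sit on; a directional variant would need an ordered difference.
* Stoichiometry is invisible (set semantics).
* The "subtraction" style of combining side fingerprints used by some
  atom-pair baselines is not implemented; its construction is not specified
  precisely enough to reproduce.
* Fragment strings are untagged by radius: an environment identical to a
  smaller-radius one contributes a single set element.
* Open Babel's aromaticity/valence model decides which inputs are valid;
  exotic organometallics may be rejected or normalized differently than by
  other toolkits.
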
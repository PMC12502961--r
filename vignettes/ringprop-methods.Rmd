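---
title: "Predicting electronic properties of cyclic molecules: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting electronic properties of cyclic molecules: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Ring systems dominate bioactive compounds and organic electronic materials,
and their electronic structure — the HOMO–LUMO gap, vertical ionization
potential (IP) and electron affinity (EA), and the aqueous redox potentials
E~ox~ and E~red~ — governs reactivity, charge transport and redox behavior.
Quantum-chemical labels for large ring libraries are expensive, so a common
strategy is to train a graph neural network on a labeled subset and predict
the rest. `ringprop` implements that full loop at desk scale for mono-, bi-
and tricyclic molecules (ring sizes 3–9, up to 24 heavy atoms): a seeded
generator of valid ring systems, a physics-structured label oracle, graph
featurization, a multi-task edge-aware graph attention regressor trained by
backpropagation, thermodynamic-cycle electrochemistry, and the downstream
analyses (learning curves, ring-stratified errors, worst-error novelty
analysis, PCA of the learned embeddings).

## The synthetic data generator

Real ring-system libraries are mined from vendor catalogs; that mining is out
of scope here, so test molecules are built by *template assembly*: ring
skeletons are sampled (size uniform on 3–9; aromatic with probability
`1 - saturation_rate`, default 0.55, for sizes that admit neutral aromatics),
joined by a sampled connection type — fused (shared edge), bridged (two
non-adjacent shared atoms), spiro (one shared atom) or linked (a single
biaryl-type bond) — and then decorated with heteroatoms under valence
checking. The default ring-count mixture 0.076/0.396/0.528 for 1/2/3 rings
reproduces the composition of a 201,546-molecule ring-system collection
(15,347 / 79,777 / 106,422). The default element palette is C/N/O/S; an
extended palette adds B, F, Si, P, Se and I, with the monovalent halogens
placed as exocyclic substituents.

Structural rules worth stating explicitly:

* **Aromatic templates are 5- and 6-membered only.** Three- and
  four-membered aromatics are anti-aromatic or unstable, and no neutral
  4n+2 aromatic exists for sizes 7–9 with this palette, so those sizes are
  generated aliphatic. Every aromatic 5-ring receives exactly one
  two-electron donor (furan/thiophene/pyrrole/selenophene type) so the ring
  is a genuine 6-π-electron system.
* **Junction atoms stay carbon**, spiro and bridged junctions are sp³ (so
  those connections force aliphatic rings), and adjacent heteroatom pairs
  are never generated.
* **Uniqueness and validity** are by canonical SMILES (Open Babel):
  every emitted string re-parses, and only strings whose canonicalization
  is idempotent are kept, which makes generation deterministic and
  byte-stable given the seed.

What the generator does *not* emulate: substituent chemistry beyond
halogens (no carbonyls, amides, chains), charged species, stereochemistry,
synthetic accessibility, and the long tail of rare ring topologies in mined
libraries. Tests passing on these fixtures therefore demonstrate that the
pipeline learns graph–property relationships of the planted physics; they do
not certify accuracy on mined chemistry with DFT labels.

## The Hückel label oracle

Labels come from a tight-binding π-electron model rather than DFT. The
conjugated subgraph (aromatic atoms plus atoms in double/triple bonds,
connected also through conjugating single bonds such as the biaryl link)
is extracted and its Hamiltonian assembled as `H = αI + βC`, with α = −6.6 eV
(Coulomb integral), β = −2.7 eV (resonance integral), diagonal corrections
`h_X` (ε~X~ = α + h~X~β) and bond factors `k_XY` in the Streitwieser
convention:

| context | h | | bond | k |
|---|---|---|---|---|
| C | 0.0 | | C–C | 1.0 |
| N pyridine-type | 0.5 | | C–N | 0.8 |
| N pyrrole-type | 1.5 | | C–O | 0.8 |
| O carbonyl | 1.0 | | C–S | 0.7 |
| O furan-type | 2.0 | | C–Se | 0.6 |
| S | 0.4 / 1.3 | | C–P | 0.7 |
| Se | 0.3 / 1.1 | | B–C | 0.7 |
| P | 0.75 / 1.5 | | C–Si | 0.75 |
| B | −1.0 | | other | 0.7 |

(the two S/Se/P values are the one-electron and two-electron-donor
contexts). Conjugating single bonds use the full k of the element pair —
classical Hückel treats the diene and biaryl link at k = 1, which gives the
textbook butadiene spectrum α ± 1.618β, α ± 0.618β. α and β were chosen so
benzene's Koopmans IP, −ε~HOMO~ = −(α+β) = 9.3 eV, is realistic, which also
puts the synthetic gap/IP/EA/E~ox~/E~red~ ranges in qualitative overlap with
DFT-labeled ring libraries. Electrons fill the ascending spectrum in pairs
(disconnected π systems are block-diagonal, so the union spectrum is filled
globally); HOMO is orbital n/2, degeneracies are resolved by ascending index
(the gap is unaffected), and Koopmans gives IP = −ε~HOMO~, EA = −ε~LUMO~,
gap = ε~LUMO~ − ε~HOMO~.

Molecules with no π system use a documented group-contribution model:
gap = 11.0 eV plus per-heteroatom corrections (N −0.25, O −0.15, S −0.6,
Si −0.5, P −0.45, Se −0.7, B −0.35, F +0.2, I −0.9, floored at 0.5 eV);
IP = 11.0 − 0.12·n~heavy~ minus per-element terms (N 0.5, O 0.3, S 0.9,
Si 0.6, P 0.7, Se 1.0, B 0.2, F −0.4, I 0.8); and EA = IP − gap so the
Koopmans identity holds in both branches.

Redox labels are *planted linear maps*: E~ox~ = 0.92·IP − 4.9 + ε and
E~red~ = −0.95·EA + 1.1 + ε with ε ~ N(0, 0.15 V). With zero noise the maps
are exactly linear (R² = 1); with noise the population R² is
slope²·Var/(slope²·Var + σ²), which the tests verify. This gives the
pipeline a ground-truth linear structure to recover, mirroring the strong
IP↔E~ox~ and EA↔E~red~ correlations seen in DFT-labeled data. Note the
planted E~red~ map is a synthetic convention (its negative slope is *not*
the thermodynamic-cycle sign); the electrochemistry module below uses the
standard convention.

## Graph featurization

Atoms are nodes, bonds are edges (two directed edges with shared features).
The published feature tables for this kind of model are frequently
supplementary material one does not have; the scheme here is a conventional
reconstruction, versioned (`rp-node-v1/edge-v1`) behind `feature_scheme()`
so it can be swapped without touching the model. Node blocks: element
one-hot over the palette plus an unknown slot; degree one-hot 0–5 (clamped);
formal charge one-hot {−1, 0, +1}; aromatic flag; in-ring flag; SSSR
ring-size flags 3–9; hybridization one-hot {sp, sp², sp³, other};
attached-H one-hot 0–4. Edge blocks: bond order one-hot {single, double,
triple, aromatic}; conjugated flag; in-ring flag. Molecules are
canonicalized before featurization, so any SMILES spelling of a molecule
yields the identical graph; hydrogens stay implicit. Ring membership comes
from a minimum-cycle-basis (SSSR) computation; ring counting uses the cycle
rank (bonds − atoms + components), which coincides with SSSR size for these
graphs — for bridged polycycles this is a deliberate, documented choice.

## The regressor

Three edge-aware graph attention layers, global mean pooling, three fully
connected layers ending in the five outputs. The attention mechanism is the
minimal edge-augmented variant of standard graph attention: for the directed
edge j→i with transformed features `Wh` and edge transform `W_e e_ij`,

```
s_ij = LeakyReLU(a_dst · W h_i + a_src · W h_j + a_e · W_e e_ij),
α_ij = softmax_j(s_ij),     h'_i = ELU( Σ_j α_ij W h_j ),
```

with a self-loop (zero edge-feature vector) added inside the layer so every
node attends to itself even in edgeless graphs. Hidden layers concatenate
the heads (default 4 heads × 32 = 128); the final message layer averages
full-width heads, conventional practice for output layers. The softmax is
computed with per-destination max subtraction for numerical stability.
Initialization is seeded uniform Glorot. Gradients are derived by hand
(reverse accumulation through the attention softmax, aggregation, pooling
and dense head) and all graph operations are expressed as matrix products
and segment reductions over a block-diagonal batch graph, so training runs
entirely in base R at useful speed.

Hidden sizes, head counts and activations for such models are typically
unpublished; the defaults (128 hidden, 4 heads, LeakyReLU slope 0.2, ELU
updates, head widths 64/32/5) are documented, configurable choices.

## Training protocol

The loss is the mean squared error averaged over the five z-scored targets
(z-scoring by training-set mean/sd gives each task equal weight — the
simplest defensible multi-task weighting); metrics are always reported back
in eV/V. The optimizer is Adam (lr 10⁻³, batch 64) with early stopping on
validation loss (patience 10) and the best-epoch parameters returned; runs
are pure functions of (data, config, seeds). The package's reference
problem size is 3,000 molecules split 2400/300/300 — a deliberate
desk-scale analog of the 30,000/3,000/3,000 protocol used with DFT labels —
with a 40-epoch budget, where the default model reaches test R² ≈ 0.99 for
the gap against noise-free oracle labels; learning-curve runs over nested
subsets {250, 500, 1000, 2000} use a 25-epoch budget, which is ample for
the trend they measure. Shuffled-label controls give |R²| < 0.2,
confirming the signal is structural rather than leakage.

## Electrochemistry

With per-molecule energies in eV, the thermodynamic cycle gives
IP = E(+1) − E(0) and EA = E(0) − E(−1) in the gas phase at the neutral
geometry, and E~ox~ = [G~aq~(+1) − G~aq~(0)]/n − E~ref~,
E~red~ = [G~aq~(0) − G~aq~(−1)]/n − E~ref~ with n = 1 and
E~ref~ = 4.28 V (the absolute potential of the standard hydrogen
electrode). Dividing by n maps eV directly to V per electron, avoiding
molar-unit bugs. Under this convention a more stable anion yields a higher
(less negative) E~red~ — i.e. a better electron acceptor. When solvation
shifts cancel (aqueous differences equal gas-phase differences), the
identities E~ox~ = IP − E~ref~ and E~red~ = EA − E~ref~ hold exactly and
are enforced by tests. Hartree input is converted at 27.211386 eV/hartree.

## Embedding-space analysis

Pooled graph embeddings are analyzed by PCA (mean-centering + SVD).
Component signs are fixed by making each component's largest-magnitude
loading positive, so plots and tests are deterministic; explained-variance
ratios are relative to the total variance. Property gradients are the
Pearson correlations of each principal axis with a property; exemplar
molecules (highest, lowest, closest-to-mean per property) break all ties by
molecule id. On trained models the first axis correlates strongly
(|r| ≈ 0.9) with the gap — the embedding organizes chemistry by
conjugation, the same qualitative structure reported for 3D-model
embeddings on DFT-labeled data.

The novelty analysis uses circular (Morgan-style) fingerprints of radius 3:
initial atom invariant (element, degree, charge, H count, in-ring flag),
three rounds of sorted neighborhood rehashing, identifiers folded modulo
2048 bits, compared by Tanimoto similarity |A∩B|/|A∪B| (defined as 1 for
two empty sets). Binary bits and 2048 bits are a documented choice where
the original analysis left counted-vs-binary and the width unstated. The
hashing is deterministic and internally consistent, but bit values are
implementation-specific — only within-package comparisons are meaningful.

## Numerical notes and edge cases

* Hückel eigenvalues come from a dense symmetric eigensolver; fixtures are
  checked against closed-form cycle/path spectra and the alternant-pairing
  theorem (spectrum symmetric about α) at 10⁻⁹ eV.
* Odd π-electron counts (open shells) and fully filled π systems (no LUMO)
  raise errors rather than returning values.
* Square cyclobutadiene has a zero gap from its degenerate nonbonding pair;
  frontier ties are resolved by the ascending-index convention.
* Finite-difference gradient checks use the standard relative error with an
  absolute floor, `|fd − an| / max(10⁻⁶, |fd| + |an|)`, because entries
  whose true gradient is ~10⁻⁷ are dominated by central-difference
  roundoff.
* The generator raises after a bounded number of assembly attempts when a
  configuration cannot yield the requested number of unique molecules.
* Zero-variance target columns are rejected at standardization; empty
  evaluation sets and zero-node graphs are errors, not silent results.

## Known limitations

The oracle is 2D-topological: no conformers, no solvation, no
DFT-quality energetics — its magnitudes only qualitatively overlap real
label distributions. The SMILES dialect covers the generator's output plus
common aromatic/aliphatic organic subsets, not the full grammar
(no stereochemistry, no multi-component strings). Fingerprints do not
reproduce any external toolkit's bits. The attention variant is one
documented reconstruction of "edge features in the attention mechanism";
other variants (e.g. edge features in the message) are plausible and can be
swapped behind the same layer interface.
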
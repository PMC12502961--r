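# ringprop

Electronic-property prediction for cyclic molecules with an edge-aware
graph attention network, in R.

Ring systems are the structural core of most bioactive compounds and
organic electronic materials, and their electronic properties — the
HOMO–LUMO gap, vertical ionization potential (IP) and electron affinity
(EA), and the aqueous redox potentials E<sub>ox</sub> and E<sub>red</sub> —
govern reactivity, charge transport and redox behavior. Computing these
properties quantum-mechanically for whole ring libraries is prohibitive;
the practical route is to train a graph neural network on a labeled subset
and predict the rest. `ringprop` implements that loop end to end for mono-,
bi- and tricyclic molecules (ring sizes 3–9, up to 24 heavy atoms):

* a **seeded generator** of valid cyclic test molecules (fused / bridged /
  spiro / linked ring systems over a configurable element palette), with
  canonical-SMILES deduplication and CSV dataset I/O;
* a **Hückel molecular-orbital label oracle**: the conjugated π system is
  extracted from the 2D graph, its tight-binding Hamiltonian
  H = αI + βC (α = −6.6 eV, β = −2.7 eV, Streitwieser heteroatom
  corrections) is diagonalized, and Koopmans' approximation gives
  gap = ε<sub>LUMO</sub> − ε<sub>HOMO</sub>, IP = −ε<sub>HOMO</sub>,
  EA = −ε<sub>LUMO</sub>; redox labels are planted linear maps
  E<sub>ox</sub> = 0.92·IP − 4.9 + ε, E<sub>red</sub> = −0.95·EA + 1.1 + ε;
* **graph featurization** (atoms = nodes, bonds = directed edge pairs) with
  a versioned one-hot feature scheme;
* a **multi-task edge-aware graph attention regressor**: three attention
  layers scoring each edge j→i as
  LeakyReLU(a<sub>dst</sub>·Wh<sub>i</sub> + a<sub>src</sub>·Wh<sub>j</sub> +
  a<sub>e</sub>·W<sub>e</sub>e<sub>ij</sub>) with per-node softmax and
  self-loops, global mean pooling, and a three-layer dense head mapping to
  the five properties; gradients are hand-derived and training (Adam, early
  stopping, z-scored targets) runs in base R;
* **thermodynamic-cycle electrochemistry**: IP/EA from gas-phase state
  energies, E<sub>ox</sub> = [G<sub>aq</sub>(M⁺) − G<sub>aq</sub>(M)]/n −
  E<sub>ref</sub> and E<sub>red</sub> = [G<sub>aq</sub>(M) −
  G<sub>aq</sub>(M⁻)]/n − E<sub>ref</sub> with n = 1 and E<sub>ref</sub> =
  4.28 V (standard hydrogen electrode);
* **analysis tools**: learning curves, ring-stratified metrics, worst-error
  ranking, Morgan-style circular fingerprints (radius 3) with Tanimoto
  similarity for novelty analysis, and PCA of the pooled embeddings with
  property gradients and exemplar selection.

SMILES canonicalization and validity checking go through Open Babel
(`ChemmineOB`); everything else is base R.

## Worked example

```r
library(ringprop)

cfg     <- generator_config(seed = 7, n_molecules = 600)
records <- generate_molecules(cfg)                      # 600 unique ring systems
labels  <- label_molecules(records, huckel_params(noise_sd = 0), seed = 8)
graphs  <- featurize_dataset(records)
split   <- split_dataset(nrow(records), split_spec(480, 60, 60, seed = 9))
model   <- train_model(graphs, labels, split,
                       train_config(max_epochs = 20, seed = 10),
                       egat_config(seed = 10))
evaluate(model, graphs[split$test], labels)
```

```
  property       MAE      RMSE        R2
1   gap_eV 0.2626683 0.3909425 0.9797519
2    ip_eV 0.3021570 0.3978803 0.7873406
3    ea_eV 0.2651288 0.3325890 0.9858259
4    eox_V 0.2836133 0.3721742 0.7801652
5   ered_V 0.2517345 0.3106228 0.9863007
```

Each row is one predicted property on the 60 held-out molecules: mean
absolute error and root-mean-square error in eV (gap, IP, EA) or V
(E<sub>ox</sub>, E<sub>red</sub>), and the coefficient of determination
against the test-set mean. After 20 epochs on 480 molecules the model
already explains ~98% of the variance of the Hückel gap; at the package's
reference scale (3,000 molecules, 40 epochs) test R² for the gap reaches
≈ 0.99. The embedding space organizes by conjugation: PCA axis 1 of the
pooled embeddings correlates with the gap at |r| ≈ 0.94 in this run.

The same pipeline is scriptable from a shell via the installed CLI:

```sh
RP=$(Rscript -e 'cat(system.file("exec", "ringprop.R", package = "ringprop"))')
Rscript $RP generate --n 300 --seed 41 --out mols.csv
Rscript $RP label    --in mols.csv --out labeled.csv --seed 42
Rscript $RP train    --in labeled.csv --out-dir run --n-train 220 --n-val 40 --n-test 40 --seed 43 --epochs 10
Rscript $RP top-errors --in labeled.csv --model run/model.rds --split run/split.csv --k 10 --out errors.csv
Rscript $RP similarity --in labeled.csv --errors errors.csv --out similarity.csv
Rscript $RP embed --in labeled.csv --model run/model.rds --out emb.csv
Rscript $RP pca   --embeddings emb.csv --in labeled.csv --k 2 --out coords.csv
```

## Scope notes

Labels are Hückel-oracle synthetics, not DFT: magnitudes overlap realistic
ranges only qualitatively, and no 3D/conformer or solvation effects are
modeled. See `vignettes/ringprop-methods.Rmd` for the model, parameter
tables, design decisions and limitations.
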
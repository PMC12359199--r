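---
title: "Assessing protein model quality with an equivariant confidence head"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing protein model quality with an equivariant confidence head}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(egnnqa)
```

## Scope

`egnnqa` implements the model-quality-assessment stack around per-residue
confidence (pLDDT) prediction: exact LDDT scoring, ensemble RMSF features,
a protein-graph featurization, a trainable E(n)-equivariant confidence
head with a bin-weighted loss, an evaluation protocol, and a synthetic
data generator that makes the whole pipeline trainable and testable at
desk scale. It does not run a structure predictor or a protein language
model: the large feature tensors those produce are consumed as opaque
inputs (or emulated synthetically), and assessing real predictions
requires exporting the real tensors into the documented bundle layout.

## The LDDT score and its conventions

For a residue *i* of the reference structure, every atom pair within the
inclusion radius (default 15 Å, measured in the *reference* only) is
tested at the four tolerances 0.5, 1, 2, 4 Å; the residue's score is 100
times the fraction of (pair, tolerance) combinations whose inter-atomic
distance is preserved in the model to within the tolerance. Several
boundary conventions are deliberately pinned:

* Comparisons are inclusive on both the radius (`d_ref ≤ 15`) and the
  tolerances (`|Δd| ≤ t`): boundary cases are measure-zero but the rule
  must be deterministic.
* `min_sequence_separation = 0` by default: only intra-residue pairs are
  excluded. The separation is configurable.
* In all-atom mode a score is computed per heavy atom from that atom's
  pairs, then averaged over the residue's atoms. Atoms absent from the
  model are dropped from numerator *and* denominator, so coverage is not
  punished as inaccuracy.
* There is no stereochemistry penalty and no symmetry-aware swapping of
  chemically equivalent side-chain atoms (ring flips). The latter biases
  all-atom scores of real side chains slightly downward; it does not
  affect the synthetic fixtures, whose residues have no symmetric atoms.
* Scores live on the 0–100 scale everywhere, including losses.

Two scorer implementations exist on purpose: the production path
(`method = "fast"`, vectorized distance matrices) and an independent
brute-force scan (`method = "reference"`). They are required to agree
*exactly*, and the test suite checks this on hundreds of random decoys in
both modes. Because the score depends on coordinates only through
inter-atomic distances it is exactly invariant under rigid motions of
either structure, and it is deliberately asymmetric in (reference, model):
the inclusion set is defined by the reference.

A residue whose inclusion set is empty has an undefined score and is
excluded from the model-level mean. During renumbering to a full sequence,
residues lacking a CA atom are dropped (with a message): without a CA
position they can neither be scored in Cα mode nor anchor a graph node.

## The confidence head

The protein is a directed graph: one node per residue, edges both ways
between residues whose Cα atoms lie within 16 Å (inclusive). Raw node
features concatenate the predictor's single representation (L×384), a
layer-averaged language-model embedding (L×33) and the ensemble RMSF
(L×1); raw edge features concatenate the pair-representation slice
`pair[i, j, ]` (128, orientation preserved — both directed edges exist
anyway) and the attention slice (33). Learned transition layers with ReLU
map these to 384 node and 128 edge features; a linear projection takes
nodes to the 128-dimensional hidden width; four equivariant graph
convolutions follow; a final projection and row softmax give each residue
a probability distribution over 50 LDDT bins of width 2.

Each convolution computes, per directed edge i→j, a message
`m_ij = φ_e(h_i, h_j, ‖x_i − x_j‖², e_ij)`, updates coordinates by
`x_i ← x_i + (1/deg i) Σ_j (x_i − x_j) φ_x(m_ij)` and node states by
`h_i ← φ_h(h_i, Σ_j m_ij)`, where φ_e, φ_x, φ_h are two-layer maps with
SiLU activations. Scalar outputs therefore see geometry only through
squared distances and are invariant to rotations and translations of the
input coordinates (verified to ~1e-13 in the tests); the coordinate
stream is equivariant and is discarded after the last layer. Message
aggregation is a sum; the coordinate update is normalized by node degree
to keep dense graphs stable.

Numerical choices worth knowing:

* Squared distances are fed to φ_e on the scale of the squared cutoff
  (d²/16²). Raw squared distances reach 256 Å² and saturate the softmax
  at initialization, killing all gradients; on the normalized scale the
  initial loss equals log 50 as the uniform-output algebra requires.
* The input weights of the aggregation block start scaled by 0.2, and the
  last layer of φ_x starts near zero, so early activations and coordinate
  updates are O(1).
* Log-probabilities in the loss are clamped at −30; clamped terms carry
  no gradient.
* Bin b covers [2(b−1), 2b), with LDDT = 100 assigned to the top bin.
  pLDDT is the expectation over bin centers (not the argmax), the usual
  convention for binned confidence heads, so predictions lie in [1, 99].

### Loss and training

Real training sets are dominated by accurately modeled residues, so a
plain cross-entropy mostly learns "predict high". Each bin therefore
receives weight `w_b = 1 − f_b`, where `f_b` is the training fraction of
residue LDDT values in bin b, and the loss is the weighted cross-entropy
normalized by the *sum of applied weights* rather than the residue count.
The normalization keeps the loss scale comparable across proteins with
different LDDT compositions; with uniform weights it reduces exactly to
mean cross-entropy (a test pins this identity).

Training uses Adam at learning rate 1e-4 (the rate appropriate for
fine-tuning a confidence head on a frozen trunk), one protein per step,
with two regularizers that matter at the small problem sizes this package
targets: decoupled weight decay (default 5) and per-step dropout of raw
feature columns (default 0.2). Of the hundreds of input feature columns
only a handful are informative; without shrinkage the head memorizes the
noise columns of 20 training proteins (training loss → 0.002) and
generalizes poorly. The default of 60 epochs is where the regularized
loss curve flattens at these sizes. All of this is exposed as arguments;
`architecture = "mlp"` trains an equally sized per-residue multilayer
perceptron under the identical loop, the natural baseline for the
equivariant head. Forward, backward and optimizer are base-R matrix code;
gradients were verified against central finite differences on every
parameter group.

`qa_head()` returns a classed fit supporting `print`, `summary`, `coef`,
`predict`, `fitted`, `residuals` and `plot` (loss trace). A `simulate`
method is not provided: the model is a conditional classifier, and
sampling bin indices is not a meaningful data-generating process for new
proteins.

### Feature ablations

The bundle's flags reproduce the standard ablation variants: `use_rmsf`
and `use_esm` drop those blocks from the node/edge inputs; `use_extra =
FALSE` keeps only the single representation (nodes) and pair
representation (edges); `use_edges = FALSE` empties the learned edge
features while *keeping the graph connectivity* — an equivariant layer
needs edges to pass messages, so the ablation removes edge information,
not the graph. `ablation_delta()` summarizes variant-minus-full error
differences.

## Ensemble RMSF

Replicate predictions of the same sequence fluctuate most where the
predictor is uncertain. `compute_rmsf()` superposes every member onto
member 1 (Kabsch on shared CA atoms, single pass — no iterative
mean-structure refinement, a deterministic and sufficient frame at 5
members) and reports, per residue, the RMS deviation of its CA about the
member-mean position. Fluctuation is measured about the mean, not the
anchor, the standard RMSF definition. Collinear CA sets make the optimal
rotation ill-determined and are flagged with a warning.

## The evaluation protocol

Two methods are compared target by target on model-level mean absolute
LDDT error. Differences under 0.5 LDDT are ties; the comparison is also
reported restricted to targets where either method errs by strictly more
than 5.0 — the subset where self-assessment actually failed. Residue-level
behaviour is summarized by row-normalized 4×4 confusion matrices over the
>90 / 70–90 / 50–70 / <50 bands (boundaries assign downward: 90 is
"70–90"); rows with no support are reported absent, not zero-filled.
Category-correctness of two methods is compared with a Pearson chi-squared
test on the 2×2 correct/incorrect table, one degree of freedom, no
continuity correction — the variant matching the convention of quoting
asymptotic p-values. For small tables the asymptotic p agrees with the
discrete conditional-exact permutation null only to order of magnitude;
the tests check exactly that, and the limitation is inherent to the
asymptotic statistic, not to this implementation.

## The synthetic generator: what it emulates, and what it does not

Every fixture is generated in code from one master seed, expanded
deterministically into per-fixture seeds, so datasets are reproducible
bit for bit.

* **Backbones** are chains of ideal α-helical segments (rise 1.5
  Å/residue, radius 2.3 Å, 100°/residue; 8–14 residues per segment)
  joined by randomly oriented turns, giving consecutive CA–CA distances
  of ≈3.8 Å and compact folds with a mean contact degree near 17 under
  the 16 Å cutoff. Each residue carries N, C, O and CB dummies at
  ideal-ish geometry so all-atom scoring is exercised.
* **Decoys** add independent Gaussian noise per atom, with the standard
  deviation set per residue by error segments (log-uniform 0.2–5 Å in
  `make_dataset`, 0.1 Å elsewhere), so all four confidence bands are
  populated and true LDDT is known exactly. Side-chain atoms receive 1.5×
  the backbone noise (`sidechain_noise_mult`): predictors place side
  chains less accurately than backbones, and this asymmetry is what makes
  all-atom LDDT measurably more stringent than Cα LDDT. Under strictly
  uniform per-atom noise the two scores differ only by a coin flip
  (measured gap ≈ 0 ± 0.1 LDDT across noise levels), so a generator
  without the asymmetry cannot reproduce the stringency property at all.
  Gaussian coordinate noise is a deliberate simplification — real decoys
  err in torsion space with correlated, physically plausible
  displacements — so passing tests show the metric and head behave
  correctly under known error, not that the generator mimics real decoy
  physics.
* **Ensembles** are copies of the assessed model jittered per residue
  with standard deviation `ensemble_jitter_scale · (100 − LDDT_i)/100` Å
  (default scale 1 Å: a fully wrong residue fluctuates by about an
  Ångström across replicates, the order observed for dropout replicates).
  This hard-codes the fluctuation–error link; the RMSF–LDDT
  anticorrelation test verifies the pipeline recovers it, not that real
  ensembles obey it.
* **Feature bundles** are standard-Gaussian tensors except designated
  signal slots carrying the standardized true LDDT at signal-to-noise
  ratio `feature_snr`: column 1 of the single representation, column 1 of
  the embedding (independent noise), and slice 1 of the pair
  representation (mean of the endpoint signals — any injective encoding
  would do). The default `feature_snr = 10` corresponds to a signal
  column correlating ≈0.99 with true LDDT, the documented recovery
  operating point of the bundle: it emulates representations that
  genuinely encode local quality, as the trunk representations of a
  predictor whose own confidence head works must. At this operating
  point, training on 20 proteins of 40–60 residues reaches a held-out
  Spearman of ≈0.89 (equivariant head) versus ≈0.71–0.80 (MLP baseline);
  with `feature_snr = 0` *and* `ensemble_jitter_scale = 0` (the negative
  control — the RMSF channel must be cut too, or it still leaks the
  error signal) recovery collapses to |ρ| < 0.2. The decoy's perturbed
  geometry remains visible to the head through the graph coordinates, as
  it would at inference time; at these training sizes that cue is not
  recovered.

## Problem sizes and determinism

The shipped tests and the acceptance script use: 200 random structures of
5–60 residues for scorer equivalence; 100 decoys of 30 residues for the
stringency comparison; 20 training and 10 held-out proteins of 40–60
residues for head recovery; 50 proteins for the RMSF anticorrelation; and
10 seeds × (8 training + 20 held-out proteins, 20 epochs) for the
negative control. These sizes make every property measurable in minutes
on a single CPU while leaving the conclusions stable across seeds (the
recovery correlation varies by ±0.02 between master seeds). Training is
exactly reproducible given a seed; LDDT scores are exact rationals with
denominator 4 × (number of pairs).

## Known limitations

* Single chains only: no assemblies, nucleic acids, ligands or insertion
  codes beyond their use in altloc resolution.
* The bundle container is an RDS file with a documented layout; exporting
  real predictor/language-model tensors requires a small conversion step
  on the producing side.
* No symmetry-aware atom swapping in all-atom scoring (see above).
* The generator's helical-segment backbones under-represent extended
  β-sheet topologies; contact-graph densities of real β-rich folds may
  differ.
* The head is trained from scratch; transfer from a pretrained trunk, and
  GPU-scale data, are out of scope.
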
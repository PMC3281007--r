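---
title: "Methods: scoring circular permutation site viability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring circular permutation site viability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its own model: what is computed,
which conventions and parameters were chosen where the design was open, and
what the synthetic-data tests do and do not demonstrate.

## The problem and the unit of analysis

A circular permutation (CP) site at position *s* of a chain means the
peptide bond between residues *s − 1* and *s* is opened and the native
termini are joined; the site is *viable* when the permutant still folds into
a stable protein. The unit of analysis is one protein chain: multi-chain
files require an explicit chain selection, only the first model of
multi-model files is used, hydrogens are ignored everywhere, and residues
are renumbered contiguously (1..n) with the author numbering carried
alongside. Residues lacking a Cα are dropped with a warning — input
structures occasionally omit atoms, and silently interpolating coordinates
would corrupt every distance-based descriptor downstream.

A candidate site is represented by the 2k-residue window around the cleavage
point, positions *s − k* .. *s + k − 1*, with k = 3 by default: narrower
windows cannot form the pair patterns used by the propensity statistics, and
wider ones dilute the local signal. Windows are truncated at chain ends
rather than discarded, because experimentally tested sites do occur near
termini.

## Tertiary descriptors

All descriptors operate on heavy atoms; where a measure is classically
computed after hydrogen restoration, this package substitutes a heavy-atom
geometric criterion and documents the measure as an approximation.

* **RSA** — Shrake–Rupley sphere sampling with a deterministic Fibonacci
  point shell (960 points/atom, probe 1.4 Å), atom SASA summed per residue
  and normalised by a fixed published Gly-X-Gly maximum-area table. The
  deterministic shell makes RSA reproducible bit for bit; 960 points put
  the discretisation error well under the 2% envelope checked against a
  high-resolution random-point oracle.
* **Depth** — distance from a residue's Cα to the nearest solvent-accessible
  atom (atom SASA > 0); zero when that nearest accessible atom is the
  residue's own.
* **CM** — distance from the unweighted Cα centroid (Cα is the package's
  residue-location convention; a mass-weighted all-atom centre is exposed
  as an option).
* **CN / WCN** — CN counts heavy atoms of *other* residues within 6.4 Å of
  the Cα (the radius with the best discrimination between viable and
  inviable sites); WCN is the cutoff-free inverse-square Cα–Cα sum.
  CN is atom-level ("number of atoms"), WCN residue-level — this asymmetry
  follows the measures' original constructions.
* **Closeness** — harmonic closeness on a unit-edge contact graph (Cα–Cα
  ≤ 8 Å): (1/(n−1)) Σ 1/sp(i,j), unreachable nodes contributing 0. The
  harmonic form was chosen because the classical (1/Σ sp) form is undefined
  on disconnected graphs, which truncated or multi-domain chains produce.
* **Hydrogen bonds** — a donor/acceptor N/O pair of different residues
  within 3.5 Å counts as one bond, excluding backbone N/O contacts of
  sequence neighbours (the trivial peptide contact). No hydrogen placement.
* **GNM-F** — diagonal of the pseudo-inverse of the Kirchhoff matrix at a
  10 Å cutoff, discarding the single zero mode; returned unnormalised
  because all features are standardized per protein anyway.
* **DIS and farness** — with core sets B (RSA < 10%), H (hydrophobic
  class), B∪H and B∩H: DIS is the mean Cα distance to the core; farness is
  F(i,G) = [Σ_{j∈G,j≠i} W(j)/d_ij]⁻¹ with W(j) = d_ij^(−q). The weight
  exponent q defaults to 2 by analogy with WCN's inverse-square weighting;
  q = 0 recovers the plain harmonic form. This one-parameter family is the
  package's fixed reading of the measure's algebra, chosen so the two
  printed limiting forms coincide.
* Undefined values (a singleton core containing the residue itself, an
  empty core set) are NA sentinels, excluded from standardization — never
  imputed.

## Propensity statistics

Pattern frequencies are per polypeptide (count/length; pairs over
length − g). Enrichment of a pattern between an experimental group (site
segments) and a comparison group (background sequences) is tested by a
two-sided permutation test on the difference of group means: group labels
are permuted preserving sizes, p = (t + 1)/(T + 1) with t the number of
resampled |θ*| ≥ |θ̂|, T = 99,999 by default; when the number of distinct
relabelings is at most 10,000 the test switches to exact enumeration. The
two-sided form was chosen because depletion is as informative as enrichment
for CP scoring.

The propensity score is S_p = (1 − p) · log₂((f_e + ε)/(f_c + ε)). It is
zero when frequencies agree or significance is nil, positive for
enrichment, and antisymmetric under swapping the groups. ε guards the
ratio: half the sum of each group's smallest *nonzero* per-polypeptide
frequency of the pattern, falling back to 1/(total group length) when a
group never shows the pattern. The "nonzero" reading is a recorded choice —
taking the plain minimum would make ε zero exactly in the cases it exists
to protect.

Per-residue propensity features (R_aa, R_aat3, R_aat5, R_sse) are the mean
scores of the window symbols under the amino-acid, 3-class, 5-class and SSE
catalogs; the 3-/5-class tables ship in the package and partition the 20
amino acids.

## The ensemble

Features are z-scored per protein (never pooled — absolute descriptor
scales vary with protein size) and then *oriented*: any feature whose mean
over viable training sites is below its mean over inviable ones is negated,
so every feature points the same way. Negation is used uniformly; the
reciprocal alternative is undefined for zero-crossing standardized values.

**Hierarchical integration (HI).** Features are grouped by meaning
(sequence propensities; SSE propensity; exposure RSA/depth/CM; packing
HB/closeness/CN/WCN; flexibility B-factor/GNM-F; core distances), each node
combining its children as IF = Σ w_f z_f with two-decimal weights summing
to exactly 1 — the sum-to-one normalisation keeps IF scale-stable from node
to root. Weights are found by exhaustive grid search ranked by 10-fold mean
MCC (each fold's threshold is picked on its training part, nearest the
(0,1) ROC corner), ties by mean AUC, then by the Welch p-value of the node
score. The desk-scale grid step is 0.05; 0.01 reproduces the full
two-decimal grid at ~50× cost, and nodes with more than 6 branches at step
0.01 are refused. The HI probability score of a value v counts training
positives ≥ v (N_p) and negatives ≤ v (N_n) and returns N_n/(N_p + N_n) —
monotone in v, 0.5 when both counts are empty.

**ANN.** Three layers, sigmoid activations, one output neuron, hidden size
Round(√(N_i · N_o)) — a standard heuristic of the era, configurable.
Training is single-case stochastic backpropagation: 5,000 iterations, one
uniformly drawn training case each (with replacement — the natural reading
of random selection per iteration), learning rate 0.5, momentum 0.1,
initial weights uniform in (−2, 2). Deterministic given the seed.

**RF.** 1,000 unpruned CART trees (rpart, cp = 0), each on a random half of
the features and a full-size bootstrap sample (~63% unique cases); each
tree is scored by MCC on its out-of-bag cases (empty out-of-bag → −1) and
the 500 best are kept. The score is the retained trees' viable-vote
fraction.

**Kernel classifier.** Soft-margin RBF support vector classification
(LIBSVM via e1071); (cost, γ) by seeded stratified cross-validated accuracy
over a small grid. Scores are produced by a logistic (Platt-style)
calibration fitted on held-out-fold decision values rather than LIBSVM's
internal probability machinery, whose un-seedable internal CV would break
the package's end-to-end determinism contract.

The four scores — all in [0, 1] — are averaged unweighted and smoothed
along the chain with the convex window (0.25, 0.50, 0.25), renormalised
over existing neighbours at the termini; the window weights are a recorded
package choice. A residue is called viable when its smoothed score is at
least 0.5.

## Evaluation conventions

Score ties at a threshold count as positive (consistent with the ≥ 0.5
labelling rule). The operating threshold defaults to the ROC point nearest
(0, 1), ties resolved to the higher threshold. PPF is the predicted
positive fraction; fixed-PPF thresholds take the largest threshold whose
PPF reaches the target, reporting any tie-induced overshoot. Retrieval
tables report precision 1 with an explicit `empty` flag at cutoffs that
retrieve nothing, so reports always print. Cross-validation folds are
seeded, class-stratified, and an exact partition.

## Synthetic data: what it emulates and what it does not

The generator builds ideal-geometry backbones (N, CA, C, O) by sequential
internal-coordinate placement: helix (φ, ψ) = (−57°, −47°), strand
(−120°, +120°), loops drawn uniformly from the polyproline/bridge region
φ ∈ (−170°, −40°), ψ ∈ (0°, 50°) — a permitted region that the
dihedral-window fallback deliberately classifies as coil. Self-clashing
conformations are resampled. Optional Gaussian coordinate noise (default
0.15 Å in the study sets) emulates coordinate uncertainty. Side chains are
not built: descriptors run in backbone-only mode on synthetic input, and
B-factors are drawn at random as a deliberate negative-control feature.

Viability labels are planted by P(viable) = logistic(β₀ + Σ β_f z_f) with
the default β₀ = 0 and β = (WCN −2, RSA +1, GNM-F +1) — viable sites
unpacked, exposed and flexible, the direction the real preferences point,
with magnitudes chosen once to give a learnable but noisy signal (single
best feature AUC well below a perfect separator). Sequence groups draw the
background from a fixed published average composition at protein length
(250 residues) and the site group as six-residue segments from the
enrichment-reweighted, renormalised composition — mirroring the
whole-protein versus site-segment contrast the statistics are designed for.
A planted Pro ×1.32 enrichment at 1,000 sequences per group is recovered
with p < 0.001 in about 93% of repeats; the binomial noise of six-residue
segments bounds the attainable power regardless of background size, so
recovery rates above ~93% should not be expected at these conditions.

Passing synthetic tests shows the machinery is self-consistent — that
descriptors match brute-force oracles, the statistics are calibrated, and
the ensemble recovers signals of the kind it assumes. It does *not* show
real-protein predictive performance: synthetic chains lack side-chain
packing, real buried cores, crystallographic B-factor physics, and real CP
viability labels.

## Problem sizes and numerical choices

The shipped study sets use 8–10 chains of 40–60 residues (a few hundred
labelled residues), 10-fold cross-validation, the full 1,000-tree forest,
and HI at grid step 0.05 — sizes chosen so a complete training/evaluation
cycle runs in minutes on one core while keeping every algorithmic component
at its stated operating point. Tolerances: descriptor oracle equivalence at
1e−8 or exact; rigid-motion invariance at 1e−6 relative; SASA within 2% of
a high-resolution oracle. Degenerate inputs fail loudly: coincident Cα
pairs (WCN), zero distance to a core member (farness), disconnected GNM
networks, single-class training sets.

## Known limitations

DSSP ingestion accepts the classic fixed-column dialect only, and the
internal fallback assigns {H, E, -} from φ/ψ windows — an approximation,
overridable by supplying DSSP output. The "+" (hydrogen-restored) variants
of the source measures are approximated by heavy-atom criteria. mmCIF is
not parsed; NMR ensembles are not averaged; the Ramachandran-code and
kappa-alpha structural-alphabet features are out of scope, as is
reproducing any published benchmark value that requires external curated
datasets.
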
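---
title: "Auditing proteochemometric models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing proteochemometric models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Proteochemometric (PCM) models predict the bioactivity of a protein-ligand
pair from a joint feature vector: a protein representation concatenated
with a ligand fingerprint. Reported PCM performance is dominated by
evaluation choices rather than by modelling choices. Random
cross-validation lets near-identical targets appear on both sides of the
split; class imbalance inflates ranking metrics; and models that appear to
exploit protein information often turn out, under permutation testing, to
rely almost entirely on the ligand block. pcmaudit packages the machinery
to quantify each of these effects on data with *known* ground truth, so
that every claim the framework makes about leakage, rebalancing or feature
attribution is itself testable.

The package treats kinase-ligand bioactivity panels as its model system:
kinase domains share a multiple sequence alignment (MSA) that defines a
common column coordinate system, kinases group into families, and activity
is measured on the pX = -log10(molar) scale and binarized at pX >= 6
(1 micromolar).

## The synthetic study generator

Everything downstream is audited against simulated data whose dependency
structure is chosen, not estimated. One `sim_config()` object fixes the
study conditions; a single master seed drives hierarchical per-component
seeds (`derive_seed()`), so any component regenerates independently and
bit-identically.

**MSA.** Each family has a random consensus sequence; members substitute
residues independently (default rate 0.1). Gaps are per-column independent
Bernoulli draws. The default `"bimodal"` gap profile gives 10% gap-free
core columns, 10% all-gap insertion columns, and 5% gapping elsewhere —
a caricature of conserved kinase cores plus family-specific insertions that
guarantees any trimming threshold in (0.05, 1) is exercised from both
sides.

**Embeddings.** Each kinase receives one row per ungapped residue and `c`
columns (default `c = 16`; a synthetic stand-in scale, since no real
language model is run). Rows are a family mean vector — each coordinate
N(0, `family_signal`^2) — plus unit noise. `family_signal = 0` makes rows
exchangeable across families; the tests verify both the exchangeable limit
and that separability is non-decreasing in the signal.

**Ligands.** Bit vectors (default 1024 bits, matching the fingerprint
width used throughout) with latent cluster structure: each ligand belongs
to one of `n_clusters` pharmacophore factors that switches a disjoint bit
subset on with probability 0.9 over a 0.02 background. Decoy pools come
from the same background library process with disjoint identifiers.

**Activities.** `pX = baseline + eta + N(0, noise_sd)` with
`noise_sd = 0.5` by default, mirroring the ~0.5 pX-unit reproducibility
floor of public biochemical panels. The regime dictates `eta`:

* `null` — zero; labels carry no information (the pipeline must score
  AUROC ~ 0.5 and MCC ~ 0).
* `ligand_only` — one effect per ligand cluster.
* `protein_only` — one effect per family.
* `interaction` — the sum of a family x cluster effect and a
  kinase x cluster effect, with equal variance shares.

The interaction decomposition is a deliberate design choice: the
kinase-level component is exactly the information a random split leaks and
a kinase-grouped split withholds, while the family-level component is what
a kinase split still shares and a family split withholds. This makes the
three split strategies measurably different by construction and gives the
split-ordering property (random >= kinase >= family mean F1) a causal
basis rather than a numerical accident.

The baseline is calibrated by an empirical quantile of `eta + noise` so
that the fraction of records at pX >= 6 matches `active_fraction`. The
default of 0.2 actives is a free choice — public panels do not pin down a
per-kinase ratio — and is exposed in the config.

## Activity standardization

`to_pX()` converts Kd/Ki/IC50 to -log10(molar) after exact power-of-ten
unit conversion (`M, mM, uM, nM, pM`); pChEMBL values pass through;
percent-inhibition/activity records are carried but never converted, since
no principled percent-to-pX map exists. Replicates merge by the median pX
per (kinase, ligand, measurement type) — robust to heavy-tailed assay
error — with the midpoint convention for even counts; measurement types
are never merged across each other. The boundary case pX = 6 is classed
*active*; this is a documented convention, configurable via the threshold
argument. Range-valued measurements are not supported and are rejected at
conversion.

## Protein featurization

**Padding** inserts 1 x c zero rows at the kinase's gap positions,
equalizing every embedding to `L_msa` rows and aligning residues across
kinases. **Trimming** removes alignment columns whose gap fraction is
*strictly greater* than the threshold (default 0.95) — "over 95%" read
literally, so a column at exactly 0.95 is retained — and applies one
retained-column set to every kinase. **Mean aggregation** is the column
mean including zero pad rows for padded/trimmed forms (the pad-inclusive
convention is the default and is recorded in the matrix's provenance
attributes; pooling the raw form uses only real residues by construction).
**Flattening** is residue-major (row 1's c values first); the order is
fixed and documented because block bookkeeping for permutation and PFI
depends on it.

Descriptor scales cover the classical alternatives to learned embeddings:
the 3-component Hellberg Z-scale and a 2-component physical scale
(Kyte-Doolittle hydropathy, residue volume) use the published tables; the
5- and 8-component scales are surrogate principal-property scales derived
deterministically by PCA of the complete AAindex indices shipped with
seqinr — they stand in for the published topological T-/ST-scales at the
correct dimensionality (vector lengths 755 and 1208 at 151 gap-free
columns) and are documented as surrogates. Numeric scales encode gap-free
columns only; one-hot encodes all columns over a 21-symbol alphabet (20
amino acids + gap). Unknown residue symbols are an error, except `X`,
which maps to the zero vector with a warning.

`fit_reduction()` compresses equal-shape embedding matrices with a compact
dense autoencoder — tanh encoder, linear decoder, softmax family head —
trained full-batch with Adam on `MSE + lambda * cross-entropy`
(`lambda = 1`; the relative weighting is a free choice, exposed as an
argument). Both loss components are logged per epoch. One caveat the tests
document: at high family signal the mean-pooled baseline is already at
ceiling for family separation (pooling averages away row noise while
retaining the family mean), so the latent space is asserted to be
*non-inferior* to pooling and strong in absolute terms, not strictly
better.

## Ligand featurization

The synthetic bit-vector path is primary: every downstream test runs
without a chemistry toolkit. For real molecules, SMILES are canonicalized
and parsed via OpenBabel (ChemmineOB/ChemmineR), after which the package
computes folded binary fingerprints itself: Morgan-style circular
environments (iterative neighbour-invariant refinement out to the radius)
and simple linear paths (canonical min(forward, reverse) strings up to the
maximum path length), hashed onto `n_bits`. Canonicalizing before graph
construction makes equivalent SMILES yield identical vectors.
Multi-fragment inputs keep the largest fragment with a logged message.
Whether published pipelines used counts or binary bits is ambiguous;
binary is implemented.

Joint representations are protein-first concatenations with exact block
index bookkeeping; the order is fixed because permutation targets and PFI
are defined per block.

## The evaluation harness

**Splits.** Random splits stratify on the label; kinase and family splits
are grouped k-fold assignments (greedy: largest group to the currently
smallest fold), with 5/5/3 folds as the standard configuration. The
leakage guarantee is *asserted*, not assumed: `check_leakage()` verifies
zero entity overlap between any train and test portion, and the acceptance
suite re-verifies it across 100 random configurations.

**SNA.** Per kinase within a fold: with `a` actives and `i < a` inactives,
`ceiling(a) - i` decoys are drawn without replacement and appended as
inactive records with provenance `sna_decoy` and no pX. Measured records
are never modified. Both the training and the held-out fold are rebalanced
independently by default (each fold individually), controllable via
`sna_folds`. Pool exhaustion is a hard error by default.

**Permutation.** `permute_block()` reassigns one feature block (or the
labels) along a single uniform permutation of the targeted phase's rows —
row-wise, the simplest reading; a per-kinase reassignment variant can be
emulated by permuting the protein feature matrix before design assembly.
The multiset of permuted items is preserved exactly and rows outside the
phase are untouched (verified by checksum in the tests).

**Grid.** `run_experiment_grid()` crosses splits x embedding variants x
SNA x permutation specs x folds, derives one seed per cell from the master
seed and the factor levels, trains a single-threaded XGBoost classifier
(fixed small defaults: 200 trees, depth 6, eta 0.1 — a deliberate
replacement for large-scale hyperparameter search), and records F1, AUROC,
Recall, MCC and PFI per cell. Cell errors are recorded fail-soft.

## Metrics and attribution

Metrics follow their standard contingency/ranking definitions; AUROC is
the tie-aware Mann-Whitney statistic, identical to the O(n^2) pairwise
oracle it is tested against. MCC with any zero denominator term is defined
as 0 — the standard convention, which makes the all-positive predictor
score 0 despite Recall 1. PFI is the protein block's share of the model's
gain-based feature importance (the importance type is recorded; gain is
the package's choice where conventions differ), with PFI = 0 at zero total
importance. With uniform importances PFI reduces *exactly* to
`p / (p + q)` — the dimension-share identity that explains why PFI
differences across embeddings track embedding size.

## Statistical analysis

Per-fold metrics (not condition means) enter a fixed-effects additive
ANOVA with Type II sums of squares — the appropriate choice for
unbalanced grids when interactions are not modelled; the SS type is a
package decision since tool-level conventions differ. Tukey HSD provides
the post-hoc pairwise comparisons with studentized-range adjusted
p-values; significance stars follow the `*, **, ***` convention with
`n.s.` at p >= 0.05. The internals delegate to `car::Anova` and
`stats::TukeyHSD`, but the test suite keeps independent brute-force
oracles mandatory: group-means sums of squares on balanced designs
(1e-10), the F = t^2 identity, and the Tukey two-level reduction to the
pooled t-test. Type-I error of both procedures is verified to sit in
[0.03, 0.07] at alpha = 0.05 over 1000 simulated null replicates.

## Problem sizes and numerical choices

The test and acceptance suites run the full pipeline at deliberately small
scale, chosen as the smallest sizes at which the audited effects are
stable: 18 kinases in 6 families, 200 ligands in 4 clusters at 64 bits,
~720 records per study, embeddings at c = 8, classifiers at 50 trees of
depth 4, and 10-20 seeds per property. Signal-attribution and
split-ordering checks aggregate means over seeds; tolerance bands
(e.g. |mean MCC| < 0.05 under label permutation) are inherited from the
property definitions, not tuned. Degenerate inputs have defined behaviour
throughout: zero-row matrices, single-class labels, constant responses and
exhausted decoy pools raise classed errors or flagged values rather than
propagating NaN.

## What the synthetic data does and does not show

The generator reproduces the statistical skeleton of a kinase panel:
family-structured sequences with realistic gap architecture, embeddings
with tunable family information, cluster-structured fingerprints, class
imbalance, and assay-level noise. It does not emulate real chemistry
(bit correlations from actual substructures), real phylogeny (branch
lengths, alignment errors), measurement-type biases between Kd/Ki/IC50, or
the long-tailed per-kinase record counts of public panels. Green tests
therefore certify the *machinery* — leakage control, rebalancing
accounting, permutation bookkeeping, metric and ANOVA correctness, and the
qualitative split/permutation effects under known signal structure — not
quantitative performance on any real data set.

## Known limitations

* The reduction model is a dense autoencoder; convolutional weight
  sharing over the residue axis is not implemented.
* Surrogate 5-/8-component descriptor scales are principal-property
  stand-ins, not the published topological tables.
* Percent-type activity records are carried but never modelled.
* The harness trains classifiers only; the regression mode
  (`train_regressor()`, MAE/R^2) is exposed for baseline studies but not
  wired into the factorial grid.
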
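---
title: "Residue interaction networks and mutation-risk scoring: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residue interaction networks and mutation-risk scoring: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`fvrin` quantifies the structural importance of every residue of a protein
— it was written around Coagulation Factor V (FV), whose missense
mutations cause the rare bleeding disorder FV deficiency — and trains an
ensemble classifier that scores the risk that substituting a residue is
detrimental. This vignette describes the models and procedures, the
parameters that matter, the synthetic data used to validate each stage,
and the numerical choices behind them.

## The residue interaction network

A protein structure is abstracted into a simple undirected, unweighted
graph: residues are nodes, and an edge connects residues *i* and *j* when
some atom pair (one atom from each residue) satisfies

$$ d(a, b) \le r_{vdW}(a) + r_{vdW}(b) + 2 r_{probe}, $$

the first-order criterion for two van der Waals surfaces that a probe
sphere rolled between them can touch simultaneously. The default probe
radius is 0.25 Å, the value used in contact-network construction for this
protein family. Default van der Waals radii are C 1.70, N 1.55, O 1.52,
S 1.80, H 1.20 Å (an editable table).

Two deliberate simplifications:

* **Heavy atoms only.** Protonation software is not a dependency; the
  contact rule ignores hydrogens by default, relying on the inflated
  heavy-atom radii to compensate. Structures with hydrogens are accepted
  (`heavy_atoms_only = FALSE` uses them).
* **Distance criterion rather than probe rolling.** An explicit
  rolling-probe surface computation is replaced by the distance
  criterion above, which is deterministic, dependency-free and testable
  by brute force (the test suite compares every fixture's edge set to an
  all-atom-pair oracle). Exact reproduction of surface-based contact
  detectors is not claimed; published node/edge counts for the real
  FV structure (1374 nodes, 4416 edges) are treated as approximate
  external reference points only, since they additionally depend on a
  stochastic side-chain relaxation we do not re-run.

Sequence-adjacent residues are kept as edges (`min_seq_separation = 1`
excludes only self-contacts); each edge carries an `SS`/`SM`/`MM`
annotation from the backbone membership of its closest qualifying atom
pair, as metadata only — every analysis uses the simple graph.

## Centralities and their conventions

Seven per-node measures are computed: degree, betweenness, closeness,
k-core number, Burt's constraint, authority score and PageRank. Published
analyses of this protein do not pin down normalization conventions, so
the package fixes them explicitly; every downstream step (rank
correlations, bins over observed ranges, Pareto dominance) is invariant
to monotone rescaling, so only interpretability depends on the choice:

* **Betweenness** is unnormalized shortest-path pair counts. This
  matches the published log10-betweenness bin edges (top edge ≈ 4.98,
  i.e. raw values near $10^5$ on a 1374-node graph).
* **Closeness** is $(n_c - 1)/\sum d$ within the node's component,
  scaled by $(n_c - 1)/(n - 1)$ on disconnected graphs, staying in
  $(0, 1]$.
* **Authority** coincides with eigenvector centrality on undirected
  graphs. It is computed by power iteration on $A + I$ (the identity
  shift suppresses sign oscillation on bipartite graphs without changing
  eigenvectors), tolerance $10^{-12}$, max-normalized.
* **PageRank** uses damping 0.85 (unstated in the source analyses; the
  field default).

Degree, betweenness, k-core, constraint and PageRank are delegated to
igraph; the test suite checks all seven against independent brute-force
oracles (BFS path counting, iterative peeling, direct formulas, power
iteration, eigendecomposition) on seeded random graphs up to 50 nodes.

## Criticality bins and the supercritical set

Residues with positive betweenness are placed on the degree versus
log10(betweenness) plane; each axis is divided into four uniform
half-open $(lo, hi]$ bins spanning its observed range, with the lowest
edge nudged down by 0.1% of the range so the minimum falls inside the
first bin. This nudge reproduces the published lower edge (1.988–1.989
for a degree range of 2 to 13) up to printing precision; published
interval endpoints deviate from exact uniform widths by ≲0.013,
presumably rounding, so agreement is asserted to two decimals.

The extreme bin combinations name the criticality groups: HDHB (top
degree bin ∧ top betweenness bin), LDHB (bottom ∧ top) and LDLB
(bottom ∧ bottom). Other combinations — including high-degree/
low-betweenness, which the source analyses leave unnamed — are
`UNCLASSIFIED`, as are zero-betweenness residues, which cannot be placed
on the log axis (consistent with the feature matrix discard rule below).

The *supercritical* residues are the Pareto front maximizing degree,
betweenness and closeness jointly: a residue is on the front unless some
other residue is at least as good on all three and strictly better on at
least one. All non-dominated ties are kept. The implementation scans
points in lexicographically decreasing order checking only current front
members; tests compare it to the quadratic all-pairs dominance oracle on
10,000 random points, and verify invariance under strictly monotone axis
transforms.

## Structural features and the 14-feature matrix

Six structural features per residue: Kyte–Doolittle hydrophobicity
(fixed 20-entry scale), solvent-accessible surface area (SASA),
solvent-excluded surface area (SESA), relative SESA, and the backbone
dihedrals φ and ψ (IUPAC sign convention; terminal residues and chain
breaks — peptide bond beyond 2.5 Å — yield missing values).

* **SASA** uses Shrake–Rupley sampling with a deterministic golden-spiral
  point set (default 960 points per atom, probe 1.4 Å). Doubling the
  point count changes per-residue areas by well under 2%. An isolated
  atom returns its exact expanded-sphere area, the standard convention.
* **SESA** is an import-only column by default: exact solvent-excluded
  surfaces are a substantial computational-geometry project orthogonal
  to this analysis, and the original feature was computed with external
  visualization software. When no import is given, a clearly labelled
  approximation (Shrake–Rupley at probe radius 0, the bare van der Waals
  surface) is used and recorded as `computed_approximate` in the
  feature-provenance attribute.
* **Relative SESA** divides the residue's solvent-excluded area by a
  per-residue-type reference area in an extended Gly-X-Gly tripeptide.
  The bundled reference (`inst/extdata/gxg_reference_areas.csv`) holds
  Tien-style theoretical values and is user-replaceable.
* **Conservation** is an imported column (low values = high
  conservation, the convention of the ConSurf family of tools).

The feature matrix holds 14 features — the 6 structural, the 7
centralities, and conservation — plus the 0/1 deficiency label. Rows
with any missing feature or zero betweenness are discarded and logged
with a reason; on the real protein this rule reduces 1374 residues to
1317 usable instances.

## The subsample-bootstrap median test

Deficiency-associated residues (n = 63 on the real data) are compared to
the remainder (n = 1254) one feature at a time with a procedure designed
to be insensitive to the group-size disparity: draw, 10,000 times, a
subsample of the larger group of the same size as the smaller group and
count how often the subsample median exceeds the smaller group's median;
that fraction is the one-sided p-value. Notes:

* Sampling is **without replacement** by default — the procedure
  subsamples the larger group — with `replace = TRUE` available.
* The source description mentions comparing means but defines the
  p-value through medians; the median definition wins (it defines the
  statistic), and `statistic = "mean"` is available for exploration.
* The p-value is one-sided as defined: near 0 means the deficiency
  group sits *high* on the feature, near 1 means it sits *low*. Both
  tails are informative, so the complement is reported alongside. No
  multiple-testing correction is applied (none is applied in the source
  analyses either).
* Under the null, a single p is approximately uniform — the small
  group's median is itself random — so validation checks the *mean* p
  across 20 regenerated datasets (expected 0.5, asserted within
  [0.35, 0.65]), plus exact endpoints on forced fixtures and p < 0.01
  power under a +2 pooled-SD planted shift at the study's group sizes.

## The classifier ensemble

Five estimator families — decision tree, random forest,
gradient-boosted trees, SVM, and k-nearest neighbours — are each tuned
by grid search under 10-fold stratified cross-validation (stratification
because only 4.78% of instances are labelled), scored by mean validation
AUC computed from continuous scores (class probabilities, or decision
values for the SVM). Four preprocessing combinations are searched:
PCA or not, ADASYN oversampling or not; features are always standardized.

Design points worth stating explicitly:

* **Leakage-safe preprocessing.** Whether preprocessing was fit inside
  or outside the folds is unstated in the source description; fitting
  inside the training folds is the only leakage-safe reading, and is
  what the package does: standardization, PCA and ADASYN are fit on the
  training folds only, and validation folds are never oversampled. A
  dedicated test verifies that pure-noise features give chance-level AUC
  (a standardize-before-split or oversample-before-split bug inflates
  it) and that validation fold class counts equal the stratified split
  of the raw data.
* **ADASYN** generates synthetic minority examples by interpolating
  towards minority neighbours, allocating more synthesis where the
  neighbourhood is majority-dominated, until class parity. With no
  usable minority neighbours it falls back to random duplication with a
  warning.
* **PCA component count** is unspecified in the source; the default
  keeps the smallest count explaining ≥95% of variance, with an integer
  override.
* **Grids.** `preset = "paper"` reproduces the published ranges
  verbatim (e.g. kNN neighbours 3–50; SVM γ 0.01–1.5 in steps of 0.05,
  polynomial degree 2–5, independent term 0.1–2 in steps of 0.05; forest
  size 50–1500 in steps of 50). The SVM grid crosses kernel with γ,
  degree and independent term, but degree and the independent term only
  affect the polynomial kernel, so radial rows are deduplicated to
  unique γ values. The default `preset = "fast"` is a small grid with
  the identical contract — the full grids are hours-scale searches.
  Ties in mean AUC resolve to the first grid point in deterministic
  order.
* **The vote score.** The five tuned models are refit on all data (with
  their selected preprocessing) and each predicts every residue; the
  vote score 0–5 counts models predicting "detrimental". Probabilistic
  models threshold their class-1 probability at 0.5; the SVM votes by
  its decision boundary. A score of 0 marks residues deemed safe to
  substitute by every model.
* **Determinism.** One run seed controls fold assignment, oversampling
  and stochastic estimators (per-fold seeds are derived from it), and is
  recorded in every result object.

## Synthetic data: what it emulates, and what it does not

The generator provides every input the pipeline needs:

* **Toy structures** are poly-alanine backbones (N, CA, C, O, CB) built
  from ideal bond lengths and angles with requested φ/ψ torsions
  (ω = 180°). Generated dihedrals round-trip through the dihedral
  calculator to machine precision (asserted within 0.5°), and an ideal
  α-helix shows the expected 3.8 Å consecutive Cα–Cα spacing. These
  fixtures have exact, known geometry — they do not emulate side-chain
  packing, alternate conformations, or experimental noise.
* **Random graphs** (Erdős–Rényi, Barabási–Albert) are the substrate for
  the centrality and binning oracles.
* **Feature tables** draw each feature as unit-SD Gaussian noise plus a
  shared latent factor giving equicorrelation (default 0.3), then shift
  the rows labelled deficient by per-feature effect sizes in pooled-SD
  units. Centrality features in these tables are drawn, not computed
  from a generated graph — this decouples the ML tests from the network
  stack; a separate integration path exercises the full
  structure → network → features chain.

The *study-calibrated preset* fixes the class split at 63 deficient of
1317 (4.78% / 95.22%) and plants |0.25| SD effects in the directions
observed on the real protein: deficient residues higher on all seven
centralities and hydrophobicity, lower on the three surface areas and on
the conservation score (low = conserved). With equicorrelation 0.3,
the Bayes-optimal linear AUC under this Gaussian model is

$$ \Phi\!\left(\sqrt{\delta^{\top}\Sigma^{-1}\delta / 2}\right) \approx 0.76, $$

so finite-sample learners land in the 0.60–0.80 "fair AUC" region that
brackets the published 0.65–0.69 range. These effect sizes were fixed
once, from this calculation; they are a statistical stand-in, not a fit
to the real feature table. Passing tests on this preset show the
pipeline detects planted effects at the study's imbalance — they do not
show that real FV features carry this much signal.

## Problem sizes and degenerate inputs

Routine tests and the analysis scripts use structures of 8–150 residues,
graphs up to 150 nodes (oracle comparisons up to 50), feature tables of
1317 rows, 10,000 bootstrap iterations, and the fast grids under 10-fold
CV — sizes chosen so the full suite runs in minutes on one core while
still exercising the study's class imbalance at full scale.

Degenerate inputs are handled explicitly: empty structures and graphs
error; an axis with fewer than two distinct values cannot be binned;
constant centrality columns yield missing (not zero) rank correlations;
zero-variance features are dropped with a warning before
standardization; collinear backbone geometry yields missing dihedrals;
residues with no atoms usable under the contact rule stay as isolated
nodes with a warning; fold counts exceeding the minority class are
rejected with a suggestion.

## Known limitations

* The contact rule approximates, not reproduces, surface-based contact
  detection; real-structure node/edge counts are approximate reference
  points.
* SESA is imported or approximated, never computed exactly.
* Conservation is always an imported column; the package does not run
  alignments.
* The classifier ensemble's published-scale AUC (~0.7) is far from
  clinical-diagnostic utility, a limitation the source analyses state as
  well; the vote score ranks candidates for experimental follow-up, it
  does not diagnose.
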
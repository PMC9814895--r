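---
title: "Methods: hydration-aware pose scoring, thermodynamic grids and relevance propagation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hydration-aware pose scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydrascore)
```

This vignette is the package's own account of its models and the
decisions behind them: what is computed, under which assumptions, which
parameters matter, and what the synthetic tests do and do not show about
real data.

## 1. Voxel featurization

A binding site is described as a multi-channel 3D image on a cubic,
cell-centered grid (`grid_spec()`; default 24 Å edge, 0.5 Å spacing,
48³ voxels). Cell-centering was chosen so the covered volume is exactly
the stated box; the alternative node-centered convention would cover one
spacing less. Each typed heavy atom contributes the density

$$\rho(r) = \begin{cases}
e^{-2r^2/R^2} & 0 \le r < R \\
\tfrac{4}{e^2 R^2} r^2 - \tfrac{12}{e^2 R} r + \tfrac{9}{e^2} & R \le r < 1.5R \\
0 & r \ge 1.5R
\end{cases}$$

to the channel of its atom type, where $R$ is the type's van der Waals
radius and $r$ the distance to the voxel center. The two branches agree
($1/e^2$) at $r=R$ and the quadratic vanishes with zero slope at
$1.5R$, so the kernel is continuous; the unit tests assert continuity
to $10^{-6}$ at both breakpoints and that the voxelized mass matches the
analytic radial integral within 2% at 0.5 Å spacing. Overlapping
same-type atoms **sum** (no clamping): summation preserves mass
additivity, and clamping would make the image non-linear in the
structure for no physical gain.

Atom types are a frozen vocabulary of 16 protein and 18 ligand keys
(`atom_type_vocabulary()`): carbon split aliphatic/polar/aromatic,
nitrogen and oxygen split by donor/acceptor status, sulfur
donor/apolar, phosphorus, halogens (one generic protein key; separate
F/Cl/Br/I ligand keys), and one generic metal/other key per role. The
exact 34-type tables used by docking tools are not published in one
place and differ in rare types; freezing our own rule table (documented
in `assign_atom_types()`) keeps typing reproducible without external
software. Typing uses element, perceived aromaticity (bond orders where
available, otherwise 5/6-rings of C/N with a planarity test at 0.15 Å
RMS), bonded neighbors, and an implicit-hydrogen estimate; hydrogens
carry no density channel, and protonation is assumed done upstream.
Known approximations: aromatic ring N without explicit hydrogens is
treated as an acceptor (a tryptophan-like NH in a ring without explicit
H will be mistyped), and charged groups are typed neutrally unless
formal charges are supplied.

Training-time augmentation (`augment_pose()`) applies one uniform
random rotation (via unit quaternions) and a translation uniform in the
2 Å ball, rigidly to protein and pose, **before** rasterization —
images are re-rendered rather than interpolated, avoiding interpolation
artifacts. A Monte-Carlo test checks the empirical mean rotation angle
against the closed-form uniform-SO(3) expectation $\pi/2 + 2/\pi$.

## 2. Grid-based hydration thermodynamics

From a trajectory of water oxygens with per-water per-frame interaction
energies, `accumulate_occupancy()` counts voxel visits (one voxel per
oxygen per frame) and normalizes by `n_frames × bulk_occupancy`, with
`bulk_occupancy = 0.0334 waters/Å³ × spacing³`. The result is a
bulk-ratio grid: 1 means bulk-like. Whether an occupancy channel should
be a probability, a count, or a bulk ratio is a genuinely open
convention; the bulk ratio was chosen because it is resolution-invariant
and makes the "twice bulk" threshold dimensionless.

Every voxel with ratio **strictly** greater than 2 is a
pseudo-hydration site; its thermodynamics are accumulated from all
(water, frame) observations within a closed 1 Å ball of the voxel
center:

* ΔH = mean interaction energy of contributors − bulk energy. The bulk
  energy default (−9.533 kcal/mol, a typical bulk value for fixed-charge
  three-site water models) is a configuration constant and should be
  matched to the force field that produced the energies.
* −TΔS = T·k·KL(q ‖ uniform) with T = 300 K, k = 0.0019872 kcal/mol/K,
  where q is the empirical distribution of contributor positions over a
  fixed 0.25 Å sub-binning of the site sphere. This is a purely
  translational, plug-in estimator: a point mass gives T·k·ln(m) for m
  sub-bins, a uniform spread gives 0. It is biased upward at small
  sample sizes and contains **no rotational entropy**; the limitation is
  recorded in the output attributes. It quantifies positional ordering,
  which is what the network channel needs, not a calorimetric ΔS.

`cluster_hydration_sites()` implements greedy quality-threshold
clustering (take the maximum-occupancy voxel above 2× bulk, remove
everything within 2 Å, repeat), giving classical hydration sites with
pairwise separations ≥ 2 Å. Network channels are squashed to [0, 1)
with tanh: occupancy as `tanh(ratio/2)` (so twice bulk maps to
tanh(1) ≈ 0.76), enthalpy split by sign into H⁻ = tanh(|ΔH|) (ΔH < 0)
and H⁺ = tanh(ΔH) (ΔH > 0), entropy as tanh(|TΔS|); scales are
configurable. The sign split preserves the qualitative distinction
between frustrated (displaceable) and stable water without forcing the
network to learn a signed encoding.

The overlap coefficient `OC = Σ min(p¹ᵢ/Σp¹, p²ᵢ/Σp²)` compares two
non-negative grids as distributions; it is symmetric, scale-invariant
and bounded in [0, 1] (property-tested on 1000 random pairs). Signed
fields must be pre-transformed (absolute value, or split by sign)
because the normalization presumes a distribution — the implementation
rejects negative entries rather than silently mangling them.

## 3. The pose classifier

`build_network()` constructs input(C × D³) → 3 × [conv 3³/stride 1/pad 1
+ ReLU + max-pool 2³] → fully connected → softmax over {decoy, native},
plus a third FC output passed through a sigmoid as the predicted
contact mode score. The CMS head is a separate regression output rather
than a reshaped classification target: it leaves the classification
probability calibrated while still letting contact information shape
the shared features. The loss is

`L = λ_cls · CE(p_native, label) + λ_cms · hinged pseudo-Huber(cms)`

with λ_cls = λ_cms = 1. The CMS term is `pseudoHuber(pred − true)` when
true CMS ≥ 0.44 and `pseudoHuber(max(0, pred − 0.44))` below it: poses
with almost no native contacts have an undefined "contact quality", so
they are only penalized for *claiming* contact quality above the
cutoff. The pseudo-Huber scale δ defaults to 1.

Optimization is minibatch SGD with classical momentum 0.9, batch 16,
base learning rate 0.01 decayed ×0.1 after 75% of iterations. He-scaled
normal initialization, zero biases, fully deterministic per seed (one
seed fixes initialization and batch sampling; two runs agree to
< 10⁻⁵ relative in final loss, asserted in the tests). Analytic
gradients are verified against central finite differences to 10⁻⁴
relative on a toy network.

Two profiles exist. The **desk profile** (default) uses a coarse grid
(12 Å / 1.5 Å → 8³ voxels), filters (8, 16, 32) and 2000 iterations:
a full train/evaluate cycle takes about a minute on one CPU, and the
whole three-seed comparison below stays under ten minutes. The **full
profile** (48³ input, filters 32/64/128, 40000 iterations) is the
full-scale configuration; it is provided for completeness and is not
exercised by the test suite. The desk filter counts matter: with very
few first-layer filters (4) occasional training seeds never discover
the ligand-water coincidence feature and collapse to the class prior,
so the default keeps enough filters for optimization robustness.

Ranking uses descending P(native) with lexicographic pose-id
tie-breaking (deterministic), and `topn_success()` reports the fraction
of systems with a native among the first N ranks.

## 4. Relevance propagation

`explain()` attributes the native-class softmax output back to input
voxels by deep-Taylor layer-wise relevance propagation with the z⁺
rule: at a linear (or convolutional, treated as shared-weight linear)
layer, node j's relevance is distributed over its inputs proportionally
to $z^+_{ij} = x_i \max(w_{ij}, 0)$, and nodes with negative
pre-activation are gated to zero. Max-pooling routes relevance to the
argmax input, splitting exact ties equally. ReLU layers are transparent
(the gating at the preceding linear map handles them). The invariants —
non-negativity everywhere, and per-layer conservation of the total on
zero-bias networks — are asserted in the tests, with single layers
checked against a brute-force double-loop evaluation to 10⁻¹⁰.

Three boundary cases deserve explanation:

* **The start node is not gated.** The relevance seed is the native
  softmax probability, which is non-negative by construction; gating the
  top FC node by the sign of its *logit* would zero the entire map for
  any pose whose native logit is negative. Gating applies at hidden
  nodes, where it is consistent: a negatively pre-activated hidden node
  has zero activation and therefore receives no relevance from above
  anyway. The standalone `relevance_backprop_linear()` applies the
  literal gating rule (its `gate` argument controls this).
* **Zero denominators distribute nothing.** A node with relevance but no
  positive-weighted active input cannot redistribute it under the z⁺
  rule; its relevance is dropped and counted (`dropped` in the map).
  Consequently conservation is only guaranteed along "live positive
  paths" — if the native logit receives no positive contribution at all,
  there is no positive evidence to decompose and the map is zero. The
  conservation tests condition on this, and count how often it occurs.
* **Biases absorb relevance.** With non-zero biases the z⁺ rule as
  stated does not conserve totals; the conservation tests therefore use
  zero-bias networks, which is also how the networks are initialized.

`aggregate_relevance()` shares each voxel's channel relevance among
atoms of that type in proportion to their density contribution, and
bins water-channel relevance into four geometric categories: *replaced*
(≤ 2 Å from a ligand heavy atom), *interface-mediating* (≤ 3.5 Å from
both a ligand and a protein polar heavy atom), *first-shell* (≤ 4.5 Å
from the ligand), *other*. These cutoffs are an operationalization of
qualitative hydration roles — displacement, bridging, first shell — at
typical hydrogen-bond and first-shell distances; all three are
arguments.

## 5. Pose metrics

`pose_rmsd()` is the heavy-atom RMSD in the shared docking frame (no
Kabsch re-superposition — pose and reference live in the same receptor
frame; a superposed variant would answer a different question),
minimized over the supplied references and over automorphisms of the
element-labeled bond graph, so chemically indistinguishable
relabelings (flipped rings, symmetric substituents) do not inflate the
deviation. The automorphism search is capped at 10000 mappings; beyond
that the identity mapping is used with a warning.

`modified_rmsd()` removes solvent-exposed rigid fragments before the
RMSD: the **reference** pose is decomposed by cutting every acyclic
single bond between two non-terminal heavy atoms, each fragment's SASA
(Shrake–Rupley, deterministic golden-spiral point set, 960 points,
probe 1.4 Å; closed-form sphere areas reproduced within 1%) is computed
bound (protein context) and unbound, and fragments with ratio > 0.25
are excluded. Using the reference's exposure — not each pose's — keeps
the retained atom set identical across all poses of a system, which is
what makes per-system rankings comparable; a flag could switch this,
and if every fragment is excluded the standard RMSD is returned with a
warning. `contact_mode_score()` is the Tanimoto of (protein heavy,
ligand heavy) contact pairs within 4.5 Å, defined as 1 when both sets
are empty (two non-binding poses are trivially identical in contact
terms); the exact published CMS variant differs in details, so cutoff
and definition are configurable. A pose is labeled native iff
RMSD < 2 Å, strictly: a pose at exactly 2.0 Å is a decoy.

`split_folds()` single-links systems whenever sequence distance < 0.5
**or** ligand similarity > 0.9, then assigns groups, largest first, to
the currently smallest fold (ties to the lowest index). Linked systems
can never cross folds — asserted as a hard property on random
matrices — and imbalance beyond one system is reported.

## 6. The synthetic generator: what it emulates, and what it does not

The generator (`synthetic_spec()`, `generate_*()`) produces: pockets of
~40 typed pseudo-atoms on a 6 Å sphere shell with an opening; ligands
as self-avoiding typed chains placed at 2.5–4.5 Å minimum contact
distance with at least one polar contact; 25 poses per system by
default (one guaranteed native-like, at least half decoys — rotations
about the ligand centroid add to the translation-induced RMSD in
quadrature, which makes the stratification exact); and water
trajectories in which each planted hotspot is occupied with its stated
fraction (default 1.0), spread σ = 0.2 Å, energy −12 ± 0.5 kcal/mol
against a −10 kcal/mol uniform bulk at 0.0334 waters/Å³, 500 frames.
Bulk waters are excluded from a 2 Å shell around hotspots (excluded
volume, as a structured water displaces bulk locally); without this the
1 Å contributor sphere would mix bulk observations into the hotspot
enthalpy and bias the recovered ΔH toward bulk.

For the labeled training datasets, the per-system occupancy grid is
synthesized analytically (bulk background 1 plus a Gaussian blob of
peak ratio 25, σ = 1.2 Å at the hotspot) rather than by simulating a
trajectory per system: it is the deterministic limit of a long
trajectory, and it keeps dataset generation exactly reproducible and
fast. With `hydration_dependent_labels` the hotspot is planted at a
randomly chosen pose atom and a pose is native iff any heavy atom lies
within 2 Å of it: the label is a deterministic function of
ligand–hotspot overlap, so the occupancy channel determines the labels
exactly while geometry alone does not identify which pose the hotspot
follows. The choice is redrawn until both classes occur in the system.

What passing these tests shows: the featurization, thermodynamic
estimators, training, ranking and relevance machinery are correct and
sensitive to hydration information *when the labels depend on it*. What
it does not show: performance on real docking data. The toy systems
have no conformational flexibility, no force-field energetics, no
correlated water structure, no pose-sampling bias, and their label
mechanism is a single hotspot rather than the several interacting
hydration effects of real binding sites.

## 7. Problem sizes and numerical choices

The test suite and the acceptance script run everything at desk scale,
chosen as the smallest sizes at which each claim is statistically
meaningful: hydration recovery uses 500 frames (≈ 0.022 kcal/mol
standard error on ΔH) on a 24³ grid at 0.5 Å, the false-positive
control 1000 frames; the classifier comparison uses 200 systems × 10
poses per seed, 160/40 train/test, three seeds, 2000 iterations each.
A 48³ full-scale image is supported throughout the featurization and
network code but not exercised in training tests. Other numerical
choices collected in one place: RMSD/automorphism cap 10000; DX
round-trip tolerance 10⁻⁶ (values are printed at 17 significant
digits); rasterization skips atoms whose 1.5R support misses the grid;
the Coulomb probe field clamps r at 0.5 Å; probe extrema are strict
26-neighborhood minima with |E| ≥ τ = 5 kcal/mol and Gaussian widths
σ = σ₀(0.5 + tanh(|E|/E₀)), σ₀ = 1 Å, E₀ = 10 kcal/mol — the width's
growth with magnitude is the contract, its exact law a design choice;
probability clamps at 10⁻⁷ in the log loss; fold assignment and pose
ranking break ties by lowest index / lexicographic id so every ordering
is deterministic.

## 8. Known limitations

* Entropy is translational-only and plug-in biased; do not read −TΔS as
  calorimetric.
* Atom typing approximates donor/acceptor perception without explicit
  hydrogens; rare chemotypes fall into generic types.
* The desk-profile classifier is a small network on a coarse grid —
  adequate for the synthetic separability task, not a pretrained pose
  scorer for real complexes.
* LRP conservation is a property of zero-bias networks; trained networks
  keep zero biases only if training leaves them (biases are trained —
  `explain()` reports layer sums so drift is visible).
* The MOL2 reader covers MOLECULE/ATOM/BOND records only; mmCIF is out
  of scope.
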
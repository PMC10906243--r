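---
title: "Methods: data-driven optimization of tripeptide catalysts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: data-driven optimization of tripeptide catalysts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepcatml)
```

`pepcatml` implements a closed loop for discovering stereoselective
tripeptide catalysts: enumerate a combinatorial in-silico library, represent
each catalyst by conformer-averaged grid descriptors, design a compact
Universal Training Set (UTS) by unsupervised clustering, model selectivity
on a free-energy scale with latent-structure regression, and iterate an
uncertainty-aware optimization campaign over the full library. This
vignette is the package's account of the science behind each stage, the
tunable parameters, and the choices made where the design was genuinely
open.

## Building blocks and library enumeration

A building block is one amino-acid residue written as a SMILES fragment
N→C. The two attachment points are annotated *positionally*: the fragment
must begin with the backbone amine nitrogen and end with the backbone
carbonyl carbon, written `C(=O)`. Tripeptide assembly is then literal
string concatenation — each trailing carbonyl bonds to the next leading
nitrogen, forming the amide, and the C-terminus is capped with `N`
(primary amide, the default: the classical Pro-Pro-Xaa catalysts are
C-terminal amides) or `O` (free acid). We chose positional annotation over
backbone-template inference because the interesting residues are exactly
the noncanonical ones — pipecolic acid, α-methyl-proline, 4-substituted
prolines — that break any template.

Enumeration fixes position 1 (default D-proline, the motif shared by the
strong catalysts of this family) and takes every ordered pair from the pool
at positions 2–3: `|pool|²` members, ordered lexicographically by
(position-2 id, position-3 id) so library indices are reproducible. A
174-residue pool gives 30,276 catalysts.

Assembly, validation and molecular formulas go through OpenBabel
(ChemmineOB); every structure the package emits has parsed to a valid
molecular graph.

## Conformer ensembles

Tripeptides are far more flexible than typical small-molecule catalysts,
so a single geometry is a poor representation; descriptors are averaged
over a conformer ensemble instead. `generate_ensemble()`:

1. embeds `n_embed` (default 200) conformers by seeded distance-geometry
   embedding (ETKDG, via the RDKit helper shipped in `inst/python/` —
   the one step of the pipeline for which the in-process toolkit has no
   seed-reproducible equivalent);
2. minimises each conformer with MMFF94 (UFF where MMFF94 lacks
   parameters, e.g. azides) and records relative energies in kcal/mol and
   Gasteiger partial charges;
3. prunes to an `energy_window` (default 5 kcal/mol above the minimum) and
   deduplicates by pairwise superposed RMSD (`rmsd_threshold`, default
   0.5 Å), keeping the lower-energy member of any near-duplicate pair.

RMSD pruning uses heavy atoms only: a methyl-rotor hydrogen permutation is
not a new conformation. The defaults are conventional for flexible
molecules of this size and are all exposed as arguments. The whole
pipeline is deterministic for a fixed seed — two calls give bit-identical
coordinates — which makes descriptor matrices, and everything downstream,
exactly reproducible.

Ensembles are aligned on a common structural motif before descriptor
evaluation: the N-terminal residue (proline ring plus its backbone
carbonyl), whose atoms the assembler can identify by construction because
it defines the SMILES atom order. `align_to_core()` performs the optimal
rigid (Kabsch) superposition of the core onto a reference geometry —
by default the first conformer's core; in multi-catalyst workflows the
first library member's core is persisted and passed as `reference` to all
others. When a SMARTS pattern is supplied, its absence is an error and
multiple matches (peptides contain several prolines) resolve to the match
containing the N-terminal nitrogen, i.e. the construction-order core.

## Grid descriptors: ASO and AEIF

On a rectilinear grid (default spacing 1.0 Å, margin 3.0 Å beyond the
bounding box of the aligned calibration ensembles):

* **Average Steric Occupancy** — ASO(g) is the fraction of conformers in
  which at least one atom's Bondi van-der-Waals sphere covers grid point
  g; values in [0, 1], and exactly {0, 1} for single-conformer ensembles.
* **Average Electronic Indicator Field** — AEIF(g) averages, over
  conformers, the Gasteiger partial charge of the *nearest covering atom*
  (zero where uncovered). This nearest-covering-atom indicator is one
  admissible realisation of an electronic companion field; it is isolated
  behind `compute_aeif()` so an alternative indicator (or charge model)
  can be swapped in without touching anything downstream.

Conformer averaging is uniform by default — the published convention for
average-occupancy descriptors — with Boltzmann weighting (temperature
configurable) available through `conformer_weights()`.

Per catalyst, the two fields are flattened (x fastest, then y, then z),
concatenated and standardised column-wise; the scaling parameters are
stored so new catalysts are projected onto the training scale
(`apply_feature_scaling()`). `reduce_features()` drops zero-variance
columns, greedily drops the later member of any column pair with
|Pearson r| ≥ 0.95 (index order, for determinism), and projects onto the
first `n_pc` principal components (default 20, a dimensionality at which
descriptor spaces of this kind retain most of their variance).

Correctness of the descriptor engine is established by tests against naive
per-point brute-force evaluation and by rigid-motion invariance: fields
change by less than 1e-9 per grid point under arbitrary rotations and
translations applied before alignment.

## Universal Training Set design

The UTS is designed in building-block space: cluster the residues'
reduced descriptors, synthesise the combinatorial square of a few
representatives. `kmeans_scan()` runs k-means over k = 1–50 with 25
restarts per k, k-means++ initialisation, and a warm start from the
previous k's solution (its centers plus the worst-fit point), which
guarantees the reported distortion — mean squared distance to the assigned
centroid, the elbow-method convention — is non-increasing in k. The elbow
plot (`autoplot()`) informs the user's choice of k; the package
deliberately does not automate elbow detection, because the judgment
whether exemplars have become chemically redundant is qualitative.

`select_exemplars()` picks, per cluster, the member nearest the centroid
(ties to the lowest id). Expert additions — e.g. glutamic-acid-type
relatives of an algorithmically chosen glutamine, which sit close in
descriptor space yet behave differently chemically — enter through
`augment_manual()`, flagged and kept disjoint from the algorithmic picks.
Ten exemplars plus three manual additions give a 13² = 169-member UTS.

`summarize_distribution()` reports sample skewness and excess kurtosis
(classical moment estimators, so a symmetric two-point sample has excess
kurtosis −2) and a Kolmogorov–Smirnov test against a normal with the
sample mean and SD. A near-normal, wide selectivity distribution from the
UTS screen is the desired diagnostic: it indicates the set samples
reactivity space without mechanism bias.

## Selectivity on the free-energy scale

Selectivities are modeled as differential activation free energies,

* ΔΔG = RT·ln((1+ee)/(1−ee)) for enantiomeric excess (sign carries the
  product enantiomer; the inverse is ee = tanh(ΔΔG/2RT)),
* ΔΔG = RT·ln(syn/anti) for the diastereomeric ratio,

with R = 1.987×10⁻³ kcal·mol⁻¹·K⁻¹ and a default temperature of 293.15 K
(screens in this family are typically run at 20 °C); per-record
temperatures override the default. Enantio- and diastereoselectivity are
fitted as separate models; when several reactions are pooled, reaction
identity enters as 0/1 indicator columns so one model spans them.

The regressor is PLS1 (NIPALS), written in the package and cross-checked
in the tests against an independent implementation and against ordinary
least squares in the single-feature case. The component count is either
given or chosen by leave-catalyst-out cross-validation capped at 10.
Validation is always *catalyst-out*: `make_catalyst_split()` holds out
whole catalysts (every reaction record of a held-out catalyst moves to the
test set), optionally pinning labels — e.g. the top performer — that must
be out-of-sample; `evaluate_model()` refuses any split in which a held-out
catalyst contributed a training row.

## Iterative optimization

`fit_model_zoo()` fits a configurable family set — PLS, Gaussian-process
kernel regression (broad RBF, bandwidth σ = 0.3/2p on standardized
features), a random forest, and a single-hidden-layer network
(min(64, 2p) units, weight decay, response standardised) — each under
5-fold cross-validation, keeping every fold model as an ensemble member.
Prediction certainty is the population SD of member predictions across
families and folds: zero for unanimous ensembles, large where the model
must extrapolate. It is one documented realisation of a certainty metric,
behind `prediction_certainty()`.

`rank_candidates()` excludes measured catalysts and sorts by |predicted
ΔΔG| descending; in certainty mode it first discards candidates at or
above the chosen certainty quantile (strictly-below filtering, so the
degenerate quantile 0 empties the pool and errors). `run_campaign()`
iterates fit → rank → pick `batch_size` → acquire → append. The default
round plans mirror a pragmatic campaign: a flexible model chosen greedily
in round 1 ("high risk, high reward"), then simpler families with
certainty filtering at the median in later rounds — the configuration
under which the extrapolation benchmark below shows certainty filtering
paying for itself.

## Synthetic study conditions

The generator defines the conditions every statistical claim is tested
under:

* **Toy building blocks** (`make_toy_building_blocks()`): glycine-type
  (L/D) and proline-type backbones crossed with side chains of varying
  length, polarity, charge-bearing groups and halogenation; ~185 valid
  distinct residues, drawn in seed-reproducible order, glycine first.
* **Landscapes** (`simulate_selectivity()`): ΔΔG = Xw + ε over reduced
  descriptor coordinates, ε gaussian. Weights are scaled so the noiseless
  ΔΔG SD is ~1 kcal/mol — a realistic screening spread in which |ee|
  mostly stays below 0.99 — and the noise SD is quoted as a fraction of
  the signal SD (10% for the modeling benchmark). ee values are capped at
  1−1e-9 in magnitude purely to keep the inverse log-ratio finite; tanh
  already guarantees |ee| < 1, and a tighter cap would censor the
  landscape and create artificial ties at the top.
* **Planted optimum**: the noiseless argmax is offset to 1.2× the maximum
  magnitude, so recovery means the campaign finds the true best member.
* **Trial screens** (`make_trial_dataset()`): a full catalysts×reactions
  cross (default 50×4 = 200 records) with a three-component conversion
  mixture (≈25% below 10%, ≈50% between 10 and 90%, ≈25% above 90%), ee
  uniform on [0.10, 0.98] and syn fractions on [0.58, 0.98] — the shape
  of a primary organocatalysis screen. Conversion is simulated
  independently of selectivity and is not modeled downstream.

What the generator does **not** emulate: real descriptor–selectivity
relationships are not latent-linear, conformer ensembles of real peptides
are not exhaustively sampled, and wet-lab measurements carry structured
(not gaussian) error. Passing the benchmarks therefore validates the
machinery — transform exactness, descriptor correctness, estimator
behaviour at a known noise floor, selection logic — not chemical accuracy
on any particular reaction.

## Benchmarks and problem sizes

Three benchmark functions, shared by the test suite and
`scripts/acceptance.R`:

* `benchmark_pls_recovery()` — 20 replicates of a 169-member UTS screen in
  20 components at 10% noise; held-out MAE is expected within
  [0.5σ, 1.5σ] of the injected noise and the coefficient/weight cosine
  above 0.9.
* `benchmark_campaign_recovery()` — 25 replicates, 150-member library,
  8 components, 30 initial measurements, 3 rounds × 5 picks, acquisition
  noise 5% of the signal range; recovery of the planted optimum is
  expected in ≥80% of replicates.
* `benchmark_selection_modes()` — an extrapolation benchmark (120
  in-distribution members, 60 shifted by 2.5 SD, an interaction term the
  linear model cannot extrapolate); the certainty-filtered round is
  expected to beat the greedy round's median |predicted − realized| error.

These sizes were chosen to exercise the statistics at the scale the
workflow targets while keeping a full run of suite plus acceptance script
in the low minutes on a single core.

## Numerical choices and degenerate inputs

* Kabsch superposition uses the SVD with a reflection guard (proper
  rotations only).
* Constant feature columns get scale 1 at standardisation and are removed
  by the variance filter; requesting more components than retained columns
  is an error rather than a silent truncation.
* k-means uses Lloyd iterations from k-means++ starts; failed restarts
  (empty clusters) are discarded and the best successful restart kept.
* PLS stops early if the response residual is exhausted (noiseless data
  with more requested components than rank); at least one component is
  required.
* Pruning always retains the minimum-energy conformer; `energy_window =
  Inf, rmsd_threshold = 0` is an exact no-op.
* Ties in exemplar selection break to the lowest id; library enumeration
  is lexicographic — both so repeated runs agree exactly.

## Known limitations

* The electronic field uses Gasteiger charges and a nearest-covering-atom
  indicator; quantum-chemical electrostatics are out of scope.
* Conformer energetics are force-field level; no solvent model, no
  quantum re-ranking.
* The campaign optimises selectivity only; conversion is not a modeled
  objective.
* Synthesis feasibility is not scored: an enumerated peptide may still
  fail on the synthesizer.
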
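---
title: "Pharmacophore screening with pharmscreen: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pharmacophore screening with pharmscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharmscreen)
```

# The problem

Pharmacophore-based virtual screening asks a qualitative question: which
abstract arrangement of chemical features — hydrogen-bond donors and
acceptors, hydrophobes, aromatic rings, ionizable groups — is necessary for
a ligand to bind a target, and which library compounds present that
arrangement in 3D? For targets with few known inhibitors (kinases such as
CDK7 are the motivating case), a *common-feature* model built from a
handful of selective actives, complemented by a *structure-based* model
read off a receptor–ligand complex, is the standard route. The resulting
hypotheses are then validated statistically against decoy sets, used to
screen drug-like libraries, and surviving hits are ranked by
binding-energy estimates from simulation snapshots.

pharmscreen implements that pipeline as plain R with explicit rules and
formulas where the commercial tools keep theirs undisclosed. Everything
stochastic takes an explicit integer seed.

# Feature perception

Perception applies an ordered SMARTS rule table to an explicit-hydrogen 3D
structure (hydrogens are added with idealized geometry when missing,
because donor detection needs them). The default rules are:

* **HBD** — O–H, N–H, S–H; the feature sits on the heavy atom.
* **HBA** — any oxygen; nitrogens with no attached hydrogen, excluding
  amide and aniline-type N and quaternary N.
* **HYP** — contiguous groups of ≥ 3 apolar, non-aromatic carbons
  (no N/O/P/S neighbour), centroid of the group; plus halogens on aromatic
  rings.
* **RA** — aromatic rings (minimum-cycle-basis perception; Kekulé
  alternation or explicit aromatic bond orders), centroid of the ring.
* **PI** — protonatable amines, amidines/guanidines, cationic N.
* **NI** — carboxylic acids/carboxylates and phosphates.

Features are deduplicated on (kind, heavy source atoms), so an NH~2~ is
one donor feature, and property counting (HBD/HBA for the rule-of-five
gate) is consistent with perception. Default tolerance radii are 1.6 Å
(1.7 Å for HYP), common values in pharmacophore tools; both rules and
tolerances are user-overridable through a plain-text table
(`read_feature_rules()`).

The SMARTS engine supports the subset needed for such rules — element and
aromaticity primitives, `#n`, `Hn`, `Xn`, charge signs, `!`/`&`/`,`/`;`
logic, branches, single-digit ring closures and recursive `$(...)`
environments — and rejects everything else at parse time, so a rules file
either loads completely or fails loudly. No installed R package exposes a
SMARTS matcher that returns matched atom indices (only match counts), so
this component is implemented here.

Aromaticity is a deliberately simple model: 5/6-rings that alternate
single/double bonds (with lone-pair heteroatoms contributing two π
electrons, Hückel-checked) or carry explicit aromatic bond orders. It
covers the ring systems of drug-like molecules; exotic fused heteroaromatics
may need explicit aromatic flags on input.

# Common-feature hypothesis generation

Candidate configurations are subsets (default 4–7 features) of a principal
training member's features. A configuration is retained when **every**
member maps it within its per-member omission allowance (`max_omit`; 0
reproduces the strict setting, 1 the "all but one feature" convention for
moderately active members). Matching is clique search on the
correspondence graph: nodes are same-kind feature pairs, edges connect
pairs whose interfeature distances agree within the match tolerance
(default 1.0 Å, a single scalar during enumeration — sphere tolerances
apply at fit time). The instances involved are small enough that
exhaustive clique extension is exact; tests verify agreement with a
brute-force enumeration of all correspondences.

Retained hypotheses are ranked by the package's own score — the sum over
members of the best fit value — with ties broken by more features, then by
the lexicographic kind string. The ranking and selectivity scores printed
by commercial suites have undisclosed formulas and are deliberately **not**
reproduced; receptor-derived hypotheses report selectivity as
"not computed" (`NA`).

# Structure-based derivation and contact classification

From a receptor–ligand complex, features are read off interaction
geometry, all positioned on ligand coordinates:

* hydrogen bonds: heavy-atom distance ≤ 3.5 Å and donor–H···acceptor
  angle ≥ 120° (distance-only when the structure carries no hydrogens,
  as in most PDB files);
* hydrophobic: contiguous clusters of ≥ 3 apolar ligand carbons within
  4.5 Å of apolar receptor atoms, centroid feature;
* aromatic stacking: ring-centroid distance ≤ 5.5 Å.

`classify_contacts()` assigns each heavy-atom pair at most one class with
priority hydrogen_bond > aromatic_stack > hydrophobic > van_der_waals
(residual contacts ≤ 4.0 Å). These cutoffs are conventional values for
interaction fingerprinting and are all configurable
(`interaction_rules()`).

# Mapping, screening and validation

A ligand maps a hypothesis through the highest-fit kind-respecting
correspondence (clique condition as above, at least `max_fit − allow_omit`
features matched). Matched centroids are superposed by Kabsch least
squares (reflection-corrected), and

$$\mathrm{fit} = \sum_i \max\!\left(0,\; 1 - (d_i/t_i)^2\right)$$

over matched features. All cliques of admissible size are scored, not only
maximal ones, because superposition couples the deviations; ties prefer
fewer omissions, then the lexicographically smallest pairing, making the
result deterministic. A compound *passes* a screen when any mapping exists
at the configured omission allowance — published screens report
mapped/not-mapped counts, so no fit threshold is applied by default.

Decoy-set validation derives the Güner–Henry statistics from the screen's
confusion counts. GF and the percentage rows are reported both at full
precision and truncated (floor) to two decimals: published validation
tables use truncation, which is observable in cells where rounding would
differ (e.g. GF 0.75929 printed as 0.75, 0.65745 as 0.65). Two derived
cells in the published table that motivated this package (one false-positive
and one false-negative/false-positive pair) are inconsistent with the
table's own definitions A−Ha and Ht−Ha; the package computes the
definitions. ROC analysis uses the Mann–Whitney AUC (ties ½) and reports
sensitivity/specificity at a user threshold.

The decoy-set composition follows the validation protocol the pipeline
emulates: D = 110 compounds with A = 6 actives (IC~50~ < 100 nM criterion
recorded as metadata). One source section of the protocol mentions 106
inactives; the counts D and A are taken as authoritative (104 inactives).

# Drug-likeness gating

The rule-of-five gate passes compounds with AlogP ≤ 5, HBD ≤ 5, HBA ≤ 10
and weight ≤ 600 Da (inclusive boundaries; the weight bound is the
extended natural-product convention, configurable). AlogP is an
atom-additive estimate over a small class scheme whose contribution table
ships as plain text (`extdata/alogp_contributions.tsv`) for
reproducibility — it is a transparent estimator in the Ghose–Crippen
tradition, not a reimplementation of any proprietary descriptor.

The ADMET gate requires absorption level 0, solubility level 3, BBB
level 3 and negative CYP2D6/hepatotoxicity flags — the level semantics of
the screening suites this surrogate replaces. The built-in predictor is an
explicitly rule-based surrogate (bands over AlogP, weight and polar-atom
counts); user-supplied levels override it verbatim, which is the intended
path when real predictions are available. The two gates are pure
per-compound functions, so their composition is order-independent (tested).

# Energetics

Binding energies follow ΔG~bind~ = G~complex~ − (G~protein~ + G~ligand~),
decomposed into van der Waals, electrostatic, polar-solvation and
nonpolar (SASA) components, kJ/mol throughout (kcal/mol converted on
input). Snapshot series — read from TSV or generated synthetically — are
aggregated over a window defaulting to the final 10 ns, the conventional
stable-tail protocol with 40 snapshots. Mean ΔG equals the sum of
component means exactly (linearity; tested to 10⁻⁹). Entropic terms are
not computed, matching the MM-PBSA convention the pipeline consumes.

For toy end-to-end systems the package provides pairwise 12-6
Lennard-Jones + Coulomb sums (Lorentz–Berthelot combination, Coulomb
constant 138.935458 kJ·nm/(mol·e²), 1-2 and 1-3 bonded exclusions) and
Shrake–Rupley SASA on a deterministic Fibonacci quadrature (default 960
points, ≤ 1% sphere error; error at least halves at 3840 points). The
nonpolar energy is γ·SASA + b with γ = 0.0226778 kJ/mol/Å²,
b = 3.84928 kJ/mol, the convention of the common MM-PBSA tooling. Polar
solvation is pluggable: the package consumes provided values rather than
solving the Poisson–Boltzmann equation.

Ranking sorts ascending by mean ΔG with stable input-order ties and flags
every candidate against every reference; the headline selection gate is
"better than the first reference", with per-reference flags kept visible
because borderline candidates (better than one reference, marginally worse
than another) are a real and reportable outcome.

# Trajectory analysis

Computations are in nm internally (Å converted on read). Backbone means
N, Cα, C (O optional, default off). RMSD is per-frame after superposing
the selection onto the reference frame. RMSF is taken about the time-mean
structure after two superposition passes (align to reference, rebuild the
mean, align to the mean) — the reference choice is not standardized in the
literature, and the iterated mean is the stable, documented choice here.
Stability requires the tail-average RMSD and every residue RMSF to be
*strictly* below the 0.3 nm threshold.

# Synthetic-data generators

The generators define the study conditions under which the pipeline is
exercised and tested:

* `gen_planted_library()` — actives as jittered copies (default SD 0.2 Å)
  of a planted ≥ 3-feature arrangement on a fixed well-separated scaffold
  (pairwise distances 4–8 Å, pharmacophore-like); decoys either lack one
  planted kind or have scrambled geometry. A spec requesting the
  all-actives-map guarantee with jitter above tolerance/2 is rejected as
  infeasible.
* `gen_decoy_set()` — defaults D = 110, A = 6; realizes a requested
  confusion table (Ht, Ha) by planting mappable vs unmappable clouds, so
  validation statistics are produced by the *real* mapping path, not by
  faked scores.
* `gen_snapshots()` — independent Gaussian components at configured
  means/SDs (defaults: the strongest reported hit's moments, n = 40 over
  the final 10 ns).
* `gen_trajectory()` — rigid drift (removed by superposition) plus
  per-residue Gaussian jitter; isotropic jitter σ gives per-atom
  RMSF → √3·σ, which the tests verify within 5%.
* `gen_toy_complex()` — contact sites placed 12 Å apart so each requested
  hydrogen-bond/hydrophobic/stacking contact satisfies its rule window and
  nothing else does.

What passing tests on synthetic data do **not** show: recovery of real
chemical-space behaviour (conformational flexibility, tautomers, real
decoy difficulty), real MM-PBSA energetics beyond the configured moments,
or the original study's commercial-tool scores (docking fitness scores,
vendor rank/selectivity values, proprietary library funnel counts, web-service
ADMET predictions) — those depend on tools and data outside this package
and are covered instead by the property-based suites on each replaced
component.

# Problem sizes and numerical choices

The test and demonstration runs use deliberately small instances — 4–100
compound libraries, 110-compound decoy sets, 4-feature hypotheses,
40-snapshot windows, 30–50-residue/≤ 400-frame trajectories, 960-point
SASA quadrature — sizes at which the exhaustive search components are
exact and a full pipeline run takes well under a minute on one CPU.
Degenerate inputs are errors, not silent skips: a training member with
zero perceived features aborts generation (it indicates perception
misconfiguration), Ht = 0 makes GF undefined, single-class ROC input is
rejected, and collinear point sets are flagged degenerate by the
superposition rather than silently resolved.

# Known limitations

* Conformer handling is pass-through: provided conformers (or a single
  OpenBabel embedding for SMILES input) stand in for vendor conformer
  ensembles; ensemble quality is explicitly out of scope.
* No tautomer/protonation-state enumeration.
* The aromaticity and valence models are minimal (documented above).
* The polar-solvation component is consumed, not computed.
* Excluded-volume spheres are not modeled.
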
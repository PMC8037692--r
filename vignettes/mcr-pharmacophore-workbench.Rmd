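---
title: "Designing scaffold-focused antagonist libraries: methods and modelling choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing scaffold-focused antagonist libraries: methods and modelling choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcrpharm)
```

## The problem this package addresses

CD44 is a transmembrane receptor for hyaluronic acid (HA) implicated in
metastasis and chemoresistance; its N-terminal HA-binding domain (HAbd)
carries a druggable subpocket that binds small
1,2,3,4-tetrahydroisoquinoline (THQ) ligands adjacent to the residues
essential for HA recognition. A practical in-silico campaign against this
site has five stages: enumerate a synthetically accessible combinatorial
library around the THQ scaffold, profile its drug-likeness and diversity,
expand compounds into conformers and screen them against an ensemble
pharmacophore distilled from the co-crystallized THQ ligands, post-process
docking poses, and finally post-process molecular-dynamics (MD)
trajectories and binding-energy tables for the surviving candidates. This
package implements each stage as reusable, tested R functions, together
with seeded synthetic-data generators so the whole pipeline can be
exercised and validated without proprietary inputs. Docking engines, MD
engines and Poisson-Boltzmann solvers are deliberately out of scope: their
outputs are inputs here.

## Library enumeration (the combinatorial chemistry stage)

Both reaction schemes couple a THQ secondary amine, an aldehyde and an
isocyanide:

* `ugi_3cr` - the Ugi three-component route, giving the alpha-amino amide
  skeleton R2N-CHR'-C(=O)-NH-R'';
* `ugi_tetrazole` - the Ugi azide variant, giving
  R2N-CHR'-C5(tetrazole) with R'' on tetrazole N1 (hydrazoic acid is the
  implicit fourth component; the aldehyde oxygen leaves as water).

`react()` validates each block against its role (THQ core with a secondary
ring nitrogen; exactly one H-C=O; exactly one terminal, charge-separated
isocyanide), reduces it to an attachable fragment (a rooted SMILES at the
reactive atom) and splices the product. Three choices deserve note:

* **Reactive-site rule.** Only the THQ ring nitrogen reacts. Blocks may
  carry exocyclic amines (one shipped THQ block is ring-aminated exactly to
  exercise this); an aromatic amine is never the Ugi amine here. Two THQ
  cores in one block are refused as ambiguous.
* **Stereochemistry.** The Ugi reaction creates a stereocentre, but
  products are enumerated and deduplicated flat: the canonical key is the
  stereochemistry-free canonical SMILES. Tetrazole regiochemistry is fixed
  to the standard 1,5-disubstitution.
* **Dedup by structure, not by provenance.** Two triples that produce the
  same molecule collapse to one record; libraries store the provenance ids,
  and `regenerate_product()` reproduces any record's structure from them.

With the default synthetic inventory (32 substituted THQ amines x 4
aldehydes x 657 isocyanides, built from fixed substituent vocabularies so
every block is valid and pairwise distinct) each scheme enumerates exactly
84,096 unique products, and the two libraries do not overlap, so the
combined unique count is 168,192.

```{r enumerate, eval = FALSE}
blocks <- load_building_blocks(gen_building_blocks())
lib <- enumerate_library(blocks, "ugi_3cr")   # ~1 min, 84,096 records
```

## Cheminformatic profiling

`compute_descriptors()` fills a fixed roster of 30 descriptors: 21
two-dimensional (the five drug-likeness quantities MW, LogP, TPSA, HBD,
HBA, plus composition, ring, flexibility and topology counts) and 9 shape
quantities from the minimum-energy conformer (principal moments of
inertia, their normalized ratios NPR1 = I1/I3 and NPR2 = I2/I3, radius of
gyration, asphericity, eccentricity, span). LogP, TPSA and molar
refractivity come from OpenBabel's additive models; HBD/HBA use the
classic Lipinski definitions (N/O bearing hydrogen; N + O count). Only the
five named quantities are fixed by the study design; the remaining 25 are
this package's documented choice of standard descriptors.

The extended rule-of-five (`ro5_extended()`) applies MW <= 500 Da,
LogP <= 5, HBD <= 5, HBA <= 10 and additionally TPSA <= 140 A^2 (a
Veber-style polar-surface extension; all limits are arguments). Rows with
failed descriptors are flagged and excluded from the pass rate, never
dropped silently.

Shape classification assigns each conformer to the nearest vertex of the
NPR triangle - rod (0,1), disc (0.5,0.5), sphere (1,1) - after checking
the triangle invariants NPR1 <= NPR2 <= 1, NPR1 + NPR2 >= 1.

Diversity analysis follows the fingerprint route: 166-bit MACCS keys,
Tanimoto dissimilarity `1 - T`, and a two-dimensional t-SNE embedding at
perplexity 50 on a 1,500-compound seeded sample per library
(`sample_library()`). No t-SNE package ships with this stack, so the
package carries an exact (non-tree-accelerated) implementation with
per-point bandwidth calibration, early exaggeration and momentum descent;
it is quadratic per iteration, which is comfortable at panel sizes of a
few thousand. The embedding is treated as qualitative - seeded and
reproducible, but no quantitative claim rests on its coordinates;
clustering quality is always computable from the returned dissimilarity
matrix as well. `cluster_by_silhouette()` runs seeded k-means over a k
range and keeps the silhouette-optimal k; a best silhouette below 0.4
raises a low-structure warning, the level an unstructured single blob
stays under while genuinely separated mixtures sit far above. Whether the
study's six clusters were silhouette-selected or imposed is ambiguous in
the source; both modes are available (pass a single-element `k_range` to
impose k).

`pca_nonredundant()` prunes the descriptor table to 10 non-redundant
columns before PCA: while more than 10 remain and some pair exceeds
|r| > 0.9, the lower-variance member of the most correlated pair is
removed; if the threshold is exhausted first, the highest-variance
descriptors are kept. The source names only "selected by their
correlation"; the variance ranking is this package's documented
tie-break, and pruning is idempotent by construction.

## Conformer expansion

`generate_conformers()` produces exactly 20 conformers per compound
(configurable), ranked by relative MMFF94 energy. The pipeline is fully
deterministic under its seed, which drove one substantive design choice:
every stochastic 3D builder available in the toolchain is
non-reproducible run to run, so the base geometry is built from the
deterministic 2D layout, a fixed sinusoidal out-of-plane perturbation
(an exactly planar start is a saddle point of the force field), and MMFF94
steepest-descent relaxation, which reaches relaxed geometries comparable
to stochastic embedding on the chemistry enumerated here.
Conformer diversity then comes from seeded torsion sampling of
all rotatable bonds (acyclic single bonds between non-terminal heavy
atoms, amides excluded), batch MMFF94 relaxation, energy ranking and
deduplication at 0.1 A heavy-atom RMSD (a choice; the source is silent on
deduplication). Rigid molecules that cannot reach the requested count are
flagged incomplete and excluded from screening totals. The count identity
"two 84,096-compound libraries x 20 = 3,363,840 conformers" is verified
as arithmetic plus exact-20 checks on a 100-compound seeded sample;
full-scale generation is not a test-time activity.

## Ensemble pharmacophore

`perceive_features()` types features at pH 7.4: aromatic ring centroids,
donors at N/O bearing hydrogen, acceptors at oxygens and lone-pair
nitrogens, positive-ionizable aliphatic amines (the THQ ring nitrogen is
protonated at this pH; aryl amines are not), carboxylate-type negative
centres, and all-carbon ring centroids as hydrophobic points.
`build_ensemble_model()` pools same-kind features across pre-aligned
ligands, merges those agreeing within 0.5 A (complete linkage) and keeps
clusters with support >= 0.5 - both parameters explicit, replacing the
source's visual feature selection. On the packaged 21-copy ensemble of the
hydroxy-THQ reference (sigma = 0.1 A) the model contains exactly four
features: one aromatic, two donors, one positive centre.

`match_conformer()` reports the minimum RMSD over kind-respecting
one-to-one assignments of model features to conformer features (exhaustive
within each kind; feature counts per kind are small), unmatched with a
reason when a kind is missing. By default the conformer is taken in the
model frame; `align = TRUE` adds a Kabsch fit over the best
correspondence. Receptor-aware local optimization is out of scope; an
optional heavy-atom clash filter against a receptor structure (1.5 A
cutoff) stands in during screening. Models persist as JSON
(kind/center/tolerance/support).

## Pose analysis

`substructure_rmsd()` computes in-place (no refit) heavy-atom RMSD over a
matched substructure, minimized over *all* pattern embeddings including
ring automorphisms (element-colored VF2 subgraph isomorphism with
bond-order filtering); in-place is the crystallographic convention when
pose and reference share the receptor frame, and a Kabsch-fitted variant
is an explicit option. The test suite holds this minimization equal to an
independent brute-force backtracking matcher on a thousand randomized
cases. On top of it sit `redock_validation()` (any pose under 3 A
reproduces the crystal mode), `match_frequency()` (exact k/N counts under
a 2 A THQ-anchored threshold; the /50 denominator pools 25 saved poses
for each of two receptors, and pooling is configurable),
`pocket_selectivity()` (pockets ranked by best score under a
header-declared convention - never guessed - with top ties counting as
similar affinity) and `cluster_poses()` (agglomerative clustering cut at a
distance threshold, best-scored member as representative for MD seeding).

## Receptor-structure comparison

`pairwise_identity()` is Needleman-Wunsch global alignment (BLOSUM62, gap
opening 10, extension 0.5 - the source does not state penalties, so these
standard values are documented defaults) with identity = matches over
aligned columns excluding terminal gaps (alternative denominators
selectable). Residue pairing for `superpose()` and
`ensemble_rmsd_profile()` follows the alignment, not residue numbers,
because orthologous chains may be offset in numbering; superposition is
the Kabsch least-squares fit over CA, backbone or all heavy atoms, and
profiles report per-residue deviations indexed by reference numbering with
gaps (not failures) at unpairable residues. Real PDB entries are accepted
from local files, with a network-requiring `fetch_pdb()` convenience; the
test suite never depends on network access and validates the aligner by
exact recovery of planted sequence divergence on synthetic homolog pairs.

## Trajectory post-analysis

`rmsd_series()` superposes each frame on the reference over the selection
before measuring; `rmsf_profile()` aligns to the iterated mean structure
and reports per-residue fluctuations (under isotropic per-coordinate
jitter sigma the profile converges to sigma*sqrt(3); a small deficit of
order 6 degrees of freedom over 3N coordinates is absorbed by the rigid
fit, which is why the convergence fixture uses backbone atoms rather than
a handful of CAs). `water_occupancy()` counts water oxygens within a 6 A
sphere - inclusive boundary, minimum-image distances under the periodic
box - around either a fixed point or the per-frame CA centroid of named
pocket residues; the source does not say whether its sphere was fixed or
tracked, so both modes exist, with the tracked pocket as default.
`ligand_residency()` declares departure only after the ligand centroid
stays outside the radius for a persistence window (default 10 frames), so
single-frame excursions do not count. `detect_interactions()` applies
standard geometric cutoffs (hydrogen bond 3.5 A with a 130-degree
donor-H-acceptor angle when hydrogens exist, falling back with a warning
to heavy-atom distance otherwise; water bridges via a shared hydrogen-
bonded water; pi-cation 6.0 A; carbon-carbon contacts 4.0 A; salt bridges
5.5 A - all configurable), and `interaction_frequencies()` reports
per-residue, per-kind fractions of frames; kinds are not exclusive, so no
sum rule is imposed.

## Energy aggregation

The MM/PBSA stage consumes per-frame component tables (molecular-mechanics,
polar and nonpolar solvation differences, complex minus receptor minus
ligand) in a documented CSV schema mirroring common solver output;
`frame_binding_energy()` is their sum (the entropy term is omitted,
matching the stated components), `summarize_energy()` adds means, SDs and
a large-fluctuation flag, and `per_residue_map()` classifies time-mean
residue contributions as favorable (negative) or unfavorable (positive) -
the sign convention under which a repulsive residue contributes
positively. When the generator plants a per-residue partition, the map
conserves each frame's total to numerical precision.

## The synthetic-data generators

Every stage has a seeded generator producing files/objects the stage
consumes, with ground truth attached: building blocks at the 32/4/657
inventory shape (deterministic, all-valid, pairwise distinct, Ro5-mixed by
construction); aligned ligand ensembles as Gaussian-perturbed copies
(sigma = 0.1 A default, emulating a sub-Angstrom crystallographic spread
of a shared binding mode across 21 ligands); pose sets built from pure
rigid translations so the planted below/above-threshold counts are exact
by analytic argument rather than by circular measurement; toy-helix
trajectories with resident or departing ligands and waters pinned inside
or held outside the monitored sphere; energy tables with exact per-residue
partitions. What they deliberately do not emulate: real conformational
correlation, solvent structure, force-field physics, or docking score
distributions - so green tests certify the analysis contracts (counts,
geometry, statistics, bookkeeping), not biological validity on real data.

## Problem sizes and numerical choices

The shipped validation runs at these scales: full 84,096-product
enumeration per scheme (about a minute each); conformer checks on a
100-compound sample at 20 conformers each; a 10,000-frame jitter fixture
for RMSF convergence; 1,000 randomized cases for the substructure-RMSD
oracle; 40 seeded runs for silhouette-k recovery. Tolerances follow the
quantity: exact equality for counts and planted integers, 1e-9 for
geometric identities, 5% for stochastic convergence laws. Degenerate
inputs are contracts, not surprises: empty role classes, all-identical
fingerprints, missing feature kinds, waterless trajectories and
single-frame trajectories all raise typed errors or warnings tested in
the suite.

## Known limitations

* Reaction generality is scoped to the two Ugi routes; other MCRs would
  need new transforms.
* The conformer search is torsion-grid based; ring conformers beyond the
  force-field relaxation basin are not sampled, and MMFF94 energies are
  not a substitute for the original conformer generator's strain model.
* Aromaticity is perceived from Kekule tables, adequate for the chemistry
  enumerated here but not a general aromaticity model.
* The t-SNE implementation is exact and therefore quadratic; use sample
  panels, not full libraries.
* Identity figures for real receptor pairs require the user to supply the
  structures (or network access for `fetch_pdb()`); the packaged evidence
  for the aligner is synthetic-recovery based.
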
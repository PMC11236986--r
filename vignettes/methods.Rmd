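---
title: "Methods: library triage and interaction profiling in chemtriage"
author: "chemtriage authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: library triage and interaction profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemtriage)
```

## Scope and model

`chemtriage` implements the computational core of a ligand-based +
structure-based discovery workflow against tissue transglutaminase (TG2), an
enzyme whose catalytically active *open* conformation exposes a saddle-shaped
active site organized around the nucleophilic cysteine C277, the charge-relay
pair H335/D358, and the auxiliary residues W241, H305, E363, N333, W332 and
Q169. The package covers two workflows:

* **Library triage** (`run_triage()`): potency-filtered actives are
  fingerprinted, clustered, and reduced to cluster representatives; a
  candidate library is searched for analogs of those representatives,
  triaged with PAINS and rule-of-five filters, and mined for frequent
  Bemis-Murcko scaffolds, which are finally intersected across datasets.
* **Structure profiling** (`run_profile()`): protein-ligand complexes are
  profiled geometrically - close contacts and hydrogen bonds, pi-stacking
  classes, occupancy of the three active-site cavities, and
  catalytic-residue deviations across superposed structures.

Chemistry parsing, canonical SMILES, SMARTS matching and the Crippen-type
clogP are delegated to the OpenBabel substrate (ChemmineR/ChemmineOB); all
pipeline logic above the substrate - fingerprints, similarity, clustering,
scaffold pruning, thermodynamics, geometry classification - is implemented in
this package.

## Thermodynamics

Assay potencies are converted to molar Gibbs free energies with

$$\Delta G = R\,T\,\ln\!\left(\frac{K_d}{c}\right),\qquad c = 1\ \mathrm{M},$$

with $R = 1.987\times10^{-3}$ kcal/(mol K). IC50 values are used directly as
$K_d$ when comparing assay data with docking energies; a Cheng-Prusoff
correction is intentionally out of scope because the substrate-competition
parameters are rarely available for heterogeneous extracts. The temperature
default is 298.15 K; both choices are recorded in every report header since
the upstream workflow states neither. At the 500 nM activity threshold this
gives $\Delta G \approx -8.60$ kcal/mol:

```{r dg}
dg_from_kd(500e-9)
ligand_efficiency(dg_from_kd(500e-9), 28)
```

Ligand efficiency (LE) is $\Delta G$ per heavy atom; a 28-atom compound at
500 nM sits at $-0.31$ kcal/mol per heavy atom, inside the 0.2-0.35
magnitude band typical of this target's scaffold series.

## Fingerprints and similarity

`circular_fingerprint()` is a hashed Morgan-type extended-connectivity
fingerprint, radius 3 over 2048 bits by default. Atom invariants are
(element, degree, bond-order sum, implicit H count, formal charge, ring
membership, aromaticity); each iteration re-hashes an atom's invariant with
its sorted (bond order, neighbor invariant) list, and all environment
identifiers from radius 0 upward are folded onto the bitset modulo `nbits`.
Bit collisions are accepted, the standard behavior for hashed fingerprints.
Two design points matter:

* **Order independence.** Neighbor contributions are sorted before hashing
  and molecules are built from their canonical SMILES, so the bitset is
  invariant to how the input SMILES was spelled. Both mechanisms are tested
  independently (the hashing alone, on deliberately non-canonicalized atom
  orders; and the full path, on spelling variants).
* **Salt stripping.** The largest covalent fragment is kept before any
  computation (library SMILES frequently carry counterions); the number of
  stripped fragments is kept on the molecule and surfaced in triage
  manifests.

Tanimoto similarity is $|A\cap B|/|A\cup B|$ over set bits, with two empty
fingerprints defined as identical (similarity 1).

## Clustering and scaffolds

`butina_cluster()` is sphere-exclusion clustering: neighbor lists are built
at Tanimoto distance $\le$ cutoff, then the unassigned item with the most
unassigned neighbors repeatedly seeds a cluster and captures its unassigned
neighbors. Ties break by input order, so runs are exactly reproducible. The
similarity-search threshold (0.3) is a stated workflow constant, but no
clustering cutoff is; the package default of 0.4 Tanimoto distance follows
common practice for 2048-bit circular fingerprints.

`murcko_scaffold()` prunes terminal non-ring heavy atoms to a fixed point,
leaving ring systems plus linkers. Note one convention consequence: an
exocyclic double-bonded terminal atom (e.g. a ring C=O oxygen) is also
pruned, which differs from implementations that retain attached `=O`.
Scaffold identity is the canonical SMILES of the pruned subgraph; a generic
(all-carbon, single-bond) framework mode exists behind a flag.
`scaffold_frequency()` uses an inclusive threshold (frequency $\ge$
min_count, defaults 5 for reference extracts and 20 for large candidate
libraries), with acyclic molecules excluded and counted separately.

## Group outliers

Two outlier rules run side by side, because boxplot-based figures and
stated kcal/mol rules are both in common use:

* **Leave-one-out median rule** (`flag_group_outliers()`): a compound is
  flagged when its $\Delta G$ deviates from the median of the *other* group
  members by more than 1.0 kcal/mol, or its LE by more than 0.5.
* **Tukey whiskers** (`whisker_outliers()`, via `boxplot.stats`): points
  beyond 1.5 IQR past the hinges.

Both outputs are reported by `scaffold_group_stats()`; they agree on
clear-cut outliers and differ only near their respective thresholds.

## Geometry classification

All cutoffs are configuration values with defaults that follow common
structural-biology practice, and every report embeds the values used:

| quantity | default | meaning |
|---|---|---|
| `hbond_max` | 3.5 A | max donor-acceptor distance (both atoms N/O/S) |
| `contact_max` | 4.0 A | max heavy-atom distance for any close contact |
| `d_stack_max` | 5.5 A | max ring-centroid distance |
| `angle_parallel_max` | 30 deg | max interplanar angle for parallel classes |
| `offset_parallel_max` | 1.5 A | parallel vs parallel-displaced split |
| `angle_t_min` | 60 deg | min angle for T-shaped |
| `cavity_capture` | 4.0 A | ligand-to-cavity-residue capture radius |

Hydrogen bonds are heavy-atom, distance-only (no explicit-hydrogen angle
term): the profiled complexes are heavy-atom models. Interplanar angles are
folded to [0, 90] degrees; the lateral offset is the displacement of the
ligand ring centroid within the protein ring plane. Ring pairs at
intermediate angles (30-60 degrees) are reported as `unclassified` rather
than forced into a class. Protein rings come from named Phe/Tyr/His/Trp
side-chain atoms; ligand rings are planar 5/6-cycles (RMS out-of-plane
< 0.15 A) of a distance-based bond graph (bond < 1.75 A).

The active site is modeled as three cavities - catalytic
(C277/W241/W332/H335), surface (Q169), and a wide pocket whose membership is
user-supplied because no authoritative residue list exists for it - and a
binding mode is accepted when the ligand occupies at least two of the
three. A ligand sulfur within covalent range (2.3 A) of the C277 SG can be
removed before profiling (`remove_bridging_sulfur()`), mirroring the
preparation used for covalently bound peptidomimetics.

Superposition is the Kabsch algorithm (SVD with determinant correction)
over atoms paired by chain/residue/atom-name; `residue_deviations()`
superposes on shared C-alpha atoms and reports per-residue heavy-atom RMSD,
with missing residues flagged rather than fatal, since partial models with
unresolved active-site loops (e.g. E319-K327) are the norm for this target.

## Alignment masking

`mask_msa_alanine()` implements the conformation-biasing preparation step:
in the alignment columns spanned by target residues 276..336 (UniProt
numbering; guard letters Q at 276 and C at 336 are verified to catch
off-by-one numbering), every amino-acid letter is replaced by alanine.
Gaps are untouched; A3M lowercase insertion states neither occupy columns
nor are masked (except insertions of the target itself inside the range,
which are masked in the target only). Masking applies to all sequences by
default - the stronger conformational bias - with a flag to restrict it to
the target.

## Synthetic data: what it emulates, what it does not

The generators provide every input type with planted ground truth:

* `gen_library()` builds compounds as scaffold + small acyclic decorations
  (halogens, alkyl, methoxy, sulfonamide, carboxamide - sulfonamide included
  deliberately, as the dominant group in realistic TG2-targeted scaffolds),
  guaranteeing by construction (and asserting) that every compound
  Murcko-reduces to its planted scaffold. IC50s are log-normal (median
  150 nM, geometric SD 2.0), the conventional noise model for potency data.
  Default scaffolds are lead-series-sized ring systems (15-18 heavy atoms:
  4-anilinoquinazoline, 2-phenylbenzoxazole, 1-benzyl-4-phenylpiperazine):
  fingerprint clustering of a decorated series is only informative when the
  scaffold carries most of the substructure signal, which is the realistic
  regime for target-focused libraries. With single-ring scaffolds the
  within-series Tanimoto similarity falls below the between-series range
  and no fingerprint method can recover the grouping. Decorated series
  spread to within-series Tanimoto distances of about 0.55, so the
  cluster-recovery checks run at cutoff 0.6 (the package default for real
  data remains 0.4).
* `gen_complex()` realizes each requested interaction analytically in its
  own pocket, 30 A from the next, with a seeded random rigid rotation per
  pocket; planted distances/angles/offsets are exact. Stacked ring pairs
  necessarily contribute extra carbon-carbon close contacts, so planted
  close-contact counts are exact only for ring-free complexes and are a
  lower bound otherwise; hydrogen-bond counts and stacking classes are
  always exact.
* `gen_docking_table()` draws per-scaffold scores with bounded noise
  (uniform, half-width 0.3 kcal/mol) and displaces each planted outlier by
  $8\sigma + 2$ kcal/mol, far past both outlier rules. The generator
  verifies its own truth and redraws a group's inliers (deterministically,
  inside the seeded stream) in the rare event noise alone would trip a
  rule - so recovery is exact by construction, which is the point: the
  recovery checks test the statistics code, not the noise draw. Heavy-atom
  counts are constant within a scaffold group (same-scaffold series are
  size-homogeneous), so LE whisker outliers coincide with binding-energy
  ones; the leave-one-out LE rule flags a displaced compound only when the
  displacement divided by the heavy-atom count exceeds 0.5, and the planted
  truth accounts for that.

None of the generators emulate conformational flexibility, tautomerism,
measurement-protocol heterogeneity, or physically realistic protein folds.
Passing the recovery checks therefore demonstrates correctness of the
pipeline's logic under its stated assumptions, not performance on noisy
experimental extracts.

## Numerical choices and degenerate inputs

* Fingerprint hashing uses exact modular arithmetic below $2^{31}-1$ in
  doubles; no platform-dependent hashing.
* Tanimoto of two all-zero fingerprints is 1 by definition; Butina ties
  break by input order; cluster ordering is size-descending with
  first-appearance tie-break.
* Acyclic molecules have no scaffold (`NULL`, counted separately), and
  acyclic scaffolds are rejected by the library generator.
* Single-atom molecules bypass a substrate limitation (its atom-block for
  one-atom molecules is a placeholder) through a direct constructor.
* Non-positive IC50s are rejected with a warning, never silently; singleton
  groups are skipped with a warning in outlier analysis and reported
  without whisker outliers in docking statistics.
* Superposition requires at least 3 paired atoms; pairing is by
  chain/residue/atom-name, and pose RMSD is deliberately non-superposed
  (docked and reference poses share the receptor frame) with strictly
  name-based pairing and no symmetry correction.

## Problem sizes used in the checks

The recovery checks run at the scale the workflow itself describes: 3
planted scaffolds x 25 compounds over 10 seeds for scaffold/cluster
recovery; 200 random fingerprint sets of up to 10 molecules against the
brute-force clustering reference; 50 seeded complexes (geometries kept at
least 5 degrees / 0.3 A away from classification boundaries) for the
interaction profiler; 12 groups x 5 compounds over 20 seeds for outlier
recovery; 10 random rigid motions for superposition recovery. These sizes
keep the full suite within a few minutes on one CPU while exercising every
decision branch.

## Known limitations

* clogP is the substrate's atomic-contribution value; no experimental logP.
* Stereochemistry is preserved in SMILES but not encoded in fingerprints.
* Murcko pruning removes exocyclic double-bonded terminal atoms (see
  above); scaffold tables built with other toolkits may differ for ring
  systems carrying exocyclic carbonyls.
* The wide active-site cavity has no default residue membership; cavity
  occupancy is reported for however many cavities are defined.
* Hydrogen-bond detection is distance-only and heavy-atom-only, so polar
  contacts with unfavorable geometry are still counted as hydrogen bonds.
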
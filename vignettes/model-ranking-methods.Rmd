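---
title: "Ligand-guided ranking of GPCR homology-model ensembles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ligand-guided ranking of GPCR homology-model ensembles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modelrank)
```

## The problem

When no crystal structure of a receptor exists, structure-based virtual
screening has to start from homology models — and a modelling run typically
produces hundreds or thousands of them, differing mostly in loop and
side-chain conformations. Docking scores are a poor guide for choosing among
them, because they correlate weakly with binding affinity. For aminergic
G-protein coupled receptors there is, however, one interaction that is
essentially non-negotiable: the salt bridge between a positively charged
amine of the ligand and the conserved aspartate at Ballesteros–Weinstein
position 3.32. `modelrank` turns that single, reliable interaction into a
model-selection score: dock a small set of known actives into every model,
and rank the models by the fraction of docking poses that can form the
charged contact.

## The score

For one receptor model and one docking run with $n$ poses, the score is

$$ s \;=\; \frac{1}{n}\sum_{p=1}^{n} \mathbf{1}\!\left[\, d_p \le 6\,\text{Å} \,\right], $$

where $d_p$ is the minimum Euclidean distance between the carboxyl **carbon**
of the anchor residue (CG for aspartate, CD for glutamate — the carbon, not
the oxygens) and any formally cationic ligand atom in pose $p$. The boundary
is inclusive: 6.00 Å counts, 6.01 Å does not. "Positively charged amine" is
generalized to *any* atom with formal charge ≥ +1, because screened head
groups (guanidino, tetramethylpiperidino, quaternary amines) place the formal
charge on different atoms depending on the file dialect; the rule is
charge-based, not element-based.

Docking is stochastic, so the protocol runs it twice; a model's aggregate
score is the arithmetic mean of its per-run fractions (the pooled fraction
over all poses is reported alongside for transparency). Ranking is by
aggregate score, descending; ties break on smaller between-run discrepancy,
then lexically on model id, which makes the ranking fully reproducible. The
replicate-mean (rather than pooled) reading was chosen because the reference
protocol reports a two-run *average* score; with equal pose counts per run
the two differ only when runs have unequal sizes.

## Locating the discriminating conformations

Given the `k` best and `k` worst ranked models (default `k = 10`), the
package superposes all `2k` models onto the pooled-ensemble mean using a
backbone heavy-atom fit, averages coordinates within each group, and reports
the per-atom distance between the two group means, sorted descending. The
superposition target and fit subset are deliberate choices — they are not
dictated by the reference protocol, which does not state them. Fitting on the
backbone makes the per-atom differences reflect side-chain rearrangement
rather than global rigid drift; using the pooled mean avoids privileging
either group. The default report subset is the side chains, since backbone
positions are largely template-driven in homology models.

On the synthetic study this analysis recovers the planted ground truth: the
carboxyl oxygen of the glutamate at 5.46 tops the report at its planted
displacement, with the distal carbon of the leucine at 7.42 as the secondary
signal.

## RMSD decomposition

Ensemble variability is summarized as per-model RMSD to a reference after a
backbone heavy-atom Kabsch fit, decomposed into backbone and side-chain
subsets evaluated under that *single* fit, so that

$$ n_\text{all}\,\text{RMSD}_\text{all}^2 =
   n_\text{bb}\,\text{RMSD}_\text{bb}^2 +
   n_\text{sc}\,\text{RMSD}_\text{sc}^2 $$

holds exactly (to numerical precision); the test suite asserts it at 1e-9
relative. The reference is the ensemble mean, computed deterministically by
one round of iterative fitting: fit all models to the first model, average,
refit once to the average, re-average. Whether published ensemble RMSDs of
this kind are to-mean or pairwise averages is often unstated; the package
computes the to-mean figure as the headline and can add the all-pairs average
on request (`include_pairwise = TRUE`), which is quadratic in ensemble size.

Hydrogens are excluded from every geometric analysis; only heavy atoms are
compared. Backbone means atoms named N, CA, C, O (plus OXT); everything else
heavy is side chain; the two partition the heavy-atom set by construction.

Degenerate inputs: the Kabsch fit refuses fewer than 3 point pairs and
collinear configurations (rotation not identifiable); reflections are
excluded by the usual determinant correction, so the rotation is always
proper.

## Residue numbering

Ballesteros–Weinstein labels are resolved through a user-supplied map
(TSV: `bw_label`, `chain`, `resnum`, `resname`) — never computed from a
sequence alignment, which is out of scope and error-prone. The map validates
the expected residue name against the structure, so a mis-specified map fails
loudly instead of silently scoring the wrong residue. Position 7.39 is a
known ambiguity in the literature for this receptor family (reported as
proline in site definitions and phenylalanine in interaction analyses); the
package does not hard-code either identity — the map decides. Similarly, an
occasional reference to "E5.42" in the source literature is treated as a typo
for E5.46.

## Extended interaction fingerprint

Beyond the headline ionic contact, `extended_fingerprint()` reports simple
geometric events per binding-site residue: hydrogen bond (polar heavy atoms
within 3.5 Å), pi-cation (cation within 6.0 Å of an aromatic ring centroid),
and hydrophobic contact (carbon–carbon within 4.5 Å). These thresholds are
package conventions — configurable, documented, and *excluded* from the
ranking score, because perception-tool geometric criteria vary. Pi-cation
detection is restricted to aromatic residues (PHE, TYR, TRP, HIS); reports of
"pi-cation to an aspartate" in the literature are perception-tool
idiosyncrasies that this package deliberately does not reproduce.

## Bioactivity curation

The curation pipeline filters ChEMBL-style activity tables in a fixed stage
order — molecular weight ≤ 500 Da, confidence score = 9, activity type in
{Ki, Kd, IC50, EC50}, relation "=", value ≤ 10, unit nM, unambiguous
stereochemistry — attributing every dropped record to the *first* stage it
fails. Both value boundaries are inclusive (a 10.0 nM record survives).
Records with `NA` in a filtered column fail at that stage: a record that
cannot be verified to satisfy a filter is not kept. Reordering stages changes
the per-stage attribution but never the kept set (a tested invariant).
Deduplication prefers binding over functional data, then newer over older,
then lower values, then stable input order. Stereo ambiguity enters as a
precomputed boolean column: deciding it from SMILES belongs to a
cheminformatics layer (unassigned stereocenter detection), whose verdict is
cached into `stereo_clear` — this keeps the pipeline testable without
chemistry. Fingerprint *generation* (Morgan/ECFP-like, diameter 4 = radius 2)
is likewise delegated: `tanimoto()` and `maxmin_pick()` operate on abstract
bit/feature sets from any source. Two empty fingerprints are defined as
similarity 1 — indistinguishable objects should not count as maximally
diverse — and the case is logged.

`cheng_prusoff()` implements $K_i = \mathrm{IC}_{50} / (1 + L/K_d)$ and
`to_pki()` the molar $-\log_{10}$ transform, both with strict positivity
checks.

## The synthetic study

The fixture generator is first-class, tested code: it stands in for the
modelling, docking and database layers so the whole method is exercisable
offline. Its defaults *are* the study conditions:

* **1000 models**, built from a hand-made seven-helix template (232 heavy
  atoms, 28 residues) whose binding site carries the anchor aspartate at
  3.32, a glutamate at 5.46, aromatics at 3.33/4.56/6.48/6.51/7.39 and a
  leucine at 7.42. The geometry is schematic — atom names, subsets and
  distances behave like a protein's; the chemistry is not force-field
  realistic, so nothing about energetics can be concluded from it.
* **Coordinate noise**: isotropic Gaussian with per-atom RMS displacement
  0.4 Å on backbone and 1.6 Å on side-chain atoms (per-coordinate sd is
  σ/√3). With this convention the ensemble's expected RMSD-to-mean per subset
  is approximately σ itself, so the defaults reproduce the flexibility scale
  typical of GPCR homology-model ensembles (≈1.2 Å over all heavy atoms).
* **9 ligands × 10 poses × 2 runs** per model, each pose a minimal cationic
  fragment (a charged nitrogen plus two carbons) placed at a controlled
  distance from the anchor carboxyl carbon of *that very model*: interacting
  poses in the 4.0–5.5 Å window, non-interacting in 7.0–12.0 Å. The ≥ 0.5 Å
  gap around the 6 Å boundary guarantees that scoring recovers the planted
  per-model fraction exactly, which is what makes parameter-recovery tests
  meaningful. Ligand fixtures are deliberately minimal valid SDF molecules,
  not real chemotypes; they exercise file I/O and charge handling.
* **Planted score distribution**: one top model at 75/90 per run, a quarter
  of the ensemble at or below 0.1 (including ~0.7% exact zeros — 7 models at
  the default size), the rest uniform over the mid-range. A two-run average
  of 0.835 is not representable as a mean of two k/90 fractions
  (0.835 × 180 is not an integer), so the top model is planted at 75/90 =
  0.8333 in both runs.
* **Planted displacements**: low-scoring models (aggregate ≤ 0.1) carry a
  4.7 Å shift of the 5.46 carboxyl oxygen and a 2.1 Å shift of the 7.42
  distal carbon, both directed radially out of the pocket — emulating a side
  chain flipping out of the binding site.

Every random draw is a pure function of (master seed, model index, run
index), so generation is reproducible, chunkable, and byte-identical across
reruns — the end-to-end test asserts file-level md5 equality.

What passing tests on these fixtures shows: the scoring criterion, the
aggregation/ranking arithmetic, the geometry, and the curation logic are
correct against independently computed ground truth. What it does not show:
anything about real docking-pose quality, force-field energetics, or the
biology of any particular receptor — those live in the modelling and docking
engines this package deliberately does not contain.

## Problem sizes and numerical conventions

The test suite runs the complete default-scale pipeline (1000 models,
180 pose sets, written to disk and read back) once, plus Monte-Carlo checks
at 100 seeds × 100 models for the noise-scale property and 100 seeds of
10-vs-10 group comparisons for displacement recovery; the Kabsch optimality
check compares against an exhaustive 2° Euler-angle grid (≈3 × 10⁶
rotations) on 20 random 4-point instances. These sizes were chosen to make
the statistical assertions sharp (≥ 99/100 seed criteria) while keeping a
full run on one CPU comfortably under half an hour.

Tolerances: exact-arithmetic claims (planted fractions, tie-breaks, counts)
are asserted with zero tolerance in memory and 1e-12 after CSV round trips
(15 significant digits); geometric identities at 1e-9; rigid-motion
invariances at 1e-6 Å (accumulated floating-point error of superposition
chains).

## Known limitations

* The anchor-distance criterion needs formal charges in the pose files. SDF
  carries them (`M CHG` or legacy codes); MOL2 does not — there, formal
  charges are inferred from SYBYL atom types (`N.4`, `C.cat`), which is a
  convention, not a guarantee. The optional amine heuristic
  (`cationic_atoms(heuristic = TRUE)`) needs a bond table and flags its
  output as inferred.
* Scores are fractions over whatever poses are present: models with missing
  pose files are excluded and logged, never scored 0 — absence of data is
  not evidence of absent interaction.
* The per-atom group-difference report makes no claim of statistical
  significance; it is a ranked nomination list, not a test.
* Altloc handling keeps the highest-occupancy conformer (ties → first altloc
  code); homology models normally have none.
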
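---
title: "Structure descriptors for antibody epitope prediction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure descriptors for antibody epitope prediction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abepitope)
```

## The problem

A therapeutic antibody raised in another species is itself an antigen to
the patient: the immune system can raise anti-drug antibodies (ADA)
against it, neutralising the drug and occasionally cross-reacting with
endogenous proteins. Humanization reduces immunogenicity by replacing
exogenous sequence with human framework, but every replaced residue risks
degrading binding. Engineering therefore wants to know *which* surface
residues of the immunogenic antibody (iAb) the ADA actually recognises —
its epitope regions — so that mutations can be focused there.

`abepitope` works from crystal structures of iAb–ADA complexes. It labels
the epitope from the complex geometry, summarises each antibody surface
residue as a 151-element structure descriptor, and trains a logistic
regression to separate epitope from non-immunogenic surface residues so
that the model can then score unbound antibodies.

## Epitope labeling and the residue partition

Given a complex with chain roles annotated (`IAB` vs `ADA`), a residue of
the antibody is an **epitope residue** when at least one of its heavy
atoms lies strictly closer than 5 Å to any heavy atom of the ADA
(`ab_params()$epitope_cutoff`; the inequality is strict, so a contact at
exactly 5.0 Å does not qualify). Hydrogens are ignored throughout:
crystal structures rarely resolve them, and heavy-atom contact cutoffs
are the established convention. Whether to include hydrogens is a genuine
choice at this cutoff; we treat the heavy-atom reading as the method
definition and expose the cutoff as a parameter.

All remaining antibody residues are split by solvent accessibility:
**surface non-immunogenic** when the relative accessible surface area
(rASA) is at least 5%, **core** otherwise. The 5% threshold with the Tien
et al. theoretical maxima as denominators is this package's definition of
"surface" — any such threshold is a convention, so it is exposed in
`ab_params()`. Epitope residues are exempt from the rASA test: a residue
in atomic contact with another protein is solvent-reachable by
construction, and exempting it keeps the three classes a partition
without a second threshold.

Epitope residues often form several spatially separate patches on one
antibody. `group_epitope_regions()` makes this concrete with
single-linkage clustering of residue centroids at a 10 Å link distance.
No published clustering rule exists for this step; single linkage is the
minimal notion of "spatially connected" and the link distance is a
parameter, not a claim.

## The 151-element descriptor

Each surface or epitope residue is described by nine named blocks
(2+3+30+30+10+10+6+30+30 = 151):

| Block | Size | Content |
|---|---|---|
| DSD | 2 | Euclidean distances to the two disulfide benchmark points |
| IAD | 3 | the residue's own ARGP820101, FAUJ880109, FAUJ880103 values |
| SEDm | 30 | per-layer maximum of the three scales over shell members |
| SEDs | 30 | per-layer sum of the three scales |
| ASAm | 10 | per-layer maximum residue ASA (Å²) |
| ASAs | 10 | per-layer sum of residue ASA (Å²) |
| InterD1 | 6 | all pairwise products DSD × IAD |
| InterD2 | 30 | per layer, ASAm × SEDm elementwise |
| InterD3 | 30 | per layer, ASAs × SEDs elementwise |

**Disulfide anchors (DSD).** Antibody Fab fragments carry a conserved
disulfide in each variable domain (e.g. light-chain Cys23–Cys88,
heavy-chain Cys22–Cys92 in Kabat-style numbering). Bonds are detected
geometrically — cysteine SG–SG pairs within 2.5 Å, matched greedily by
ascending distance so no cysteine is used twice — rather than trusting
SSBOND records. Per chain, the intra-chain bond whose first cysteine has
the lowest residue number is taken as the variable-domain bond; its SG
midpoint is the benchmark point (light chain → p1, heavy chain → p2).
This lowest-number rule matches conventional variable-domain numbering
but can be overridden (`light_chain`, `heavy_chain`, or explicit `p1`/`p2`
coordinates) for unusual numbering, single-chain or Fc-only inputs, where
the definition genuinely does not apply.

**Radial shells (SEDm/SEDs/ASAm/ASAs).** The micro-environment of a
residue is every other residue whose heavy-atom centroid lies strictly
within 20 Å of the target's centroid, partitioned into ten 2 Å shells.
Bins are half-open, `[2(k−1), 2k)`: a neighbour at exactly 2.0 Å falls in
the second shell and one at exactly 20 Å is excluded, so the shells
partition the neighbourhood with no double counting. An empty shell
contributes 0 to both the maximum and the sum — zero is the additive
identity and keeps every descriptor finite. Residue–residue distance uses
heavy-atom centroids by default (a Cα mode exists for the anchor
distances); centroids are insensitive to atom-name conventions in
pseudo-atom fixtures and weight side-chain bulk naturally.

**Cross-terms.** InterD2/InterD3 couple surface prominence and chemistry
within a shell multiplicatively; InterD1 is defined as the full 2×3 outer
product of DSD and IAD, consistent with the explicitly multiplicative
definition of the other two cross blocks.

AAindex scales used: ARGP820101 (hydrophobicity), FAUJ880109 (H-bond
donors), FAUJ880103 (normalized van der Waals volume) in the descriptor;
those three plus FAUJ880108 (localized electrical effect), LEVM760101
(hydrophobic parameter) and ZIMJ680104 (isoelectric point) in the
region-level property tests. The 20-value tables are embedded
(`aaindex_table()`), so no external database is read at run time.

The ASA entering the descriptor is absolute (Å²), the primary output of
accessibility programs; rASA is used only for the core/surface split.

## Accessible surface area

ASA is computed by Shrake–Rupley sphere sampling implemented in the
package: each heavy atom carries `n_points` (default 960) test points on
a deterministic Fibonacci lattice over its solvent-expanded sphere (van
der Waals radius + 1.4 Å water probe; radii C 1.70, N 1.55, O 1.52,
S 1.80 Å, unknown elements fall back to 1.70 with a warning). A point is
exposed when it is outside every neighbour's expanded sphere; the atom's
ASA is the exposed fraction times the sphere area. Residue ASA is the
exact sum over its atoms.

Two numerical choices deserve note:

* **Orientation canonicalization.** A fixed lattice makes ASA depend
  slightly (≈1%) on the structure's orientation. `compute_asa()`
  therefore lays the lattice out in the structure's principal-axes frame,
  with axis signs fixed by the third moment of the coordinate projections
  (falling back to an atom-order moment for symmetric clouds). The frame
  co-rotates with the structure, so ASA — and with it every descriptor
  element — is invariant under rigid motions to machine precision.
* **Occlusion monotonicity.** At fixed lattice orientation
  (`canonical = FALSE`), adding an atom can only bury test points, so no
  other atom's ASA ever increases — exactly. Under the default
  canonicalization the added atom also perturbs the frame, so
  monotonicity holds up to the lattice resolution (< 2% per residue at
  960 points). The two properties cannot both be exact at finite
  sampling; the package prioritises exact rigid-motion invariance and
  documents the trade.

For descriptor work the antibody's ASA is computed on the antibody alone,
with ADA chains removed. This makes descriptors identical for the bound
complex and the unbound antibody, which is what prediction on monomers
requires; computing on the bound complex instead would leak the interface
into the features.

Relative ASA divides by the per-amino-acid theoretical maximum; values
are not clipped at 1. As a sanity anchor, the central alanine of an
idealised fully extended Gly-Ala-Gly tripeptide
(`generate_extended_tripeptide()`) computes to rASA ≈ 0.87.

## The classifier

Descriptors of surface and epitope residues (core residues are outside
the classification universe) are standardized to zero mean and unit scale
and fitted with a logistic regression under a weak L2 ridge penalty
(`glmnet`, α = 0, λ = 10⁻⁴ by default). The weak penalty stabilises
separable fits without materially biasing coefficients; it is exposed as
a parameter. No class re-weighting is applied: epitope residues are a
small minority of the surface, and the accuracy/AUC pattern of the model
on imbalanced residue classes is part of its honest characterisation
(accuracy near the majority-class rate can coexist with a modest AUC, so
both are always reported). The decision threshold is fixed at 0.5.

Evaluation is seeded, stratified k-fold cross-validation (default ten
folds), with AUC computed as the midrank Mann–Whitney statistic over
held-out probabilities. Two modes mirror two questions: `pooled` folds
all residues from all structures together (how well does one integrated
model separate the classes?), and `per_structure` cross-validates each
antibody on its own residues (how well is each structure's epitope
recovered?). Residue-level folds within a structure are the only possible
reading of per-structure ten-fold CV; whether to stratify folds is not
dictated by anything, and stratification is used because unstratified
folds on a 5%-positive structure routinely lack positives entirely. When
a class has fewer members than folds, the fold count drops to the class
size; below two members the structure is skipped with a warning.

The fitted artifact (coefficients, intercept, standardization, metadata)
serializes to JSON, so models are portable across languages.

## Region-level analyses

* `region_composition()` pools residue counts over classified structures
  and contrasts amino-acid frequencies in epitope vs. surface
  non-immunogenic regions.
* `aaindex_region_test()` compares per-residue property values between an
  iAb epitope region and the corresponding background-antibody region
  with a two-tailed Welch (unequal-variance) t-test. Welch is chosen
  because the two groups come from different proteins with no reason to
  share variance. Constant-data edge: both groups constant gives p = 1
  for equal means, 0 otherwise.
* `classify_cdr_epitope()` flags a region as CDR-based when more than
  half of its residues are CDR residues under Kabat numbering (heavy
  31–35b, 50–65, 95–102; light 24–34, 50–56, 89–97). The phrase "contains
  over 50% of the CDR residues" admits a second reading — the region
  covers most of the CDR — which is available as `mode = "cdr_coverage"`
  without any claim that it is the intended one.
* `substitution_insertion_census()` compares an iAb sequence with aligned
  background antibodies column by column: a column whose background is
  majority-gap while the iAb has a residue is an insertion; otherwise the
  modal non-gap background residue (ties broken alphabetically, for
  determinism) decides SAME vs SUBSTITUTED. The three statuses partition
  the epitope columns by construction.

Multiple sequence alignment and Kabat numbering assignment are consumed
as annotated input (gapped FASTA; TSV), not computed: both are separate
published algorithms, and treating them as input keeps this package's
scope at the structure-descriptor method itself.

## Synthetic fixtures: what they do and do not show

`generate_toy_antibody()` emits a three-chain complex on a jittered
straight-line lattice: two antibody chains with one CA and one
pseudo-side-chain atom per residue, a planted intra-chain CYS–CYS pair
per chain at SG distance 2.03 Å, and an ADA chain whose contact residues
are placed so that exactly the planted antibody residues have
nearest-atom distances inside (3.8, 4.9) Å while every other residue
stays ≥ 6 Å away. Margins are wide on both sides of every cutoff, and the
generator validates its own plant arithmetically before emitting,
refusing infeasible requests. Coordinates are written with standard
fixed-width PDB formatting, so a seed reproduces the file byte for byte.

These fixtures exercise the *logic* of every geometric operation with
known ground truth: contact labeling, shell membership, disulfide
matching, region grouping, rigid-motion invariance. They are not
physically realistic antibodies — no fold, no rotamers, two atoms per
residue — so passing tests demonstrate correctness of the computations,
not predictive performance on real structures. Performance claims on
real iAb–ADA complexes require the curated PDB dataset described in the
README's reproduction notes.

`generate_descriptor_dataset()` plants a known logistic signal in
Gaussian features (coefficients on the first ten feature positions,
norm = `effect_size`, intercept = `qlogis(imbalance)` so the baseline
positive rate is explicit). It verifies the estimation machinery:
cross-validated AUC ≥ 0.95 at effect 5 and n = 5000, chance-level AUC
under permuted labels, and cosine ≥ 0.95 between fitted and planted
coefficient directions.

## Problem sizes and determinism

The test suite runs on 30-residue-per-chain fixtures (ASA at 240–480
points) with one ~200-residue complex for the brute-force oracle
comparisons, and n = 5000 rows for classifier behaviour; the full suite
completes in well under a minute. Descriptor geometry is exact
arithmetic, so those checks are seed-free; everything stochastic (fold
assignment, fixtures, datasets) flows from explicit integer seeds, and
identical seeds give bit-identical results.

## Known limitations

* Chain roles (which molecule is the drug, which the ADA, light vs heavy)
  are user-supplied; the package does not infer them.
* PDB format only; no mmCIF, no biological-assembly expansion.
* The benchmark-point rule needs one intra-chain disulfide per antibody
  chain; engineered constructs without them require explicit anchor
  coordinates.
* Logistic regression is the only learner, by design.
* The synthetic generator's pseudo-side-chains make absolute ASA values
  fixture-specific; only their relative structure (layer maxima/sums,
  thresholding behaviour) is meaningful there.
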
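---
title: "Structure-based stability assessment of VHH-Fc antibodies"
author: "HcAbStab authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-based stability assessment of VHH-Fc antibodies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HcAbStab)
```

## The problem

Heavy-chain-only antibodies fuse a camelid VHH (nanobody) domain to a
human Fc through a short hinge carrying three interchain disulfides.
They are attractive therapeutics but frequently fail on *stability*:
hinge disulfides get reduced and reshuffle into covalent oligomers,
hydrophobic surface patches drive aggregation into subvisible and
visible particles, and exposed methionine/tryptophan side chains
oxidise. HcAbStab implements the computational side of a stability
assessment and variant-design pipeline for this molecule class: given a
structure (or the outputs of external predictors), it scores the risk
factors, combines them into a hotspot report, enumerates stabilising
substitutions and screens calculated features against measured
stability attributes.

## The models and rules

**Solvent accessibility.** Per-atom SASA is computed by Shrake-Rupley
quadrature: each atom's solvent-expanded sphere (van der Waals radius +
1.4 Å probe) is covered with a deterministic golden-spiral point set
(default 960 points) and the accessible fraction is the share of points
outside every neighbour's expanded sphere. Per-residue SASA is the atom
sum; relative SASA divides by a fully-exposed reference per residue
type (Tien-style theoretical maxima; the Met entry defaults to
231.7 Å², the value implied by published absolute/percent pairs for
antibody methionines). Because the point set is fixed in the laboratory
frame, SASA is exactly invariant under translation and exactly
monotone (adding an atom can only block points), but rotating a
structure perturbs per-atom values at quadrature-noise level — about
0.1–0.5% of the sphere area at 960 points. This is a property of every
fixed-point-set implementation; the tests therefore check translation
invariance at machine precision and rotation invariance at quadrature
tolerance. Raise `nPoints` when tighter reproducibility across
orientations is needed.

**Surface patches.** Hydrophobic patches cluster exposed atoms
(SASA > 0.1 Å²) carrying positive atomic hydrophobicity into connected
components at a 4.5 Å centre-centre cutoff and keep components whose
summed SASA exceeds 50 Å²; ionic patches do the same for formal
side-chain charges with a 40 Å² threshold. The atomic hydrophobicity
table is a simplified logP-style typing (side-chain carbons with no
bonded heteroatom positive; aromatic carbons weighted lower; sulfur
slightly positive), and formal charges sit on the terminal side-chain
heavy atoms (Asp/Glu carboxylate oxygens −0.5 each, Lys NZ +1, Arg
NH1/NH2 +0.5 each, His ND1/NE2 +0.5 each only when the working pH is
below the His pKa). Both tables ship as data and are arguments, because
the commercial implementations they stand in for do not publish theirs.
The 4.5 Å cutoff is small enough to keep opposite faces of a helix in
separate patches.

**Charge.** Net charge is the Henderson-Hasselbalch sum over ionizable
groups with intrinsic (EMBOSS-style) pKa values including termini; pI
is found by bisection on [0, 14] to |q| < 1e-4 (reproducible to well
under 0.01 pH units). Structure-aware pKa shifts are out of scope; a
per-group override can inject them. The default working pH is 6.0, a
typical histidine-buffer formulation pH for this antibody class, and is
the pH at which the net charge entering the developability index is
evaluated (the choice is configurable because published tables rarely
state it).

**SAP and DI.** The spatial aggregation propensity of atom *i* sums,
over every residue with an atom within 5 Å (boundary inclusive), the
solvent accessibility of that residue's side-chain atoms inside the
sphere divided by the fully-exposed side-chain accessibility of the
residue type, weighted by residue hydrophobicity (Black & Mould,
shifted so Gly = 0). The fully-exposed reference is precomputed on
extended Gly-X-Gly tripeptides *with the same SASA engine* — keeping
numerator and denominator mutually consistent matters more than the
absolute values; `inst/scripts/make-sidechain-reference.R` regenerates
the table. The SAP score is the sum of positive atom SAP over the CDRs,
and the developability index is `DI = SAP score − 0.0498 · q²` with q
the net charge. On multi-model input (the stand-in for a simulation
average) SAP is the mean of per-model values; a single model gives the
static value.

**Disulfide redox.** Reduction free energies convert to potentials via
`E = −ΔG/(nF)` (n = 2 electrons, F = 96.485 kJ mol⁻¹ V⁻¹), and an
affine empirical correction `E_corr = 1.5·E_cal − 43` (mV) maps
calculated onto experimental scale. Bonds below −330 mV are
stabilising; −330 to −89 mV marks reduction-prone bonds (the −330 mV
boundary goes to the risk class — conservative flagging), and values
above −89 mV are additionally "highly labile". Published tables of
calculated potentials are ~4–6% more negative than −ΔG/(2F) applied to
their own ΔG column (a reference-state or temperature term the source
does not specify), so `redoxTable()` passes an `E_cal_mV` column
through unchanged and only derives it from ΔG when absent.

**Interfaces.** Docked homodimer pose ensembles (multi-model PDB, two
chains per model) are scanned for cross-partner heavy-atom contacts at
5 Å (inclusive). Each pose's binding mode is the unordered pair of the
domains owning the most contacts on each partner, with ties resolved by
the fixed priority VHH > hinge > Fc (the designable domain is flagged
preferentially). Per-residue interface preference (PPIP) sums contacts
over poses, over both partner roles (the chains are identical, so both
map to one numbering) and over all supplied ensembles before a single
global normalisation by the maximum — the residues with PPIP > 0.5 form
the aggregation interface. Mode percentages are reported over
classifiable poses; contactless poses are excluded as "unbound".

**Oxidation and hotspots.** Met with relative SASA strictly above 20%
and Trp strictly above 30% are oxidation-flagged. Histidine catalysis
generalises the buried-Met case: a Met is catalysis-prone when a His
imidazole heavy atom lies within 10 Å of its sulfur and either the Met
itself is exposure-flagged or an exposure-flagged Met sulfur sits
within 6 Å (the exposed neighbour relays the oxidation). The STAP
filter intersects externally supplied structure-corrected aggregation
scores (> 1.0) with the aggregation interface and removes conserved
residues. Binding-critical residues are those whose alanine scan ΔΔG
exceeds 1.0 kcal/mol; they are reported but never mutable. Conservation
is an input list (empty by default) — the platform-process argument for
leaving conserved framework residues alone is captured by that list,
not by geometry, so no flagged residue is dropped for being far from
the CDRs (an `in_cdr`/`near_cdr` annotation is attached instead).

**Variants.** Substitution rules per site: Cys→Ser (removes the labile
thiol with a chemically similar hydroxyl), Trp→Phe (similar side chain
without the oxidation liability), hydrophobics→Lys/Asp (charged,
aggregation-breaking). Enumeration produces all combinations up to
three substitutions that contain every always-on site (by default the
reduction-prone cysteines — the hinge Cys→Ser substitution is carried
in every variant), never touches binding-critical sites, and names
variants deterministically. Structure-level mutation renames the
residue and truncates the side chain beyond Cβ — no rotamer building —
so variant SAP uses the mutated identity on wild-type exposure
geometry; that approximation is why variant evaluation reports deltas
rather than absolute aggregation predictions. Two or more Asp
substitutions trigger a colloidal-risk warning: lowering pI toward the
formulation pH reduces electrostatic repulsion.

**Correlation screen.** Stability attributes (per-week rates from
`(day28 − day0)/4`, 1/3/5/7/9 appearance grades) are screened against
calculated features by Pearson correlation with the two-sided p from
the t statistic on n−2 degrees of freedom. A pair is significant when
|r| > 0.5 and p < 0.1 — the absolute value is deliberate: negative
correlations (for example DI against diameter growth) are as
informative as positive ones, and published heatmaps treat them so. No
multiple-testing correction enters the flag (matching practice at a
dozen samples); a Benjamini-Hochberg column is emitted for reference.
Pairwise complete-case deletion handles missing values; pairs under 3
shared samples are skipped with a warning.

## What the synthetic generators emulate

All tests run on generated inputs. `buildPeptide()` constructs
idealised extended/helical backbones with side chains in one canonical
rotamer — deterministic, clash-free geometry with correct atom names,
which is what the scoring rules consume; it does not emulate real
packing, secondary-structure context or conformational ensembles.
`makeToyStructure()` plants controlled facts: burial under a sealed
carbon shell, a histidine at an exact distance from a methionine
sulfur. `makePoseEnsemble()` stacks three domain rods at unequal z
offsets so that, after the pose transform, exactly one planted domain
pair can touch — mode recovery is therefore exact by construction, and
the truth tables (planted modes, double-loop contact counts) are
computed independently of the engines under test.
`makeStabilityTable()` draws feature/attribute columns from standard
normals with planted Pearson correlations. Passing tests show the
engines implement their definitions exactly; they do not show that the
thresholds transfer to real antibodies, whose structures are neither
ideal-geometry monomers nor ensembles of cleanly separated binding
modes.

Monte-Carlo problem sizes used by the test suite and the acceptance
script: 1000 replicates at n = 12 samples for the correlation-screen
calibration (null p < 0.1 rate and planted ρ = 0.8 recovery), 100
random pose ensembles for mode recovery, dipeptide fixtures for the
SASA (engine at 3000 points vs an independent 80000-point
latitude-longitude oracle) and SAP oracles. These sizes give
Monte-Carlo standard errors well inside the tolerances being checked
while keeping a full run in tens of seconds.

## Numerical choices and degenerate inputs

* Distance boundaries are inclusive (`<= 5 Å` contacts and SAP
  neighbourhoods); score thresholds are strict (`> 1.0` STAP,
  `> 1.0 kcal/mol` binding-critical, `> 20%/30%` oxidation,
  `> 0.5` PPIP) — boundary cases are pinned by tests.
* Patch clustering uses single-linkage components at the cutoff
  (`hclust`/`cutree`), which is exactly the threshold-graph connected
  components.
* A zero variant degradation rate makes fold improvement "not
  measurable" (`NA`), not an error; an empty CDR set, an ensemble
  without contacts, an unknown appearance descriptor and a malformed
  PDB line all raise informative errors.
* Kabat CDR identification uses conserved anchor patterns (first
  framework Cys + 9 to the next Trp; +15 to second Cys − 27; second
  Cys + 3 to the W-G-x-G Trp). Anchors fail loudly and the explicit
  `override` is authoritative — in any real reproduction the CDR ranges
  should be supplied, since sequence numbering conventions vary.
* Residue numbering is taken verbatim from the input file; no
  renumbering ever happens, so hotspot labels (C130, W111, ...) match
  the chain's own numbering.

## Worked example

```{r example}
# disulfide classification from calculated potentials
redoxTable(data.frame(
  bond_label = c("C130-C130", "C136-C136", "C139-C139"),
  E_cal_mV = c(-137.1, -261.2, -270.4)))[, -2]

# a small peptide end to end: SASA, SAP score, DI
pep <- buildPeptide("GFKDWMG")
prof <- shrakeRupley(pep)
sap <- sapProfile(pep, prof)
score <- sapScore(sap, cdr = IRanges::IRanges(2, 6))
q <- netCharge(as.character(chainSequences(pep)[[1]]), pH = 6)
c(sap_score = score, net_charge = q,
  di = developabilityIndex(score, q))

# docked ensemble: planted modes are recovered and PPIP normalises to 1
fx <- makePoseEnsemble(c("Fc-VHH" = 3, "VHH-VHH" = 1), seed = 7)
modeSummary(fx$ensemble, fx$annotation)[, 1:3]
```

## Known limitations

Single static structures stand in for conformational ensembles
(multi-model input approximates averaging); pKa values are intrinsic,
not structure-aware; atomic hydrophobicity and charge placement are
simplified typings, so patch areas are comparable within this package
but not against commercial surface tools; structure-level mutation does
not rebuild side chains; and external predictors' scores (structural
aggregation scores, alanine-scan ΔΔG, docking energies) are consumed as
inputs, never recomputed.
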
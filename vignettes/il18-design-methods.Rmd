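---
title: "Methods: interface-energetics driven design of IL-18 variants"
author: "il18design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interface-energetics driven design of IL-18 variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(il18design)
```

## The design problem

Interleukin-18 (IL-18) signals through a two-receptor system: binding sites
I and II on the cytokine engage IL-18Rα, and site III engages IL-18Rβ. The
cytokine's activity therefore depends on the energetics of its
protein–protein interface, and a residue-level decomposition of the complex
binding energy (ΔG per residue, kcal/mol) identifies where that interface
is suboptimal. `il18design` implements a design loop built on that idea:

1. **Classify** interface residues from a per-residue energy table:
   favorable (ΔG~residue~ < 0), unfavorable (ΔG~residue~ > 0), and the key
   (hotspot) subset with ΔG~residue~ ≤ −1 kcal/mol.
2. **Calibrate** a scoring rule against experiment: for a panel of
   characterized mutants, each of three relative free-energy changes
   (ΔΔG~binding~, ΔΔG~folding\ of\ complex~, ΔΔG~folding\ of\ free\ ligand~,
   all ΔG~mutant~ − ΔG~wild-type~) is regressed on the natural log of %
   in-vitro activity, and the Pearson correlation of each regression,
   rounded to three decimals, becomes that term's weight.
3. **Enumerate** candidate substitutions: saturation mutagenesis (19
   substitutions per unfavorable position) and all pairwise-position-
   distinct combinations of the favorable singles.
4. **Score and rank**: mutation score = w~1~ΔΔG~bind~ + w~2~ΔΔG~fold,complex~
   + w~3~ΔΔG~fold,ligand~. Because the weights are negative (higher ΔΔG
   correlates with lower activity), more negative ΔΔG triples give higher,
   more promising scores.
5. **Analyse dynamics** of selected designs with standard trajectory
   statistics: RMSD after Kabsch superposition, per-residue RMSD, RMSF,
   backbone distance patterns, geometric hydrogen-bond detection and
   interaction-distance classification.

The external engines that produce the inputs — the per-residue
decomposition, the ΔΔG evaluations and the molecular-dynamics sampling —
are out of scope by design. They are consumed from files, and seeded
synthetic generators with planted ground truth stand in for them so the
entire pipeline is testable offline.

## Classification thresholds

The key-residue threshold is −1 kcal/mol and **inclusive** (≤ −1): the
boundary convention matters for residues reported at the threshold, and an
inclusive rule keeps "key ⊆ favorable" exact. A contribution of exactly
zero is neither favorable nor unfavorable. Site membership (I/II/III) is an
annotation supplied with the data — it derives from the receptor-complex
crystal structure, not from the energetics — so the classifier never
invents it.

## Calibration and weights

The regression direction is ΔΔG on x = ln(% activity) (wild-type = 100%),
matching how such calibrations are reported; `predict_activity()` inverts
the fitted line when a ΔΔG is to be read back as an expected activity.
Note that these are empirical least-squares lines, **not** constrained to
pass through (ln 100, 0); inverse predictions are only meaningful relative
to the panel that produced the line. The p-value attached to each Pearson
correlation is the two-sided t test with n − 2 degrees of freedom.

Weight derivation rounds the correlations to three decimals
**half-away-from-zero**. With the published panel correlations (−0.7019,
−0.7443, −0.5770) this yields exactly the published weight vector
(−0.702, −0.744, −0.577), which ships as
`il18_published_calibration()` so screening can run when the panel's raw
activities (supplementary material of the original study) are not at hand.
The published 17-mutant panel itself is treated as an optional input file
and is **not** reconstructed or invented here.

## Variant algebra

Variants are sets of single substitutions in 1-based mature-protein
numbering; labels canonicalize to ascending position (`"R131G+E6M"` parses
to `E6M+R131G`), and variants compare by mutation set, never by string.
Saturation of a site yields exactly 19 variants; combinations of size k
keep only subsets whose positions are pairwise distinct — two substitutions
at one position (R131K and R131G) cannot coexist — which is what reduces
C(5,2) = 10 to 9 doubles, C(5,3) = 10 to 7 triples and C(5,4) = 5 to 2
quadruples for the canonical five favorable singles. Ranking ties are
broken by ascending ΔΔG~binding~ (binding affinity is the primary design
objective) and then label order, so output order is deterministic. ΔΔG
triples of combined variants are inputs (they are non-additive in
general); `additive_ddg()` provides an explicitly flagged additive
approximation only.

## Trajectory statistics

Superposition is the closed-form Kabsch solution with the determinant
correction, so only proper rotations are returned; collinear selections
are rejected rather than silently fit. All RMSD-family metrics superpose
on the four-atom backbone (N, CA, C, O). The distance pattern is the
per-residue mean distance of the backbone geometric center from the
origin, computed after aligning every frame to the reference — a
drift-insensitive conformational fingerprint. RMSF uses one atom per
residue (Cα by default) about its window-mean position and assumes an
aligned trajectory.

Hydrogen bonds are purely geometric: donors are N/O atoms owning a
hydrogen (covalency inferred at < 1.2 Å when no topology is given),
acceptors are N/O, and a bond requires donor–acceptor distance ≤ 3.5 Å
and donor–hydrogen–acceptor angle ≥ 150° measured at the hydrogen (180° =
linear). Both cutoffs are inclusive. Structures without hydrogens raise an
error asking for protonation instead of silently returning nothing.
No same-residue or sequence-adjacency exclusion is applied beyond
"acceptor ≠ donor": the criteria are the contract, and the exhaustive
test oracle applies the identical rule.

Interaction distances use standard charged-group conventions —
Asp/Glu carboxylate-oxygen midpoint, Lys NZ, Arg CZ, His ring centroid —
and aromatic ring centroids for π partners. The published favorable bands
are a range ("≤ 4–5 Å" for electrostatic/π; "> 6 Å" long-range), so the
classifier uses a single configurable 5 Å cutoff and additionally flags
the ≤ 4 Å subset as *strong*.

The default analysis window discards the leading 60% of frames (the
equilibration fraction used for a 2500-snapshot production run analysed
over its last 1000), and the mean-RMSD < 3 Å stability convention is
reported as a boolean quality flag, never enforced.

Trajectories interchange as multi-model PDB: text, desk-scale and
readable by every structural toolchain. Coordinates round-trip at the
format's 3-decimal precision, which is the acknowledged tolerance in all
file-based tests. Insertion codes are rejected.

## What the synthetic generators emulate

* `gen_energy_table()` plants key/favorable/unfavorable classes in the
  magnitude bands observed for this interface (key in [−5, −1],
  unfavorable up to +2.5 kcal/mol) with a favorable-electrostatics /
  unfavorable-desolvation decomposition.
* `gen_validation_set()` reproduces the calibration's statistical
  structure: ΔΔG = slope·ln(activity) + intercept + N(0, σ), with the
  published lines as default slopes/intercepts, n = 17 mutants, and σ =
  0.5 kcal/mol — a noise level at which the planted negative correlation
  is strong but clearly imperfect, comparable to the published |r| ≈
  0.58–0.74. Activities are log-uniform on [2, 400]% of wild-type,
  spanning loss-of-function alanine mutants through gain-of-function
  designs.
* `gen_ddg_landscape()` draws single-mutant triples i.i.d. Gaussian with
  means (0.6, 0.8, 0.7) and sds (1.6, 1.5, 1.3) kcal/mol, chosen so that
  roughly 30%/20%/25% of substitutions are favorable per term — the
  proportions a saturation scan of unfavorable interface residues
  produces. Combinations are additive plus N(0, epistasis_sd) per term
  (default 0.3 kcal/mol, a typical coupling magnitude); the additive
  optimum is recorded as planted truth. In the recovery property tests
  the epistatic sd is set to 0.01 kcal/mol, an order of magnitude below
  the typical additive score gap (~0.2) between the best and runner-up
  design, because recovery of the planted optimum is only an
  identifiable property when the coupling noise is small against that
  gap.
* `gen_trajectory()` adds isotropic per-atom Gaussian displacements to a
  reference, with the amplitude multiplied inside a designated loop
  (default residues 106–112, the flexible β-hairpin analogue), and
  optionally a random global rigid transform per frame to exercise
  alignment. For uniform amplitude σ the analytic RMSF limit is √3·σ,
  which the tests verify within 5%.
* `gen_toy_structure()` builds an extended chain at 7 Å residue spacing
  (so no accidental contact satisfies hydrogen-bond geometry) and
  engineers exactly one N–H···O triple at a requested distance and angle
  by construction.

All generators take an integer seed, are bitwise reproducible for a fixed
seed, and restore the session RNG state.

What passing these tests shows — and does not show: the pipeline's
statistics are correct on data whose generating process is known. The
generators do not emulate force-field physics, correlated backbone
dynamics, solvent effects or real ΔΔG landscapes; agreement here says
nothing about the accuracy of any particular energy function on real
IL-18.

## Problem sizes and numerical choices

The test and analysis runs use desk-scale sizes chosen to make the
statistical assertions stable: 1000-frame trajectories for the √3·σ RMSF
check (sampling error ~2%), 100 seeds for oracle-equality and
best-variant-recovery rates, 200 replicate panels for the unbiasedness
check of the regression slope (2 standard errors), and 30-atom random
structures for the O(n³) hydrogen-bond oracle. Score display rounds to 2
decimals as in published tables, with full precision retained internally;
recomputing published scores from their printed one-decimal ΔΔG inputs
reproduces the printed values within ±0.05 for most rows and ±0.10 for
all candidate rows, the expected print-rounding envelope. One published
control row (E6K, printed score 1.95 against ≈ 1.61 from its printed
inputs) disagrees beyond that envelope, indicating unrounded inputs were
used in print; it is reported as-is, not reconciled.

## Known limitations

* ΔΔG values are consumed, never computed: there is no energy function.
* The multi-model PDB reader/writer handles single-character chains and
  no insertion codes; trajectories must share one topology.
* Hydrogen-bond detection requires explicit hydrogens.
* The curated interface-energy table shipped in `extdata` is synthetic in
  magnitude wherever no per-residue value was published (file name and
  documentation say so); only the site assignments, class memberships and
  the three published site III values are constrained by the study.
* The scoring weights assume the linear ΔΔG–ln(activity) relation holds
  outside the calibration panel's range; extrapolated activity
  predictions inherit that assumption.
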
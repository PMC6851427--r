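---
title: "Assessing protein model refinement: metrics, rankings, and synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing protein model refinement: metrics, rankings, and synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refinemetrics)
```

## The assessment problem

In a CASP-style refinement experiment, predictor groups receive a starting
model of a protein domain (usually the best available server prediction) and
attempt to move it closer to the experimental structure. The assessor's job
is then threefold: score every submission against the target with a battery
of complementary metrics, combine those metrics into a composite ranking on
a common scale across targets of very different difficulty, and ask the
sobering control question — would a "naïve predictor" that simply resubmits
every starting model unchanged have ranked higher?

`refinemetrics` implements that pipeline: structure similarity metrics
(sequence-dependent Cα RMSD, GDT_TS/GDT_HA, lDDT, SphereGrinder),
self-estimate scoring (ASE), torsion-space scoring with a good/bad region
decomposition, CASP-convention z-score rankings with the published composite
weight presets, and a synthetic-structure generator that provides known
ground truth for testing all of the above.

## Metrics and their assumptions

**Residue pairing.** Refinement submissions share the target's author
residue numbering, so all metrics pair residues strictly by
`(number, insertion code)` — there is no structural alignment search. This
is the sequence-dependent convention; a model with a register error is
*meant* to score badly rather than be realigned.

**RMS_CA** is the RMSD over paired Cα atoms after a least-squares (Kabsch)
fit on all of them. Lower is better; it is dominated by the worst regions.

**GDT_TS / GDT_HA.** The global distance test asks, for each distance
cutoff, what is the largest fraction of Cα atoms that *some* superposition
places within the cutoff, then averages over cutoffs ({1, 2, 4, 8} Å for
GDT_TS, {0.5, 1, 2, 4} Å for the high-accuracy GDT_HA). The reference LGA
implementation is closed-source with many options, so this package uses a
deterministic seed-and-refine search: superpositions are seeded from every
contiguous Cα window of lengths 3, 5 and 7 plus the global fit, and each
seed is iteratively refit on the residues currently inside the cutoff until
the subset stabilises (capped at 10 iterations, with repetition detection to
break oscillations). Absolute values can therefore differ from LGA by a
small margin; on small instances where exhaustive enumeration over all Cα
subsets is feasible (≤ 12 residues) the test suite verifies the heuristic
attains the exhaustive optimum, and by construction it can never fall below
the single global fit.

**lDDT** is superposition-free: over all target atom pairs within a 15 Å
inclusion radius on different residues (both atoms present in the model),
it measures the fraction of inter-atomic distances reproduced within
{0.5, 1, 2, 4} Å, averaged over thresholds. Our implementation is
stereochemistry-unaware (no penalty term) and matches side-chain atoms by
label, so chemically equivalent label swaps (e.g. OD1/OD2) are not
canonicalised — a known limitation recorded here deliberately.

**SphereGrinder** scores local environments: for each residue, all target
atoms within 6 Å of its Cα (plus the residue's own atoms) are superposed
independently onto the corresponding model atoms; the score is the mean
over {2, 4} Å cutoffs of the percentage of residues whose local-sphere
RMSD falls below the cutoff. Spheres sharing fewer than three atoms between
model and target are skipped with a warning.

**ASE.** The accuracy self-estimate judges the modeller's per-residue
*error estimates* rather than the model: with the CASP sigmoid
$S(d) = 1/(1 + (d/d_0)^2)$ and $d_0 = 5$ Å,
$\mathrm{ASE} = 100\,(1 - \overline{|S(e_i) - S(d_i)|})$, where $e_i$ is
the predicted Cα error carried in the B-factor column and $d_i$ the actual
Cα deviation under the RMS_CA superposition. We use Cα deviations (an
all-atom variant would be a straightforward extension but the Cα choice is
the one made here, and is stated as such). Submissions whose B-factor
column is constant 0 or constant 1 carry placeholder values, not estimates;
they are flagged estimate-free and their ASE is `NA` — excluded from
ranking pools rather than zero-filled, because a missing estimate is not
the same observation as a maximally wrong one.

## Torsion-space scoring

Distance-based metrics reward getting the fold right; torsion metrics ask
whether each residue's local conformation is right. `extract_torsions()`
computes φ/ψ/ω (nulled at termini and across chain breaks, detected by a
C–N distance over 2.5 Å) and χ1–χ4 from the standard atom quadruples.
Two-fold symmetric terminal torsions (Phe/Tyr χ2, Asp χ2, Glu χ3) are
mapped to a 180°-periodic representative so indistinguishable labelings
compare as identical; their deviations can therefore never exceed 90°.

The per-residue backbone error is the mean circular difference over φ and ψ
(ω is excluded by default — the 30° criterion below refers to backbone
torsions in the φ/ψ sense — but `torsion_config(include_omega = TRUE)`
adds it). Residues are classified **good** when the *starting model's*
backbone error against the target is below 30°, and **bad** otherwise:
good regions are where the start model already had the right local
conformation, and a cautious refinement protocol should perturb them
little. `region_summaries()` reports, per region, the mean backbone and
side-chain torsion change the model made from the start and its residual
against the target, together with Cα RMSDs computed after an all-Cα
alignment — the six-panel view of what a protocol actually did.

The composite `s_torsion()` score is the negated weighted mean of the
backbone and side-chain terms, so identical conformations score 0 and any
degradation is negative. The published description defers the exact
weighting to a companion methods paper, so we default to equal weights
(0.5/0.5), expose them in `torsion_config()`, and always report the two
terms separately so no analysis needs to trust the combination. When one
term is undefined (a backbone-only chain has no χ angles) the weights are
renormalised over the available term rather than silently treating the
missing term as zero deviation.

## z-scores, composite rankings, and the naïve predictor

Metrics live on incomparable scales across targets, so each metric is
standardised within the pool of model-1 submissions per target: orient so
higher is better, compute mean and SD, drop values more than 2 SD below the
mean, recompute the statistics on the survivors, assign final z-scores to
all rows from the recomputed statistics, and floor at −2. The published
assessments invoke "the usual CASP conventions" without printing these
constants; the defaults here (population SD, drop below −2, floor −2)
follow the Prediction Center convention and are all exposed in
`zscore_config()`. A pool with zero spread yields all-zero z-scores.

Three published weight presets are provided:

$$S_\mathrm{CASP12} = 0.46\,z_{RMS\_CA} + 0.17\,z_{GDT\_HA} + 0.20\,z_{SG}
  + 0.15\,z_{QCS} + 0.02\,z_{MP}$$

$$S_\mathrm{TBM} = \tfrac13 z_{GDT\_HA} + \tfrac19(z_{lDDT} + z_{CADaa} +
  z_{SG}) + \tfrac13 z_{ASE}$$

$$S_\mathrm{TBM'} = \tfrac12 z_{GDT\_HA} + \tfrac16(z_{lDDT} + z_{CADaa} +
  z_{SG})$$

QCS, MolProbity and CADaa are not computed natively — they are
well-established external programs and this package scores what it can
verify — but `metric_table()` accepts them as ingested columns so the full
presets can be evaluated when those values are available. Three
missing-metric policies are offered: `strict` (error, the default — a
silent partial composite is worse than a loud one), `renormalize` (drop
missing components and rescale, also applied to metric columns absent from
a table), and `pool_min` (missing ASE filled with the per-target pool
minimum, reproducing how estimate-free groups score below average on the
ASE component rather than dropping out of it).

`rank_groups()` sums positive per-target scores per group (clamping
negatives to zero, so one disaster does not erase all credit) and breaks
ties lexicographically by group id for determinism. `naive_baseline()`
z-scores the starting models against the statistics of the *real*
predictions — the naïve predictor never enters the pools that define
mean and SD, so it is judged by the field without distorting it.
`fraction_improved()` defaults to the composite score for its
better-than-start comparison, since the published figure does not pin the
comparison to a single metric; ties count as not improved. Ranking over
each group's best-of-five models instead of model 1 is available via
`model_index = "best"` but is not the default, because the published
rankings are stated over model-1 submissions.

## What the synthetic generator does and does not emulate

`generate_scenario()` builds an idealised chain per target (alternating
helical and extended conformations over a 20-residue mixed sequence,
side chains included), derives the starting model by Gaussian coordinate
noise of σ = 2 Å — chosen to land starting models in the mid-range
difficulty band typical of refinement targets — and derives each group's
submission by re-noising the target with a magnitude drawn from the
group's quality spread, smaller than the start's when an
improvement-biased draw succeeds and larger otherwise. Submissions carry
informative error estimates (the realised deviation with lognormal noise),
so ASE is scorable; starting models carry the constant-zero placeholder
column, so the naïve predictor is estimate-free, as in reality.

Four perturbation primitives mirror the error modes the assessment
discusses: isotropic coordinate noise, rigid displacement of a
secondary-structure element (the mis-placed-helix failure mode, typically
5–10 Å), register shifts (a segment renumbered against its spatial
position, with residues pushed onto occupied numbers dropped), and
side-chain scrambling at fixed backbone. The last pair deliberately
decouples the metric families: scrambles move `s_torsion` while leaving
GDT_HA untouched, and small coordinate noise does the reverse — the test
suite asserts both directions.

What this does **not** emulate: real decoys are physically plausible
(bonded geometry intact under noise, side chains from rotamer libraries,
compact hydrophobic cores); ours are not — Gaussian noise distorts bond
lengths, and side chains are built as idealised chi-chains with
1.52 Å / 111° geometry along the chi-defining path only. Passing tests
therefore demonstrate that the metrics and ranking machinery compute the
right quantities on known-truth inputs, not that the metric values match
what real CASP submissions would receive. Full-scale group rankings
additionally require all participants' submissions and experimental
structures, which is why the package validates its ranking machinery on
constructed scenarios with known answers instead.

## Numerical choices

* Superpositions use the SVD-based Kabsch algorithm with the reflection
  guard (determinant-corrected), optional weights, and a warning on
  collinear point sets; the test suite cross-checks RMSDs against an
  independent quaternion-eigenvalue implementation at 1e-8.
* GDT refit subsets must retain at least three residues; iteration stops
  when a subset repeats. Fractions are computed over paired residues only,
  so residues missing from the experimental structure never count against
  a model.
* Distance comparisons use strict inequality at lDDT thresholds and
  SphereGrinder cutoffs, and non-strict (≤) at GDT cutoffs.
* Dihedrals follow the IUPAC sign convention (verified against bio3d) and
  are reported in (−180, 180]; collinear quadruples raise an error rather
  than returning an arbitrary angle.
* Atoms missing from either partner are excluded pairwise from all-atom
  metrics and the exclusion count is recorded by `common_atoms()`; the
  published material does not state how such residues were treated, and
  pairwise exclusion is the choice least likely to punish a model for
  atoms the experiment could not see.
* All randomness flows through explicit seeds (`withr::with_seed`); no
  function touches the global RNG state.
* Test and example problem sizes (chains of 12–40 residues, scenarios of
  3–4 targets × 4–6 groups, 20-replicate noise ladders) were chosen so the
  full suite exercises every code path at interactive speeds while the
  exhaustive GDT oracle remains enumerable.

## Known limitations

* GDT values approximate LGA's; agreement is exact on enumerable toys but
  unverified against LGA on full-size proteins.
* lDDT is symmetry-naive for equivalent side-chain labelings and carries
  no stereochemical penalty.
* Single-chain monomer evaluation only: oligomeric targets are assessed as
  their monomeric unit, and interface-specific scores are out of scope.
* QCS, MolProbity, CADaa and crystallographic LLG scores are ingested, not
  computed; the `llg` column is reserved in the schema but no molecular
  replacement machinery is provided.

## A worked example

```{r example, eval = FALSE}
library(refinemetrics)

sc <- generate_scenario(scenario_spec(
  n_targets = 3, n_groups = 4, n_residues = 30,
  improvement_bias = c(1, 0.3, 0.3, 0), seed = 2024))

w <- ranking_weights(c(gdt_ha = 0.5, lddt = 1/6, sg = 1/6, ase = 1/6))
r <- naive_baseline(sc$metrics, sc$start_metrics, weights = w,
                    missing = "renormalize")
tidy(r)
glance(r)
autoplot(r)
```

The always-improving group ranks first and beats the naïve predictor; the
always-degrading group's positive-z total collapses to zero. The README
shows the numbers this prints.
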
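# refinemetrics

Tools for assessing protein model refinement the way CASP refinement
assessments are run. Given PDB coordinates for a target structure, a
starting model, and refined submissions, the package computes the standard
battery of model-quality metrics, combines them into composite ranking
scores via CASP z-score conventions, and benchmarks every predictor group
against a **naïve predictor** that simply resubmits the starting model —
the baseline any refinement method must beat to have added value.

It is aimed at assessors and method developers in protein structure
prediction who need reproducible, scriptable scoring of refinement
experiments, and at anyone who wants to understand *why* a refined model
ranked where it did.

## What it computes

**Structure-similarity metrics** (residues paired strictly by author
numbering — the sequence-dependent refinement convention):

- `rms_ca()` — Cα RMSD after a least-squares (Kabsch) superposition;
- `gdt()` — GDT_TS and GDT_HA: the mean over distance cutoffs
  ({1, 2, 4, 8} Å and {0.5, 1, 2, 4} Å respectively) of the maximal
  fraction of Cα atoms superposable within the cutoff, found by a
  deterministic seed-and-refine search;
- `lddt()` — superposition-free agreement of all-atom distance maps within
  a 15 Å inclusion radius;
- `sphere_grinder()` — per-residue local-environment score: all-atom RMSD
  of each residue's 6 Å sphere, summarised as the percentage of residues
  under {2, 4} Å cutoffs;
- `ase()` — accuracy self-estimate: with S(d) = 1/(1 + (d/d₀)²), d₀ = 5 Å,
  ASE = 100·(1 − mean |S(eᵢ) − S(dᵢ)|) compares predicted per-residue
  coordinate errors (B-factor column) with realised Cα deviations.

**Torsion-space scoring**: φ/ψ/ω/χ extraction with symmetry folding for
two-fold ambiguous χ angles, circular deviations, the 30° good/bad
backbone-region classification, the composite `s_torsion()` score, and
`region_summaries()` — per-region change-from-start and residual-vs-target
summaries of backbone torsions, side-chain torsions, and Cα positions.

**Ranking**: per-target two-pass z-scores (outlier rejection at −2,
recomputation, floor at −2), the published composite weight presets

    S_CASP12 = 0.46 z_RMS_CA + 0.17 z_GDT_HA + 0.20 z_SG + 0.15 z_QCS + 0.02 z_MP
    S_TBM    = 1/3 z_GDT_HA + 1/9 (z_lDDT + z_CADaa + z_SG) + 1/3 z_ASE
    S_TBM'   = 1/2 z_GDT_HA + 1/6 (z_lDDT + z_CADaa + z_SG)

(QCS, MolProbity and CADaa enter as ingested columns, not native
computations), sum-of-positive-z group rankings, the naïve-predictor
baseline, per-group fractions improved, and best-refined-vs-best-initial
comparisons per target.

**Synthetic ground truth**: `make_ideal_chain()` builds idealised chains at
requested torsions; `apply_perturbation()` applies coordinate noise, rigid
element shifts, register shifts, or side-chain scrambles;
`generate_scenario()` emits a full prediction round (targets, starts,
submissions, metric table) with known answers, so every metric and ranking
operation is testable without confidential prediction data.

The packaged CASP13 refinement target table ships as
`inst/extdata/casp13_refinement_targets.tsv`;
`target_table_stats(read_target_table(...))` reproduces its published
descriptive statistics.

## Worked example

```r
library(refinemetrics)

sc <- generate_scenario(scenario_spec(
  n_targets = 3, n_groups = 4, n_residues = 30,
  improvement_bias = c(1, 0.3, 0.3, 0), seed = 2024))

w <- ranking_weights(c(gdt_ha = 0.5, lddt = 1/6, sg = 1/6, ase = 1/6))
r <- naive_baseline(sc$metrics, sc$start_metrics, weights = w,
                    missing = "renormalize")
tidy(r)
#> # A tibble: 4 × 5
#>   group_id total n_targets  rank beats_baseline
#>   <chr>    <dbl>     <int> <int> <lgl>
#> 1 G01      4.78          3     1 TRUE
#> 2 G02      0.444         3     2 FALSE
#> 3 G03      0             3     3 FALSE
#> 4 G04      0             3     4 FALSE
glance(r)
#> # A tibble: 1 × 5
#>   n_groups n_targets mode         baseline_total n_above_baseline
#>      <int>     <int> <chr>                 <dbl>            <int>
#> 1        4         3 sum_positive          0.564                1
```

Group G01 was generated to improve every starting model: it ranks first
with a summed positive z of 4.78 and is the only group above the naïve
predictor's 0.564. G04, generated to always degrade, has every per-target
score clamped at zero. `autoplot(r)` draws the ranking with the baseline
as a dashed line.

On the packaged target table:

```r
st <- target_table_stats(read_target_table(
  system.file("extdata", "casp13_refinement_targets.tsv",
              package = "refinemetrics")))
st
#> Refinement target set: 29 targets
#>   start GDT_HA: 32-69 (mean 53.2, median 53, SD 10.2)
#>   residues per target: 59-204
#>   categories: TBM-easy 13, FM 6, TBM-hard 5, TBM/FM 5
```

A thin command-line front end (`inst/scripts/refinemetrics.R`) exposes
`score`, `rank`, `baseline`, and `table-stats` subcommands over the same
functions.

## Vignette

`vignettes/refinement-assessment.Rmd` documents the models and
conventions: metric definitions and their assumptions, the z-score and
missing-metric policies, what the synthetic generator does and does not
emulate, numerical choices, and known limitations.
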
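---
title: "Quantifying tumor-microenvironment heterogeneity on simulated cell maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tumor-microenvironment heterogeneity on simulated cell maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmearch)
```

## Scope and model

`tmearch` couples three layers:

1. a stochastic lattice agent-based model (ABM) of a tumor under
   anti-PD-1 checkpoint therapy;
2. a metric layer that scores 2-D cell maps — simulated or external —
   with four spatial intratumoral-heterogeneity metrics plus the
   cancer:immune cell ratio;
3. a classification layer that maps metric values, or their change under
   treatment, onto the immunoarchitecture archetypes *cold*, *mixed* and
   *compartmentalized*.

The design premise is that a spatial simulation becomes comparable with
multiplexed immunohistochemistry once it is reduced to the same data
product a pathology pipeline produces: a table of cell positions and
types on a thin 2-D tile. The simulator therefore runs in a flattened
3-D box (default 2 × 2 × 0.2 mm at desk scale; 10 × 10 × 0.2 mm at full
scale, 2.5 million voxels of 20 µm), and all metrics are computed on a
1 × 1 mm region of interest (ROI) center-cropped from a one-voxel-thick
(20 µm) slice through the mid-plane. The slab thickness is our choice —
one voxel layer is the thinnest section the lattice supports and is
closest to a histologic section; metrics use in-plane 2-D distances
after slicing.

## The agent-based model

**Cells and lattice.** Each voxel holds at most one cancer cell, plus at
most one immune cell — or up to eight immune cells if no cancer cell is
present. Cancer cells follow a stem-cell hierarchy: cancer stem-like
cells (CSC) divide without limit, symmetrically (CSC + CSC, probability
`p_sym` = 0.3) or asymmetrically into a progenitor; progenitors carry a
division potential (`max_divisions` = 4) and become senescent when it is
spent; senescent cells die after `senescent_lifespan` = 20 days.
Daughters occupy a uniformly chosen cancer-free Moore neighbor (26-voxel
cubic neighborhood) with at most one resident immune cell; division is
blocked when none exists. The run starts from a centered seed block
(25 × 25 × 4 voxels, one cancer cell each, exactly 10% CSC) and no
immune cells.

**Immune compartment.** Vascular entry points are resampled every step
among voxels with a cancer cell in their Moore neighborhood (the tumor
boundary moves, so fixed entry points would detach from the lesion);
each eligible voxel hosts an entry point with probability 0.002 per
step. CD8+ effector cells and regulatory T cells (Tregs) are recruited
at entry points (1.2 and 0.3 cells/day respectively), walk randomly to
Moore neighbors with free immune capacity, and CD8+ cells kill: a cell
with a Moore-adjacent (or co-resident — we count sharing a voxel as
adjacency) cancer cell removes one uniformly chosen adjacent cancer
cell with probability

`base_kill_prob × blockade(t) × (treg_suppression_factor if a Treg is adjacent)`.

Effectors become cytotoxic after their first kill and exhausted after 8
kills; exhausted cells stop killing but persist. The kill-count
thresholds, the 0.25-day step, and the fixed phase order
(division → entry refresh → recruitment → movement → killing → cytokine
deposition → diffusion) are artifact choices; we verified that the
per-step event bookkeeping (births − kills − senescent deaths)
reconciles the cancer count exactly under this ordering.

**Pharmacology surrogate.** Whole-patient pharmacology is deliberately
out of scope; a one-compartment surrogate stands in for it. A single
dose (3 mg/kg high dose, 0.3 low dose, 0 untreated) is applied at day
25; the effective level decays exponentially and gates killing through a
Hill factor `conc / (conc + ec50)`:

```{r}
cfg <- sim_config()
curve_t <- c(10, 25, 85, 180)
data.frame(day = curve_t,
           conc = drug_concentration(curve_t, cfg),
           blockade = pd1_blockade_factor(drug_concentration(curve_t, cfg),
                                          cfg))
```

Killing is fully checkpoint-gated (no drug, no killing), which makes the
untreated scenario a pure growth control. We use an *effective
engagement* half-life of 60 days — longer than the plasma half-life of
an IgG — because PD-1 receptor occupancy outlasts circulating antibody;
with `ec50` = 0.5 mg/kg the 3 mg/kg dose starts near saturation (0.86)
and the 0.3 mg/kg dose below half-maximum (0.375). Division, recruitment
and killing rates were calibrated once so that, at desk scale, the
untreated tumor grows steadily across the 180-day course, the low dose
slows growth, and the high dose regresses the tumor below baseline.
These values are the package defaults and every one of them is exposed
in `sim_config()`.

**Cytokines.** Kills deposit IL-2 and IFNγ source terms; the fields obey
∂C/∂t = D∇²C − λC + S, solved by an explicit finite-volume step with
no-flux boundaries. Fluxes are assembled per face, so with λ = 0 and no
sources total mass is conserved to machine precision; the step is
rejected up front unless dt ≤ h²/(6D). The default D = 200 µm²/day and
λ = 1/day describe a slow, strongly consumed mediator on the lattice
scale; the fields are reported but, by default, do not feed back on cell
behavior — the coupling switch exists for experimentation and is off so
that the dynamics stay attributable to the checkpoint mechanism alone.

## Metric definitions and unit conventions

All metrics binarize the seven cell types into cancer vs immune classes
through a configurable `type_grouping()`; by default all three cancer
states are CANCER and all four T-cell states IMMUNE (Tregs can be
excluded from the immune class if a CD8-only reading is wanted).

* **Mixing score** — fraction of immune cells with ≥ 1 cancer cell
  within the neighborhood radius (default 50 µm; 30–50 µm are customary
  cell-interaction scales, and we use the top of that range so one
  length scale is shared with the G-cross radius). Distance ties at
  exactly the radius are included, so lattice-valued distances behave
  deterministically.
* **Average neighbor frequency** — mean per-immune-cell fraction of
  cancer among all neighbors within the radius, the focal cell excluded;
  an empty neighborhood contributes 0. The per-cell fraction is bounded
  by the per-cell indicator, so this metric never exceeds the mixing
  score.
* **Spatial Shannon entropy** — ESP = −(d_int/d_ext) · p · log₂ p
  computed for the cancer class. Unit consistency forces the readings we
  use: p must be the dimensionless cancer *fraction* of all ROI cells
  (otherwise log₂ p is undefined and the cold-pattern limit p → 1 ⇒
  ESP → 0 is lost), and d_int/d_ext must be a ratio of mean distances,
  which we take over *all* pairs — the literal reading of "average
  Euclidean distance" — rather than nearest neighbors. Beyond 2000 cells
  per class (4 × 10⁶ pairs) the means are estimated on a fixed-seed
  subsample; `exact_distances = TRUE` restores the exact computation.
  Degenerate inputs follow explicit conventions: p = 1 or fewer than two
  cancer cells give 0; an empty ROI is undefined.
* **G-cross AUC** — we evaluate the parametric Poisson form
  G(s) = 1 − exp(−p_y π s²) with the *local* density p_y = k/(π r²)
  seen by each immune cell (k = cancer cells within r = 50 µm), not the
  empirical nearest-neighbor CDF: the parametric form is the definition
  we implement, and p_y must be a per-area density (µm⁻²) for p_y π r²
  to be dimensionless. Each immune cell's curve is integrated to r by
  200-node trapezoidal quadrature; the quadrature agrees with the
  closed form r − ½√(π/a)·erf(√a·r), a = p_y π, to better than 0.01%
  on uniform densities. The AUC is bounded by r and approaches it only
  at saturating density.

Metrics that are undefined on an input — any immune-dependent metric
when the ROI has no immune cells, which is every sample before first
recruitment — propagate as `NA` with a warning, never silently as 0.

## Synthetic archetypes and what they test

`generate_pattern()` draws labeled point patterns for the three
archetypes with exact requested counts, reproducibly from a seed. COLD
places immune cells on the ROI margin and rejection-samples them against
the realized cancer pattern so each has a cancer cell within 50 µm —
turning the statement "cold patterns have mixing score 1" into a
constructible test rather than a tendency. For COMPARTMENTALIZED the
default geometry is an immune core with a cancer rim. This choice is
deliberate: at *matched* class counts the entropy prefactor d_int/d_ext
is what separates the archetypes, and a segregated pattern only exceeds
a mixed one (whose ratio is ≈ 1) when the cancer compartment is spread
around a central immune compartment — which is also the configuration
effective therapy produces in the simulator, as T cells hollow out the
tumor from within. With this geometry all three discriminating orderings
(mixing score and G-cross AUC higher for mixed; entropy higher for
compartmentalized) hold in every one of 20 seeded pairs in the test
suite. The alternative `"half-split"` geometry separates the first two
metrics but not the entropy, and is kept for experimentation.

The generators emulate archetype *geometry* only: uniform densities,
sharp compartment boundaries, no cell-size exclusion effects, no
stromal class. Passing tests on them demonstrates that the metrics rank
architectures correctly, not that the simulator reproduces any specific
tissue.

## Classification

Two schemes are provided. The **bivariate** scheme labels one
observation from a spatial metric together with the cell ratio: a ratio
at or above `ratio_cold_above` (default 10) is cold regardless of the
metric — an immune-scarce ROI should not be called compartmentalized on
the strength of a metric computed from a handful of immune cells — and
otherwise the metric decides between compartmentalized and mixed, with
fixed directions (low mixing score, low neighbor frequency, low G-cross
AUC, high entropy ⇒ compartmentalized). No canonical split values exist,
so the defaults are round numbers for the simulator's output scale and
`calibrate_bivariate_thresholds()` derives them as midpoints between an
effective and an ineffective reference run; they are always
user-overridable.

The **percent-change** scheme compares before-treatment (BT, the last
sample strictly before the dose day) with after-treatment (AT, the final
sample): absolute changes below 1% ⇒ cold, 1–10% ⇒ mixed, above 10% ⇒
compartmentalized, boundaries assigned to the mixed band. We use the
absolute change for all metrics so that the entropy, which responds by
increasing, shares the scale of the three decreasing metrics. The
consensus label is the label of the median change across supplied
metrics — a package choice; per-metric labels are always returned
alongside. The scheme is scale-free in the underlying measurements.

```{r}
classify_by_change(c(mixing_score = 2.82, avg_neighbor_frequency = 3.28,
                     gcross_auc = 2.91, shannon_entropy = 4.24))$consensus
```

The package bundles a reference cohort of five responder and five
non-responder virtual patients (`virtual_cohort()`); applying the change
rule to its metric columns labels all responders compartmentalized and
the coldest non-responder cold. Two responder rows of that table carry
printed ratio reductions that are inconsistent with their own BT/AT
entries (likely computed from unrounded replicate means upstream);
consistency tests therefore use the internally consistent rows only.

## Numerical choices and problem sizes

* Desk-scale defaults (100 × 100 × 10 voxels, 180 days at dt = 0.25,
  10 replicates) keep a full three-scenario replicate study within
  minutes on one CPU; the full-scale 500 × 500 × 10 domain is available
  through the same configuration. The test suite runs its invariants on
  a 100 × 100 × 5 two-month run checked after every step, dose-response
  ordering on 10 replicates per scenario at full desk scale, and the
  vascular-density comparison on 3 replicates per arm.
* Metric sampling every 3 simulated days resolves the metric trends at
  a fraction of per-step cost.
* Replicate r of a run is seeded with `random_seed + r`; everything
  downstream (patterns, subsampling) restores the RNG state it found, so
  a run is bit-reproducible from its configuration.
* Neighbor counting uses a grid-bucket index with bin width equal to the
  query radius, processed one bin at a time against pooled candidates;
  it is checked against an O(n²) all-pairs scan in the tests.
* Movement and killing conflicts (two cells targeting one voxel or one
  victim) are resolved by uniform random priority; blocked events are
  dropped for the step rather than retried, a standard synchronous-ABM
  convention.

## Known limitations

* The pharmacology surrogate has no absorption phase, no redosing
  schedule, and no inter-patient variability; responder/non-responder
  cohorts must be emulated by varying configuration, not sampled from a
  population model.
* Oxygenation, vasculature heterogeneity, stromal cells, macrophages and
  additional cytokines are absent; the ROI position is therefore
  statistically exchangeable, and a single center-crop suffices.
* Cytokine fields do not feed back on behavior by default, so they are
  descriptive outputs in the standard configuration.
* At matched counts the entropy ordering between compartmentalized and
  mixed patterns is geometry-dependent (see above); on real tissue,
  where compositions differ, the density term usually dominates.
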
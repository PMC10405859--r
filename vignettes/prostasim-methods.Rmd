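---
title: "prostasim: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{prostasim: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the model and its
assumptions, the parameters that matter and why their defaults are what
they are, what the synthetic-data generators do and do not emulate, and
the design decisions taken where the design was genuinely open.

## The model

`prostasim` is a two-dimensional, on-grid, stochastic agent-based model
(ABM). The lattice is 125×125 grid spaces (15,625), one space holding at
most one cellular agent; the nominal area of a space is that of one tumor
cell (~143 µm²), used only as metadata. One scheduler step represents
12 hours; the standard horizon is 800 steps = 400 days. All action
parameters are probabilities per step.

Each step applies four rounds in fixed order — (1) luminal + stem + tumor
cells, (2) basal cells, (3) fibroblasts + CAFs, (4) macrophage influx,
then resident macrophages — and within a round visits the agents in a
fresh uniformly random order. Within one agent's turn the eligible
actions are sampled independently in a fixed order (exhaustion check,
death, proliferation, mutation, threshold actions, EMT, migration); death
pre-empts the rest of the turn. Actions needing a target position
(proliferation, migration, breakdown) pick uniformly among eligible
targets in the Moore neighborhood and fail silently when none exists.
Borders are absorbing (no wraparound).

### Cell types and rules

* **Luminal cells** proliferate (`LCpprol`) only within their physiologic
  region, die (`LCpdeath`), and mutate (`TUpmut`), which converts them
  into tumor cells.
* **Tumor cells** die (`TUpdeath`), proliferate anywhere
  (`TUpprol + mutations·TUaddedProl`, plus `CFprom` with a CAF neighbor
  and `M2TUadd` with an M2 neighbor, clamped at 1), mutate at an
  escalating rate (`TUpmut·(1 + mutations·TUmutEscalation)`), and — once
  past the mutation thresholds — break basement membrane
  (`TUthrshBM`/`TUpkill`), polarize M1 macrophages
  (`TUthrshM`/`TUpMdiff`) and cleave ECM (`TUthrshMMP`/`TUpMMP`). EMT is
  an irreversible flag set by CAF (`CFemt`) or M2 (`M2emt`) adjacency;
  only EMT cells migrate (`TUpmig`).
* **Division budgets.** Every non-stem cell carries a finite budget of
  divisions. On division the mother decrements her budget and the
  daughter inherits the decremented value, so a lineage founded with
  budget *B* is finite; a cell whose budget reaches zero dies of
  exhaustion at the start of its next turn. Each mutation adds
  `TUaddedMax` to the carrying cell's remaining budget. The
  budget-inheritance rule is what makes the mutation-only minimal
  scenario collapse deterministically: with a fresh budget per daughter
  any configuration with `TUpprol > TUpdeath` would be supercritical and
  the scenario could never go extinct.
* **Cancer stem cells** divide without limit; with probability `SCrenew`
  a division yields a second stem cell, otherwise a tumor daughter with a
  fresh budget `TUpmax + mutations·TUaddedMax`. Stem cells are exempt
  from the generic spontaneous death but carry their own small death
  probability `SCpdeath` (macrophages can also kill mutated stem cells).
  Both properties are forced by the maintenance behavior the model must
  reproduce, see *Stem-cell dynamics* below.
* **Basal cells** proliferate only into the basal ring and must keep a
  basement-membrane position in their Moore neighborhood to survive.
* **Fibroblasts** idle; with a tumor cell within two grid spaces (so
  signalling crosses the basement membrane) they convert to **CAFs**
  (`Fdiff`), which proliferate (`CFpprol`, budget `Fpmax`), die
  (`CFpdeath`), cleave one adjacent ECM position per step (`CFmmp`) and
  polarize adjacent M1 macrophages (`CFmdiff`). Their growth parameters
  `Fpprol`/`Fpmax`/`Fpdeath` are measured in the in-vitro culture model.
* **Macrophages** enter as M1 at a 2×2 top-left corner block (one
  attempt per step, probability `M1influxProb`, plus `M1influxadd` once
  any macrophage has sensed a tumor cell within `sensing_radius` = 17;
  the detection flag is sticky by default, a config switch re-evaluates
  it per step). They kill one adjacent tumor/mutated-stem cell
  (`M1pkill`/`M2pkill`) up to a kill cap (`M1kmax`/`M2kmax`, exhaustion
  death after), die (`M1pdeath`) and migrate within Moore range 2
  (`M1pmig`) — uniformly when nothing is sensed, otherwise minimizing
  the Chebyshev distance to the nearest sensed tumor cell (ties
  uniform, never moving farther than they stand).

### Geometry

The acinus is rasterized from a Euclidean disk: the lumen (`lumen_radius`
13 grid spaces, doubled from the anatomical ~6 to compensate for the two
missing growth directions in 2D) plus four one-space rings grown by
successive Chebyshev dilations — luminal (with `stem_fraction_luminal` =
5% stem cells), basal, basement membrane (passive), resident fibroblasts.
An optional `axis_ratio` turns the disk elliptical; the default is a
circle since only one radius is anatomically given.

Two densities make the stroma *porous*, and both are deliberate
departures from a fully packed picture:

* `fibro_ring_density` = 0.6 — a *closed* fibroblast ring plus the intact
  membrane would form a double wall that no Moore-range-2 hop can cross
  (the only landing position at distance 2 is the membrane itself), so
  macrophages could never infiltrate the acinus and the entire
  immunosurveillance race would be structurally dead.
* `ecm_density` = 0.45 with `ecm_fibroblast_density` = 0.15 — at ECM
  densities ≳0.7 the interstitial network barely percolates for range-2
  movement and macrophages never leave the entry corner. Roughly half
  interstitial space restores realistic stromal motility, and 15%
  stromal fibroblasts give the CAF compartment a meaningful supply.

### Stem-cell dynamics

The minimal model's stem-only scenario must sustain ~15,000 cells
indefinitely with the stem fraction converging to ~17% *from any starting
fraction*. Two structural facts follow:

1. If stem cells died at the generic tumor rate, the stem subpopulation
   would be demographically subcritical for any `SCrenew` < 1 in the
   crowded regime (per-stem division rate ≈ turnover rate, so renewal
   gain `SCrenew·d` < loss `d`) and the scenario could never persist.
   Hence stem cells are exempt from the generic death.
2. If stem cells never died at all, the crowded-phase stem fraction would
   drift monotonically to 100%. A stem-specific death probability
   `SCpdeath` creates the genuine attractor
   `SCrenew · turnover · (1 − s) ≈ SCpdeath`, whose fixed point is
   independent of the seeded fraction.

`SCrenew` = 0.25 and `SCpdeath` = 0.03 (with `TUpprol` = 0.55,
`TUpdeath` = 0.06, `TUpmax` = 5) place that attractor at 16–17% stem on
a ~14,000-cell plateau. In the combined scenario the mutation ratchet
(escalating mutation rate, heritable bonuses) continuously strengthens
the non-stem halo, so there is no true fixed point; the fraction passes
through ~0.5% at the 400-day horizon (reported, like the figures it
mirrors, as the mean over the final 10% of the run) for a wide range of
seeded fractions. `TUaddedProl` = 0.015, `TUaddedMax` = 1,
`TUmutEscalation` = 0.75 with scenario mutation probabilities around
0.005 are the values fixed by this calibration.

## Parameter defaults

No canonical parameter table is available to this package; every default
is therefore a *surrogate*,
chosen once by the calibrations described here and in the decisions
recorded below, and the quantitative endpoints (cancer fractions,
sensitivity rankings) are indicative rather than canonical. The cell
parameters that the calibration module fits (`TUpprol`, `TUpmax`,
`TUpdeath`, `Fpprol`, `Fpmax`, `Fpdeath`, `M1pkill`, `M1kmax`,
`M2pkill`; `M2kmax` assumed equal to `M1kmax`) default to values of the
magnitude such fits produce on 7-day growth/apoptosis curves. The
macrophage motility values (`M1pmig` = 0.9, `M1pdeath` = 0.002,
`M1influxProb` = 0.3) are set so that the corner-entry random-walk
search actually reaches the acinus within 400 days — with slower, shorter
-lived macrophages the kill parameters are provably inert. The initiation
probability `TUpmut` = 2.1×10⁻³ places basement-membrane breakdown at
~36% of default runs (pooled estimate over 100 runs: 0.37).

The eight patient groups vary exactly four parameters
(`default_group_values()`): `CFprom` 0.1/0.4, `TUpmut` 1.2×10⁻³/6.5×10⁻³,
and the merged macrophage axis — protumor = `M1pmig` 0.95 with
`TUthrshM` 2, antitumor = `M1pmig` 0.6 with `TUthrshM` 5. High migration
is "protumor" through its pairing with early polarization, yet it also
speeds early surveillance; this is why the protumor-macrophage groups
with low mutation probability almost never progress (<8%), while all
high-mutation groups progress in ≳88% of attempts.

## Sensitivity analysis and its noise floor

`oat_sensitivity()` perturbs each parameter by +10% (integers: round half
away from zero, then +1 if unchanged; probabilities at 1 and parameters
at 0 are reported non-perturbable) and measures the change in tumor load
(mutated cells at day 400) with seed-paired replicates, so a parameter
with no causal pathway yields exactly 0%.

Because the default model develops cancer in only ~a third of runs, the
tumor load is strongly bimodal and the mean over 5–10 replicates carries
a noise floor of several tens of percent: at small replicate counts the
>10% flag is dominated by whether the perturbation happens to flip
individual runs between clearance and progression. Measured with 30
paired replicates, the strongest true effects among the four
microenvironment parameters are `M1pmig` (≈−40%) and `TUthrshM` (≈−20%),
while `CFprom` and `TUpmut` sit near the 5–10% boundary. `CFprom` is
structurally muted in this parameterization: the invasive mass is
division-budget-limited (most post-invasion tumor deaths are exhaustion,
not kills), so a proliferation-rate bonus mainly makes lineages burn
their budgets faster, and large values saturate against the probability
clamp at 1. Screens at the protocol's small replicate counts should be
read accordingly.

## Calibration module

The culture model runs the same engine in a third mode: cells seeded
uniformly on an 80×80 lattice for 14 steps (7 days), fibroblasts
proliferative (as in vitro), tumor cells non-mutating, and cocultures
seeded 4:1:1 (tumor : fibroblast : macrophage). Growth signals are cell
counts; the apoptosis signal is the cumulative tumor-death count
(a cumulative caspase-reporter analogue). `generate_synthetic_curves()`
simulates each condition once and emits triplicates (duplicates for
apoptosis) under multiplicative Gaussian noise — it emulates curve
*shapes* (exponential rise, exhaustion turnover, kill-induced
suppression), not plate-level artifacts such as confluence saturation of
the optics, edge effects or medium exhaustion, so passing recovery tests
demonstrates pipeline correctness, not wet-lab realism.

`sequential_calibration()` reproduces the staged protocol — tumor growth
→ apoptosis → fibroblast growth → M1 coculture → M2 coculture — fixing
each stage's estimates before the next, with `M2kmax := M1kmax`. The
objective is the mean squared error between the observed replicate-mean
curve and the simulated mean curve under fixed evaluation seeds (common
random numbers), which makes the objective deterministic and the
optimization reproducible. PSO is a standard global-best swarm (inertia
0.7, cognitive = social = 1.5, absorbing bounds, integer dimensions
rounded at evaluation); the published protocol's 50 restarts are the
default, while tests and the acceptance script use reduced budgets
(~3 restarts, 12×25 evaluations) that already recover `TUpprol` within
~13% and `TUpmax` exactly on noise-free curves. The in-vitro fibroblast
parameters seed the CAF compartment (tissue fibroblasts stay quiescent).

## Numerical and bookkeeping choices

* Effective probabilities clamp at 1 after additive bonuses.
* Uniform choices use a single RNG draw; all randomness flows from R's
  generator, so `set.seed()` makes runs bit-reproducible; batch and
  cohort runs derive child seeds as `base_seed + replicate`.
* The event log emits one event per state change (birth, death with a
  cause code, mutation, differentiation with the source kind, breakdown,
  migration, kill, influx, EMT), giving exact per-step conservation:
  Δcount(kind) = births + influx + differentiation-in − deaths −
  differentiation-out.
* Milestones: basement-membrane breakdown is the first *destroyed
  membrane position* (the cancer marker), recorded separately from the
  first emigrant tumor cell (invasion); covariates (CAF count, mean
  mutation load, M2:M1) are captured at the breakdown step. The M2:M1
  ratio is `NA` while no M1 macrophage exists.
* Physiologic regions are frozen from the initial geometry: luminal =
  luminal ring plus adjacent lumen-side positions; basal = basal ring.
* Snapshots encode kinds/layers as published integer codes (lossless for
  kinds and layers; per-cell counters are not round-tripped).

## Problem sizes used by the tests and the acceptance script

Full-length (800-step) runs are used wherever an endpoint is defined at
400 days: 9 stem-only runs (3 starting fractions × 3 seeds), 60
mutation-only runs, 12 combined runs, 50 default acinus runs for the
breakdown fraction, 25 attempts per constrained cohort group, and a
5-replicate sensitivity screen; parameter recovery runs the five-stage
PSO at the reduced budget above. These sizes are the package's scaled
study design; the corresponding Monte-Carlo tolerance bands are binomial
3σ at the same sizes.

## Known limitations

* All numeric defaults are surrogates (see above); they reproduce the
  qualitative phenomenology and the printed stochastic outcomes, not a
  canonical parameter table.
* 2D lattice, implicit cytokines (distance-based interactions), no
  androgen signalling, T cells, castration resistance or metastasis.
* The combined-scenario stem fraction is a horizon quantity, not a fixed
  point (mutation ratchet).
* Tumor load at fixed horizon is budget-supply-limited, which mutes
  proliferation-rate sensitivities (see the sensitivity section).
* The patient classifier consumes externally quantified markers (TMB,
  deconvolved cell fractions, expression); no genomics processing is
  performed in-package.
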
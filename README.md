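# prostasim

An agent-based simulator of prostate cancer onset and progression in a
prostatic acinus, for computational oncologists studying how the tumor
microenvironment — cancer-associated fibroblasts (CAFs) and M1/M2
macrophages — shapes the earliest stages of the disease.

## The model

`prostasim` implements a two-dimensional, on-grid, stochastic agent-based
model (ABM). Cells are agents on a 125×125 lattice (one grid space = one
cell); time advances in 12-hour steps, 800 steps = 400 days. At every step
each agent acts with predefined per-step probabilities, in four scheduler
rounds: (1) luminal, stem and tumor cells, (2) basal cells,
(3) fibroblasts and CAFs, (4) macrophage influx and resident macrophages.
Agents compete for space in their Moore neighborhood (8 spaces; range 2,
24 spaces, for macrophage movement).

Two simulators share this engine:

* **Minimal tumor-maintenance model** — 1,500 tumor and cancer stem cells
  seeded at random. Non-stem cells carry a finite division budget
  (`TUpmax`) that daughters inherit decremented; exhausted cells die. Stem
  cells divide without limit and renew symmetrically with probability
  `SCrenew`. Mutations (probability `pmut`) add proliferation probability
  (`TUaddedProl`), division budget (`TUaddedMax`) and further mutation
  risk (`TUmutEscalation`). Three scenarios probe what sustains a tumor:
  stem cells only, mutations only, or both.
* **Acinus model** — a healthy prostatic acinus (empty lumen, luminal ring
  with a stem-cell fraction, basal ring, passive basement membrane,
  fibroblast layer, porous ECM stroma) in which luminal cells can mutate
  into tumor cells; the simulation then traces prostatic intraepithelial
  neoplasia (PIN), CAF differentiation, macrophage influx from a corner
  "blood vessel", M1→M2 polarization, basement-membrane breakdown (the
  model's cancer marker), EMT and stromal invasion.

Around the core sit the study-level tools: stage detection and batch
summaries (`detect_stage()`, `summarize_batch()`), one-at-a-time +10%
parameter sensitivity (`oat_sensitivity()`, `sweep_parameter()`,
`pairwise_sweep()`), sequential particle-swarm calibration of cell
parameters against growth/apoptosis curves (`generate_synthetic_curves()`,
`pso_fit()`, `sequential_calibration()`), and the eight-group in-silico
patient cohort with the 2-of-3 above-median marker classifier
(`group_definitions()`, `run_cohort()`, `classify_patients()`).

See `vignette("prostasim-methods")` for the full model description,
parameter table and design choices.

## Worked example

```r
library(prostasim)

# stem-cell-only maintenance: the population fills the grid and the stem
# fraction settles near 17% regardless of the seeded fraction
res <- run_minimal(minimal_config("stem_only", sc_start = 0.05), seed = 1)
res
#> <abm_result: minimal model> 800 steps (400 days)
#>   final counts: 11950 tumor, 2257 stem, 11950 mutated total
round(plateau_stats(res), 1)
#> tumor_count    stem_pct       total
#>     11793.1        16.1     14061.6

# one acinus for 400 days
ra <- run_acinus(acinus_config(), seed = 42)
ra
#> <abm_result: acinus model> 800 steps (400 days)
#>   final counts: 335 tumor, 44 stem, 373 mutated total
#>   milestones (steps):  first_mutation=2, first_basal_occupancy=110,
#>   first_caf=119, first_m2=415, bm_breakdown=673, first_emt=428,
#>   first_invasion=682
ra$developed_cancer
#> [1] TRUE
```

The milestone steps read as history: the first luminal mutation at step 2
(day 1), tumor cells entering the basal layer at day 55, the first CAF at
day 59.5, the first M2 macrophage at day 207.5, basement-membrane
breakdown — the cancer marker — at day 336.5, and the first invasive cell
outside the membrane at day 341. In this particular run the macrophages
cleared the short-lived emigrants again before day 400, so the final
snapshot sits at the EMT stage while `developed_cancer` stays `TRUE`.

A command-line interface wraps the same functions:

```sh
inst/cli/prostate-abm acinus --seed 42 --out out/ --snapshot
inst/cli/prostate-abm minimal --scenario combined --sc-start 0.05 \
    --pmut 0.005 --seed 1 --out out/
```

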
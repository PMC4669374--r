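# pahsoiltox

Quantification toolkit for soil ecotoxicology under polycyclic aromatic
hydrocarbon (PAH) contamination. Given a laboratory design of four model
PAHs (naphthalene, phenanthrene, anthracene, pyrene) at doses of 0, 1000,
2000 and 4000 mg per kg soil dry matter with three replicates, the package
computes every quantity such a study reports:

* **Plate counts** — colony-forming units per kg dry matter from dilution
  plate observations: `cfu = a · n · (100/%DM) · 10³`.
* **Community strategy indices** — the colony development index
  `CD = 100 Σ fᵢ/i` (100 = all colonies on day 1, fast r-strategists;
  10 = all on day 10 of the window) and the ecophysiological diversity
  index `EP = −Σ pᵢ log₁₀ pᵢ` (0–1 for a 10-day window) from daily
  colony-appearance series.
* **Soil resistance** — the Orwin–Wardle index
  `RS = 1 − 2|D₀|/(C₀ + |D₀|)`, `D₀ = C₀ − P(t₀)`, from control and
  treated enzyme activities (dehydrogenases, urease); 1 = unaffected,
  0 = 100 % impact.
* **Dose–response summaries** — treatment means, fold changes versus the
  uncontaminated control, and Pearson dose correlations.
* **Phytotoxicity** — Phytotoxkit percent inhibition of seed germination
  (SG) and root growth (RI), `(A − B)/A · 100`, for *Lepidium sativum*,
  *Sorghum saccharatum* and *Sinapis alba*, with species- and
  hydrocarbon-level means.
* **Variance partitioning** — from-scratch balanced two-way ANOVA
  (type × dose) with η² shares (`100 · SS_term/SS_total`) and Tukey HSD
  homogeneous groups rendered as compact letter displays at p = 0.01.
* **Synthetic data** — a seeded generator emulating the full design
  (two-class fast/slow colonizer mixture, linear enzyme decline with
  multiplicative noise, per-seed germination and root-length draws), so
  every stage is testable by parameter recovery without external data.

The package also ships plain-CSV transcriptions of the study's printed
treatment tables (`load_printed_table()`), on which `reproduce_tables()`
recomputes all published summary values and flags the handful of printed
resistance cells that are irreconcilable with the printed inputs.

## Worked example

```r
library(pahsoiltox)

# resistance of urease under pyrene from printed treatment means
rt <- resistance_table(printed_activity_means("urease"))
subset(rt, hydrocarbon == "pyrene")
#>    hydrocarbon dose_mg_per_kg   c0 p_t0   d0        rs
#> 10      pyrene           1000 2.76 2.22 0.54 0.6727273
#> 11      pyrene           2000 2.76 1.63 1.13 0.4190231
#> 12      pyrene           4000 2.76 1.14 1.62 0.2602740

# headline fold change: pyrene raised mean counts 2.2-fold over control
dr <- dose_response_summary(printed_activity_means("organotrophic_count"),
                            level = "mean")
round_half_up(dr$fold_change[dr$hydrocarbon == "pyrene" &
                             dr$dose == "average"], 1)
#> [1] 2.2

# synthetic cohort -> CD/EP indices per plate
colony <- simulate_colony_series(community_sim_params(seed = 1))
summary(colony_indices(colony)$cd)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>   24.28   25.60   26.48   26.57   27.37   30.24
```

RS = 0.419 at 2000 mg kg⁻¹ means the urease impact is roughly 41 % of the
control level's worth of disturbance; the CD mean near 26.6 indicates a
slow-growing, K-strategist-dominated community (the generator's calibrated
regime). The `analysis/` directory runs the whole workflow as numbered
scripts (simulate → indices → dose–response/RS → ANOVA/letters → phytotox →
table reproduction), writing CSVs under `results/`.

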
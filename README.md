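# vitroquant

Digital-pathology quantification of extracellular-matrix immunostaining —
built around vitronectin (VN) in neuroblastoma tissue-microarray (TMA)
cores — together with the cohort statistics needed to evaluate the
resulting measurements as prognostic biomarkers.

Matrix glycoproteins occupy two spatially distinct compartments:
**territorial** deposit (inside tumour cells plus the thin capsular and
paracapsular matrix bands wrapping each cell or nest of cells) and
**interterritorial** deposit (the matrix peripheral to those territories).
Separating the two requires measuring staining *intensity* and *location*
jointly, per pixel. `vitroquant` implements that measurement for
brightfield DAB/hematoxylin images:

* **Stain unmixing.** Beer–Lambert optical densities,
  `OD = −log10((v + ε)/I0)`, decomposed against the standard
  hematoxylin/DAB stain vectors; DAB concentration classified into
  negative / weak / moderate / strong at configurable thresholds.
* **Segmentation and zoning.** Tissue detection by OD floor, nuclei by
  hematoxylin threshold + watershed, and a zone map (intracellular /
  capsular / paracapsular / interterritorial) built from Euclidean
  distance transforms in physical micrometres.
* **Morphometry.** Percent stained area
  `%SA = 100·|positive ∩ tissue| / |tissue|` split by zone, nuclei density
  (objects/mm²), class-ratio percentages and the pixel H-score
  `H = 100·(1·f_weak + 2·f_mod + 3·f_strong) ∈ [0, 300]`.
* **Cohort statistics.** Mann–Whitney / Kruskal–Wallis rank tests against
  prognostic factors, third-quartile (Q3) dichotomization, Kaplan–Meier +
  log-rank survival, and Cox proportional-hazards regression with backward
  Wald elimination.
* **Synthetic ground truth.** A seeded generator of IHC-like cores (known
  masks, zones, classes) and of survival cohorts with covariate-linked
  exponential hazards, so every stage is validated against exact truth.

## Worked example

```r
library(vitroquant)

# Render a synthetic core (known truth), then measure it blind
rc <- render_core(core_spec(seed = 7, od_noise_sd = 0))
rc$truth$true_terr_sa      # 3.907044
rc$truth$true_inter_sa     # 11.09276
m <- core_metrics(rc$image)
as.data.frame(m)
#>       core_id nuclei_density nuclei_sa inter_vn_sa terr_vn_sa ratio_weak
#> 1 synthetic-7       732.9372  3.945157    11.09276   3.907044   4.662458
#>   ratio_moderate ratio_strong  hscore
#> 1       6.430303     3.907044 29.2442
```

The measured territorial and interterritorial %SA (3.907, 11.093) equal the
generator's ground truth, and all 75 generated nuclei are recovered
(732.9 objects/mm² on a 0.102 mm² disc). On the statistics side:

```r
cohort <- simulate_cohort(cohort_sim_params(n_cases = 200, seed = 11))
report <- run_cohort(cohort)
report
#> <cohort_report> 200 cases analyzed (0 excluded for no immunoreactivity)
#> rank tests significant at 0.05: 18 of 64
#> Cox EFS retained: age_ge18m, hist_unb_pdnb, mycn_mna, del_11q, high_terr_vn_sa
#> Cox OS retained: age_ge18m, hist_unb_pdnb, mycn_mna, del_11q, high_terr_vn_sa
```

The simulated high-territorial-VN indicator (hazard ratio 2.344 in the
generator) survives backward elimination alongside the INRG covariates,
which is the qualitative behaviour expected of the workflow.

A thin command-line wrapper with `generate-cores`, `generate-cohort`,
`quantify`, `analyze` and `demo` subcommands ships in
`inst/cli/vitroquant.R`:

```sh
Rscript inst/cli/vitroquant.R demo --out-dir demo --seed 5
```

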
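# repairkinetics

Population-scale DNA repair kinetics from damage-sequencing time courses.

UV light induces cyclobutane pyrimidine dimers (CPDs) at adjacent
pyrimidines; nucleotide excision repair removes them — fast on the
transcribed strand of active genes (transcription-coupled repair), slowly
genome-wide (global-genome repair). Assays such as CPD-seq map the
remaining damage at a handful of time points after irradiation, over an
entire cell culture. `repairkinetics` treats that signal as the
superposition of independent cells — the amplitude at a position counts
the cells still damaged there — and models the per-region repaired
fraction with the KJMA (Kolmogorov–Johnson–Mehl–Avrami) form

    f(t) = θ · (1 − exp[−(t/τ)^m])

where `m` is the Avrami exponent (time dependence / anomalous-diffusion
regime), `τ` the characteristic repair time in minutes (`β = 1/τ`), and
`θ` the fraction of cells that repair the lesion at all. `f(t)/θ` is the
Weibull(shape `m`, scale `τ`) CDF. The package is for genomicists who
want region-resolved repair dynamics, not just per-time-point
comparisons, from sparse (three or four time point) damage tracks.

It provides:

* **Signal processing** — bedGraph/FASTA/BED ingestion, dipyrimidine
  normalization, the damage-to-repair transform
  `R_a(t) = (ΣC(0) − ΣC(t)) / ΣC(0)`, and monotone rectification.
* **Fitting** — the double-log linearization of `f(t)`, OLS for `m` and
  `τ`, a θ grid search maximising adjusted R², and the `m ∈ [0.5, 5]`,
  `τ ∈ [20, 200]` plausibility filter.
* **Segmentation** — TCR classification from early TS repair,
  TS/NTS start–centre–end thirds, strand-merged non-TCR blocks (or a
  traditional genes/intergenic split), and a centromere/telomere
  distance covariate.
* **Validation & association** — predicted repair rates `f'(t)` vs
  excision (XR-seq style) signals via distance correlation, and a
  kNN-vs-shuffled-labels significance procedure linking `(m, β, θ)` to
  arbitrary per-region features.
* **A simulator** — a cells × positions grid with Bernoulli(θ)
  competence and Weibull(m, τ) repair times that emits damage tracks,
  excision tracks, synthetic genomes/annotations and
  correlated-or-null features with known ground truth.

## Worked example

Simulate a small cohort with known ground truth, run the full
damage → repair → fit pipeline, and inspect the fits:

```r
library(repairkinetics)

cfg  <- sim_config(n_cells = 500, n_regions = 20,
                   positions_per_region = 80, seed = 42)
sim  <- simulate_cohort(cfg)
fits <- fit_regions(sim$courses)
head(fits[, c("region_id", "m", "tau", "theta", "adj_r2", "passes_filter")])
#>    region_id     m    tau theta adj_r2 passes_filter
#> 1 region_001 2.578 183.95  1.00 0.9994          TRUE
#> 2 region_002 2.942 104.91  0.68 1.0000          TRUE
#> 3 region_003 1.402 106.54  0.68 1.0000          TRUE
#> 4 region_004 2.968 137.04  0.89 1.0000          TRUE
#> 5 region_005 1.017 116.15  0.62 1.0000          TRUE
#> 6 region_006 1.705  72.75  0.59 1.0000          TRUE

idx <- match(fits$region_id, sim$truth$region_id)
median(abs(fits$m - sim$truth$m[idx]), na.rm = TRUE)
#> [1] 0.089
```

Each row is one region: `m` near 1 means repair rate is highest right
after irradiation (TCR-like); `m` around 2–3 with a larger `τ` means a
delayed peak (GGR-like); `theta` is the plateau repair fraction; and
`adj_r2` is the goodness of the linearized fit. At 500 cells the median
error on `m` is already below 0.1. Evaluating the model:

```r
p <- kjma_params(m = 2, tau = 60, theta = 0.8)
repair_fraction(p, c(20, 60, 120))
#> [1] 0.0841 0.5057 0.7853
repair_rate(p, c(5, 20, 60))   # per minute; what an excision assay sees
#> [1] 0.002207 0.007954 0.009810
```

See `vignettes/repair-kinetics-methods.Rmd` for the model's assumptions,
the fitting and significance-testing details, and the simulator's scope.

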
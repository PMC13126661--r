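# wmnet — multiscale structural connectivity of the working-memory network

`wmnet` is an R package for analysing the structural brain network that
supports working memory, at two parcellation scales, in case–control
cohorts. It is aimed at neuroimaging researchers who already have
whole-brain weighted structural connectomes (e.g. SIFT2-weighted
tractography matrices over the 379-region HCP-MMP1 + subcortex
parcellation) and want a reproducible route from those matrices to
nodewise group-difference maps and a cross-scale interpretation.

The pipeline:

1. **Atlas** — a packaged hierarchy of 76 working-memory parcels (35
   bilateral cortical areas with robust 2-back − 0-back activation, plus
   bilateral caudate, putamen, thalamus), grouped into 24 bilateral
   anatomical regions (`wm_hierarchy()`).
2. **Build** — volume-normalize the whole-brain matrix
   (w′ᵢⱼ = 2wᵢⱼ/(vᵢ+vⱼ)), extract the 76 × 76 sub-network, coarse-grain to
   24 × 24 by summing all fine edge weights between region pairs
   (`build_multiscale()`); total connectivity is conserved and checkable.
3. **Metrics** — four weighted nodal graph measures per subject and scale
   (`compute_metrics()`): Onnela clustering coefficient (CC), eigenvector
   centrality (EC), local assortativity (LA; a nodal decomposition whose
   sum reconstructs the global weighted assortativity), and participation
   coefficient (PC) over the anatomical module partition.
4. **Statistics** — per node × metric, OLS of `metric ~ group + age + sex`
   with HC3 heteroskedasticity-consistent standard errors, and
   Benjamini–Hochberg FDR across nodes within each metric
   (`run_group_analysis()`); plus cohort frequency matching on age (±1 y)
   and sex (`frequency_match()`).
5. **Cross-scale classification** — each region × metric cell is labelled
   `consistent`, `fine_only`, `convergent`, `cancelling` or `null` by
   boolean rules over the FDR-significant calls at the two scales
   (`classify_crossscale()`), with a red/blue/grey summary grid
   (`render_summary()`, `autoplot()`).

Because the motivating clinical data are access-restricted, the package
includes a seeded synthetic-cohort generator (`generate_cohort()`) that
emulates the study structure — 70 ALL survivors vs 70 matched healthy
controls, ages 6.2–20.3, 40:30 males:females — with planted, configurable
group effects, and an end-to-end recovery benchmark
(`recovery_benchmark()`).

See `vignettes/wmnet-methods.Rmd` for the models, formulas, default
parameters and their rationale, and known limitations.

## Worked example

Simulate a cohort with a ×1.5 boost on within-subcortical edge weights in
the ALL group, run the full analysis, and classify the effects:

```r
library(wmnet)
library(dplyr)

hierarchy <- attach_wholebrain_indices(wm_hierarchy())
cfg <- sim_config(n_per_group = 70, seed = 1, effect_subcortical_seg = 1.5)
cohort <- generate_cohort(cfg, hierarchy)

ms <- purrr::map(cohort$connectomes, build_multiscale,
                 volumes = cohort$volumes, hierarchy = hierarchy)
coarse_metrics <- compute_metrics(purrr::map(ms, "coarse"), hierarchy, "coarse24")
fine_metrics   <- compute_metrics(purrr::map(ms, "fine"), hierarchy, "fine76")

coarse_res <- run_group_analysis(coarse_metrics, cohort$covariates)
fine_res   <- run_group_analysis(fine_metrics, cohort$covariates)
glance(coarse_res)
#> # A tibble: 1 × 5
#>   scale    n_tests n_significant alpha min_p_fdr
#>   <chr>      <int>         <int> <dbl>     <dbl>
#> 1 coarse24      96            18  0.05  2.41e-11

coarse_res %>% filter(significant, metric == "CC") %>%
  select(node, beta_group, p_fdr, direction)
#> # A tibble: 6 × 4
#>   node       beta_group      p_fdr direction
#> 1 caudate_L     0.00745 0.000229   ALL>HC
#> 2 caudate_R     0.00827 0.000239   ALL>HC
#> 3 putamen_L     0.00830 0.00000864 ALL>HC
#> 4 putamen_R     0.00756 0.0000851  ALL>HC
#> 5 thalamus_L    0.00955 0.0000869  ALL>HC
#> 6 thalamus_R    0.0111  0.0000330  ALL>HC

report <- classify_crossscale(fine_res, coarse_res, hierarchy)
glance(report)
#> # A tibble: 1 × 6
#>   n_cells consistent fine_only convergent cancelling  null
#> 1      48          8         4          2          0    34
```

Exactly the planted pattern comes back out: clustering of all six
subcortical nodes is significantly *higher* in the ALL group at the
coarse scale (positive `beta_group`, i.e. ALL − HC in CC units), the
matching fine nodes agree, so caudate/putamen/thalamus × CC are
classified `consistent`; their participation coefficient drops (the
boosted within-system weight crowds out cross-module strength), the
segregation–integration trade-off the framework is designed to expose.
`autoplot(report)` draws the summary grid.

The same analysis runs from files: `run_pipeline()` takes a YAML config
(either a `simulate:` block or paths to per-subject matrix files,
covariates and volumes) and writes matrices, metric tables, statistics,
the cross-scale report and a manifest into a run directory. A thin CLI
wrapper lives at `inst/scripts/wmnet.R`
(`wmnet simulate|build|run`).

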
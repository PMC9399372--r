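# radiosig

Discovery of cellular **radiosensitivity gene signatures** from
post-irradiation time-course expression and per-cell-line survival
fractions at 2 Gy (SF2), for radiobiology and systems-biology analysts
working with cell-line panels.

The package chains five screens into one funnel:

1. one-way **ANOVA** across post-IR timepoints (p < 0.05, cell lines as
   replicates);
2. **short time-series profile clustering** against a library of
   unit-change model profiles, with permutation significance and BH
   correction (q < 0.01);
3. a **cluster eigengene screen**: PC1 of each significant cluster's
   baseline expression, retained when its Spearman correlation with SF2
   exceeds 0.1 in absolute value;
4. **single-gene models**: random-forest permutation importance for SF2,
   and the single-gene linear-quadratic (**SGLQ**) survival model

   SF = e^(αE − βE²),

   fit without intercept on the log scale (so SF(0) = 1 exactly), the
   expression-space analogue of the classical dose–survival LQ law
   SF = e^(−αD − βD²). Genes failing *both* models are excluded;
5. a **four-layer multi-omics network** — insulated heat diffusion
   (random walk with restart, F = β(I − (1−β)W)⁻¹) on mutation and
   copy-number heats, topological-overlap co-expression modules, and a
   confidence-filtered protein edge list — whose union graph is screened
   for **hub genes**: degree, betweenness and harmonic closeness all
   strictly above their medians.

A synthetic-data generator (`simulationConfig()` / `simulateBundle()`)
plants ground-truth signature genes with all the structure the stages
assume (temporal archetypes, SGLQ-linked SF2, elevated network heats,
dense wiring, co-expression blocks), so the whole pipeline is verifiable
without any external download. The methods vignette
(`vignettes/radiosensitivity-discovery.Rmd`) documents every model,
default and numerical convention.

## Worked example

```r
library(radiosig)

cfg    <- simulationConfig(seed = 20220810)   # 2,000 genes, 20 planted
bundle <- simulateBundle(cfg)
report <- runPipeline(bundle, pipelineConfig(seed = 20220810))
report
```

```
CandidateReport [ ok ]: 42 final candidates
  funnel:
              stage n_in n_out pct_retained
              anova 2000   397         19.9
   profile_clusters  397   339         85.4
 sf2_cluster_screen  339   339        100.0
   fail_both_filter  339   333         98.2
         hub_screen  333    42         12.6
  truth: precision = 0.476 , recall = 1.000
```

Reading the funnel: 397 of 2,000 genes respond to irradiation over time;
339 of them sit in significant temporal clusters whose eigengenes also
correlate with SF2; the single-gene models exclude a handful more; the hub
screen keeps 42. All 20 planted signature genes are recovered
(recall 1.0), and they are massively over-represented among the hubs:

```r
enrichment(report)[1, ]
#>                 set setSize overlap            p            q
#> 1 PLANTED_SIGNATURE      20      20 7.958041e-21 3.183216e-20
```

Each candidate carries its per-stage evidence, and any gene can be
inspected with the SGLQ model directly:

```r
e <- setNames(baselineMatrix(bundle$tce)["G1552", ], cellLines(bundle$tce))
fitSGLQ(e, bundle$sf2, gene = "G1552")
#> SGLQFit G1552 : alpha = -0.1871 , beta = 0.03928 , R2(log) = 0.893 ,
#>                 F p = 2.14e-11 [pass]
```

Here alpha and beta are the per-expression-unit linear and quadratic
radiosensitivity coefficients of that gene; R² and the F-test refer to the
no-intercept fit of ln SF2 on (E, E²).

A thin command-line wrapper is included for shell use:

```sh
Rscript inst/scripts/radiosig.R simulate --out bundle/ --seed 1
Rscript inst/scripts/radiosig.R run --bundle bundle/ --out results/
```

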
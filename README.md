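# ph4screen

Receptor-based 3D pharmacophore modelling, virtual screening and
active/decoy validation for multi-kinase inhibitor discovery, in R.

Type II kinase inhibitors of VEGFR-2, FGFR-1 and BRAF share a common
interaction signature in the inactive (DFG-out) kinase domain: a
hydrogen-bond acceptor at the hinge region, a donor to the
alpha-C-helix glutamate, an acceptor to the DFG-motif aspartate (each
with a projected site point marking the bond's direction), and a
hydrophobic group in the allosteric back pocket, fenced in by excluded
volumes marking receptor-occupied space. `ph4screen` implements the
computational route built on such models:

* **ph4 models** — typed tolerance spheres + projections + excluded
  volumes, with a canonical JSON format (`pharmacophore()`,
  `read_pharmacophore()`, `interfeature_distances()`);
* **feature perception** — rule-based donor/acceptor/hydrophobe typing
  and site-point projection on SDF conformers (`perceive_features()`,
  `project_site_points()`);
* **model building** — alpha-carbon (Kabsch) superposition of
  protein–ligand complexes, interaction detection, single-linkage
  common-feature clustering, greedy excluded-volume placement, and
  hypothesis enumeration (`align_complexes()` … `enumerate_hypotheses()`);
* **screening** — feature mapping with an admissible distance prefilter,
  RMSD-minimising rigid superposition, excluded-volume rejection, and
  per-molecule hit reduction (`screen_library()`); the per-conformer
  RMSD equals an exhaustive permutation search, verified in the tests;
* **validation** — the eight-metric suite

  `se = tp/A`, `sp = tn/D`, `ya = tp/(tp+fp)`, `E = ya·N/A`,
  `acc = (tp+tn)/N`, `DR = se/sp`, `F1 = 2tp/(2tp+fp+fn)`,
  `MCC = (tp·tn − fp·fn)/√((tp+fp)(tp+fn)(tn+fp)(tn+fn))`

  with half-up table rounding, model ranking, and integer
  confusion-matrix back-solving from rounded metrics
  (`compute_metrics()`, `rank_models()`, `back_solve_counts()`);
* **synthetic data** — planted-match libraries with a prescribed
  confusion matrix and toy complexes with known interactions, so the
  whole pipeline is testable offline (`plant_matched_library()`,
  `make_toy_complex()`).

## Worked example

Plant a three-kinase benchmark library (26/801, 20/600, 27/913
actives/decoys; 55 matchers among the actives, 91 among the decoys),
screen it, and validate:

```r
library(ph4screen)

targets <- split_planted_totals(benchmark_test_sets(),
                                tp_total = 55, fp_total = 91, seed = 1)
pl     <- plant_matched_library(plant_spec(targets, seed = 1),
                                rmsd_threshold = 1.0)
report <- screen_library(pl$library, pl$query, rmsd_threshold = 1.0)
glance(report)
#> # A tibble: 1 × 5
#>   query       n_screened n_hits n_skipped best_rmsd
#>   <chr>            <int>  <int>     <int>     <dbl>
#> 1 plant-query       2387    146         0    0.0169

per_target <- lapply(split(pl$labels, pl$labels$target),
                     function(l) confusion_from_screen(report, l))
compute_metrics(aggregate_counts(per_target))
#> <metrics_report tp=55 fp=91 tn=2223 fn=18 (A=73, D=2314, N=2387)>
#> se= 0.7530  sp= 0.9610  ya= 0.3770  e=12.3180  acc= 0.9540  dr= 0.7840  f1= 0.5023  mcc= 0.5131
```

The screen retrieves 146 hits out of 2387 compounds, of which 55 are
true actives: sensitivity 0.753 with specificity 0.961, a yield of
actives of 0.377 and a 12.3-fold enrichment over random selection. The
F1 (0.5023) and Matthews correlation (0.5131) summarise the balance
between the two error types. Ranking the bundled 17-model benchmark
table by MCC picks the same balanced model first:

```r
rank_models(benchmark_model_metrics(), key = "mcc")[1:3, c("model", "se", "sp", "mcc")]
#> # A tibble: 3 × 4
#>   model    se    sp   mcc
#>   <chr> <dbl> <dbl> <dbl>
#> 1 Ph4-4 0.753 0.961 0.513
#> 2 Ph4-5 0.74  0.962 0.513
#> 3 Ph4-6 0.726 0.964 0.511
```

A thin command-line front end ships at `inst/cli/ph4.R`
(`model validate`, `model distances`, `screen`, `validate`,
`simulate library`); see the file header for usage. The methods
vignette (`vignettes/pharmacophore-screening.Rmd`) documents the
matching algorithm, the metric formulas, all defaults and the
generator's scope.

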
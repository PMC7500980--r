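# mothdrift

Tools for analysing multi-decade change in moth communities assembled from
museum collections and standardized light-trap surveys, using incidence
(presence/absence) data only.

The package is aimed at community ecologists working with heterogeneous
long-term insect records. It answers two linked questions: *which species
were lost, persisted, or newly appeared around a cut year*, and *whether the
community changed directionally in body size, ecological specialization or
habitat affiliation — or merely drifted*.

## What it computes

* **Status partition.** Records are pooled into time layers (museum decades
  and survey years), a binary species × layer incidence matrix is built, and
  species are partitioned into *lost* / *persistent* / *previously
  unrecorded* around a cut year (default 1997).
* **Specialization register.** A rule-based score on three niche dimensions
  — larval food breadth, northern distribution limit (43–71° N in
  whole-degree bands), habitat breadth — each ranked 1 (specialist) to 4
  (generalist) and summed to a 3–12 total.
* **Functional dispersion (FDis).** From 12 mixed-type functional traits, a
  Gower dissimilarity matrix, a principal-coordinate embedding (square-root,
  Cailliez or Lingoes correction for non-Euclidean matrices), and the
  weighted mean distance to the community centroid:
  with weights *a<sub>j</sub>*, centroid **c** = Σ*a<sub>j</sub>***x**<sub>j</sub> / Σ*a<sub>j</sub>*
  and *z<sub>j</sub>* = ‖**x**<sub>j</sub> − **c**‖,
  FDis = Σ*a<sub>j</sub>z<sub>j</sub>* / Σ*a<sub>j</sub>*.
  Implemented from the definition, with an independent brute-force oracle
  used in the tests.
* **Trend and status models.** Penalized-spline GAM trends of per-layer
  community metrics over time; a linear mixed model of log wingspan on
  status with a taxonomic-family random intercept (Nakagawa–Schielzeth
  marginal/conditional R²); Poisson mixed models of the register scores.
* **Ordination.** Sørensen dissimilarities between layers, seeded-restart
  NMDS (Kruskal stress-1), and envfit-style permutation tests (999
  permutations) of community descriptors.
* **Synthetic communities.** A scenario-driven generator (neutral drift,
  size filtering, succession, generalization) producing trait pools and
  occurrence histories with the structure the analysis assumes, used for
  calibration and power analysis of the entire pipeline.

## Worked example

Run the full pipeline on a simulated succession scenario (open-habitat
species decline while forest species colonize — the signature expected
after land-use abandonment in a forest reserve):

```r
library(mothdrift)
res <- run_pipeline(list(
  scenario = list(scenario = "succession", n_species = 300, n_layers = 12),
  seed = 42, n_restarts = 30, n_permutations = 999))

res$manifest$status_counts
#> $lost
#> [1] 45
#> $persistent
#> [1] 89
#> $previously_unrecorded
#> [1] 58

res$trends$fdis
#> Trend in fdis: edf 1.78, beta -0.929, t -6.14, p 3.442e-05, adj R2 0.88

res$ordination
#> NMDS over 12 layers: stress 0.0253 (30 restarts)

res$vector_fits[, c("variable", "r_squared", "p_value")]
#>                    variable  r_squared p_value
#> 1         log_mean_wingspan 0.78134777   0.002
#> 2 mean_total_specialization 0.02100306   0.899
#> 3           logit_prop_open 0.91729324   0.001

head(res$series[, c("layer_label", "n_species", "prop_open_habitat", "fdis")])
#>   layer_label n_species prop_open_habitat      fdis
#> 1         H01        95        0.29473684 0.4467955
#> 2         H02        80        0.22500000 0.4425291
#> 3         H03        70        0.10000000 0.4299487
#> 4         H04        62        0.04838710 0.4245628
#> 5        1997        69        0.02898551 0.4255543
#> 6        1998        78        0.03846154 0.4304807
```

Reading the output: 192 species were ever observed and partition into
45/89/58 statuses; the proportion of open-habitat species collapses from
29% to ~3% across layers, dragging FDis down (a significant negative trend,
β = −0.93, p < 0.001) — functional homogenization driven by succession. The
vector fits show community composition shifting along gradients of wingspan
and open-habitat share, while mean register score moves not at all: the
coarse score misses a shift that the multivariate FDis captures, which is
exactly the methodological contrast the pipeline is designed to expose.

A command-line front end (`inst/cli/mothdrift.R`) wraps the same functions:

```sh
Rscript inst/cli/mothdrift.R simulate --scenario succession --seed 42 --out sim/
Rscript inst/cli/mothdrift.R analyze --config run.json --out results/
```

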
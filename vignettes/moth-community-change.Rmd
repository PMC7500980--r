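---
title: "Quantifying long-term change in moth communities: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying long-term change in moth communities: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mothdrift)
```

## The problem

Long-term insect data are rare. Where they exist they are usually a patchwork:
museum vouchers aggregated over decades, followed by standardized light-trap
surveys with annual resolution. `mothdrift` provides a pipeline for asking,
from such a patchwork, whether a moth community has changed *directionally* —
in body size, in ecological specialization, in habitat affiliation — or
whether the observed turnover is compatible with ecological drift (stochastic
local extinction and colonization with no trait filter).

Only incidence (presence/absence) information is used throughout: historic
collections do not support abundance estimates, and pooling all records of a
year or decade into one species list is the only aggregation robust to
differences in collector behaviour and trap type.

## Data model

Three inputs drive the analysis:

1. **Occurrence records** — one row per species × year detection, with the
   source collection. Duplicates are tolerated and collapse when the binary
   species × time-layer incidence matrix is built.
2. **A species trait table** — wingspan (mm), taxonomic family, the inputs to
   the specialization register, expert-assigned phenological cleaning flags
   (early/late flyers, long-distance migrants, strictly diurnal species —
   removed because light-trap surveys sample them incomparably), and the 12
   mixed-type functional traits.
3. **A time-layer scheme** — a table of labelled year spans. Pooled museum
   partitions ("1940s" = 1933–1949, "1960s" = 1950–1976, "1970s" =
   1977–1984, "1980s" = 1985–1996) and single survey years are both just
   rows in this table, so alternative layerings (the 12-layer ordination
   variant with the eight sampled survey years, or finer per-year variants)
   are data, not code. Sources differ on the exact layer count (12 vs 15
   layers for different analyses); `default_layer_scheme()` therefore takes
   the survey years as an argument instead of hard-coding one count.

Species are partitioned around a **cut year** (default 1997, the start of the
systematic survey period): *lost* (recorded only before), *previously
unrecorded* (only from the cut year on; the cut year itself counts as
post-cut, since it belongs to the survey era), and *persistent* (both).
Every layer must fall entirely on one side of the cut; straddling layers are
a configuration error rather than something to be silently split.

## The specialization register

Each species is scored 1 (most specialized) to 4 (least specialized) on
three niche dimensions, and the total is the sum (range 3–12):

| Dimension | 1 | 2 | 3 | 4 |
|---|---|---|---|---|
| Larval food | monophagous within a genus | oligophagous within a family | polyphagous, >1 family | highly polyphagous, >5 families |
| Northern range limit | 43–46° N | 47–50° N | 51–54° N | 55–71° N |
| Habitat breadth | 1–2 types | 3–4 types | ≥5 or common/nonspecial types | numerous and/or anthropogenic |

Interpretation choices worth making explicit:

* Latitudes are rounded to whole degrees before binning; the register is
  defined on integer-degree bands, so 46.4° scores 1 and 46.6° scores 2.
* The habitat column conflates a count rule with two qualifiers. We resolve
  it ordinally: the count decides up to 3; a "common/nonspecial habitats"
  qualifier promotes to at least 3; an anthropogenic-habitat qualifier
  always scores 4.
* For food breadth, "polyphagous: >1 family" (score 3) is read as 2–5
  families, with >5 escalating to score 4 and exactly one family remaining
  score 2.

The register is deliberately coarse; that coarseness is one of the things
the pipeline is designed to probe, by comparing it against the multivariate
alternative below.

## Functional dispersion from first principles

Twelve functional traits (wingspan; proboscis presence; larval food-source
labels; salt-tolerant and ruderal host use; host growth form; food
specialization; habitat type; phenology; voltinism; hibernating stage;
range extent) form a mixed-type matrix. From it we compute:

* **Gower dissimilarity.** Quantitative and ordinal traits contribute
  |x~i~ − x~j~| / range; binary and categorical traits contribute a 0/1
  mismatch; the set-valued larval-food slot contributes the mean mismatch
  over its label block, so it counts as *one* trait of the twelve rather
  than seventeen. Missing values are excluded pairwise (the denominator for
  a pair counts only traits observed in both species); nothing is imputed.
  Ordinal traits use their numeric codes (classic Gower); a rank-based
  variant is available via `ordinal = "rank"`.
* **Principal-coordinate embedding.** Gower matrices are usually
  non-Euclidean. When negative eigenvalues exceed `1e-9` of the largest,
  the element-wise square root of the dissimilarities is taken and the
  matrix re-embedded — for a complete-case Gower matrix the square root is
  provably Euclidean, and this mirrors the common default of distance-based
  functional-diversity software. Cailliez and Lingoes additive corrections
  are available by configuration; the applied correction is recorded in the
  result and in the pipeline manifest, since published analyses rarely state
  which was active. Axes with eigenvalue below `1e-9` of the largest are
  dropped.
* **FDis.** With weights $a_j$ (unit weights for present species under
  incidence data), centroid $\mathbf{c} = \sum a_j \mathbf{x}_j / \sum a_j$
  and $z_j = \lVert \mathbf{x}_j - \mathbf{c} \rVert$,
  $\mathrm{FDis} = \sum a_j z_j / \sum a_j$. Since functional
  specialization can be defined as a species' distance from the community
  centroid, FDis is the community's *mean functional specialization*. The
  species pool is embedded once and every layer is evaluated in that shared
  trait space, so per-layer values are comparable.

A definitional oracle (`fdis_brute_oracle()`) recomputes FDis through
`stats::cmdscale` at full rank and a direct centroid calculation; the test
suite holds the two paths together to 10^-8^ across random mixed-trait
fixtures, and checks closed-form cases (two species at distance *d* give
*d*/2; unit-square corners give √2/2).

## Community trend and status models

Per layer we compute: species richness, mean wingspan and its log, mean
total specialization, the proportion of open-habitat species with an
empirical-logit transform (ε = 0.5/n, so proportions of 0 or 1 stay
finite), and FDis. The layer midpoint year (e.g. 1941 for "1940s") is the
time covariate.

* **Trends** are penalized-spline GAMs, `y ~ s(year, k = 4)` with GCV
  smoothing. A dozen time points cannot support a richer basis. Because a
  smooth has no single slope, the reported trend coefficient is the
  standardized slope of the linear projection of the fitted smooth onto
  year — an interpretation, flagged as such, of the single "regression
  coefficient" convention used when summarizing GAM trends in tables.
* **Body size vs status** is `log(wingspan) ~ status` with a family random
  intercept (REML, via `nlme`), reference level *previously unrecorded* so
  the primary contrast is lost-vs-new. Marginal and conditional R² follow
  the Nakagawa–Schielzeth variance decomposition.
* **Specialization vs status** uses Poisson-log GLMMs (`lme4`) for each
  score. The scores are bounded ranks, not open counts; the Poisson family
  is retained as the field's convention for these models, with the caveat
  that dispersion should be checked. The observation-level variance in the
  R² decomposition uses the lognormal approximation ln(1 + 1/λ̄).

## Ordination

Layer-to-layer Sørensen dissimilarity (1 − 2a/(2a + b + c)) feeds a
monotone-regression NMDS (Kruskal stress-1) run from one metric start plus
49 random restarts under a fixed seed; the best solution is kept and
centred. Three community descriptors — log mean wingspan, mean total
specialization, logit proportion of open-habitat species — are fitted as
vectors, and each descriptor's R² is tested against 999 permutations of its
values across layers, with the add-one p-value convention (minimum p =
1/1000).

## The synthetic-community generator

Because the empirical species list cannot be redistributed with the
package, every stage is exercised on synthetic communities whose structure
mirrors the study system: a pool of 300 species; log-normal wingspans with
median 33 mm (the observed community means run from 37 mm in the lost group
to 31 mm among new arrivals) and a family-level size component; 12 families;
habitat guilds forest/open/shrub/reed at 45/30/15/10%; guild-correlated
functional traits; register inputs drawn so totals span 3–12 with the mode
at 10 (these faunas are generalist-dominated). Occupancy evolves as a
two-state Markov chain per species across 12 layers (the first third are
pooled "museum" spans, the rest single survey years), and latent presences
are thinned by a detection probability (0.9 by default; a size-biased
detection option exists to probe museum-collection bias, but is off by
default because sampling bias is treated as a caveat, not a modelled
effect).

Baseline rates (extinction 0.15, colonization 0.08 per layer) were chosen
once so that all three status groups are well populated at n = 300 — they
are free parameters of a power analysis, not estimates. The initial
occupancy defaults to the stationary value c/(c + e): starting off
stationarity makes richness itself trend under pure drift, which would
contaminate the neutral baseline (mean distance to an *estimated* centroid
shrinks with the number of species, so a richness trend masquerades as an
FDis trend).

Four scenarios:

* **neutral** — trait-independent rates: ecological drift.
* **size_filter** — extinction log-odds increase by 2 per unit of centred
  log-wingspan (chosen for realistic power at n = 300: the lost group ends
  up a few millimetres larger than new arrivals, the magnitude seen in
  long-term data).
* **succession** — open-habitat species' survival is multiplied by 0.7 per
  layer and their colonization decays geometrically while forest
  colonization ramps up: land-use abandonment.
* **generalization** — species first appearing in the second half of the
  series have traits shrunk toward the pool centroid by a factor 0.4:
  community-wide loss of specialization without any guild dying out.

Both succession and generalization depress late-layer FDis; drift does not,
*in expectation*. What drift does do — and the tests document this rather
than hide it — is mimic trends in any single short series: community
composition is autocorrelated across layers, so per-series FDis random-walks
and a 12-point GAM flags a "significant" trend in roughly 20% of neutral
replicates, split evenly between declines and increases. The honest neutral
signature is therefore *directional symmetry* (equal rates of significant
declines and increases, mean trend ≈ 0), not a 5% rejection rate. This is
worth remembering when interpreting a single observed series: one
significant FDis decline is evidence, not proof, against drift; its
strength comes from converging evidence across responses.

What the generator does **not** emulate: spatial structure, phylogenetic
trait conservatism beyond the family size effect, collector preference
(unless the size-biased detection switch is used), and abundance dynamics.
Passing the synthetic suites therefore validates the *machinery* and the
qualitative scenario contrasts, not the empirical conclusions from any real
data set.

## Problem sizes and numerical choices

The shipped test and acceptance suites use n = 300 species and 12 layers;
calibration checks run 1000 replicates for the wingspan type-I rate and 200
replicates per scenario for power and trend-recovery rates, with all seeds
fixed. The eigenvalue tolerance for retained PCoA axes is 1e-9 of the
largest eigenvalue; NMDS uses 50 restarts and a 1e-6 stress-improvement
convergence criterion; permutation tests use 999 permutations. Degenerate
inputs are handled explicitly: zero-range quantitative traits are dropped
from Gower with a warning, single-species communities have FDis 0 by
definition, empty layers are dropped before ordination, and singular
mixed-model fits fall back to fixed-effects models with a warning.

## Known limitations

* The Poisson GLMM for bounded scores is a convention, not a good
  distributional model; its p-values are approximate.
* GAM smooth p-values at a dozen time points are approximate and, on
  autocorrelated community series, anticonservative (see above).
* The register's habitat dimension mixes a count with qualitative
  judgements; two species with identical totals can occupy entirely
  different niches. That limitation is the very motivation for the
  FDis-based alternative.
* NMDS solutions are unique only up to rotation/reflection; downstream
  vector fits are invariant to this, but coordinates themselves are not
  comparable across runs with different seeds.
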
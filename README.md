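# rhizoweb

Quantitative analysis of legume–rhizobium interaction webs from 16S rRNA
nodule surveys.

Legumes host nitrogen-fixing rhizobia (alpha- and beta-proteobacteria) in
root nodules. Sequencing one bacterial isolate per nodule across many
nodules, plant species and sites yields a nodule-occupancy survey; counting
records per plant–taxon pair gives a weighted bipartite web in which edge
weights are frequencies of nodule occupancy. `rhizoweb` is for ecologists
asking how such webs are structured — are they modular (co-evolved
specialization) or nested (generalists plus specialist subsets)? — and how
they change along a plant-invasion gradient: do invasive legumes infiltrate
the native web or arrive with their own symbionts and form separate
modules?

## What it computes

For a web with counts `a_ij`, marginals `A_i` and `D_j`, grand total `F`
and `I` realized links among `P` plants and `B` bacterial taxa:

* **Taxon delineation** — pairwise identity from an alignment (gap–base =
  mismatch; gap–gap and `N` columns excluded), genotype collapsing, and
  complete-linkage clustering at 99/98/95 % identity, producing nested
  partitions with monotone taxon counts.
* **Network metrics** — connectance `I/(P·B)`; interaction evenness
  `H/ln L`; weighted nestedness **WNODF** (0–100); Blüthgen network
  specialization **H2′** (0–1); generality of plants (`Gp`) and bacteria
  (`Gb`) as marginal-weighted effective partner numbers.
* **Species metrics** — degree, effective partners `exp(H_i)`, and
  specialization `d′` (standardized Kullback–Leibler divergence of partner
  use from availability).
* **Modularity** — Barber's weighted bipartite
  `Q = (1/F) Σ [a_ij − A_i D_j/F] δ(m_i, m_j)`, maximised by greedy
  agglomeration plus simulated annealing with hill-climb polish (C++ core).
* **Significance** — fixed-marginal (Patefield) null webs: 1000 for
  nestedness, 100 for modularity (each null searched at the same budget),
  with z-scores and add-one empirical p-values.
* **Composition** — G-tests of clade-level nodule occupancy
  (beta-*Burkholderia* / alpha-*Rhizobium* / alpha-*Bradyrhizobium*)
  between native and invasive hosts and along the gradient, plus
  ANOVA/Kruskal–Wallis comparisons of species-level metrics.
* **Synthetic surveys** — generators with planted ground truth: sequence
  communities at exact identity bands, modular and nested webs, and a full
  three-site invasion-gradient survey (5 species/site, ~20 nodules each,
  site totals 100/97/99) under co-introduction, infiltration or random
  partner regimes.

## Worked example

```r
library(rhizoweb)

report <- simulate_and_run("co-introduction", seed = 1, levels = "genotype",
                           nestedness_nulls = 1000, modularity_nulls = 100,
                           runs = 5, steps = 1e4)
report$networks[, c("web", "plants", "taxa", "nodules", "connectance",
                    "wnodf", "wnodf_p", "Q", "Q_z", "n_modules", "h2prime")]
#>        web plants taxa nodules connectance wnodf wnodf_p     Q  Q_z n_modules h2prime
#> 1   site_U      5   30     100       0.200 14.38   0.450 0.800 22.3         5       1
#> 2   site_S      5   29      97       0.200 14.42   0.943 0.800 18.1         5       1
#> 3   site_H      5   30      99       0.200 12.58   0.956 0.800 21.0         5       1
#> 4 combined      8   48     296       0.125  9.17   1.000 0.853 46.1         8       1
```

Each row is one web (three sites plus the pooled web) at the genotype
delineation level. Reading the combined row: 8 plant species interact with
48 bacterial genotypes over 296 nodules; only 12.5 % of possible links are
realized; nestedness is low (WNODF 9.2) and no higher than in
marginal-conserving null webs (p = 1.0), while modularity is high
(Q = 0.85) and hugely in excess of the nulls (z = 46), with every plant
species forming its own module (8 modules) and specialization at the
ceiling (H2′ = 1). That is the signature of co-introduced, host-private
symbionts: significantly modular, not nested.

```r
report$composition$g_tests[, c("grouping", "G", "df", "p", "n")]
#>                      grouping         G df         p   n
#> 1           status_at_invaded 265.06376  2 2.768e-58 196
#> 2 gradient_for_shared_natives   0.01765  1 8.943e-01 120
```

Clade usage differs radically between native and invasive hosts at the
invaded sites (G = 265, df = 2), while the natives present along the whole
gradient keep the same clade profile at invaded sites (G = 0.02, ns).

Lower-level entry points (`delineate_taxa()`, `build_web()`,
`network_metrics()`, `find_modules()`, `null_distribution()`, `g_test()`,
…) operate on your own aligned FASTA plus a nodule-record TSV; see
`vignettes/interaction-webs.Rmd` for the model details and design choices,
and `autoplot()` methods for web heatmaps with module outlines.

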
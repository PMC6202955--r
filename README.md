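# nomtrait

Functional groups — sets of species that use an ecosystem in similar
ways — are usually derived by clustering a species-by-trait matrix. When
the traits are *nominal* (diet class, fin shape, spawning location, …),
the standard continuous-data toolkit breaks down: Euclidean distances
are meaningless, most validity indices assume numeric data, and trait
compilations arrive riddled with missing cells. `nomtrait` is an R
package for exactly this setting. It covers the whole workflow:

* **Data model** — validated species-by-trait matrices with explicit
  per-trait category sets (codebooks), missingness screening (default
  cutoff: drop traits with ≥ 25% missing), and log-scale discretization
  of continuous traits.
* **Imputation** — mode baseline and polytomous (multinomial logistic)
  chained equations, a plug-in registry for external imputers, and an
  MCAR deletion benchmark that measures the proportion of masked cells
  each method restores.
* **Dissimilarity** — the five categorical measures in common use for
  trait data: simple matching (SM), Eskin, IOF, Goodall and Lin. Per
  trait c with K_c categories, frequencies f_c and relative frequencies
  p_c, the per-trait similarities are

  | measure | match | mismatch |
  |---|---|---|
  | SM | 1 | 0 |
  | Eskin | 1 | K_c²/(K_c²+2) |
  | IOF | 1 | 1/(1 + ln f_c(x)·ln f_c(y)) |
  | Goodall | 1 − p2_c(x) | 0 |
  | Lin | 2 ln p_c(x) | 2 ln(p_c(x)+p_c(y)) |

  averaged over traits (Lin: normalized by Σ_c ln p_c(x_c)+ln p_c(y_c)),
  with dissimilarity 1 − S.
* **Clustering** — agglomerative hierarchical clustering with single,
  complete and average linkage (D(A,B) = min / max / mean of cross-pair
  dissimilarities, maintained by Lance–Williams updates with
  deterministic tie-breaks), plus k-medoids (PAM, BUILD + SWAP).
* **Validity** — the within-cluster entropy coefficient
  WCE(k) = Σ_g (n_g/nm) Σ_c −Σ_u (n_gcu/n_g) ln(n_gcu/n_g)
  (compactness), the entropy pseudo-F
  PSFE(k) = (n−k)[nWCE(1)−nWCE(k)] / ((k−1) nWCE(k)) (separation, whose
  argmax selects k), their Gini-impurity twins, ΔWCE, and the
  Hubert–Arabie adjusted Rand index for comparing partitions.
* **Stability** — bootstrap cluster-wise stability: resample species
  with replacement, recompute frequencies + dissimilarities + PAM, and
  track each reference cluster's maximum Jaccard overlap.
* **Synthetic data** — a seeded generator planting controllable group
  structure (group-preferred categories with separability θ, MCAR
  amputation), defaulting to the reference study's shape
  (116 species × 22 traits, 3 groups).
* **Pipeline** — `run_pipeline()` chains everything from one config and
  one master seed into a directory of CSV/Newick outputs plus a
  checksummed manifest; identical seeds reproduce byte-identical runs.

## Worked example

Generate a study-shaped matrix with 8% missing cells, impute, evaluate
the Goodall and Lin measures under average linkage, and check stability:

```r
library(nomtrait)
g  <- generate_traits(synthetic_spec(missing_fraction = 0.08), seed = 1)
sum(is.na(g$tm$values))                       # 204 missing cells
tm <- impute_polytomous(g$tm, seed = 1)

ev <- evaluate_grid(tm, measures = c("goodall", "lin"),
                    linkages = "average", k_range = 2:6)
ev[, c("measure", "linkage", "k", "wce", "psfe", "delta_wce", "optimal")]
#>    measure linkage k   wce  psfe delta_wce optimal
#> 1  goodall average 2 0.725  69.7   0.44337   FALSE
#> 2  goodall average 3 0.408 105.3   0.31709    TRUE
#> 3  goodall average 4 0.401  71.6   0.00754   FALSE
#> 4  goodall average 5 0.389  55.7   0.01190   FALSE
#> 5  goodall average 6 0.380  45.6   0.00855   FALSE
#> 6      lin average 2 0.725  69.7   0.44337   FALSE
#> ...

part <- attr(ev, "partitions")[["goodall.average.3"]]
adjusted_rand(part, setNames(g$truth, rownames(tm$values)))
#> [1] 1

bootstrap_stability(tm, "goodall", k = 3, B = 50, seed = 1)
#> bootstrap stability: measure=goodall, k=3, B=50
#>   cluster size mean_jaccard sd_jaccard n_replicates
#> 1       1   39            1          0           50
#> 2       2   39            1          0           50
#> 3       3   38            1          0           50
```

Reading the numbers: WCE drops sharply up to k = 3 and flattens after
(ΔWCE collapses from 0.317 to 0.008), PSFE peaks at k = 3 — so both the
compactness and separation indices flag the planted three-group
structure, the cut recovers it exactly (adjusted Rand index 1 against
the generator's truth), and all three clusters are perfectly stable
under resampling (mean Jaccard 1).

The packaged transcription of the reference fish trait table is
available as `tbgb_trait_table()` (21 traits, 13 fully observed,
worst-case missingness 23.3%), with its canonical log-width binning
rules in `tbgb_binning_rules()`.

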
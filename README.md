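# metstab

Stability analysis for multi-environment trials (METs) in plant breeding.
When the same genotypes are grown at several test sites, genotype-by-
environment interaction (GEI) reshuffles their ranking from site to site;
the breeder's problem is to separate genuine, repeatable genotype merit from
site-specific noise and to find genotypes that are both high-yielding and
stable. `metstab` implements the two standard multivariate answers —
the AMMI model and the GGE biplot — together with the combined ANOVA that
precedes them and a synthetic MET generator with known ground truth so that
every stage of the pipeline can be validated end to end.

All user-facing functions take a data frame of plot records and return
tibbles (or small fitted objects with `tidy()`, `glance()` and `autoplot()`
methods), so analyses compose with the pipe.

## The models

**AMMI** (additive main effects and multiplicative interaction) fits

    Y_ij = mu + G_i + E_j + sum_k  lambda_k * gamma_ik * delta_jk + rho_ij

where `mu`, `G_i`, `E_j` are the grand mean and the genotype and environment
main effects, and the doubly-centered interaction matrix is decomposed by
SVD into interaction principal components (IPCA) with singular values
`lambda_k` and orthonormal genotype/environment scores `gamma`, `delta`.
Each component gets Gollob degrees of freedom `g + e - 1 - 2k` and a
plot-basis F-test against the error mean square. Per genotype the package
computes the AMMI stability value

    ASV_i = sqrt( ( (SS_IPCA1 / SS_IPCA2) * IPCA1_i )^2 + IPCA2_i^2 )

and the yield stability index `YSI = rank(ASV) + rank(mean yield)`, whose
low values flag genotypes that are simultaneously stable and high-yielding.

**GGE** removes only the environment means, keeping genotype main effect
plus GEI, and displays the first two SVD components under a configurable
singular value partitioning (environment-focused by default). On top of the
scores the package constructs the which-won-where polygon (convex hull with
perpendicular sector boundaries, assigning each environment a winning
genotype), the average-environment-coordination (AEC) view separating mean
performance from instability, per-environment discriminativeness and
representativeness, and the distance of every genotype to the ideal point.

## A worked example

```r
library(metstab)
library(dplyr)

# a 60-genotype, 5-site, 2-replicate alpha-lattice trial with known truth
sim <- simulate_met(sim_config(n_genotypes = 60, n_environments = 5,
                               blocks_per_rep = 6, seed = 2026))

combined_anova(sim$records, "yield")
#>                     source  df      ss     ms statistic p.value  ptss
#> 1              Environment   4 1493.88 373.47    253.23    0.00 49.23
#> 2         Rep(Environment)   5   24.48   4.90      3.32    0.01  0.81
#> 3 Block(Rep x Environment)  50  130.22   2.60      1.77    0.00  4.29
#> 4                 Genotype  59  471.45   7.99      5.42    0.00 15.54
#> 5   Genotype x Environment 236  553.07   2.34      1.59    0.00 18.23
#> 6                    Error 245  361.33   1.47        NA      NA 11.91
```

Environment dominates the partition (49% of the total SS), as is typical
for rainfed cereal METs; genotype and GEI are both significant, so a
stability analysis is warranted.

```r
tab <- cell_means(sim$records, "yield")
fit <- fit_ammi(tab)
stability_table(fit) |> arrange(ysi) |> head(5)
#>   genotype mean_yield   ipca1   ipca2   ipca3   asv rank_asv rank_yield   ysi
#> 1 G007           9.05  0.0412  0.137  -0.0421 0.153        3          1     4
#> 2 G019           8.26  0.120  -0.0549 -0.427  0.208        7          5    12
#> 3 G039           8.12 -0.0118 -0.188   0.770  0.189        5          7    12
#> 4 G055           8.31  0.179   0.106   0.384  0.316       13          3    16
#> 5 G014           8.30  0.221   0.0111 -0.183  0.369       14          4    18
```

G007 combines the highest mean yield (rank 1) with a near-zero interaction
signature (ASV rank 3), giving the best YSI of 4. The GGE view agrees:

```r
gge <- fit_gge(tab)                      # environment-centered, SVP = 2
which_won_where(gge)$environments
#>   environment  angle sector winner
#> 1 E01         -0.636      8 G024
#> 2 E02          0.942      2 G018
#> 3 E03          0.237      1 G007
#> 4 E04          0.441      1 G007
#> 5 E05         -0.185      1 G007
ideal_genotype_distance(gge) |> head(3)
#>   genotype distance  rank
#> 1 G007       0.0279     1
#> 2 G036       0.101      2
#> 3 G019       0.107      3
autoplot(gge, "which_won_where")         # polygon view
```

Three sites form one environment-group won by G007, while E01 and E02 are
each won by a different vertex genotype; G007 is also the closest genotype
to the ideal point on the average environment axis.

`run_pipeline()` drives all stages for one or more traits and writes a TSV
report bundle (ANOVA, component tests, stability table, per-site top-k
selections, biplot coordinates, sectors, AEC projections, environment
diagnostics) plus a manifest.

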
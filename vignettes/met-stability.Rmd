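---
title: "Models and methods: AMMI and GGE stability analysis for multi-environment trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: AMMI and GGE stability analysis for multi-environment trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metstab)
library(dplyr)
```

## The problem

A multi-environment trial (MET) evaluates a set of genotypes at several
test sites. Because genotype-by-environment interaction (GEI) re-ranks
genotypes across sites, neither the overall mean nor any single-site result
identifies the material a breeder should advance. `metstab` implements the
two standard multivariate treatments of the genotype × environment
cell-mean table — AMMI and the GGE biplot — plus the combined ANOVA that
establishes whether GEI is worth modelling at all, and a generator of
synthetic METs with known ground truth.

The package is organised around plot-level records (genotype, environment,
replicate, incomplete block, trait values), the design unit of an
alpha-lattice trial with two replicates: a resolvable layout in which each
replicate is cut into small incomplete blocks to absorb within-site soil
trends.

## Combined analysis of variance

`combined_anova()` partitions the total sum of squares sequentially into
Environment, Rep(Environment), Block(Rep × Environment), Genotype,
Genotype × Environment and Error. Two choices deserve comment.

* **Fixed-effects F-tests.** Every tested source is compared against the
  plot-level error mean square. Field MET reports often treat sites as
  random, which would change the denominators via expected mean squares;
  those denominators depend on variance components that a fixed-effects
  partition does not estimate, so the package tests everything against
  error and leaves REML variance components out of scope.
* **Intra-block analysis.** The lattice blocks enter as fixed effects
  *before* genotypes, so genotype SS is adjusted for blocks (sequential,
  type-I). No recovery of inter-block information is attempted: the
  adjusted means such recovery produces depend on software-specific
  shrinkage choices, whereas the intra-block fixed-effects partition is
  deterministic and can be checked against a brute-force sequence of
  least-squares fits — which is exactly what the test suite does.

Because the design is balanced and complete, the main strata are mutually
orthogonal and the order of everything except Block/Genotype is immaterial.

`bartlett_homogeneity()` checks the assumption behind pooling errors across
sites. Within each environment, residuals are taken about the genotype cell
means, so each site contributes a pure replicate-error variance on
`n_j - g` degrees of freedom; the Bartlett chi-square statistic is computed
on those variances with their residual degrees of freedom (the classic
`n_j - 1` convention would overstate the information in each group once
genotype effects are removed). Identical data in every group give a
statistic of exactly 0; a zero-variance group is an error rather than a
silent `-Inf`.

## The AMMI model

`fit_ammi()` removes the additive part (grand mean, genotype and
environment main effects) and decomposes the doubly-centered interaction
matrix by SVD:

$$Y_{ij} = \mu + G_i + E_j + \sum_{k=1}^{N} \lambda_k \gamma_{ik}
\delta_{jk} + \rho_{ij}.$$

All `min(g-1, e-1)` components are always computed; `n_components` only
controls how many enter the reconstruction, with the remainder forming the
residual $\rho$. Numerical conventions:

* **Sign.** An SVD is unique only up to joint sign flips of each
  $(\gamma_k, \delta_k)$ pair. The package makes the environment score of
  largest magnitude positive within each component, so output is identical
  across linear-algebra backends.
* **Score scaling.** Biplot scores, ASV inputs and the stability table use
  symmetric scaling, $\lambda^{1/2}\gamma$ and $\lambda^{1/2}\delta$, on
  the cell-means basis. Published MET reports rarely state their scaling,
  and printed ASV columns are often irreconcilable with the printed IPCA
  scores they supposedly derive from; fixing one convention and applying it
  consistently is the only reproducible option, and symmetric scaling is
  the common default for AMMI biplots.
* **Gollob tests.** Component $k$ receives $df_k = g + e - 1 - 2k$ and a
  plot-basis SS of $r\lambda_k^2$ (the means-basis SS times the replicate
  count), tested against the plot error mean square. For a 420-genotype,
  five-site trial this gives the familiar df sequence 422, 420, 418, 416.
  Gollob df are liberal; the package offers no cross-validation-based
  component selection.

`asv()` implements the AMMI stability value with the weight defined as the
*ratio of component sums of squares* $\lambda_1^2/\lambda_2^2$ — the
definition in terms of SS, not of singular values. A second singular value
of (numerically) zero leaves the weight undefined and is an error. `ysi()`
adds fractional ranks: ASV ascending, mean yield descending, ties averaged
(two genotypes tied for positions 26 and 27 both rank 26.5), and
`YSI = RASV + RY` exactly. YSI is reported as a real number; truncating
fractional rank sums to integers would discard the tie information.

`top_k_per_environment()` ranks genotypes within each site by the
AMMI-reconstructed cell value using the retained components (a flag
switches to raw cell means), with ties broken by input order.

## The GGE biplot

`fit_gge()` subtracts each environment's mean — no transformation, no
scaling — leaving genotype main effect plus GEI, and decomposes the
centered matrix by SVD. The singular value partitioning (SVP) mode decides
where $\lambda$ goes: environment-focused $(\gamma, \lambda\delta)$ is the
default (appropriate when the display is used to compare environments, and
the convention used for AEC views), with genotype-focused and symmetric
available. SVP affects the displayed scores only: explained percentages,
reconstruction and sector winners are SVP-invariant, which the tests
assert. Score columns belonging to null components (singular value
numerically zero) are set to exactly zero, because the SVD basis beyond the
matrix rank is backend-arbitrary.

All geometry uses the first two components only, as in published biplots;
variation beyond rank 2 is reported as unexplained percentage.

* `which_won_where()` takes the convex hull of the genotype scores, drops a
  ray from the origin perpendicular to each hull edge, and assigns each
  environment to the angular sector containing its score vector; the
  sector's hull vertex is its winner. The construction is equivalent to
  maximising the rank-2 inner product over genotypes, which supplies an
  independent brute-force oracle for the tests. Environments that land
  exactly on a boundary ray go to the counter-clockwise sector; a
  zero-length environment vector is unassignable and reported `NA`. A
  sector containing at least one environment is an "environment-group" —
  the single-season analogue of a mega-environment, which strictly requires
  multi-year repeatability.
* `mean_vs_stability()` projects genotype scores onto the average
  environment axis (AEA, the direction of the mean environment vector):
  the on-axis component orders genotypes by mean performance, the signed
  perpendicular component measures instability.
* `discriminativeness_representativeness()` reports each environment's
  vector length (discriminating power; under environment-focused SVP the
  squared lengths sum to $\lambda_1^2 + \lambda_2^2$) and the cosine of its
  angle with the AEA (representativeness).
* `ideal_genotype_distance()` places the ideal genotype on the AEA at the
  maximum observed mean projection and ranks genotypes by Euclidean
  distance to it.

## The synthetic generator

`simulate_met()` draws plot values as

$$y = \mu + G_i + E_j + \mathrm{GEI}_{ij} + \mathrm{rep}_{jr} +
\mathrm{block}_{jrb} + \varepsilon,$$

with every stratum normal and each drawn from its own substream of the
master seed, so identical configurations are bit-identical and adding a
stratum never perturbs another. $G$ and $E$ are centered to sum exactly to
zero; the interaction matrix is built as $\sum_k \lambda_k u_k v_k^T$ from
Gram–Schmidt-orthonormalised Gaussian vectors, each orthogonal to the
all-ones vector, so it is exactly doubly centered and carries exactly the
requested singular values. Genotypes are assigned to incomplete blocks by a
fresh seeded permutation per replicate within each site, mimicking a
resolvable alpha-lattice layout.

Defaults mirror a national durum wheat trial: 420 genotypes × 5 sites ×
2 replicates, 21 blocks of 20 plots per replicate, grand mean 7 t/ha.
Effect scales (sd 1.0 t/ha for genotypes, 1.8 t/ha for sites, interaction
spectrum 10, 6, 3, 1 on the cell-mean scale, rep sd 0.2, block sd 0.3,
plot error sd 1.3 t/ha) were chosen once to reproduce the qualitative
profile of such trials — environment dominating the SS partition, GEI on
the order of a fifth of the total, IPCA1 carrying roughly half the
interaction — not to match any particular published table, whose raw data
are not available. When a smaller design is requested without an explicit
spectrum, the default spectrum truncates to the design's capacity
`min(g-1, e-1)`.

What the generator deliberately omits: spatial field trend beyond the block
stratum, non-normal error, multi-year weather structure, and genetic
(marker-level) structure among genotypes. Tests passing on synthetic data
therefore demonstrate the correctness of the computations and the
recoverability of a low-rank GEI signal — not that real field data satisfy
the model.

## Validation strategy and problem sizes

The suite validates each stage against an independent route: sequential
least-squares refits for the ANOVA partition, `stats::bartlett.test` on the
configuration where the df conventions coincide, SVD of constructed
known-spectrum matrices (recovered to 1e-9), brute-force argmax for
which-won-where winners (200 random tables), and direct arithmetic for
ASV/YSI/distances. Simulation-based checks use desk-scale designs chosen
for statistical adequacy: parameter recovery at 50 × 5 × 2 and at the full
420 × 5 × 2, error-variance calibration at 10⁴ plots, and the Bartlett
type-I rate over 1000 replicates of a 5 × 20 × 2 null design.

One calibration fact surfaced by the full-scale recovery check is worth
recording: with plot error sd 0.1 and two replicates, the cell-mean noise
matrix of a 420 × 5 trial contributes about 2.1 expected SS to each
interaction component, so the second singular value of a {8, 3} spectrum is
estimated around 3.3–3.4 — an ~11% upward bias that no seed avoids. This
is the familiar inflation of trailing singular values by noise (it shrinks
with more replicates and grows with $\sqrt{g}$), not an implementation
defect: the same estimator recovers the same spectrum within 5% at
50 × 5 × 2. Readers comparing recovered spectra across trial sizes should
expect this bias; the package reports the raw SVD values and applies no
shrinkage.

## Known limitations

* Balanced, single-season, complete two-way tables only; no imputation of
  empty genotype × site cells.
* No REML variance components, no mixed-model F denominators, no recovery
  of inter-block information.
* No stability statistics beyond ASV/YSI, and no bootstrap confidence
  regions on biplot points.
* Biplot geometry is strictly rank-2; conclusions about environments whose
  vectors are poorly represented in two components should be read against
  the explained percentages.
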
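test_that("AMMI recovers constructed spectra and reconstructs cell means", {
  # purely additive table: all singular values 0, residual 0
  ct <- constructed_table(8, 4, spectrum = numeric(0), seed = 51)
  fit <- fit_ammi(ct$values)
  expect_lt(max(fit$singular_values), 1e-9)
  expect_lt(max(abs(fit$residual)), 1e-9)

  # constructed spectrum {4, 2} recovered within 1e-9
  ct2 <- constructed_table(10, 5, spectrum = c(4, 2), seed = 52)
  fit2 <- fit_ammi(ct2$values)
  expect_equal(fit2$singular_values, c(4, 2, 0, 0), tolerance = 1e-9)
  expect_equal(fit2$mu, ct2$mu, tolerance = 1e-12)
  expect_equal(unname(fit2$G), ct2$G, tolerance = 1e-12)

  # full-rank reconstruction is exact; AMMI0 fitted = mu + G + E
  tab <- random_table(9, 5, seed = 53)
  full <- fit_ammi(tab, "all")
  recon <- full$mu + outer(full$G, full$E, `+`) +
    full$genotype_scores %*% (full$singular_values *
                                t(full$environment_scores))
  expect_matrix_equal(recon, tab$values)
  expect_lt(max(abs(full$residual)), 1e-9)
  a0 <- fit_ammi(tab, 0)
  expect_matrix_equal(a0$residual,
                      sweep(sweep(tab$values - a0$mu, 1, a0$G), 2, a0$E))

  # orthonormal score columns, non-increasing spectrum
  expect_matrix_equal(crossprod(full$genotype_scores), diag(4))
  expect_matrix_equal(crossprod(full$environment_scores), diag(4))
  expect_false(is.unsorted(rev(full$singular_values)))

  # sum of squared singular values equals the interaction SS
  eff <- marginal_effects(tab)
  z <- sweep(sweep(tab$values - eff$mu, 1, eff$G), 2, eff$E)
  expect_equal(sum(full$singular_values^2), sum(z^2), tolerance = 1e-9)
  expect_equal(sum(full$ptiss), 100, tolerance = 1e-9)

  # PTISS is scale-invariant
  fit_scaled <- fit_ammi(tab$values * 3.7)
  expect_equal(fit_scaled$ptiss, full$ptiss, tolerance = 1e-9)

  expect_error(fit_ammi(tab, 5), "n_components")
})

test_that("sign convention is deterministic and flips scores together", {
  tab <- random_table(12, 5, seed = 54)
  fit <- fit_ammi(tab)
  for (k in seq_along(fit$singular_values)) {
    d <- fit$environment_scores[, k]
    expect_gt(d[which.max(abs(d))], 0)
  }
  # reconstruction unaffected by the convention
  recon <- fit$genotype_scores %*% (fit$singular_values *
                                      t(fit$environment_scores))
  eff <- marginal_effects(tab)
  z <- sweep(sweep(tab$values - eff$mu, 1, eff$G), 2, eff$E)
  expect_matrix_equal(recon, z)
})

test_that("Gollob tests use g + e - 1 - 2k df on the plot basis", {
  tab <- random_table(20, 5, seed = 55)
  fit <- fit_ammi(tab)
  gt <- gollob_tests(fit, ms_error = 1.3, df_error = 100, n_reps = 2)
  expect_equal(gt$df, as.integer(20 + 5 - 1 - 2 * (1:4)))
  expect_equal(gt$ss, 2 * fit$singular_values^2)
  expect_equal(gt$statistic, (gt$ss / gt$df) / 1.3)
  expect_equal(gt$p.value,
               stats::pf(gt$statistic, gt$df, 100, lower.tail = FALSE))

  # rank-1 interaction: component 1 carries 100% of PTISS, later F = 0
  ct <- constructed_table(10, 4, spectrum = 5, seed = 56)
  g1 <- gollob_tests(fit_ammi(ct$values), ms_error = 1, df_error = 50,
                     n_reps = 2)
  expect_equal(g1$ptiss[1], 100, tolerance = 1e-6)
  expect_equal(g1$statistic[2:3], c(0, 0), tolerance = 1e-12)

  expect_error(gollob_tests(fit, ms_error = 0, df_error = 10), "positive")
})

test_that("ASV follows the weighted-norm formula and is monotone", {
  ct <- constructed_table(15, 5, spectrum = c(6, 3, 1), seed = 57)
  fit <- fit_ammi(ct$values)
  a <- asv(fit)
  l <- fit$singular_values
  s1 <- sqrt(l[1]) * fit$genotype_scores[, 1]
  s2 <- sqrt(l[2]) * fit$genotype_scores[, 2]
  expect_equal(unname(a), unname(sqrt(((l[1]^2 / l[2]^2) * s1)^2 + s2^2)),
               tolerance = 1e-12)

  # monotone bounds from the formula
  w <- l[1]^2 / l[2]^2
  expect_true(all(unname(a) >= abs(unname(s2)) - 1e-12))      # adding |IPCA1| never decreases
  expect_true(all(unname(a) >= w * abs(unname(s1)) - 1e-12))  # adding |IPCA2| never decreases

  # degenerate weight
  ct1 <- constructed_table(10, 4, spectrum = 5, seed = 58)
  expect_error(asv(fit_ammi(ct1$values)), "undefined")
})

test_that("fractional ranks average tied positions", {
  expect_equal(rank_with_ties(c(5, 3, 9)), c(2, 1, 3))
  expect_equal(rank_with_ties(rep(1, 4)), rep(2.5, 4))
  expect_equal(rank_with_ties(c(2, 1, 1), ascending = FALSE), c(1, 2.5, 2.5))
  # two values tied for positions 26 and 27 both get 26.5
  x <- c(seq(100, 76, by = -1), 50, 50, seq(40, 20, by = -1))
  expect_equal(rank_with_ties(x, ascending = FALSE)[26:27], c(26.5, 26.5))
  expect_error(rank_with_ties(c(1, NA)), "non-finite")
  expect_error(rank_with_ties(numeric(0)), "empty")
})

test_that("YSI is the exact sum of the ASV and yield ranks", {
  set.seed(61)
  n <- 25
  a <- stats::setNames(abs(rnorm(n)), sprintf("G%02d", 1:n))
  y <- stats::setNames(rnorm(n, 7), names(a))
  tab <- ysi(a, y)
  expect_equal(tab$ysi, tab$rank_asv + tab$rank_yield)
  expect_equal(sum(tab$rank_asv), n * (n + 1) / 2)
  expect_equal(sum(tab$rank_yield), n * (n + 1) / 2)
  expect_equal(tab$rank_yield[which.max(tab$mean_yield)], 1)
  expect_equal(tab$rank_asv[which.min(tab$asv)], 1)

  # single genotype: both ranks are 1, YSI = 2
  expect_equal(ysi(c(G1 = 0.5), c(G1 = 9))$ysi, 2)

  # mismatched genotype sets
  expect_error(ysi(a, y[-1]), "same genotype set")

  # stability_table carries the same identities plus scaled scores
  ct <- constructed_table(12, 5, spectrum = c(4, 2), seed = 62)
  fit <- fit_ammi(ct$values)
  st <- stability_table(fit)
  expect_equal(st$ysi, st$rank_asv + st$rank_yield)
  expect_equal(st$asv, unname(asv(fit)))
  expect_equal(st$mean_yield, unname(fit$mu + fit$G))
  expect_equal(st$ipca1, sqrt(fit$singular_values[1]) *
                 unname(fit$genotype_scores[, 1]))
})

test_that("AMMI biplot coordinates follow the symmetric scaling", {
  ct <- constructed_table(10, 5, spectrum = c(4, 2), seed = 63)
  fit <- fit_ammi(ct$values)
  c1 <- ammi_biplot_coords(fit, "AMMI1")
  env1 <- c1[c1$type == "environment", ]
  gen1 <- c1[c1$type == "genotype", ]
  expect_equal(gen1$x, unname(fit$mu + fit$G))
  expect_equal(env1$x, unname(fit$mu + fit$E))
  # environment IPCA1 scores sum to 0 (centering)
  expect_lt(abs(sum(env1$y)), 1e-9)
  expect_lt(abs(sum(gen1$y)), 1e-9)

  c2 <- ammi_biplot_coords(fit, "AMMI2")
  expect_equal(c2$x[c2$type == "genotype"],
               sqrt(fit$singular_values[1]) * unname(fit$genotype_scores[, 1]))

  # additive table: all AMMI2 points at the origin
  add <- constructed_table(8, 4, spectrum = numeric(0), seed = 64)
  cadd <- ammi_biplot_coords(fit_ammi(add$values), "AMMI2")
  expect_lt(max(abs(c(cadd$x, cadd$y))), 1e-6)

  # ASV is monotone in |IPCA1| and |IPCA2|: dominance in both coordinates
  # implies dominance in ASV (so the origin is always minimal)
  a <- unname(asv(fit))
  x <- abs(c2$x[c2$type == "genotype"]); y <- abs(c2$y[c2$type == "genotype"])
  for (i in seq_along(a)) for (j in seq_along(a)) {
    if (x[i] <= x[j] && y[i] <= y[j]) expect_lte(a[i], a[j] + 1e-12)
  }
})

test_that("top-k selection ranks by reconstructed cell value", {
  # purely additive: every environment lists the same genotypes, by G effect
  add <- constructed_table(10, 4, spectrum = numeric(0), seed = 65)
  fit <- fit_ammi(add$values)
  tk <- top_k_per_environment(fit, 3)
  expected <- rownames(add$values)[order(-add$G)][1:3]
  for (e in unique(tk$environment)) {
    expect_equal(tk$genotype[tk$environment == e], expected)
  }

  # brute-force argmax oracle on the reconstructed means, incl. a spike
  ct <- constructed_table(12, 4, spectrum = c(5, 2), seed = 66)
  fit2 <- fit_ammi(ct$values, 2)
  tk2 <- top_k_per_environment(fit2, 4)
  recon <- fit2$mu + outer(fit2$G, fit2$E, `+`) +
    fit2$genotype_scores[, 1:2] %*% (fit2$singular_values[1:2] *
                                       t(fit2$environment_scores[, 1:2]))
  for (j in seq_len(ncol(recon))) {
    expect_equal(tk2$genotype[tk2$environment == colnames(recon)[j]],
                 rownames(recon)[order(-recon[, j])][1:4])
  }

  # k = number of genotypes gives a permutation of all genotypes
  tkall <- top_k_per_environment(fit, 10)
  for (e in unique(tkall$environment)) {
    expect_setequal(tkall$genotype[tkall$environment == e],
                    rownames(add$values))
  }
  # raw-mean ranking flag uses the cell means themselves
  tkraw <- top_k_per_environment(fit2, 2, use_fitted = FALSE)
  for (j in 1:2) {
    expect_equal(tkraw$genotype[tkraw$environment == colnames(recon)[j]],
                 rownames(ct$values)[order(-ct$values[, j])][1:2])
  }
  expect_error(top_k_per_environment(fit, 50), "exceeds")
})

test_that("tidy and glance summarise AMMI fits", {
  ct <- constructed_table(10, 5, spectrum = c(4, 2), seed = 67)
  fit <- fit_ammi(ct$values)
  comp <- tidy(fit, "components")
  expect_equal(comp$singular_value, fit$singular_values)
  gen <- tidy(fit, "genotypes")
  expect_equal(gen$mean, unname(fit$mu + fit$G))
  gl <- glance(fit)
  expect_equal(gl$ptiss_retained, 100, tolerance = 1e-6)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
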
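#' Fit the AMMI model to a cell-mean table
#'
#' Additive main effects and multiplicative interaction: the grand mean and
#' genotype/environment main effects are removed from the cell means and the
#' doubly-centered interaction matrix is decomposed by SVD,
#' \deqn{Y_{ij} = \mu + G_i + E_j + \sum_k \lambda_k \gamma_{ik} \delta_{jk} + \rho_{ij},}
#' with \eqn{\gamma, \delta} orthonormal interaction principal component
#' (IPCA) scores and \eqn{\lambda_k} the singular values. The first
#' `n_components` terms are retained; the rest form the residual
#' \eqn{\rho}. Sign convention: within each component, the environment score
#' of largest absolute value is made positive (the genotype and environment
#' vectors flip together), so results are reproducible across linear-algebra
#' backends.
#'
#' @param table A `two_way_table` from [cell_means()], or a numeric matrix.
#' @param n_components Number of multiplicative terms to retain, or `"all"`
#'   for `min(g - 1, e - 1)`.
#'
#' @return An `ammi_fit` with elements `mu`, `G`, `E`, `singular_values`,
#'   `genotype_scores` and `environment_scores` (orthonormal, all
#'   `min(g - 1, e - 1)` components), `n_components`, `residual`,
#'   `ss_interaction`, `component_ss` (\eqn{\lambda_k^2}) and `ptiss`
#'   (percent of the interaction SS per component), plus the cell-mean
#'   matrix `values` and `n_reps`.
#' @export
#' @examples
#' sim <- simulate_met(sim_config(n_genotypes = 30, n_environments = 5,
#'                                blocks_per_rep = 5, seed = 9))
#' fit <- fit_ammi(cell_means(sim$records, "yield"))
#' fit$ptiss
fit_ammi <- function(table, n_components = "all") {
  m <- if (inherits(table, "two_way_table")) table$values else as.matrix(table)
  n_reps <- if (inherits(table, "two_way_table")) table$n_reps else 1L
  if (anyNA(m)) stop("incomplete table", call. = FALSE)
  g <- nrow(m); e <- ncol(m)
  if (g < 2 || e < 2) stop("need >= 2 genotypes and >= 2 environments",
                           call. = FALSE)
  kmax <- min(g - 1, e - 1)
  n_comp <- if (identical(n_components, "all")) kmax else as.integer(n_components)
  if (n_comp > kmax) {
    stop("n_components exceeds min(g - 1, e - 1) = ", kmax, call. = FALSE)
  }

  eff <- marginal_effects(m)
  interaction <- sweep(sweep(m - eff$mu, 1, eff$G), 2, eff$E)
  sv <- svd(interaction, nu = kmax, nv = kmax)
  lambda <- sv$d[seq_len(kmax)]
  gamma <- sv$u
  delta <- sv$v
  for (k in seq_len(kmax)) {            # deterministic sign convention
    if (delta[which.max(abs(delta[, k])), k] < 0) {
      gamma[, k] <- -gamma[, k]
      delta[, k] <- -delta[, k]
    }
  }
  rownames(gamma) <- rownames(m); rownames(delta) <- colnames(m)

  trunc_rec <- if (n_comp > 0) {
    gamma[, seq_len(n_comp), drop = FALSE] %*%
      (lambda[seq_len(n_comp)] * t(delta[, seq_len(n_comp), drop = FALSE]))
  } else {
    matrix(0, g, e)
  }
  ss_int <- sum(interaction^2)
  comp_ss <- lambda^2
  structure(
    list(mu = eff$mu, G = eff$G, E = eff$E,
         singular_values = lambda,
         genotype_scores = gamma, environment_scores = delta,
         n_components = n_comp,
         residual = interaction - trunc_rec,
         ss_interaction = ss_int,
         component_ss = comp_ss,
         ptiss = if (ss_int > 0) 100 * comp_ss / ss_int else rep(0, kmax),
         values = m, n_reps = n_reps),
    class = "ammi_fit"
  )
}

#' @export
print.ammi_fit <- function(x, ...) {
  cat("AMMI fit: ", length(x$G), " genotypes x ", length(x$E),
      " environments, ", x$n_components, " of ",
      length(x$singular_values), " IPCA component(s) retained\n", sep = "")
  cat("Interaction SS ", format(x$ss_interaction, digits = 6),
      "; PTISS: ", paste(sprintf("%.1f", x$ptiss), collapse = " "),
      "\n", sep = "")
  invisible(x)
}

# Symmetric (lambda^1/2) scaled IPCA scores on the cell-means basis; used by
# ASV, the stability table and the AMMI biplots.
scaled_scores <- function(fit, side = c("genotype", "environment")) {
  side <- match.arg(side)
  sc <- if (side == "genotype") fit$genotype_scores else fit$environment_scores
  sweep(sc, 2, sqrt(fit$singular_values), `*`)
}

#' Gollob F-tests for AMMI components
#'
#' Assigns each multiplicative term `k` Gollob degrees of freedom
#' `g + e - 1 - 2k` and a plot-basis sum of squares `n_reps * lambda_k^2`,
#' then tests `MS_k` against the plot-level error mean square.
#'
#' @param fit An [fit_ammi()] result.
#' @param ms_error Error mean square on the plot basis (from
#'   [combined_anova()]).
#' @param df_error Error degrees of freedom.
#' @param n_reps Replicates per cell; defaults to the fit's.
#'
#' @return A tibble with one row per component: `component`, `df`, `ss`,
#'   `ms`, `statistic`, `p.value`, `ptiss`.
#' @export
gollob_tests <- function(fit, ms_error, df_error, n_reps = fit$n_reps) {
  if (ms_error <= 0) stop("ms_error must be positive", call. = FALSE)
  g <- length(fit$G); e <- length(fit$E)
  k <- seq_along(fit$singular_values)
  df <- g + e - 1 - 2 * k
  ss <- n_reps * fit$singular_values^2
  ms <- ss / df
  f <- ms / ms_error
  tibble::tibble(
    component = paste0("IPCA", k), df = as.integer(df), ss = ss, ms = ms,
    statistic = f,
    p.value = stats::pf(f, df, df_error, lower.tail = FALSE),
    ptiss = fit$ptiss
  )
}

#' AMMI stability value
#'
#' \deqn{ASV_i = \sqrt{\left(\frac{SS_{IPCA1}}{SS_{IPCA2}} IPCA1_i\right)^2 + IPCA2_i^2}}
#' where the weight is the ratio of the first two component sums of squares
#' (\eqn{\lambda_1^2 / \lambda_2^2}) and the IPCA scores are the
#' symmetric-scaled genotype scores. Small ASV means the genotype sits near
#' the biplot origin: little interaction with environments.
#'
#' @param fit An [fit_ammi()] result with at least 2 components.
#' @return A named per-genotype numeric vector.
#' @export
asv <- function(fit) {
  if (length(fit$singular_values) < 2) {
    stop("ASV needs at least two interaction components", call. = FALSE)
  }
  l <- fit$singular_values
  if (l[2] <= 1e-10 * max(l[1], 1)) {
    stop("second singular value is zero; ASV weight undefined", call. = FALSE)
  }
  sc <- scaled_scores(fit, "genotype")
  w <- l[1]^2 / l[2]^2
  sqrt((w * sc[, 1])^2 + sc[, 2]^2)
}

#' Fractional (average) ranks
#'
#' Ties share the mean of the positions they occupy; the best value (the
#' smallest when `ascending`, the largest otherwise) gets rank 1.
#'
#' @param values Numeric vector of finite values.
#' @param ascending If `TRUE` small values rank first.
#' @return A numeric vector of ranks.
#' @export
#' @examples
#' rank_with_ties(c(5, 3, 9))            # 2 1 3
#' rank_with_ties(c(2, 1, 1), ascending = FALSE)  # 1 2.5 2.5
rank_with_ties <- function(values, ascending = TRUE) {
  if (length(values) == 0) stop("empty input", call. = FALSE)
  if (any(!is.finite(values))) stop("non-finite value in input", call. = FALSE)
  if (ascending) rank(values, ties.method = "average")
  else rank(-values, ties.method = "average")
}

#' Yield stability index
#'
#' Ranks genotypes by stability (ASV, ascending: most stable first) and by
#' mean performance (descending: highest mean first) and sums the two ranks:
#' `YSI = RASV + RY`. Low YSI flags genotypes that are both stable and
#' high-yielding. Tied ranks are fractional, so YSI can be fractional.
#'
#' @param asv_values Named per-genotype ASV vector (see [asv()]).
#' @param mean_yields Named per-genotype mean performance, same genotype set.
#' @return A tibble with `genotype`, `mean_yield`, `asv`, `rank_asv`,
#'   `rank_yield`, `ysi`, in the genotype order of `asv_values`.
#' @export
ysi <- function(asv_values, mean_yields) {
  if (is.null(names(asv_values)) || is.null(names(mean_yields)) ||
      !setequal(names(asv_values), names(mean_yields)) ||
      anyDuplicated(names(asv_values)) || anyDuplicated(names(mean_yields))) {
    stop("asv_values and mean_yields must be named by the same genotype set",
         call. = FALSE)
  }
  mean_yields <- mean_yields[names(asv_values)]
  rank_asv <- rank_with_ties(unname(asv_values), ascending = TRUE)
  rank_yield <- rank_with_ties(unname(mean_yields), ascending = FALSE)
  tibble::tibble(
    genotype = names(asv_values),
    mean_yield = unname(mean_yields),
    asv = unname(asv_values),
    rank_asv = rank_asv,
    rank_yield = rank_yield,
    ysi = rank_asv + rank_yield
  )
}

#' Per-genotype stability summary table
#'
#' Convenience wrapper combining the genotype means, the first IPCA scores,
#' [asv()] and [ysi()] into one table, sorted by the input genotype order.
#'
#' @param fit An [fit_ammi()] result with at least 2 components.
#' @param n_scores Number of IPCA score columns to include (default 3,
#'   capped at the number of components).
#' @return A tibble with `genotype`, `mean_yield`, `ipca1`, `ipca2`, ...,
#'   `asv`, `rank_asv`, `rank_yield`, `ysi`.
#' @export
stability_table <- function(fit, n_scores = 3) {
  a <- asv(fit)
  means <- fit$mu + fit$G
  out <- ysi(a, means)
  sc <- scaled_scores(fit, "genotype")
  n_scores <- min(n_scores, ncol(sc))
  for (k in seq_len(n_scores)) out[[paste0("ipca", k)]] <- unname(sc[, k])
  out[, c("genotype", "mean_yield", paste0("ipca", seq_len(n_scores)),
          "asv", "rank_asv", "rank_yield", "ysi")]
}

#' AMMI biplot coordinates
#'
#' `"AMMI1"` plots mean performance (`mu + G_i`, `mu + E_j`) against the
#' first IPCA score; `"AMMI2"` plots the first two IPCA scores. Scores are
#' symmetric-scaled (\eqn{\lambda^{1/2}\gamma}, \eqn{\lambda^{1/2}\delta}).
#'
#' @param fit An [fit_ammi()] result.
#' @param kind `"AMMI1"` or `"AMMI2"`.
#' @return A tibble with `type` (genotype/environment), `id`, `x`, `y`.
#' @export
ammi_biplot_coords <- function(fit, kind = c("AMMI2", "AMMI1")) {
  kind <- match.arg(kind)
  need <- if (kind == "AMMI1") 1 else 2
  if (length(fit$singular_values) < need) {
    stop(kind, " needs at least ", need, " component(s)", call. = FALSE)
  }
  gs <- scaled_scores(fit, "genotype")
  es <- scaled_scores(fit, "environment")
  if (kind == "AMMI1") {
    x_g <- fit$mu + fit$G; y_g <- gs[, 1]
    x_e <- fit$mu + fit$E; y_e <- es[, 1]
  } else {
    x_g <- gs[, 1]; y_g <- gs[, 2]
    x_e <- es[, 1]; y_e <- es[, 2]
  }
  x_g <- unname(x_g); y_g <- unname(y_g)
  x_e <- unname(x_e); y_e <- unname(y_e)
  tibble::tibble(
    type = rep(c("genotype", "environment"),
               c(length(fit$G), length(fit$E))),
    id = c(names(fit$G), names(fit$E)),
    x = c(x_g, x_e), y = c(y_g, y_e)
  )
}

#' Top-k genotypes per environment by AMMI-fitted value
#'
#' Ranks genotypes within each environment by the AMMI-reconstructed cell
#' value `mu + G_i + E_j + sum of retained multiplicative terms` (or by the
#' raw cell mean with `use_fitted = FALSE`). Ties keep genotype input order.
#'
#' @param fit An [fit_ammi()] result.
#' @param k Number of genotypes per environment.
#' @param use_fitted Use AMMI-fitted values (default) or raw cell means.
#' @return A tibble with `environment`, `rank`, `genotype`, `value`.
#' @export
top_k_per_environment <- function(fit, k = 4, use_fitted = TRUE) {
  g <- length(fit$G)
  if (k > g) stop("k exceeds the number of genotypes", call. = FALSE)
  fitted <- if (use_fitted) ammi_fitted(fit) else fit$values
  purrr::map_dfr(seq_along(fit$E), function(j) {
    ord <- order(-fitted[, j], seq_len(g))[seq_len(k)]
    tibble::tibble(environment = names(fit$E)[j], rank = seq_len(k),
                   genotype = names(fit$G)[ord], value = unname(fitted[ord, j]))
  })
}

# AMMI model matrix: additive part plus retained multiplicative terms.
ammi_fitted <- function(fit) {
  n_comp <- fit$n_components
  rec <- if (n_comp > 0) {
    fit$genotype_scores[, seq_len(n_comp), drop = FALSE] %*%
      (fit$singular_values[seq_len(n_comp)] *
         t(fit$environment_scores[, seq_len(n_comp), drop = FALSE]))
  } else {
    0
  }
  outer(fit$G, fit$E, `+`) + fit$mu + rec
}

#' @rdname tidy.ammi_fit
#' @method glance ammi_fit
#' @export
glance.ammi_fit <- function(x, ...) {
  tibble::tibble(
    n_genotypes = length(x$G), n_environments = length(x$E),
    n_components = x$n_components,
    ss_interaction = x$ss_interaction,
    ptiss_retained = sum(x$ptiss[seq_len(x$n_components)])
  )
}

#' Tidy an AMMI fit
#'
#' @param x An `ammi_fit`.
#' @param type `"genotypes"` (main effect + scaled IPCA scores),
#'   `"environments"` (likewise) or `"components"` (singular values and
#'   PTISS).
#' @param ... Unused.
#' @return A tibble.
#' @method tidy ammi_fit
#' @export
tidy.ammi_fit <- function(x, type = c("genotypes", "environments",
                                      "components"), ...) {
  type <- match.arg(type)
  if (type == "components") {
    return(tibble::tibble(component = paste0("IPCA",
                                             seq_along(x$singular_values)),
                          singular_value = x$singular_values,
                          ss = x$component_ss, ptiss = x$ptiss))
  }
  side <- if (type == "genotypes") "genotype" else "environment"
  eff <- if (side == "genotype") x$G else x$E
  sc <- scaled_scores(x, side)
  out <- tibble::tibble(!!side := names(eff), effect = unname(eff),
                        mean = x$mu + unname(eff))
  for (k in seq_len(min(3, ncol(sc)))) out[[paste0("ipca", k)]] <- unname(sc[, k])
  out
}

#' AMMI biplot
#'
#' @param object An `ammi_fit`.
#' @param kind `"AMMI2"` (IPCA1 vs IPCA2) or `"AMMI1"` (mean vs IPCA1).
#' @param label_environments Draw environment labels (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ammi_fit
#' @export
autoplot.ammi_fit <- function(object, kind = c("AMMI2", "AMMI1"),
                              label_environments = TRUE, ...) {
  kind <- match.arg(kind)
  coords <- ammi_biplot_coords(object, kind)
  p <- ggplot2::ggplot(coords, ggplot2::aes(x = .data$x, y = .data$y,
                                            colour = .data$type)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(data = ~ dplyr::filter(.x, .data$type == "genotype"),
                        alpha = 0.6, size = 1) +
    ggplot2::labs(
      x = if (kind == "AMMI1") "Mean" else "IPCA1",
      y = if (kind == "AMMI1") "IPCA1" else "IPCA2",
      colour = NULL
    ) +
    ggplot2::theme_minimal()
  if (kind == "AMMI2") {
    p <- p + ggplot2::geom_vline(xintercept = 0, linetype = 2,
                                 colour = "grey60")
  }
  env <- dplyr::filter(coords, .data$type == "environment")
  p <- p + ggplot2::geom_segment(
    data = env,
    ggplot2::aes(x = if (kind == "AMMI1") .data$x else 0,
                 xend = .data$x, y = 0, yend = .data$y),
    arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))
  )
  if (label_environments) {
    p <- p + ggplot2::geom_text(data = env,
                                ggplot2::aes(label = .data$id),
                                vjust = -0.5, show.legend = FALSE)
  }
  p
}
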
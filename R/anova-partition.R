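#' Combined fixed-effects ANOVA for a balanced MET
#'
#' Partitions the total sum of squares of one trait into Environment,
#' Rep(Environment), Block(Rep x Environment), Genotype, Genotype x
#' Environment and Error strata, using sequential (type-I) sums of squares
#' in that order. Blocks are the incomplete blocks of the lattice layout,
#' fitted as fixed effects before genotypes (an intra-block analysis). Every
#' tested source is compared against the error mean square.
#'
#' @param records A data frame of plot records (see [read_met_csv()]);
#'   the design must be balanced and complete (every genotype in every
#'   environment x replicate).
#' @param trait Name of the trait column.
#'
#' @return A tibble of class `met_anova` with columns `source`, `df`, `ss`,
#'   `ms`, `statistic` (F), `p.value` and `ptss` (percent of total SS), plus
#'   attributes `total_df` and `total_ss`.
#' @export
#' @examples
#' sim <- simulate_met(sim_config(n_genotypes = 12, n_environments = 3,
#'                                blocks_per_rep = 3, seed = 2))
#' combined_anova(sim$records, "yield")
combined_anova <- function(records, trait) {
  stopifnot(is.data.frame(records))
  if (!trait %in% names(records)) {
    stop("trait column '", trait, "' not found", call. = FALSE)
  }
  d <- data.frame(
    y = records[[trait]],
    genotype = factor(records$genotype, levels = unique(records$genotype)),
    environment = factor(records$environment,
                         levels = unique(records$environment)),
    replicate = factor(records$replicate),
    block = factor(records$block)
  )
  if (anyNA(d$y)) stop("missing trait values", call. = FALSE)
  counts <- table(d$genotype, d$environment, d$replicate)
  if (any(counts != 1)) {
    bad <- which(counts != 1, arr.ind = TRUE)
    stop("unbalanced design: ", nrow(bad),
         " genotype x environment x replicate cell(s) without exactly one plot",
         call. = FALSE)
  }
  if (nlevels(d$replicate) < 2) {
    stop("need >= 2 replicates for the Rep(Environment) stratum",
         call. = FALSE)
  }

  fml <- y ~ environment + environment:replicate +
    environment:replicate:block + genotype + environment:genotype
  fit <- stats::lm(stats::terms(fml, keep.order = TRUE), data = d)
  av <- stats::anova(fit)

  src_map <- c("environment" = "Environment",
               "environment:replicate" = "Rep(Environment)",
               "environment:replicate:block" = "Block(Rep x Environment)",
               "genotype" = "Genotype",
               "environment:genotype" = "Genotype x Environment",
               "Residuals" = "Error")
  out <- tibble::tibble(
    source = unname(src_map[rownames(av)]),
    df = as.integer(av$Df),
    ss = av$`Sum Sq`,
    ms = av$`Sum Sq` / av$Df
  )
  ms_error <- out$ms[out$source == "Error"]
  df_error <- out$df[out$source == "Error"]
  out$statistic <- ifelse(out$source == "Error", NA_real_, out$ms / ms_error)
  out$p.value <- ifelse(out$source == "Error", NA_real_,
                        stats::pf(out$statistic, out$df, df_error,
                                  lower.tail = FALSE))
  total_ss <- sum(out$ss)
  out$ptss <- 100 * out$ss / total_ss
  structure(out, class = c("met_anova", class(out)),
            total_df = sum(out$df), total_ss = total_ss)
}

#' @export
print.met_anova <- function(x, ...) {
  cat("Combined MET analysis of variance (sequential SS)\n")
  NextMethod()
  invisible(x)
}

#' Bartlett's test of error-variance homogeneity across environments
#'
#' Within each environment, residuals are taken about the genotype cell
#' means (the pure replicate error), giving each group a residual variance
#' on `n_j - g_j` degrees of freedom, where `g_j` is the number of genotype
#' cells in the group. The Bartlett chi-square statistic is computed on
#' these variances with their residual degrees of freedom.
#'
#' @param records A data frame of plot records.
#' @param trait Name of the trait column.
#' @param group_by Grouping column; only `"environment"` is supported.
#'
#' @return A one-row tibble with `statistic`, `df` (groups - 1) and
#'   `p.value` (upper chi-square tail).
#' @export
#' @examples
#' sim <- simulate_met(sim_config(n_genotypes = 20, n_environments = 4,
#'                                blocks_per_rep = 4, seed = 3))
#' bartlett_homogeneity(sim$records, "yield")
bartlett_homogeneity <- function(records, trait, group_by = "environment") {
  stopifnot(group_by == "environment")
  y <- records[[trait]]
  env <- factor(records$environment, levels = unique(records$environment))
  gen <- records$genotype
  k <- nlevels(env)
  if (k < 2) stop("need >= 2 environments", call. = FALSE)

  df_j <- s2_j <- numeric(k)
  for (j in seq_len(k)) {
    sel <- env == levels(env)[j]
    yj <- y[sel]
    cells <- factor(gen[sel])
    if (length(yj) < 2) stop("group with < 2 observations", call. = FALSE)
    res <- yj - stats::ave(yj, cells)
    df_j[j] <- length(yj) - nlevels(cells)
    if (df_j[j] < 1) stop("no residual degrees of freedom in group ",
                          levels(env)[j], call. = FALSE)
    s2_j[j] <- sum(res^2) / df_j[j]
  }
  if (any(s2_j <= 0)) {
    stop("degenerate (zero) residual variance in at least one group",
         call. = FALSE)
  }
  n_tot <- sum(df_j)
  s2_pooled <- sum(df_j * s2_j) / n_tot
  stat <- (n_tot * log(s2_pooled) - sum(df_j * log(s2_j))) /
    (1 + (sum(1 / df_j) - 1 / n_tot) / (3 * (k - 1)))
  tibble::tibble(statistic = stat, df = k - 1L,
                 p.value = stats::pchisq(stat, k - 1, lower.tail = FALSE))
}
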
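#' Configuration for a synthetic multi-environment trial
#'
#' The defaults emulate a national durum-wheat trial: 420 genotypes grown at
#' 5 test sites in an alpha-lattice layout with 2 replicates and 21
#' incomplete blocks of 20 plots per replicate. Trait units are t/ha
#' throughout. Effect scales default to an environment-dominant profile
#' (site effects larger than genotype effects, a decaying interaction
#' spectrum), the pattern typical of rainfed cereal METs.
#'
#' @param n_genotypes,n_environments,n_reps Design dimensions.
#' @param blocks_per_rep Incomplete blocks per replicate; must divide
#'   `n_genotypes`.
#' @param mu Grand mean of the trait.
#' @param sd_G,sd_E Standard deviations of the genotype and environment
#'   main effects (drawn normal, then centered to sum exactly to zero).
#' @param interaction_singular_values Non-increasing, non-negative singular
#'   values of the true genotype-by-environment interaction matrix (on the
#'   cell-mean scale); at most `min(n_genotypes - 1, n_environments - 1)`.
#' @param sd_rep,sd_block SDs of replicate-within-environment and
#'   block-within-replicate effects.
#' @param sd_error SD of the i.i.d. plot error.
#' @param seed Master seed; every stratum draws from a substream derived
#'   from it, so identical configs give bit-identical data.
#'
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genotypes = 420, n_environments = 5, n_reps = 2,
                       blocks_per_rep = 21, mu = 7,
                       sd_G = 1.0, sd_E = 1.8,
                       interaction_singular_values = c(10, 6, 3, 1),
                       sd_rep = 0.2, sd_block = 0.3, sd_error = 1.3,
                       seed = 1L) {
  if (missing(interaction_singular_values)) {
    # default spectrum adapts to smaller designs; explicit values must fit
    keep <- min(length(interaction_singular_values),
                n_genotypes - 1, n_environments - 1)
    interaction_singular_values <- interaction_singular_values[seq_len(keep)]
  }
  cfg <- list(n_genotypes = as.integer(n_genotypes),
              n_environments = as.integer(n_environments),
              n_reps = as.integer(n_reps),
              blocks_per_rep = as.integer(blocks_per_rep),
              mu = mu, sd_G = sd_G, sd_E = sd_E,
              interaction_singular_values = as.numeric(interaction_singular_values),
              sd_rep = sd_rep, sd_block = sd_block, sd_error = sd_error,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_genotypes < 2 || n_environments < 2 || n_reps < 1) {
      stop("design dimensions too small", call. = FALSE)
    }
    if (n_genotypes %% blocks_per_rep != 0) {
      stop("blocks_per_rep must divide n_genotypes", call. = FALSE)
    }
    sv <- interaction_singular_values
    if (length(sv) > min(n_genotypes - 1, n_environments - 1)) {
      stop("too many interaction singular values for the design dimensions",
           call. = FALSE)
    }
    if (length(sv) > 0 && (any(sv < 0) || is.unsorted(rev(sv)))) {
      stop("singular values must be non-increasing and non-negative",
           call. = FALSE)
    }
    for (s in c(sd_G, sd_E, sd_rep, sd_block, sd_error)) {
      if (s < 0) stop("standard deviations must be >= 0", call. = FALSE)
    }
  })
  invisible(cfg)
}

# Deterministic substream: each named stratum gets its own seed derived from
# the master seed, so adding a stratum never shifts the draws of another.
with_substream <- function(seed, stratum, code) {
  offset <- match(stratum, c("G", "E", "interaction", "rep", "block",
                             "error", "layout"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed((seed %% 1000000L) * 1000L + offset)
  force(code)
}

#' Low-rank doubly-centered interaction matrix with a chosen spectrum
#'
#' Builds \eqn{\sum_k \lambda_k u_k v_k^T} from random orthonormal factors
#' that are each orthogonal to the all-ones vector (Gram-Schmidt), so the
#' result has exactly zero row and column sums and exactly the requested
#' non-zero singular values.
#'
#' @param n_genotypes,n_environments Matrix dimensions.
#' @param singular_values Non-increasing, non-negative values; length at
#'   most `min(n_genotypes - 1, n_environments - 1)`.
#' @param seed Integer seed for the random factors.
#' @return A `n_genotypes` x `n_environments` numeric matrix.
#' @export
#' @examples
#' m <- make_lowrank_interaction(10, 5, c(3, 1), seed = 7)
#' svd(m)$d[1:2]
make_lowrank_interaction <- function(n_genotypes, n_environments,
                                     singular_values, seed = 1L) {
  k <- length(singular_values)
  if (k > min(n_genotypes - 1, n_environments - 1)) {
    stop("too many singular values for the dimensions", call. = FALSE)
  }
  if (k == 0) return(matrix(0, n_genotypes, n_environments))
  with_substream(seed, "interaction", {
    u <- orthonormal_factors(n_genotypes, k)
    v <- orthonormal_factors(n_environments, k)
    u %*% diag(singular_values, k, k) %*% t(v)
  })
}

# k random unit vectors in R^n, mutually orthogonal and orthogonal to 1.
orthonormal_factors <- function(n, k) {
  basis <- cbind(rep(1 / sqrt(n), n))
  out <- matrix(0, n, k)
  for (i in seq_len(k)) {
    repeat {
      x <- stats::rnorm(n)
      x <- x - basis %*% crossprod(basis, x)
      nx <- sqrt(sum(x^2))
      if (nx > 1e-8) break
    }
    out[, i] <- x / nx
    basis <- cbind(basis, out[, i])
  }
  out
}

#' Simulate a plot-level MET dataset with known ground truth
#'
#' Generates `plot value = mu + G_i + E_j + GEI_ij + rep + block + error`,
#' each stratum drawn from its own seeded substream. Genotypes are assigned
#' to incomplete blocks by a fresh seeded permutation per replicate within
#' each environment (an alpha-lattice-style resolvable layout).
#'
#' @param config A [sim_config()].
#' @return A list with `records` (tibble of plot records with trait column
#'   `yield`) and `truth` (`mu`, centered `G` and `E` vectors, the
#'   doubly-centered `interaction` matrix and its `singular_values`).
#' @export
#' @examples
#' sim <- simulate_met(sim_config(n_genotypes = 20, n_environments = 4,
#'                                blocks_per_rep = 4, seed = 42))
#' head(sim$records)
#' sim$truth$singular_values
simulate_met <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  validate_sim_config(config)
  ng <- config$n_genotypes; ne <- config$n_environments; nr <- config$n_reps
  nb <- config$blocks_per_rep
  block_size <- ng %/% nb
  seed <- config$seed

  G <- with_substream(seed, "G", center(stats::rnorm(ng, 0, config$sd_G)))
  E <- with_substream(seed, "E", center(stats::rnorm(ne, 0, config$sd_E)))
  interaction <- make_lowrank_interaction(ng, ne,
                                          config$interaction_singular_values,
                                          seed = seed)
  rep_eff <- with_substream(seed, "rep",
                            matrix(stats::rnorm(ne * nr, 0, config$sd_rep), ne, nr))
  block_eff <- with_substream(seed, "block",
                              array(stats::rnorm(ne * nr * nb, 0, config$sd_block),
                                    c(ne, nr, nb)))
  layout <- with_substream(seed, "layout", {
    a <- array(0L, c(ne, nr, ng))
    for (j in seq_len(ne)) for (r in seq_len(nr)) {
      perm <- sample.int(ng)                 # plot order within the replicate
      a[j, r, perm] <- rep(seq_len(nb), each = block_size)
    }
    a                                        # block index per genotype
  })
  errors <- with_substream(seed, "error",
                           stats::rnorm(ng * ne * nr, 0, config$sd_error))

  genotype_ids <- sprintf("G%03d", seq_len(ng))
  environment_ids <- sprintf("E%02d", seq_len(ne))

  grid <- expand.grid(genotype = seq_len(ng), environment = seq_len(ne),
                      replicate = seq_len(nr))
  i <- grid$genotype; j <- grid$environment; r <- grid$replicate
  b <- layout[cbind(j, r, i)]
  y <- config$mu + G[i] + E[j] + interaction[cbind(i, j)] +
    rep_eff[cbind(j, r)] + block_eff[cbind(j, r, b)] + errors

  records <- tibble::tibble(
    genotype = genotype_ids[i],
    environment = environment_ids[j],
    replicate = as.integer(r),
    block = sprintf("B%02d", b),
    yield = y
  )
  truth <- list(
    mu = config$mu,
    G = stats::setNames(G, genotype_ids),
    E = stats::setNames(E, environment_ids),
    interaction = structure(interaction,
                            dimnames = list(genotype_ids, environment_ids)),
    singular_values = config$interaction_singular_values
  )
  list(records = records, truth = truth)
}

center <- function(x) x - mean(x)

#' Write simulation ground truth as TSV sidecar files
#'
#' @param truth The `truth` component of [simulate_met()] output.
#' @param dir Output directory (created if needed).
#' @return A character vector of file paths, invisibly.
#' @export
write_true_effects <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("effects_genotype.tsv", "effects_environment.tsv",
                            "interaction.tsv", "spectrum.tsv"))
  utils::write.table(data.frame(genotype = names(truth$G), effect = truth$G),
                     paths[1], sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(data.frame(environment = names(truth$E), effect = truth$E),
                     paths[2], sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(data.frame(genotype = rownames(truth$interaction),
                                truth$interaction, check.names = FALSE),
                     paths[3], sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(data.frame(component = seq_along(truth$singular_values),
                                singular_value = truth$singular_values),
                     paths[4], sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(paths)
}
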
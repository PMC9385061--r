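# Small builders shared across test files.

# Balanced plot records for given effect structure; deterministic values.
toy_records <- function(g = 4, e = 3, r = 2, values) {
  grid <- expand.grid(genotype = sprintf("G%02d", seq_len(g)),
                      environment = sprintf("E%d", seq_len(e)),
                      replicate = seq_len(r),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$block <- paste0("B", ((seq_len(nrow(grid)) - 1) %% 2) + 1)
  grid$yield <- values
  tibble::as_tibble(grid[c("genotype", "environment", "replicate",
                           "block", "yield")])
}

# Cell-mean matrix with known additive + low-rank interaction structure.
constructed_table <- function(g = 10, e = 5, mu = 7, spectrum = c(4, 2),
                              seed = 123) {
  set.seed(seed)
  G <- rnorm(g); G <- G - mean(G)
  E <- rnorm(e); E <- E - mean(E)
  m <- mu + outer(G, E, `+`) +
    make_lowrank_interaction(g, e, spectrum, seed = seed)
  dimnames(m) <- list(sprintf("G%02d", seq_len(g)),
                      sprintf("E%d", seq_len(e)))
  list(values = m, mu = mu, G = G, E = E, spectrum = spectrum)
}

# Random seeded cell-mean table wrapped as a two_way_table.
random_table <- function(g, e, seed) {
  set.seed(seed)
  m <- matrix(rnorm(g * e, mean = 5), g, e,
              dimnames = list(sprintf("G%02d", seq_len(g)),
                              sprintf("E%d", seq_len(e))))
  structure(list(values = m, genotypes = rownames(m),
                 environments = colnames(m), n_reps = 1L),
            class = "two_way_table")
}

expect_matrix_equal <- function(a, b, tol = 1e-9) {
  expect_lt(max(abs(unname(as.matrix(a)) - unname(as.matrix(b)))), tol)
}
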
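# Brute-force sequential least-squares oracle: each stratum's SS is the drop
# in residual SS when its term enters the model, fitted with successively
# larger lm() fits.
sequential_ss_oracle <- function(records, trait) {
  d <- data.frame(y = records[[trait]],
                  g = factor(records$genotype),
                  e = factor(records$environment),
                  r = factor(records$replicate),
                  b = factor(records$block))
  forms <- list(y ~ 1,
                y ~ e,
                y ~ e + e:r,
                y ~ e + e:r + e:r:b,
                y ~ e + e:r + e:r:b + g,
                y ~ e + e:r + e:r:b + g + e:g)
  rss <- vapply(forms, function(f) {
    sum(stats::resid(stats::lm(stats::terms(f, keep.order = TRUE),
                               data = d))^2)
  }, numeric(1))
  c(Environment = rss[1] - rss[2],
    `Rep(Environment)` = rss[2] - rss[3],
    `Block(Rep x Environment)` = rss[3] - rss[4],
    Genotype = rss[4] - rss[5],
    `Genotype x Environment` = rss[5] - rss[6],
    Error = rss[6])
}

# Brute-force winner: the genotype maximising the rank-2 inner product with
# the environment's score vector (the defining property of the polygon
# construction).
argmax_winner <- function(fit) {
  gs <- fit$genotype_scores[, 1:2, drop = FALSE]
  es <- fit$environment_scores[, 1:2, drop = FALSE]
  apply(es, 1, function(v) rownames(gs)[which.max(gs %*% v)])
}
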
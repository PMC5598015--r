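# Shared fixtures; everything is generated in code.

small_cohort <- function(seed = 11L, effects = list(), ...) {
  simulate_cohort(cohort_config(n_cases = 15L, n_controls = 18L,
                                n_genes = 30L, n_snps = 60L,
                                effects = effects, seed = seed, ...))
}

# independent two-sided exact rank-sum p-value by enumerating all
# assignments of the observed values to the two groups
wmw_enum_p <- function(x, y) {
  vals <- c(x, y)
  n <- length(vals)
  idx <- utils::combn(n, length(x))
  obs <- sum(rank(vals)[seq_along(x)])
  stats <- apply(idx, 2L, function(i) sum(rank(vals)[i]))
  mu <- mean(stats)
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

digest_file <- function(path) unname(tools::md5sum(path))

# independent nested-model F oracle via two explicit lm fits
f_oracle <- function(y, X_full, X_red) {
  ff <- lm(y ~ X_full - 1)
  fr <- lm(y ~ X_red - 1)
  a <- anova(fr, ff)
  list(statistic = a$F[2L], p.value = a$`Pr(>F)`[2L])
}
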
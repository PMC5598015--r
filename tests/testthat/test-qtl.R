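test_that("cis pair enumeration matches a brute-force interval oracle", {
  genes <- data.frame(gene = c("gA", "gB", "gC"), chrom = c("1", "1", "2"),
                      start = c(2e6, 5e6, 1e6), end = c(2.1e6, 5.4e6, 1.2e6))
  snps <- data.frame(snp = paste0("s", 1:5), chrom = c("1", "1", "1", "2", "2"),
                     pos = c(1.5e6, 3.7e6, 2.05e6, 1.1e6, 2.9e6))
  got <- cis_pairs(genes, snps, window = 1e6)
  oracle <- do.call(rbind, lapply(1:3, function(g) do.call(rbind, lapply(1:5, function(s) {
    if (genes$chrom[g] != snps$chrom[s]) return(NULL)
    if (snps$pos[s] < genes$start[g] - 1e6 ||
        snps$pos[s] > genes$end[g] + 1e6) return(NULL)
    d <- if (snps$pos[s] < genes$start[g]) snps$pos[s] - genes$start[g]
         else if (snps$pos[s] > genes$end[g]) snps$pos[s] - genes$end[g] else 0
    data.frame(gene = genes$gene[g], snp = snps$snp[s], distance = as.integer(d))
  }))))
  oracle <- oracle[order(oracle$gene, oracle$snp), ]
  expect_equal(got, oracle, ignore_attr = TRUE)
  # SNP inside a gene has distance 0; a 1.5 Mb SNP is excluded
  expect_equal(got$distance[got$gene == "gA" & got$snp == "s3"], 0L)
  expect_false(any(got$gene == "gB" & got$snp == "s1"))  # 3.5 Mb away
})

test_that("cis eQTL scan is numerically identical to per-pair lm", {
  set.seed(17)
  n <- 40L
  expr <- matrix(rnorm(3 * n), nrow = 3, dimnames = list(paste0("g", 1:3), NULL))
  geno <- matrix(rbinom(2 * n, 2, 0.4), nrow = 2,
                 dimnames = list(paste0("s", 1:2), NULL))
  cov <- data.frame(age = rnorm(n), sex = factor(rep(c("m", "f"), n / 2)))
  pairs <- expand.grid(gene = rownames(expr), snp = rownames(geno),
                       stringsAsFactors = FALSE)
  pairs$distance <- 0L
  res <- cis_eqtl_scan(expr, geno, cov, pairs)
  for (i in seq_len(nrow(res))) {
    fit <- summary(lm(expr[res$gene[i], ] ~ geno[res$snp[i], ] + cov$age + cov$sex))
    expect_equal(res$beta[i], fit$coefficients[2L, 1L], tolerance = 1e-10)
    expect_equal(res$p[i], fit$coefficients[2L, 4L], tolerance = 1e-8)
  }
  # constant genotype pairs are skipped and counted
  geno0 <- rbind(geno, s3 = rep(1, n))
  pairs0 <- rbind(pairs, data.frame(gene = "g1", snp = "s3", distance = 0L))
  res0 <- cis_eqtl_scan(expr, geno0, cov, pairs0)
  expect_equal(attr(res0, "n_skipped"), 1L)
  expect_false(any(res0$snp == "s3"))
})

test_that("null eQTL p-values are calibrated", {
  set.seed(23)
  n <- 60L
  m <- 800L
  expr <- matrix(rnorm(m * n), nrow = m, dimnames = list(sprintf("g%04d", 1:m), NULL))
  geno <- matrix(rbinom(m * n, 2, 0.3), nrow = m,
                 dimnames = list(sprintf("s%04d", 1:m), NULL))
  pairs <- data.frame(gene = rownames(expr), snp = rownames(geno), distance = 0L)
  res <- cis_eqtl_scan(expr, geno, NULL, pairs)
  frac <- mean(res$p < 0.01)
  expect_lt(abs(frac - 0.01), 3 * sqrt(0.01 * 0.99 / m) + 1e-9)
})

test_that("condition-specific eQTL fit, calls and guards", {
  set.seed(5)
  n1 <- 30L; n0 <- 35L
  g <- c(rep(1, n1), rep(0, n0))
  x <- rbinom(n1 + n0, 2, 0.4)
  # case-specific effect
  y <- 0.9 * x * g + rnorm(n1 + n0, sd = 0.5)
  fit <- specific_eqtl_test(y, x, g)
  expect_lt(fit$p.value, 1e-4)
  expect_equal(fit$call, "case_only")
  # oracle for the nested F
  Xf <- cbind(g, g * x, 1 - g, (1 - g) * x)
  Xr <- cbind(g, 1 - g, x)
  o <- f_oracle(y, Xf, Xr)
  expect_equal(fit$statistic, o$statistic, tolerance = 1e-10)
  expect_equal(fit$p.value, o$p.value, tolerance = 1e-10)
  # shared effect: both slope CIs exclude zero -> shared, whatever the p
  ys <- 1.2 * x + rnorm(n1 + n0, sd = 0.3)
  expect_equal(specific_eqtl_test(ys, x, g)$call, "shared")
  # monomorphic genotype in one group -> call none with reason
  xm <- c(rep(1, n1), rbinom(n0, 2, 0.4))
  fm <- specific_eqtl_test(rnorm(n1 + n0), xm, g)
  expect_equal(fm$call, "none")
  expect_match(fm$reason, "monomorphic")
  expect_error(specific_eqtl_test(rnorm(4), rbinom(4, 2, .5), c(1, 1, 0, 0)),
               ">= 3 samples")
})

test_that("specific-eQTL null p-values are uniform", {
  set.seed(6)
  n <- 50L
  g <- rep(c(1, 0), each = n / 2)
  p <- replicate(300, {
    x <- rbinom(n, 2, 0.4)
    y <- 0.5 * x + rnorm(n)
    specific_eqtl_test(y, x, g)$p.value
  })
  p <- p[!is.na(p)]
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("Armitage trend test matches prop.trend.test and is symmetric", {
  tab <- rbind(cases = c(10, 20, 10), controls = c(20, 20, 0))
  got <- armitage_trend_test(tab)
  oracle <- stats::prop.trend.test(tab[1L, ], colSums(tab), score = 0:2)
  expect_equal(got$statistic, unname(oracle$statistic), tolerance = 1e-10)
  expect_equal(got$p.value, oracle$p.value, tolerance = 1e-10)
  expect_equal(armitage_trend_test(tab[2:1, ])$statistic, got$statistic,
               tolerance = 1e-12)
  same <- rbind(c(10, 20, 10), c(20, 40, 20))
  expect_equal(armitage_trend_test(same)$statistic, 0)
  expect_equal(armitage_trend_test(same)$p.value, 1)
  expect_error(armitage_trend_test(rbind(c(0, 0, 0), c(1, 2, 3))), "zero total")
  set.seed(2)
  for (i in 1:5) {
    t2 <- matrix(rpois(6, 15) + 1, 2)
    o2 <- stats::prop.trend.test(t2[1L, ], colSums(t2), score = 0:2)
    expect_equal(armitage_trend_test(t2)$p.value, o2$p.value, tolerance = 1e-10)
  }
})

test_that("sQTL interaction F equals an explicit two-regression oracle", {
  set.seed(40)
  L <- 2L; n <- 6L
  m <- matrix(rnorm(L * n), nrow = L, dimnames = list(c("e1", "e2"), NULL))
  gf <- c(0, 0, 0, 1, 1, 1)
  fit <- sqtl_interaction_test(m, "e2", gf, min_class = 3L)
  y <- as.vector(m)
  exon_f <- factor(rep(1:L, times = n))
  sample_f <- factor(rep(1:n, each = L))
  inter <- as.numeric(exon_f == 2L) * as.numeric(rep(gf, each = L) == 1)
  Xr <- model.matrix(~ sample_f + exon_f)
  o <- f_oracle(y, cbind(Xr, inter), Xr)
  expect_equal(fit$statistic, o$statistic, tolerance = 1e-10)
  expect_equal(fit$p.value, o$p.value, tolerance = 1e-10)
  expect_equal(unname(fit$df), c(1L, L * n - (1L + (n - 1L) + (L - 1L) + 1L)))
  expect_error(sqtl_interaction_test(m[1, , drop = FALSE], 1, gf), "2 exon")
  expect_error(sqtl_interaction_test(m, "e9", gf), "unknown target")
  expect_error(sqtl_interaction_test(m, "e2", rep(0, n)), "2 observed")
})

test_that("rare genotype classes are merged before the sQTL F test", {
  set.seed(41)
  n <- 30L
  m <- matrix(rnorm(3 * n), nrow = 3, dimnames = list(paste0("e", 1:3), NULL))
  gf <- c(rep(0, 20), rep(1, 8), rep(2, 2))  # class 2 has < 3 carriers
  fit <- sqtl_interaction_test(m, "e1", gf)
  expect_equal(fit$n_classes, 2L)
  expect_equal(unname(fit$df["df1"]), 1L)
})

test_that("planted sQTL interactions are detected, nulls are uniform", {
  # world: exon main effects N(0,1), per-sample effects N(0,0.7), residual
  # sd 0.3 after within-sample normalization; the absorbed terms do not
  # change the F statistic, only the residual scale drives power
  set.seed(42)
  n <- 80L; L <- 3L
  gf <- rbinom(n, 2, 0.4)
  sim_gene <- function(effect = 0) {
    m <- matrix(rnorm(L), L, n) + matrix(rnorm(n, sd = 0.7), L, n,
                                         byrow = TRUE) +
      matrix(rnorm(L * n, sd = 0.3), L, n)
    m[2, ] <- m[2, ] + effect * gf
    m
  }
  hits <- replicate(20, sqtl_interaction_test(sim_gene(0.5), 2, gf)$p.value < 1e-4)
  expect_gte(mean(hits), 0.9)
  nulls <- replicate(200, sqtl_interaction_test(sim_gene(0), 2, gf)$p.value)
  expect_gt(stats::ks.test(nulls, "punif")$p.value, 0.01)
})

test_that("Storey q-values: pi0, monotonicity and bounds", {
  set.seed(50)
  p <- runif(1e4)
  qv <- storey_qvalues(p)
  expect_gte(qv$pi0, 0.9)
  expect_lte(qv$pi0, 1.0)
  o <- order(p)
  expect_true(all(diff(qv$qvalues[o]) >= -1e-12))
  expect_true(all(qv$qvalues <= p.adjust(p, "BH") + 1e-12))
  tiny <- rep(1e-6, 200)
  expect_true(all(storey_qvalues(tiny)$qvalues <= 1e-6))
})

test_that("small p-value sets fall back to plain BH", {
  set.seed(51)
  p <- runif(50)
  expect_warning(qs <- storey_qvalues(p), "fewer than 100")
  expect_equal(qs$pi0, 1)
  expect_equal(sort(qs$qvalues), sort(p.adjust(p, "BH")), tolerance = 1e-12)
})

test_that("trans-confounding bound is small under the null", {
  set.seed(52)
  G <- matrix(rbinom(200 * 60, 2, 0.3), nrow = 200)
  y <- rnorm(60)
  b <- trans_confounding_bound(y, G)
  expect_true(b$bound >= 0 && b$bound <= 1)
  expect_lt(b$bound, 0.35)
  # p-values share one response vector so they are dependent; check the
  # rejection rate rather than full KS uniformity
  expect_lt(mean(b$p_values < 0.05), 0.2)
})
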
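test_that("LD blocks are connected components, order-invariant", {
  pairs <- data.frame(snp_a = c("A", "B"), snp_b = c("B", "C"),
                      r2 = c(0.7, 0.65))
  bl <- build_ld_blocks(c("A", "B", "C", "D"), pairs)
  expect_length(bl$blocks, 2L)
  expect_setequal(bl$blocks[[bl$membership[["A"]]]], c("A", "B", "C"))
  expect_setequal(bl$blocks[[bl$membership[["D"]]]], "D")
  # at the threshold (r2 = 0.6 not > 0.6): singletons
  low <- build_ld_blocks(c("A", "B"),
                         data.frame(snp_a = "A", snp_b = "B", r2 = 0.6))
  expect_length(low$blocks, 2L)
  expect_error(build_ld_blocks("A", data.frame(snp_a = "A", snp_b = "A",
                                               r2 = 1.2)), "r2")
  # invariance to pair ordering and duplication, vs a BFS oracle
  set.seed(70)
  ids <- paste0("v", 1:30)
  rp <- data.frame(snp_a = sample(ids, 40, TRUE),
                   snp_b = sample(ids, 40, TRUE),
                   r2 = runif(40))
  b1 <- build_ld_blocks(ids, rp)
  b2 <- build_ld_blocks(ids, rp[rev(seq_len(nrow(rp))), ][c(1:40, 1:10), ])
  part <- function(b) unname(lapply(b$blocks, sort))
  expect_setequal(part(b1), part(b2))
  # BFS oracle
  adj <- lapply(setNames(ids, ids), function(i) {
    keep <- rp$r2 > 0.6
    unique(c(rp$snp_b[keep & rp$snp_a == i], rp$snp_a[keep & rp$snp_b == i]))
  })
  seen <- character(); comps <- list()
  for (s in ids) {
    if (s %in% seen) next
    q <- s; comp <- character()
    while (length(q)) {
      v <- q[1L]; q <- q[-1L]
      if (v %in% comp) next
      comp <- c(comp, v)
      q <- c(q, setdiff(adj[[v]], comp))
    }
    seen <- c(seen, comp)
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  expect_setequal(part(b1), comps)
})

test_that("block enrichment test equals the exact rank-sum oracle", {
  bl <- build_ld_blocks(paste0("v", 1:6),
                        data.frame(snp_a = character(), snp_b = character(),
                                   r2 = numeric()))
  gwa <- data.frame(snp = paste0("v", 1:6),
                    p = c(0.01, 0.02, 0.03, 0.5, 0.6, 0.7))
  res <- block_enrichment_test(bl, paste0("v", 1:3), gwa)
  # exact one-sided rank-sum enumeration for 3 vs 3 fully separated
  expect_equal(res$p.value, 1 / choose(6, 3), tolerance = 1e-12)
  expect_equal(res$n_marked, 3L)
  # second_min falls back to min for singleton blocks
  res2 <- block_enrichment_test(bl, paste0("v", 1:3), gwa,
                                summary = "second_min")
  expect_equal(res2$p.value, res$p.value)
  expect_error(block_enrichment_test(bl, paste0("v", 1:6), gwa), "contrast")
  expect_error(block_enrichment_test(bl, character(), gwa), "contrast")
  expect_error(block_enrichment_test(bl, "v1", gwa[1:3, ]), "GWA p")
  # min vs second_min summaries within multi-SNP blocks
  bl2 <- build_ld_blocks(c("a", "b", "c"),
                         data.frame(snp_a = "a", snp_b = "b", r2 = 0.9))
  g2 <- data.frame(snp = c("a", "b", "c"), p = c(0.2, 0.05, 0.5))
  r_min <- block_enrichment_test(bl2, "a", g2)
  expect_equal(unname(r_min$block_p[bl2$membership[["a"]]]), 0.05)
  r_2nd <- block_enrichment_test(bl2, "a", g2, summary = "second_min")
  expect_equal(unname(r_2nd$block_p[bl2$membership[["a"]]]), 0.2)
})

test_that("enriched blocks are detected; null is flat", {
  set.seed(71)
  ids <- paste0("v", 1:120)
  bl <- build_ld_blocks(ids, data.frame(snp_a = character(),
                                        snp_b = character(), r2 = numeric()))
  marked <- ids[1:30]
  hits <- replicate(30, {
    gwa <- simulate_gwa_summary(bl, unique(bl$membership[marked]), effect = 2,
                                seed = sample.int(1e6, 1))
    block_enrichment_test(bl, marked, gwa)$p.value < 0.001
  })
  expect_gte(mean(hits), 0.95)
  nulls <- replicate(60, {
    gwa <- simulate_gwa_summary(bl, character(), 0, seed = sample.int(1e6, 1))
    block_enrichment_test(bl, marked, gwa)$p.value
  })
  expect_gt(suppressWarnings(stats::ks.test(nulls, "punif"))$p.value, 0.01)
})

test_that("single-feature logistic enrichment equals the marginal odds ratio", {
  set.seed(72)
  n <- 400L
  x <- rbinom(n, 1, 0.4)
  y <- rbinom(n, 1, plogis(-1 + 1.2 * x))
  d <- data.frame(label = y, feat = x)
  res <- annotation_enrichment(d)
  tab <- table(factor(y, 0:1), factor(x, 0:1))
  cross <- (tab[2, 2] * tab[1, 1]) / (tab[2, 1] * tab[1, 2])
  expect_equal(res$or, unname(cross), tolerance = 1e-6)
  expect_lt(res$p, 0.05)
  # degenerate feature columns are dropped with a warning
  d$flat <- 1L
  expect_warning(res2 <- annotation_enrichment(d), "degenerate")
  expect_identical(res2$feature, "feat")
  expect_error(annotation_enrichment(data.frame(label = rep(1, 5), f = 0:4)),
               "both labels")
})

test_that("annotation dataset applies the top-hit labels and exclusion rule", {
  q <- data.frame(
    target = c("g1", "g1", "g1", "g2", "g2"),
    snp = c("a", "b", "c", "a", "d"),
    p = c(1e-8, 1e-6, 0.5, 0.2, 0.01),
    significant = c(TRUE, TRUE, FALSE, FALSE, FALSE))
  feats <- expand.grid(target = c("g1", "g2"), snp = c("a", "b", "c", "d"),
                       stringsAsFactors = FALSE)
  feats$f1 <- 1L
  ds <- build_annotation_dataset(q, feats)
  # (g1, b) is significant but not top -> excluded
  expect_equal(attr(ds, "n_excluded"), 1L)
  expect_false(any(ds$target == "g1" & ds$snp == "b"))
  expect_equal(ds$label[ds$target == "g1" & ds$snp == "a"], 1L)
  expect_equal(ds$label[ds$target == "g2" & ds$snp == "d"], 1L)
  expect_equal(ds$label[ds$target == "g1" & ds$snp == "c"], 0L)
})

test_that("distance bins follow the 10-kb boundary convention", {
  b <- distance_bins(c(0, 1, 5000, 10000, 10001, 40000, 40001, 50000, 60000))
  expect_equal(unname(b[1, ]), c(1, 0, 0, 0, 0, 0))        # inside
  expect_equal(unname(b[2, "bin1"]), 1)
  expect_equal(unname(b[3, "bin1"]), 1)
  expect_equal(unname(b[4, "bin1"]), 1)                     # 10,000 in bin 1
  expect_equal(unname(b[5, "bin2"]), 1)                     # 10,001 in bin 2
  expect_equal(unname(b[6, "bin4"]), 1)
  expect_equal(unname(b[7, "bin5"]), 1)
  expect_equal(unname(b[8, "bin5"]), 1)
  expect_equal(unname(b[9, ]), rep(0, 6))                   # reference
  expect_equal(unname(rowSums(b[-1, 2:6])), c(1, 1, 1, 1, 1, 1, 1, 0))
  expect_error(distance_bins(-5), "non-negative")
})

test_that("hexamer matching allows overlaps and matches a naive oracle", {
  expect_equal(match_hexamers("GAAGAAGAA", "GAAGAA"), c(1L, 4L))
  expect_length(match_hexamers("ACGTACGTAC", "TTTTTT"), 0L)
  expect_length(match_hexamers("ACG", "ACGTAA"), 0L)
  expect_warning(m <- match_hexamers("GAANAAGAAGAA", "GAAGAA"), "non-ACGT")
  expect_equal(m, 7L)  # every window containing the N is skipped
  set.seed(73)
  seq1k <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
  hx <- c("ACGTAC", "TTGACA", "GGGCCC")
  oracle <- which(vapply(1:995, function(i)
    substr(seq1k, i, i + 5) %in% hx, logical(1)))
  expect_equal(match_hexamers(seq1k, hx), oracle)
})

test_that("gene-set Fisher enrichment with Woolf CI and Haldane path", {
  uni <- paste0("g", 1:100)
  res <- geneset_fisher(uni[1:10], uni[c(1:5, 11:25)], uni)
  # table: a=5 b=5 c=15 d=75
  expect_equal(unname(res$table), matrix(c(5, 5, 15, 75), 2, byrow = TRUE))
  expect_equal(res$p, fisher.test(matrix(c(5, 5, 15, 75), 2, byrow = TRUE))$p.value,
               tolerance = 1e-12)
  lor <- log(5) - log(5) - log(15) + log(75)
  expect_equal(res$or, exp(lor))
  expect_true(res$ci_lo < res$or && res$or < res$ci_hi)
  # zero cell: Haldane correction with warning, finite OR
  expect_warning(z <- geneset_fisher(uni[1:5], uni[1:5], uni), "Haldane")
  expect_true(is.finite(z$or))
  expect_error(geneset_fisher("g1", "g1", character()), "universe")
})

test_that("GWA/eQTL overlap uses self first, then the best proxy", {
  qtl <- data.frame(gene = c("g1", "g1", "g1", "g2"),
                    snp = c("t1", "p1", "p2", "t1"),
                    p = c(1e-6, 1e-7, 1e-3, 0.5),
                    significant = c(TRUE, TRUE, FALSE, FALSE))
  proxies <- data.frame(gwa_snp = c("w1", "w1", "w2"),
                        proxy = c("p1", "p2", "p9"),
                        r2 = c(0.9, 0.85, 0.95), distance = c(100, 50, 10))
  gwa <- data.frame(snp = c("t1", "w1", "w2"))
  res <- gwa_eqtl_overlap(gwa, proxies, qtl, expressed_genes = c("g1", "g2"))
  a <- res$annotated
  # t1 tested itself: used directly for both genes
  expect_setequal(a$used_snp[a$gwa_snp == "t1"], "t1")
  # w1 not tested: best proxy by r2 is p1 (0.9 > 0.85)
  expect_equal(a$used_snp[a$gwa_snp == "w1"], "p1")
  # w2's only proxy is untested -> unevaluable
  expect_equal(res$unevaluable, "w2")
  expect_true(all(dim(res$enrichment$table) == c(2, 2)))
})
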
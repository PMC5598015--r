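#' Enumerate cis gene-SNP pairs
#'
#' Pairs every SNP with every gene whose body, extended by `window` on both
#' sides, contains the SNP.  Distance is signed from the nearest gene edge
#' (negative upstream of the start, positive downstream of the end, 0 inside
#' the gene body); computed in 1-based inclusive coordinates, strand ignored.
#'
#' @param gene_models data.frame(gene, chrom, start, end, ...)
#' @param snp_table data.frame(snp, chrom, pos, ...)
#' @param window cis window in bp (default 1e6)
#' @return data.frame(gene, snp, distance)
#' @export
cis_pairs <- function(gene_models, snp_table, window = 1e6) {
  gr <- GenomicRanges::GRanges(
    gene_models$chrom,
    IRanges::IRanges(pmax(1L, gene_models$start - window),
                     gene_models$end + window))
  sr <- GenomicRanges::GRanges(snp_table$chrom,
                               IRanges::IRanges(snp_table$pos, snp_table$pos))
  hits <- GenomicRanges::findOverlaps(sr, gr)
  gi <- S4Vectors::subjectHits(hits)
  si <- S4Vectors::queryHits(hits)
  pos <- snp_table$pos[si]
  d <- ifelse(pos < gene_models$start[gi], pos - gene_models$start[gi],
              ifelse(pos > gene_models$end[gi], pos - gene_models$end[gi], 0L))
  out <- data.frame(gene = gene_models$gene[gi], snp = snp_table$snp[si],
                    distance = as.integer(d), stringsAsFactors = FALSE)
  out[order(out$gene, out$snp), , drop = FALSE]
}

#' cis-eQTL scan with covariates
#'
#' For each (gene, SNP) pair, the slope, t statistic and p-value of the
#' additive linear model `expression ~ dosage + covariates`.  Computed via
#' Frisch-Waugh residualization (expression and dosage both residualized on
#' the covariate design) with the exact residual degrees of freedom, so the
#' results are numerically identical to fitting each pair with `lm`.
#' Pairs whose genotype is constant are skipped and counted in the
#' `n_skipped` attribute.
#'
#' @param expr gene x sample matrix (rank-inverse-normalized upstream)
#' @param genotypes SNP x sample dosage matrix
#' @param covariates data.frame of per-sample covariates (may include
#'   expression PCs and genotype PCs), or NULL
#' @param pairs data.frame(gene, snp, distance) from \code{\link{cis_pairs}}
#' @param p_threshold nominal significance threshold (default 1e-5)
#' @return data.frame: gene, snp, distance, beta, se, ci_lo, ci_hi,
#'   statistic, p, fdr, significant
#' @export
cis_eqtl_scan <- function(expr, genotypes, covariates = NULL, pairs,
                          p_threshold = 1e-5) {
  Y <- as.matrix(expr)
  G <- as.matrix(genotypes)
  n <- ncol(Y)
  stopifnot(ncol(G) == n)
  if (is.null(covariates)) {
    X <- matrix(1, n, 1L)
  } else {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == n)
    X <- drop_aliased(stats::model.matrix(~ ., covariates),
                      context = "cis_eqtl_scan covariates")
  }
  rank_x <- qr(X)$rank
  df <- n - rank_x - 1L
  if (df < 1L) stop("not enough residual degrees of freedom")
  Yr <- t(as.matrix(lm.fit(X, t(Y))$residuals))
  dimnames(Yr) <- dimnames(Y)
  Gr <- t(as.matrix(lm.fit(X, t(G))$residuals))
  dimnames(Gr) <- dimnames(G)
  keep_snp <- apply(G, 1L, function(x) stats::var(x) > 0)
  use <- pairs$gene %in% rownames(Y) & pairs$snp %in% rownames(G)
  pr <- pairs[use, , drop = FALSE]
  polymorphic <- keep_snp[pr$snp]
  skipped <- sum(!polymorphic)
  pr <- pr[polymorphic, , drop = FALSE]
  yr <- Yr[pr$gene, , drop = FALSE]
  gr <- Gr[pr$snp, , drop = FALSE]
  sxx <- rowSums(gr^2)
  sxy <- rowSums(gr * yr)
  syy <- rowSums(yr^2)
  beta <- sxy / sxx
  rss <- syy - beta^2 * sxx
  se <- sqrt(pmax(rss, 0) / df / sxx)
  tstat <- beta / se
  p <- 2 * pt(-abs(tstat), df)
  ci <- qt(0.975, df) * se
  out <- data.frame(gene = pr$gene, snp = pr$snp, distance = pr$distance,
                    beta = beta, se = se, ci_lo = beta - ci, ci_hi = beta + ci,
                    statistic = tstat, p = p,
                    fdr = p.adjust(p, method = "BH"),
                    significant = p < p_threshold,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- skipped
  out
}

#' Condition-specific eQTL test
#'
#' Compares the full model with separate intercepts and slopes per group,
#' `y = g(b0 + b1 x) + (1-g)(b2 + b3 x) + e`, against the reduced model with
#' a common slope, `y = g b0 + b1 x + (1-g) b2 + e`, via the nested-model F
#' test.  The specificity call requires significance AND exactly one of the
#' two slope 95% confidence intervals containing zero; when both slope CIs
#' exclude zero the eQTL is `shared` regardless of the interaction p-value.
#' An Armitage trend test on the group x genotype table is reported as a
#' guard against allele-frequency differences masquerading as specificity.
#'
#' @param y adjusted log expression (one gene), length n
#' @param x genotype dosage, length n
#' @param group 0/1 or two-level factor; 1 / second level = case
#' @param fdr optional externally computed FDR for this fit; when NULL the
#'   nominal p is compared with `alpha`
#' @param alpha significance level (default 0.05)
#' @return object of class `SpecificEqtlFit`: list with `beta` (b0..b3),
#'   `se`, `ci` (2x2 matrix for the slopes b1, b3), `statistic`, `df`,
#'   `p.value`, `armitage_p`, `call`, `reason`
#' @export
specific_eqtl_test <- function(y, x, group, fdr = NULL, alpha = 0.05) {
  g <- if (is.factor(group)) as.numeric(group == levels(group)[2L]) else as.numeric(group)
  stopifnot(length(y) == length(x), length(x) == length(g), all(g %in% 0:1))
  n <- length(y)
  if (sum(g == 1) < 3L || sum(g == 0) < 3L) stop("each group needs >= 3 samples")
  mono <- stats::var(x[g == 1]) == 0 || stats::var(x[g == 0]) == 0
  Xf <- cbind(b0 = g, b1 = g * x, b2 = 1 - g, b3 = (1 - g) * x)
  Xr <- cbind(b0 = g, b2 = 1 - g, b1 = x)
  if (mono) {
    return(structure(list(beta = NULL, se = NULL, ci = NULL,
                          statistic = NA_real_, df = c(NA, NA),
                          p.value = NA_real_, armitage_p = NA_real_,
                          call = "none",
                          reason = "genotype monomorphic in one group"),
                     class = "SpecificEqtlFit"))
  }
  full <- lm.fit(Xf, y)
  red <- lm.fit(Xr, y)
  df2 <- n - full$rank
  ft <- nested_f_test(sum(red$residuals^2), sum(full$residuals^2), 1L, df2)
  sigma2 <- sum(full$residuals^2) / df2
  xtxi <- chol2inv(chol(crossprod(Xf)))
  se <- sqrt(diag(xtxi) * sigma2)
  names(se) <- colnames(Xf)
  beta <- full$coefficients
  tq <- qt(0.975, df2)
  ci <- rbind(b1 = c(beta["b1"] - tq * se["b1"], beta["b1"] + tq * se["b1"]),
              b3 = c(beta["b3"] - tq * se["b3"], beta["b3"] + tq * se["b3"]))
  colnames(ci) <- c("lo", "hi")
  tab <- rbind(case = tabulate(round(x[g == 1]) + 1L, 3L),
               control = tabulate(round(x[g == 0]) + 1L, 3L))
  arm <- armitage_trend_test(tab)
  zero_in <- ci[, "lo"] <= 0 & ci[, "hi"] >= 0
  sig <- if (is.null(fdr)) ft$p.value < alpha else fdr < alpha
  call <- if (!any(zero_in)) "shared"
          else if (sig && sum(zero_in) == 1L) {
            if (zero_in["b3"]) "case_only" else "control_only"
          } else "none"
  structure(list(beta = beta, se = se, ci = ci,
                 statistic = ft$statistic, df = c(1L, df2),
                 p.value = ft$p.value, armitage_p = arm$p.value,
                 call = call, reason = NA_character_),
            class = "SpecificEqtlFit")
}

#' Cochran-Armitage trend test
#'
#' Dose-linear association between genotype class (scores 0, 1, 2) and group
#' membership, from a 2 x 3 table of genotype counts (rows = groups).
#'
#' @param genotype_counts 2 x 3 matrix of counts
#' @return list(statistic = chi-squared, p.value) with 1 df
#' @export
armitage_trend_test <- function(genotype_counts) {
  tab <- as.matrix(genotype_counts)
  stopifnot(nrow(tab) == 2L, ncol(tab) == 3L, all(tab >= 0))
  if (any(rowSums(tab) == 0)) stop("a group has zero total count")
  s <- c(0, 1, 2)
  N <- sum(tab)
  R <- sum(tab[1L, ])
  n_i <- colSums(tab)
  r_i <- tab[1L, ]
  num <- N * sum(s * r_i) - R * sum(s * n_i)
  den <- R * (N - R) * (N * sum(s^2 * n_i) - sum(s * n_i)^2)
  chi2 <- if (den <= 0) 0 else N * num^2 / den
  list(statistic = chi2, p.value = pchisq(chi2, 1L, lower.tail = FALSE))
}

#' Splicing QTL via an exon-by-genotype interaction model
#'
#' Linear-model adaptation of the DEXSeq design for one gene, one target
#' exon part and one SNP: the full model contains per-sample terms (which
#' absorb both overall expression and any genotype main effect), per-exon
#' terms, and an interaction allowing the target exon to deviate per
#' observed genotype class; the reduced model omits the interaction.  The
#' likelihood ratio is evaluated on the exact F scale with
#' df1 = (observed genotype classes - 1) and
#' df2 = (samples x exons) - fitted parameters.  Genotype classes carried by
#' fewer than `min_class` samples are merged into the nearest class first.
#'
#' Exon expression values are expected to be quantile-normalized across all
#' exons within each sample (see
#' \code{\link{quantile_normalize_exons_within_sample}}).
#'
#' @param exon_expr exon-part x sample matrix of normalized exon expression
#'   for one gene (>= 2 parts)
#' @param target_part row name (or index) of the tested exon part
#' @param genotype_factor per-sample genotype classes (rounded dosages)
#' @param min_class minimum carriers per genotype class (default 3)
#' @return object of class `SqtlFit`: list with `statistic`, `df`, `p.value`,
#'   `interaction` (per-class deviations of the target exon), `target`,
#'   `n_classes`
#' @export
sqtl_interaction_test <- function(exon_expr, target_part, genotype_factor,
                                  min_class = 3L) {
  m <- as.matrix(exon_expr)
  L <- nrow(m)
  n <- ncol(m)
  if (L < 2L) stop("gene needs at least 2 exon parts for the interaction model")
  ti <- if (is.character(target_part)) match(target_part, rownames(m)) else as.integer(target_part)
  if (is.na(ti) || ti < 1L || ti > L) stop("unknown target part")
  gf <- round(as.numeric(if (is.factor(genotype_factor))
    as.character(genotype_factor) else genotype_factor))
  stopifnot(length(gf) == n)
  # merge rare classes into the nearest observed class
  repeat {
    tb <- table(gf)
    rare <- names(tb)[tb < min_class]
    if (length(rare) == 0L || length(tb) <= 1L) break
    lev <- as.numeric(names(tb))
    r <- as.numeric(rare[1L])
    others <- lev[lev != r]
    gf[gf == r] <- others[which.min(abs(others - r))]
  }
  classes <- sort(unique(gf))
  G <- length(classes)
  if (G < 2L) stop("genotype factor has fewer than 2 observed classes")
  # long format: observation (l, j); sample terms absorb the genotype main
  # effect, so beta^S contributes no degrees of freedom
  exon_f <- factor(rep(seq_len(L), times = n))
  sample_f <- factor(rep(seq_len(n), each = L))
  y <- as.vector(m)
  Xr <- stats::model.matrix(~ sample_f + exon_f)
  delta <- as.numeric(exon_f == ti)
  inter <- vapply(classes[-1L], function(cl) {
    delta * as.numeric(rep(gf, each = L) == cl)
  }, numeric(length(y)))
  colnames(inter) <- paste0("int_g", classes[-1L])
  Xf <- cbind(Xr, inter)
  full <- lm.fit(Xf, y)
  red <- lm.fit(Xr, y)
  df1 <- G - 1L
  df2 <- length(y) - full$rank
  if (df2 < 1L) stop("no residual degrees of freedom")
  ft <- nested_f_test(sum(red$residuals^2), sum(full$residuals^2), df1, df2)
  structure(list(statistic = ft$statistic, df = c(df1 = df1, df2 = df2),
                 p.value = ft$p.value,
                 interaction = full$coefficients[colnames(inter)],
                 target = rownames(m)[ti] %||% ti, n_classes = G),
            class = "SqtlFit")
}

#' Quantile-normalize exon expression within each sample
#'
#' Maps the exon expression values of every sample to standard normal
#' quantiles across all exons of that sample (ties averaged), the input
#' scale expected by \code{\link{sqtl_interaction_test}}.
#'
#' @param exon_expr exon x sample matrix (all genes stacked)
#' @return matrix of the same shape
#' @export
quantile_normalize_exons_within_sample <- function(exon_expr) {
  m <- as.matrix(exon_expr)
  k <- nrow(m)
  out <- apply(m, 2L, function(x) qnorm(rank(x, ties.method = "average") / (k + 1)))
  dimnames(out) <- dimnames(m)
  out
}

#' Storey q-values and the null proportion pi0
#'
#' Estimates pi0 with Storey's smoother over a lambda grid (natural cubic
#' smoothing spline, df = 3, evaluated at the largest lambda) and converts
#' p-values to q-values.  With fewer than 100 p-values pi0 is fixed at 1
#' (plain Benjamini-Hochberg) with a warning.
#'
#' @param p_values numeric vector in [0, 1]
#' @param lambda_grid grid for the pi0 smoother (default seq(0.05, 0.95, 0.05))
#' @return object of class `QvalueResult`: list(pi0, qvalues,
#'   one_minus_pi0, lambda, pi0_lambda)
#' @export
storey_qvalues <- function(p_values, lambda_grid = seq(0.05, 0.95, 0.05)) {
  p <- as.numeric(p_values)
  stopifnot_prob(p, "p_values")
  n <- length(p)
  if (n < 100L) {
    warning("fewer than 100 p-values; pi0 fixed at 1 (plain BH)", call. = FALSE)
    pi0 <- 1
    pi0_l <- NULL
  } else {
    pi0_l <- vapply(lambda_grid, function(l) mean(p > l) / (1 - l), numeric(1))
    pi0 <- tryCatch({
      fit <- stats::smooth.spline(lambda_grid, pi0_l, df = 3)
      stats::predict(fit, x = max(lambda_grid))$y
    }, error = function(e) {
      message("pi0 smoother failed; falling back to lambda = 0.5")
      mean(p > 0.5) / 0.5
    })
    pi0 <- min(max(pi0, 1 / n), 1)
  }
  o <- order(p, decreasing = TRUE)
  q <- numeric(n)
  q[o] <- cummin(pi0 * n * p[o] / rank(p, ties.method = "max")[o])
  q <- pmin(q, 1)
  structure(list(pi0 = pi0, qvalues = q, one_minus_pi0 = 1 - pi0,
                 lambda = lambda_grid, pi0_lambda = pi0_l),
            class = "QvalueResult")
}

#' Upper bound on trans-factor confounding of a cis-QTL set
#'
#' Regresses the expression of a designated trans-acting factor (e.g. a
#' splicing regulator) on each QTL SNP and reports the Storey 1 - pi0 of the
#' resulting p-value collection: an upper limit on the fraction of QTL that
#' could be driven by correlation with that factor rather than local
#' genotype.
#'
#' @param factor_expr per-sample expression of the trans factor
#' @param genotypes SNP x sample dosage matrix of the QTL SNPs
#' @return list(p_values, pi0, bound = 1 - pi0)
#' @export
trans_confounding_bound <- function(factor_expr, genotypes) {
  G <- as.matrix(genotypes)
  y <- as.numeric(factor_expr)
  stopifnot(length(y) == ncol(G))
  n <- length(y)
  yc <- y - mean(y)
  gc <- G - rowMeans(G)
  sxx <- rowSums(gc^2)
  ok <- sxx > 0
  r <- rowSums(gc * yc)[ok] / sqrt(sxx[ok] * sum(yc^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(-abs(tstat), n - 2)
  qv <- storey_qvalues(p)
  list(p_values = p, pi0 = qv$pi0, bound = qv$one_minus_pi0)
}
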
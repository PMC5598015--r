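#' Build LD blocks as connected components
#'
#' Groups SNPs into blocks of high linkage disequilibrium: connected
#' components of the graph with an edge wherever r-squared exceeds the
#' threshold.  SNPs without qualifying pairs form singleton blocks, so the
#' blocks partition the SNP universe.
#'
#' @param snp_ids character vector, the SNP universe
#' @param ld_pairs data.frame(snp_a, snp_b, r2); symmetric, duplicates fine
#' @param rsq_threshold linkage threshold (default 0.6, strict)
#' @return object of class `LdBlockSet`: list with `blocks` (named list of
#'   member id vectors) and `membership` (block id per SNP)
#' @export
build_ld_blocks <- function(snp_ids, ld_pairs, rsq_threshold = 0.6) {
  snp_ids <- unique(as.character(snp_ids))
  lp <- as.data.frame(ld_pairs)
  if (nrow(lp) > 0 && (any(lp$r2 < 0) || any(lp$r2 > 1))) {
    stop("r2 values must lie in [0, 1]")
  }
  lp <- lp[lp$r2 > rsq_threshold &
             lp$snp_a %in% snp_ids & lp$snp_b %in% snp_ids, , drop = FALSE]
  comp <- components_union_find(snp_ids, as.character(lp$snp_a),
                                as.character(lp$snp_b))
  blocks <- split(snp_ids, comp)
  names(blocks) <- sprintf("block%04d", seq_along(blocks))
  membership <- stats::setNames(rep(names(blocks), lengths(blocks)),
                                unlist(blocks, use.names = FALSE))
  structure(list(blocks = blocks, membership = membership[snp_ids]),
            class = "LdBlockSet")
}

#' GWA enrichment of marked SNPs at the LD-block level
#'
#' Classifies each LD block as marked when it contains at least one marked
#' SNP (e.g. a QTL variant), summarizes each block by the smallest (or, for
#' the outlier-robustness check, second-smallest) GWA p-value of its
#' members, and compares marked against unmarked blocks with a one-sided
#' Wilcoxon-Mann-Whitney test (alternative: marked blocks have smaller
#' summary p-values).
#'
#' @param blocks an \code{\link{build_ld_blocks}} result
#' @param marked_snps character vector of marked SNP ids
#' @param gwa_p data.frame(snp, p) of GWA summary statistics
#' @param summary "min" (default) or "second_min"
#' @return list(p.value, statistic, n_marked, n_unmarked, block_p, marked)
#' @export
block_enrichment_test <- function(blocks, marked_snps, gwa_p,
                                  summary = c("min", "second_min")) {
  stopifnot(inherits(blocks, "LdBlockSet"))
  summary <- match.arg(summary)
  pmap <- stats::setNames(gwa_p$p, gwa_p$snp)
  block_p <- vapply(blocks$blocks, function(members) {
    p <- sort(pmap[members])
    p <- p[!is.na(p)]
    if (length(p) == 0L) return(NA_real_)
    if (summary == "min") p[1L] else p[min(2L, length(p))]
  }, numeric(1))
  if (anyNA(block_p)) stop("every block needs at least one SNP with a GWA p")
  marked <- vapply(blocks$blocks, function(m) any(m %in% marked_snps), logical(1))
  if (all(marked) || !any(marked)) stop("no contrast: all or no blocks marked")
  wt <- suppressWarnings(wilcox.test(block_p[marked], block_p[!marked],
                                     alternative = "less"))
  list(p.value = wt$p.value, statistic = unname(wt$statistic),
       n_marked = sum(marked), n_unmarked = sum(!marked),
       block_p = block_p, marked = marked)
}

#' Functional-annotation enrichment of putatively causal QTL SNPs
#'
#' Multiple logistic regression of the causal label (SNP is the top
#' associated variant for its target) on binary annotation features, over
#' (SNP, target) pairs.  The caller must already have applied the exclusion
#' rule: pairs whose SNP is significantly associated with the target but is
#' not its top hit are removed (see \code{\link{build_annotation_dataset}}).
#'
#' @param dataset data.frame with column `label` (0/1) and binary feature
#'   columns
#' @return object of class `EnrichmentResult`: data.frame with feature,
#'   beta, or, ci_lo, ci_hi, p (LRT); attributes `converged`, `separated`,
#'   `dropped` (degenerate feature columns removed)
#' @export
annotation_enrichment <- function(dataset) {
  d <- as.data.frame(dataset)
  stopifnot("label" %in% names(d))
  if (length(unique(d$label)) < 2L) stop("need both labels present")
  feats <- setdiff(names(d), "label")
  degen <- feats[vapply(feats, function(f) length(unique(d[[f]])) < 2L, logical(1))]
  if (length(degen)) {
    warning("dropping degenerate feature column(s): ",
            paste(degen, collapse = ", "), call. = FALSE)
    d <- d[, c("label", setdiff(feats, degen)), drop = FALSE]
    feats <- setdiff(feats, degen)
  }
  if (length(feats) == 0L) stop("no usable feature columns")
  fit <- suppressWarnings(stats::glm(label ~ ., data = d, family = binomial()))
  beta <- coef(fit)[feats]
  se <- sqrt(diag(vcov(fit)))[feats]
  separated <- !fit$converged | abs(beta) > 15 | se > 100
  lrt <- suppressWarnings(stats::drop1(fit, test = "LRT"))
  p <- lrt[feats, "Pr(>Chi)"]
  res <- data.frame(feature = feats, beta = beta, or = exp(beta),
                    ci_lo = exp(beta - 1.96 * se),
                    ci_hi = exp(beta + 1.96 * se),
                    p = p, row.names = NULL, stringsAsFactors = FALSE)
  res$ci_lo[separated] <- 0
  res$ci_hi[separated] <- Inf
  structure(res, class = c("EnrichmentResult", "data.frame"),
            converged = fit$converged, separated = feats[separated],
            dropped = degen)
}

#' Assemble the causal-SNP annotation dataset
#'
#' Labels each (SNP, target) pair as causal (1) when the SNP is the most
#' significantly associated variant for that target, applies the exclusion
#' rule (pairs whose SNP is significant for the target but not the top hit
#' are removed, per target), and joins the supplied binary feature columns.
#'
#' @param qtl_results data.frame(target, snp, p, significant)
#' @param features data.frame keyed by (target, snp) with binary feature
#'   columns
#' @return data.frame ready for \code{\link{annotation_enrichment}};
#'   attribute `n_excluded` counts the removed significant-but-not-top pairs
#' @export
build_annotation_dataset <- function(qtl_results, features) {
  q <- as.data.frame(qtl_results)
  top <- unlist(lapply(split(seq_len(nrow(q)), q$target), function(idx) {
    idx[which.min(q$p[idx])]
  }), use.names = FALSE)
  q$label <- 0L
  q$label[top] <- 1L
  excl <- q$significant & q$label == 0L
  out <- merge(q[!excl, c("target", "snp", "label")], features,
               by = c("target", "snp"))
  structure(out, n_excluded = sum(excl))
}

#' Distance-bin annotation features
#'
#' One-hot encoding of SNP-to-target distance over five 10-kb bins starting
#' at 1 bp: [1, 10 kb], (10, 20 kb], ..., (40, 50 kb].  Distances beyond
#' 50 kb map to the all-zero reference category; distance 0 (inside the
#' target) sets the `inside` flag instead.
#'
#' @param distance non-negative distances in bp (vectorized)
#' @return matrix with columns inside, bin1..bin5
#' @export
distance_bins <- function(distance) {
  d <- as.numeric(distance)
  if (any(d < 0)) stop("distances must be non-negative")
  bins <- vapply(1:5, function(b) {
    as.numeric(d > (b - 1) * 1e4 & d <= b * 1e4)
  }, numeric(length(d)))
  out <- cbind(inside = as.numeric(d == 0),
               matrix(bins, ncol = 5L,
                      dimnames = list(NULL, paste0("bin", 1:5))))
  rownames(out) <- names(distance)
  out
}

#' Match a hexamer set against a sequence
#'
#' All (possibly overlapping) 1-based start positions where any member of
#' the set occurs; used for exonic-splice-enhancer annotation.  Windows
#' containing non-ACGT characters are skipped with a warning.
#'
#' @param sequence single uppercase DNA string
#' @param hexamer_set character vector of 6-mers
#' @return integer vector of 1-based match start positions (sorted, unique)
#' @export
match_hexamers <- function(sequence, hexamer_set) {
  if (length(hexamer_set) == 0L) return(integer())
  stopifnot(all(nchar(hexamer_set) == 6L))
  n <- nchar(sequence)
  if (n < 6L) return(integer())
  starts <- seq_len(n - 5L)
  windows <- substring(sequence, starts, starts + 5L)
  valid <- !grepl("[^ACGT]", windows)
  if (any(!valid)) {
    warning("skipping windows with non-ACGT characters", call. = FALSE)
  }
  sort(starts[valid & windows %in% hexamer_set])
}

#' Fisher gene-set enrichment with Woolf confidence interval
#'
#' 2 x 2 Fisher's exact test of hit membership against set membership over
#' a gene universe, with the odds ratio and Woolf (log-normal) CI computed
#' from the table cells (Haldane 0.5 correction when any cell is zero).
#'
#' @param hits character vector of hit genes (subset of universe)
#' @param gene_set character vector defining the set (subset of universe)
#' @param universe character vector of all eligible genes
#' @return list(or, ci_lo, ci_hi, p, table)
#' @export
geneset_fisher <- function(hits, gene_set, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("empty universe")
  stopifnot(all(hits %in% universe), all(gene_set %in% universe))
  in_hit <- universe %in% hits
  in_set <- universe %in% gene_set
  a <- sum(in_hit & in_set); b <- sum(in_hit & !in_set)
  c_ <- sum(!in_hit & in_set); d <- sum(!in_hit & !in_set)
  tab <- matrix(c(a, b, c_, d), 2L, byrow = TRUE,
                dimnames = list(c("hit", "nonhit"), c("in_set", "out_set")))
  p <- fisher.test(tab)$p.value
  cells <- c(a, b, c_, d)
  if (any(cells == 0)) {
    warning("zero cell: applying Haldane 0.5 correction to the OR/CI",
            call. = FALSE)
    cells <- cells + 0.5
  }
  lor <- log(cells[1]) - log(cells[2]) - log(cells[3]) + log(cells[4])
  se <- sqrt(sum(1 / cells))
  list(or = exp(lor), ci_lo = exp(lor - 1.96 * se),
       ci_hi = exp(lor + 1.96 * se), p = p, table = tab)
}

#' Intersect GWA loci with eQTL results via best proxies
#'
#' For each GWA SNP and candidate gene, the SNP itself is used when it was
#' tested for that gene; otherwise its best tested proxy (highest r-squared,
#' ties broken by smaller distance) contributes — one proxy per (GWA SNP,
#' gene) pair, to avoid double counting under LD.  Genes are restricted to
#' the expressed set.  An overall enrichment Fisher test classifies every
#' tested SNP as eQTL/non-eQTL and GWA (a GWA SNP or a best proxy) vs not.
#'
#' @param gwa_table data.frame(snp, ...) of GWA SNPs
#' @param proxy_table data.frame(gwa_snp, proxy, r2, distance)
#' @param qtl_results data.frame(gene, snp, p, significant) - all tested pairs
#' @param expressed_genes character vector of eligible genes
#' @return list: `annotated` (per GWA SNP x gene: used snp, r2, p,
#'   significant), `unevaluable` (GWA SNPs with no tested proxy),
#'   `enrichment` (\code{\link{geneset_fisher}}-style list over SNPs)
#' @export
gwa_eqtl_overlap <- function(gwa_table, proxy_table, qtl_results,
                             expressed_genes) {
  q <- qtl_results[qtl_results$gene %in% expressed_genes, , drop = FALSE]
  tested <- unique(q$snp)
  rows <- list()
  unevaluable <- character()
  used_snps <- character()
  for (gs in unique(as.character(gwa_table$snp))) {
    cand <- proxy_table[proxy_table$gwa_snp == gs, , drop = FALSE]
    cand <- rbind(data.frame(gwa_snp = gs, proxy = gs, r2 = 1,
                             distance = 0, stringsAsFactors = FALSE),
                  cand[, c("gwa_snp", "proxy", "r2", "distance")])
    cand <- cand[cand$proxy %in% tested, , drop = FALSE]
    if (nrow(cand) == 0L) {
      unevaluable <- c(unevaluable, gs)
      next
    }
    hits <- merge(cand, q, by.x = "proxy", by.y = "snp")
    # best proxy per gene: highest r2, then smallest distance
    for (gidx in split(seq_len(nrow(hits)), hits$gene)) {
      h <- hits[gidx, , drop = FALSE]
      h <- h[order(-h$r2, abs(h$distance)), , drop = FALSE]
      best <- h[1L, ]
      rows[[length(rows) + 1L]] <- data.frame(
        gwa_snp = gs, gene = best$gene, used_snp = best$proxy,
        r2 = best$r2, p = best$p, significant = best$significant,
        stringsAsFactors = FALSE)
      used_snps <- c(used_snps, best$proxy)
    }
  }
  annotated <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gwa_snp = character(), gene = character(),
               used_snp = character(), r2 = numeric(), p = numeric(),
               significant = logical(), stringsAsFactors = FALSE)
  is_eqtl <- vapply(split(q$significant, q$snp), any, logical(1))
  is_gwa <- names(is_eqtl) %in% unique(used_snps)
  tab <- matrix(c(sum(is_eqtl & is_gwa), sum(is_eqtl & !is_gwa),
                  sum(!is_eqtl & is_gwa), sum(!is_eqtl & !is_gwa)),
                2L, byrow = TRUE,
                dimnames = list(c("eqtl", "non_eqtl"), c("gwa", "non_gwa")))
  fet <- fisher.test(tab)
  list(annotated = annotated, unevaluable = unevaluable,
       enrichment = list(or = unname(fet$estimate), p = fet$p.value,
                         table = tab))
}
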
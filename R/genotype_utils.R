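#' Fold rare minor-allele homozygotes into heterozygotes
#'
#' For each SNP (row) of a rounded-dosage genotype matrix, if the
#' minor-allele homozygote class occurs in fewer than `min_count` samples,
#' those samples are recoded as heterozygous.  Stabilizes per-genotype-class
#' tests against singleton classes.
#'
#' @param genotypes SNP x sample matrix of genotypes in \{0, 1, 2\}
#' @param min_count minimum carriers of the minor homozygote class (default 3)
#' @return recoded matrix with attribute `n_folded` (SNPs touched)
#' @export
fold_rare_homozygotes <- function(genotypes, min_count = 3L) {
  g <- round(as.matrix(genotypes))
  if (any(!g %in% c(0, 1, 2))) stop("genotypes must round to 0/1/2")
  folded <- 0L
  for (i in seq_len(nrow(g))) {
    af <- mean(g[i, ]) / 2           # alt allele frequency
    minor_hom <- if (af <= 0.5) 2 else 0
    idx <- g[i, ] == minor_hom
    if (sum(idx) > 0 && sum(idx) < min_count) {
      g[i, idx] <- 1
      folded <- folded + 1L
    }
  }
  attr(g, "n_folded") <- folded
  g
}

#' Genotype call concordance and efficacy
#'
#' @param calls_a truth genotype calls (0/1/2, NA allowed)
#' @param calls_b test genotype calls (0/1/2, NA allowed)
#' @param confidences optional per-call confidence of `calls_b`
#' @param minor_allele which allele (count) is minor in the truth set; calls
#'   with `calls_a` > 0 carry at least one minor allele under the default
#'   coding where the alternate allele is minor
#' @return list: `accuracy` (agreement among jointly called),
#'   `nonref_accuracy` (agreement among truth calls carrying >= 1 minor
#'   allele; NA when the denominator is empty), `efficacy` (fraction with
#'   confidence > 0.95, NULL without confidences)
#' @export
genotype_concordance <- function(calls_a, calls_b, confidences = NULL) {
  stopifnot(length(calls_a) == length(calls_b))
  joint <- !is.na(calls_a) & !is.na(calls_b)
  if (!any(joint)) stop("no overlapping calls")
  acc <- mean(calls_a[joint] == calls_b[joint])
  nonref <- joint & calls_a > 0
  nonref_acc <- if (any(nonref)) mean(calls_a[nonref] == calls_b[nonref]) else NA_real_
  eff <- NULL
  if (!is.null(confidences)) {
    stopifnot(length(confidences) == length(calls_a))
    eff <- mean(confidences > 0.95, na.rm = TRUE)
  }
  list(accuracy = acc, nonref_accuracy = nonref_acc, efficacy = eff)
}

#' Principal components of a genotype matrix
#'
#' Scores from the singular value decomposition of the column-centred (and
#' unit-variance scaled) dosage matrix; monomorphic SNPs are dropped before
#' scaling.  Used as ancestry covariates in the QTL models.
#'
#' @param genotypes SNP x sample dosage matrix
#' @param k number of components (default 3)
#' @return sample x k matrix of PC scores, ordered by variance explained,
#'   with attribute `var_explained`
#' @export
genotype_pcs <- function(genotypes, k = 3L) {
  g <- as.matrix(genotypes)
  keep <- apply(g, 1L, function(x) stats::var(x) > 0)
  g <- g[keep, , drop = FALSE]
  x <- scale(t(g))            # samples x SNPs, centred/scaled per SNP
  if (ncol(x) < 1L) stop("no polymorphic SNPs")
  s <- svd(x, nu = min(k, min(dim(x))), nv = 0)
  if (k > sum(s$d > 1e-8)) stop("k exceeds the rank of the genotype matrix")
  scores <- s$u[, seq_len(k), drop = FALSE] %*% diag(s$d[seq_len(k)], k, k)
  rownames(scores) <- colnames(genotypes)
  colnames(scores) <- paste0("PC", seq_len(k))
  attr(scores, "var_explained") <- (s$d[seq_len(k)]^2) / sum(s$d^2)
  scores
}
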
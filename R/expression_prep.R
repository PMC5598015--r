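#' Quantile-based scaling of a count matrix
#'
#' Scales every sample (column) so that its upper-quantile of non-zero counts
#' equals the geometric mean of that quantile across samples (upper-quartile
#' scaling by default).  Within-sample ordering is preserved because the
#' transform is a positive per-sample constant.
#'
#' @param counts numeric matrix, features in rows, samples in columns
#' @param quantile fraction in (0, 1); the scaling quantile of the non-zero
#'   counts (default 0.75, upper-quartile scaling)
#' @return scaled matrix of the same shape, with attribute `scale_factors`
#' @examples
#' m <- matrix(c(1, 5, 10, 2, 10, 20), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), c("a", "b")))
#' scale_counts_quantile(m)
#' @export
scale_counts_quantile <- function(counts, quantile = 0.75) {
  counts <- as.matrix(counts)
  stopifnot(quantile > 0, quantile < 1)
  if (any(counts < 0)) stop("counts must be non-negative")
  q <- apply(counts, 2L, function(x) {
    nz <- x[x > 0]
    if (length(nz) == 0L) return(NA_real_)
    stats::quantile(nz, probs = quantile, names = FALSE, type = 7)
  })
  if (anyNA(q)) {
    bad <- colnames(counts)[is.na(q)] %||% which(is.na(q))
    stop(sprintf("sample(s) with all-zero counts: %s",
                 paste(bad, collapse = ", ")))
  }
  target <- exp(mean(log(q)))
  sf <- target / q
  out <- sweep(counts, 2L, sf, `*`)
  attr(out, "scale_factors") <- sf
  out
}

#' Reads per kilobase of transcript per million mapped reads
#'
#' @param counts feature x sample count matrix
#' @param gene_lengths feature lengths in bp (recycled per sample)
#' @param library_sizes per-sample mapped read totals
#' @return RPKM matrix: `count / ((length/1e3) * (library/1e6))`
#' @export
rpkm <- function(counts, gene_lengths, library_sizes) {
  counts <- as.matrix(counts)
  stopifnot(length(gene_lengths) == nrow(counts),
            length(library_sizes) == ncol(counts))
  if (any(gene_lengths <= 0)) stop("gene lengths must be positive")
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  sweep(counts / (gene_lengths / 1e3), 2L, library_sizes / 1e6, `/`)
}

#' Expression filter on an RPKM matrix
#'
#' Keeps features whose value strictly exceeds `min_rpkm` in more than (or at
#' least, with `fraction_strict = FALSE`) `min_fraction` of samples.  The two
#' study rules are `filter_expressed(m, 0, 0.5, fraction_strict = FALSE)`
#' (expressed genes entering the eQTL scan) and
#' `filter_expressed(m, 1, 0.05)` (genes considered for GWA follow-up).
#'
#' @param rpkm_matrix feature x sample matrix
#' @param min_rpkm value threshold (strict inequality)
#' @param min_fraction sample-fraction threshold
#' @param fraction_strict if TRUE require fraction > min_fraction, else >=
#' @return character vector of surviving feature ids
#' @export
filter_expressed <- function(rpkm_matrix, min_rpkm, min_fraction,
                             fraction_strict = TRUE) {
  m <- as.matrix(rpkm_matrix)
  frac <- rowMeans(m > min_rpkm)
  keep <- if (fraction_strict) frac > min_fraction else frac >= min_fraction
  rn <- rownames(m) %||% as.character(seq_len(nrow(m)))
  rn[keep]
}

#' Quantile normalization across samples
#'
#' Forces every sample (column) onto the common distribution given by the
#' means of the order statistics; within-sample ranks are preserved and ties
#' receive the average of the corresponding reference values.
#'
#' @param m feature x sample matrix
#' @return normalized matrix
#' @export
quantile_normalize_samples <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m)
  sorted <- apply(m, 2L, sort)
  ref <- rowMeans(sorted)
  out <- apply(m, 2L, function(x) {
    r <- rank(x, ties.method = "average")
    # non-integer (tied) ranks interpolate between neighbouring reference values
    lo <- ref[floor(r)]
    hi <- ref[ceiling(r)]
    (lo + hi) / 2
  })
  dimnames(out) <- dimnames(m)
  out
}

#' Rank-based inverse normal transform
#'
#' Maps each feature (row) to quantiles of the standard normal using
#' plotting positions r/(n+1); ties are broken by a seeded random
#' permutation, as in the study's eQTL preprocessing.
#'
#' @param m feature x sample matrix (or a single numeric vector)
#' @param seed integer seed for the random tie-breaks
#' @return transformed matrix/vector
#' @export
rank_inverse_normal <- function(m, seed = 1L) {
  vec <- is.null(dim(m))
  m <- if (vec) matrix(m, nrow = 1L) else as.matrix(m)
  n <- ncol(m)
  if (n < 3L) stop("need at least 3 samples")
  set.seed(seed)
  out <- t(apply(m, 1L, function(x) {
    qnorm(rank(x, ties.method = "random") / (n + 1))
  }))
  dimnames(out) <- dimnames(m)
  if (vec) out[1L, ] else out
}

#' Residualize expression on covariates
#'
#' Per feature, ordinary least-squares residuals against the covariate design
#' (factors expanded to dummies), optionally re-centred at the feature mean so
#' absolute expression information is preserved.  Aliased design columns are
#' dropped with a warning.  When `center` and `group` are both present and
#' perfectly confounded, the group column is aliased and a warning names it;
#' disease status is then adjusted implicitly through `center`.
#'
#' @param m feature x sample matrix
#' @param covariates data.frame, one row per sample (same order as columns)
#' @param keep_mean add back the per-feature mean (default TRUE)
#' @return adjusted matrix
#' @export
adjust_covariates <- function(m, covariates, keep_mean = TRUE) {
  m <- as.matrix(m)
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(covariates) == ncol(m))
  if (anyNA(covariates)) stop("covariates contain missing values")
  X <- stats::model.matrix(~ ., data = covariates)
  X <- drop_aliased(X, context = "adjust_covariates")
  fit <- lm.fit(X, t(m))
  res <- t(as.matrix(fit$residuals))
  if (keep_mean) res <- res + rowMeans(m)
  dimnames(res) <- dimnames(m)
  res
}

#' Fibroblast signature score
#'
#' Per-sample sum of z-scaled log10 expression over a set of marker genes;
#' used as a composition covariate in all downstream models.
#'
#' @param expr feature x sample matrix of scaled (non-log) expression
#' @param marker_gene_ids character vector of marker feature ids
#' @param offset pseudo-count added before log10 (default 1)
#' @return named per-sample numeric score
#' @export
fibroblast_score <- function(expr, marker_gene_ids, offset = 1) {
  expr <- as.matrix(expr)
  missing <- setdiff(marker_gene_ids, rownames(expr))
  if (length(missing)) {
    stop(sprintf("marker gene(s) missing from matrix: %s",
                 paste(missing, collapse = ", ")))
  }
  lg <- log10(expr[marker_gene_ids, , drop = FALSE] + offset)
  z <- t(scale(t(lg)))
  z[is.nan(z)] <- 0  # constant marker contributes nothing
  colSums(z)
}
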
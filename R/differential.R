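#' Wilcoxon-Mann-Whitney differential expression with a fold-change gate
#'
#' Two-sided rank-sum test per gene on covariate-adjusted log expression,
#' Benjamini-Hochberg adjusted across tested genes.  A gene is flagged
#' differential only when the adjusted p-value is below `alpha` AND the
#' absolute effect (difference of group means of adjusted log values)
#' exceeds `fc_threshold` — the double gate guards against spurious
#' small-magnitude hits.
#'
#' @param adjusted_expr gene x sample matrix of adjusted log expression
#' @param groups factor/vector with two levels; the second level of
#'   `factor(groups)` is treated as the case group for the effect sign
#' @param fc_threshold absolute log fold-change gate (default log(1.2))
#' @param alpha FDR level for the flag (default 0.05)
#' @return data.frame: feature, statistic (W), effect, p, fdr, differential
#' @export
wmw_differential_expression <- function(adjusted_expr, groups,
                                        fc_threshold = log(1.2),
                                        alpha = 0.05) {
  m <- as.matrix(adjusted_expr)
  g <- factor(groups)
  stopifnot(nlevels(g) == 2L, length(g) == ncol(m))
  if (any(table(g) < 2L)) stop("each group needs at least 2 samples")
  case <- g == levels(g)[2L]
  res <- t(apply(m, 1L, function(x) {
    wt <- suppressWarnings(wilcox.test(x[case], x[!case]))
    c(W = unname(wt$statistic), p = wt$p.value,
      effect = mean(x[case]) - mean(x[!case]))
  }))
  fdr <- p.adjust(res[, "p"], method = "BH")
  data.frame(feature = rownames(m) %||% as.character(seq_len(nrow(m))),
             statistic = res[, "W"], effect = res[, "effect"],
             p = res[, "p"], fdr = fdr,
             differential = fdr < alpha & abs(res[, "effect"]) > fc_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Differential exon usage on PSI values
#'
#' For each exon part with 0 < PSI < 1 in all samples, fits the nested
#' Gaussian linear models `PSI ~ group + covariates` (full) versus
#' `PSI ~ covariates` (reduced) and evaluates the likelihood ratio via the
#' exact nested-model F statistic.  Parts are flagged when BH FDR < `alpha`
#' and the absolute group coefficient exceeds `effect_threshold` (0.1, i.e.
#' a 10 percentage-point PSI difference).
#'
#' Parts violating the open-interval PSI condition are dropped before
#' testing; pass `prefiltered = TRUE` to assert the input already satisfies
#' it.  If the group factor is aliased with the covariates (e.g. a covariate
#' equal to group), a warning is raised and the affected fits return NA
#' rather than a spurious p-value.
#'
#' @param psi exon-part x sample matrix of PSI values
#' @param groups two-level factor; second level of `factor(groups)` = case
#' @param covariates optional data.frame of per-sample covariates
#' @param effect_threshold absolute PSI-difference gate (default 0.1)
#' @param alpha FDR level for the flag (default 0.05)
#' @param prefiltered input already restricted to 0 < PSI < 1 everywhere
#' @return data.frame: feature, statistic (F), effect (group beta = case
#'   minus control), p, fdr, differential
#' @export
diff_exon_usage <- function(psi, groups, covariates = NULL,
                            effect_threshold = 0.1, alpha = 0.05,
                            prefiltered = FALSE) {
  m <- as.matrix(psi)
  g <- factor(groups)
  stopifnot(nlevels(g) == 2L, length(g) == ncol(m))
  if (!prefiltered) {
    ok <- apply(m, 1L, function(x) all(is.finite(x)) && all(x > 0 & x < 1))
    m <- m[ok, , drop = FALSE]
  } else if (anyNA(m)) {
    stop("prefiltered PSI matrix contains missing values")
  }
  if (nrow(m) == 0L) {
    return(data.frame(feature = character(), statistic = numeric(),
                      effect = numeric(), p = numeric(), fdr = numeric(),
                      differential = logical(), stringsAsFactors = FALSE))
  }
  case <- as.numeric(g == levels(g)[2L])
  n <- ncol(m)
  if (is.null(covariates)) {
    Xr <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  } else {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == n)
    Xr <- drop_aliased(stats::model.matrix(~ ., covariates),
                       context = "diff_exon_usage covariates")
  }
  Xf <- cbind(Xr, group = case)
  aliased <- qr(Xf)$rank == qr(Xr)$rank
  if (aliased) {
    warning("group factor is aliased with the covariates; returning NA fits",
            call. = FALSE)
    return(data.frame(feature = rownames(m), statistic = NA_real_,
                      effect = NA_real_, p = NA_real_, fdr = NA_real_,
                      differential = FALSE, row.names = NULL,
                      stringsAsFactors = FALSE))
  }
  Y <- t(m)
  full <- ols_rss(Xf, Y, want_coef = TRUE)
  red <- ols_rss(Xr, Y)
  df2 <- n - full$rank
  ft <- nested_f_test(red$rss, full$rss, df1 = 1L, df2 = df2)
  beta <- full$coef["group", ]
  fdr <- p.adjust(ft$p.value, method = "BH")
  data.frame(feature = rownames(m), statistic = unname(ft$statistic),
             effect = unname(beta), p = unname(ft$p.value), fdr = unname(fdr),
             differential = unname(fdr < alpha & abs(beta) > effect_threshold),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Method-of-moments negative binomial fit with upper trimming
#'
#' Fits mean and size of a negative binomial to observed counts after
#' discarding counts above the `trim_quantile` quantile, as used to
#' parameterize the exon-usage simulation from real total counts.
#'
#' @param counts non-negative integer counts
#' @param trim_quantile upper trim (default 0.9: drop above 90th percentile)
#' @return list(mean, size); size is capped at 1e8 with a warning when the
#'   trimmed sample is under-dispersed (variance <= mean)
#' @export
fit_negative_binomial <- function(counts, trim_quantile = 0.9) {
  stopifnot(all(counts >= 0))
  cut <- stats::quantile(counts, trim_quantile, names = FALSE)
  x <- counts[counts <= cut]
  if (length(x) == 0L) stop("no counts left after trimming")
  if (length(x) < 30L) stop("need at least 30 observations after trimming")
  m <- mean(x)
  v <- stats::var(x)
  if (v <= m) {
    warning("trimmed counts are not over-dispersed; size capped", call. = FALSE)
    return(list(mean = m, size = 1e8))
  }
  list(mean = m, size = m^2 / (v - m))
}

#' Operating characteristics of the PSI exon-usage caller
#'
#' Replays the study's simulation: per replicate, exon-total reads are drawn
#' from a negative binomial, true PSI from Uniform(0,1), a fraction
#' `frac_differential` of exons gets the case-group PSI shifted by
#' `delta_psi` (additively, clipped to [0,1]; set
#' `multiplicative = TRUE` for the proportional reading), inclusion reads
#' are Binomial(total, PSI), and observed PSI = inclusion/total.  Exons not
#' satisfying 0 < PSI < 1 in every sample are excluded from testing but kept
#' in the sensitivity denominator.  \code{\link{diff_exon_usage}} (no
#' covariates) is then applied with the double gate (BH FDR < 0.05 and
#' |effect| > 0.1).
#'
#' @param n_cases,n_controls group sizes (study design: 97 / 108)
#' @param nb_mean,nb_size negative-binomial parameters of the total counts
#' @param frac_differential fraction of exons with a planted shift (0.1)
#' @param delta_psi planted PSI shift (0.1)
#' @param n_exons exons per replicate
#' @param replicates number of replicates
#' @param seed integer seed (one child seed per replicate)
#' @param multiplicative if TRUE, shift PSI by `psi * (1 + delta_psi)`
#' @param effect_threshold,alpha caller gates, see \code{\link{diff_exon_usage}}
#' @return object of class `UsageSimReport`: list with `per_replicate`
#'   (data.frame of TP/FP/FN/TN, sensitivity, fdr, n_tested) and `summary`
#'   (means and sds), plus the simulation parameters
#' @export
simulate_exon_usage_study <- function(n_cases = 97L, n_controls = 108L,
                                      nb_mean = 100, nb_size = 1,
                                      frac_differential = 0.1,
                                      delta_psi = 0.1,
                                      n_exons = 5000L, replicates = 20L,
                                      seed = 1L, multiplicative = FALSE,
                                      effect_threshold = 0.1, alpha = 0.05) {
  if (frac_differential < 0 || frac_differential >= 1) {
    stop("frac_differential must lie in [0, 1)")
  }
  n <- n_cases + n_controls
  groups <- factor(rep(c("control", "case"), c(n_controls, n_cases)),
                   levels = c("control", "case"))
  case <- groups == "case"
  n_diff <- round(frac_differential * n_exons)
  reps <- lapply(seq_len(replicates), function(r) {
    set.seed(child_seed(seed, paste0("usage_rep", r)))
    total <- matrix(rnbinom(n_exons * n, mu = nb_mean, size = nb_size),
                    nrow = n_exons)
    psi_true <- runif(n_exons)
    psi <- matrix(psi_true, n_exons, n)
    is_diff <- seq_len(n_exons) <= n_diff
    if (n_diff > 0) {
      shifted <- if (multiplicative) {
        psi[is_diff, case, drop = FALSE] * (1 + delta_psi)
      } else {
        psi[is_diff, case, drop = FALSE] + delta_psi
      }
      psi[is_diff, case] <- pmin(1, pmax(0, shifted))
    }
    inc <- matrix(rbinom(n_exons * n, size = total, prob = psi), nrow = n_exons)
    obs <- inc / ifelse(total > 0, total, NA)
    rownames(obs) <- sprintf("ex%05d", seq_len(n_exons))
    testable <- apply(obs, 1L, function(x) all(is.finite(x)) && all(x > 0 & x < 1))
    called <- rep(FALSE, n_exons)
    n_tested <- sum(testable)
    if (n_tested > 0L) {
      res <- diff_exon_usage(obs[testable, , drop = FALSE], groups,
                             effect_threshold = effect_threshold,
                             alpha = alpha, prefiltered = TRUE)
      called[testable] <- res$differential
    }
    tp <- sum(called & is_diff); fp <- sum(called & !is_diff)
    fn <- sum(!called & is_diff); tn <- sum(!called & !is_diff)
    data.frame(replicate = r, TP = tp, FP = fp, FN = fn, TN = tn,
               n_tested = n_tested,
               sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               fdr = if (tp + fp > 0) fp / (tp + fp) else 0)
  })
  per_rep <- do.call(rbind, reps)
  structure(list(
    per_replicate = per_rep,
    summary = list(mean_fdr = mean(per_rep$fdr), sd_fdr = sd(per_rep$fdr),
                   mean_sensitivity = mean(per_rep$sensitivity, na.rm = TRUE),
                   sd_sensitivity = sd(per_rep$sensitivity, na.rm = TRUE),
                   mean_tested = mean(per_rep$n_tested)),
    params = list(n_cases = n_cases, n_controls = n_controls,
                  nb_mean = nb_mean, nb_size = nb_size,
                  frac_differential = frac_differential, delta_psi = delta_psi,
                  n_exons = n_exons, replicates = replicates, seed = seed,
                  multiplicative = multiplicative)),
    class = "UsageSimReport")
}

#' @export
print.UsageSimReport <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "Exon-usage simulation: %d replicates of %d exons (%d vs %d samples)\n",
    x$params$replicates, x$params$n_exons, x$params$n_cases, x$params$n_controls))
  cat(sprintf("  mean FDR         %.4f (sd %.4f)\n", s$mean_fdr, s$sd_fdr))
  cat(sprintf("  mean sensitivity %.4f (sd %.4f)\n",
              s$mean_sensitivity, s$sd_sensitivity))
  cat(sprintf("  mean exons passing the 0<PSI<1 filter: %.1f\n", s$mean_tested))
  invisible(x)
}
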
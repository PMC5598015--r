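#' Filter heterozygous sites for allele-specific expression analysis
#'
#' Keeps sites with base quality strictly above `min_phred`, total coverage
#' of at least `min_reads`, both alleles observed (a site with one allele
#' unseen cannot be confirmed heterozygous from the reads), and not listed
#' in either allelic-mapping-bias mask.
#'
#' @param site_table data.frame with columns sample, site, ref_reads,
#'   alt_reads, phred (chrom/pos carried through)
#' @param min_phred base-quality threshold (default 30, strict)
#' @param min_reads coverage threshold (default 30, inclusive)
#' @param mappability_mask,sim_bias_mask character vectors of masked site ids
#' @return filtered site table, with attribute `n_removed`
#' @export
filter_ase_sites <- function(site_table, min_phred = 30, min_reads = 30,
                             mappability_mask = character(),
                             sim_bias_mask = character()) {
  st <- as.data.frame(site_table)
  total <- st$ref_reads + st$alt_reads
  keep <- st$phred > min_phred &
    total >= min_reads &
    st$ref_reads > 0 & st$alt_reads > 0 &
    !(st$site %in% mappability_mask) &
    !(st$site %in% sim_bias_mask)
  out <- st[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Per-individual expected reference-allele ratio
#'
#' Unweighted mean of per-site reference ratios over the passing
#' heterozygous sites of one sample; absorbs genome-wide mapping and GC
#' bias into the null of the per-site binomial test.
#'
#' @param records site table rows of one sample (ref_reads, alt_reads)
#' @return scalar expected reference ratio
#' @export
individual_expected_ratio <- function(records) {
  if (nrow(records) == 0L) stop("no passing heterozygous sites for sample")
  mean(records$ref_reads / (records$ref_reads + records$alt_reads))
}

#' Binomial allele-specific expression test at one site
#'
#' To stop coverage differences from driving significance, the observed
#' counts are first resampled to the cohort mean total allele count: a
#' seeded binomial redraw of the reference count at n = round(mean_total)
#' with the observed reference fraction.  The resampled counts are then
#' tested against the individual's expected reference ratio with a
#' two-sided exact binomial test.
#'
#' @param ref,alt observed allele read counts
#' @param expected_ratio individual expected reference ratio, in (0, 1)
#' @param mean_total mean total allele count over all heterozygous sites
#' @param seed integer seed for the resampling draw
#' @param resample set FALSE to test the observed counts directly
#' @return list(p.value, ref, alt) where ref/alt are the tested counts
#' @export
ase_site_test <- function(ref, alt, expected_ratio, mean_total, seed = 1L,
                          resample = TRUE) {
  stopifnot(ref >= 0, alt >= 0, ref + alt >= 1)
  if (expected_ratio <= 0 || expected_ratio >= 1) {
    stop("expected_ratio must lie strictly in (0, 1)")
  }
  if (mean_total < 1) stop("mean_total must be >= 1")
  if (resample) {
    nt <- round(mean_total)
    set.seed(seed)
    r <- rbinom(1L, nt, ref / (ref + alt))
    a <- nt - r
  } else {
    r <- ref
    a <- alt
  }
  p <- binom.test(r, r + a, p = expected_ratio)$p.value
  list(p.value = p, ref = r, alt = a)
}

#' Cohort-level allele-specific expression testing
#'
#' Applies \code{\link{ase_site_test}} to every record of a filtered site
#' table, using per-individual expected ratios and the global mean total
#' count, and attaches Storey q-values.
#'
#' @param site_table filtered table from \code{\link{filter_ase_sites}}
#' @param seed integer seed; each record gets its own derived seed
#' @param q_threshold imbalance call threshold (default 0.05)
#' @param resample see \code{\link{ase_site_test}}
#' @return site table with added columns expected_ratio, p, q, imbalanced
#' @export
ase_scan <- function(site_table, seed = 1L, q_threshold = 0.05,
                     resample = TRUE) {
  st <- as.data.frame(site_table)
  if (nrow(st) == 0L) stop("empty site table")
  er <- vapply(split(st, st$sample), individual_expected_ratio, numeric(1))
  er <- pmin(pmax(er, 1e-6), 1 - 1e-6)
  st$expected_ratio <- er[st$sample]
  mean_total <- mean(st$ref_reads + st$alt_reads)
  st$p <- vapply(seq_len(nrow(st)), function(i) {
    ase_site_test(st$ref_reads[i], st$alt_reads[i], st$expected_ratio[i],
                  mean_total, seed = child_seed(seed, paste0("ase", i)),
                  resample = resample)$p.value
  }, numeric(1))
  st$q <- if (nrow(st) >= 100L) storey_qvalues(st$p)$qvalues
          else p.adjust(st$p, "BH")
  st$imbalanced <- st$q < q_threshold
  st
}

#' Differential allelic imbalance between groups at one site
#'
#' Fisher's exact test on the 2 x 2 table of (imbalanced vs balanced
#' heterozygotes) x group, plus a two-proportion test on the pooled
#' alternative-allele read fractions.  The differential flag requires
#' FET p < `alpha` and an absolute difference in mean alternative-allele
#' ratio above `ratio_threshold`.
#'
#' @param case_records,control_records per-group rows of an
#'   \code{\link{ase_scan}} result for one site (columns ref_reads,
#'   alt_reads, imbalanced)
#' @param alpha FET significance level (default 0.05)
#' @param ratio_threshold minimum |delta mean alt ratio| (default 0.10)
#' @return list: per-group het/imbalanced counts, `fet_p`, `prop_p`,
#'   `ratio_case`, `ratio_control`, `delta_ratio`, `differential`
#' @export
differential_imbalance <- function(case_records, control_records,
                                   alpha = 0.05, ratio_threshold = 0.10) {
  if (nrow(case_records) == 0L || nrow(control_records) == 0L) {
    stop("site must be heterozygous in at least one individual per group")
  }
  n1 <- nrow(case_records); k1 <- sum(case_records$imbalanced)
  n0 <- nrow(control_records); k0 <- sum(control_records$imbalanced)
  tab <- matrix(c(k1, n1 - k1, k0, n0 - k0), nrow = 2L, byrow = TRUE)
  fet <- fisher.test(tab)
  a1 <- sum(case_records$alt_reads); t1 <- a1 + sum(case_records$ref_reads)
  a0 <- sum(control_records$alt_reads); t0 <- a0 + sum(control_records$ref_reads)
  pp <- suppressWarnings(prop.test(c(a1, a0), c(t1, t0)))$p.value
  r1 <- mean(case_records$alt_reads /
               (case_records$alt_reads + case_records$ref_reads))
  r0 <- mean(control_records$alt_reads /
               (control_records$alt_reads + control_records$ref_reads))
  list(het_case = n1, imbalanced_case = k1,
       het_control = n0, imbalanced_control = k0,
       fet_p = fet$p.value, prop_p = pp,
       ratio_case = r1, ratio_control = r0,
       delta_ratio = abs(r1 - r0),
       differential = fet$p.value < alpha && abs(r1 - r0) > ratio_threshold)
}

#' Greedy LD pruning of a ranked site list
#'
#' Iterates sites by ascending differential p-value (ties broken by
#' position), keeping a site only if it is not linked above `r2_threshold`
#' to any already-kept site.
#'
#' @param sites data.frame(site, p, pos)
#' @param ld_pairs data.frame(snp_a, snp_b, r2); treated as symmetric
#' @param r2_threshold linkage threshold (default 0.8, strict)
#' @return character vector of kept site ids
#' @export
ld_prune <- function(sites, ld_pairs, r2_threshold = 0.8) {
  s <- as.data.frame(sites)
  s <- s[order(s$p, s$pos), , drop = FALSE]
  linked <- ld_pairs[ld_pairs$r2 > r2_threshold, , drop = FALSE]
  kept <- character()
  for (i in seq_len(nrow(s))) {
    id <- s$site[i]
    hit <- (linked$snp_a == id & linked$snp_b %in% kept) |
           (linked$snp_b == id & linked$snp_a %in% kept)
    if (!any(hit)) kept <- c(kept, id)
  }
  kept
}
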
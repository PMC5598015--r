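#' Configuration for a synthetic study cohort
#'
#' Captures the statistical structure the downstream analyses assume: a
#' case/control cohort (defaults mirror the 97 case / 108 control study
#' design), Hardy-Weinberg genotypes at common allele frequencies,
#' negative-binomial gene and exon-total counts with log-normal library
#' sizes, binomially sampled exon-inclusion reads given a true PSI, and
#' planted effects for every analysis stage.
#'
#' Planted effect tables (all optional, NULL = none):
#' \describe{
#'   \item{eqtl}{data.frame(gene, snp, beta): additive shift per dosage unit
#'     on the log-expression scale}
#'   \item{specific_eqtl}{data.frame(gene, snp, beta, group): eQTL active in
#'     one group only ("case" or "control")}
#'   \item{de}{data.frame(gene, lfc): natural-log fold change in cases}
#'   \item{dpsi}{data.frame(exon, delta): additive PSI shift in cases,
#'     clipped to [0, 1]; exon ids look like "g001:E02"}
#'   \item{sqtl}{data.frame(gene, exon, snp, beta): additive PSI shift per
#'     dosage unit for the target exon part}
#'   \item{ase}{data.frame(snp, ref_fraction): true reference-allele read
#'     fraction at heterozygous samples of that site}
#' }
#'
#' @param n_cases,n_controls group sizes (defaults 97 / 108)
#' @param n_genes number of genes (default 200)
#' @param n_exons_per_gene integer range, exon parts per gene (default 2..6)
#' @param n_snps number of SNPs (default 400); SNPs are placed within 1 Mb of
#'   genes, round robin, so every SNP is cis to some gene
#' @param maf_range minor-allele-frequency range (default (0.1, 0.5))
#' @param nb_mean,nb_size negative-binomial mean and size for gene counts
#'   (defaults 200, 5)
#' @param exon_nb_mean,exon_nb_size negative binomial for exon totals
#'   (defaults 100, 1 - the heavy-tailed regime of the exon-usage study)
#' @param library_size_sd sd of log-normal library size factors (default 0.2)
#' @param ase_coverage mean total allele count at ASE sites (default 100)
#' @param ref_bias global expected reference-allele fraction (default 0.5)
#' @param covariate_confounding shift (in sd units) of age/RIN in cases
#'   (default 0.3); all cases share one recruitment center, so center and
#'   group are perfectly confounded, as in the study
#' @param effects list of planted-effect tables, see above
#' @param seed master integer seed
#' @return object of class `cohort_config`
#' @export
cohort_config <- function(n_cases = 97L, n_controls = 108L,
                          n_genes = 200L, n_exons_per_gene = c(2L, 6L),
                          n_snps = 400L, maf_range = c(0.1, 0.5),
                          nb_mean = 200, nb_size = 5,
                          exon_nb_mean = 100, exon_nb_size = 1,
                          library_size_sd = 0.2,
                          ase_coverage = 100, ref_bias = 0.5,
                          covariate_confounding = 0.3,
                          effects = list(), seed = 1L) {
  stopifnot(n_cases >= 2L, n_controls >= 2L, n_genes >= 1L, n_snps >= 1L,
            nb_mean > 0, nb_size > 0, exon_nb_mean > 0, exon_nb_size > 0,
            library_size_sd >= 0, ase_coverage >= 1,
            ref_bias > 0, ref_bias < 1,
            length(maf_range) == 2L, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            length(n_exons_per_gene) == 2L, n_exons_per_gene[1] >= 1L)
  known <- c("eqtl", "specific_eqtl", "de", "dpsi", "sqtl", "ase")
  bad <- setdiff(names(effects), known)
  if (length(bad)) stop("unknown effect class(es): ", paste(bad, collapse = ", "))
  structure(c(as.list(environment())), class = "cohort_config")
}

gene_ids <- function(n) sprintf("g%03d", seq_len(n))
snp_ids <- function(n) sprintf("s%04d", seq_len(n))

check_planted <- function(effects, genes, snps, exons) {
  chk <- function(vals, universe, what) {
    missing <- setdiff(as.character(vals), universe)
    if (length(missing)) {
      stop(sprintf("planted effect references unknown %s: %s",
                   what, paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  e <- effects
  if (!is.null(e$eqtl)) { chk(e$eqtl$gene, genes, "gene"); chk(e$eqtl$snp, snps, "SNP") }
  if (!is.null(e$specific_eqtl)) {
    chk(e$specific_eqtl$gene, genes, "gene"); chk(e$specific_eqtl$snp, snps, "SNP")
    stopifnot(all(e$specific_eqtl$group %in% c("case", "control")))
  }
  if (!is.null(e$de)) chk(e$de$gene, genes, "gene")
  if (!is.null(e$dpsi)) chk(e$dpsi$exon, exons, "exon part")
  if (!is.null(e$sqtl)) {
    chk(e$sqtl$gene, genes, "gene"); chk(e$sqtl$exon, exons, "exon part")
    chk(e$sqtl$snp, snps, "SNP")
  }
  if (!is.null(e$ase)) chk(e$ase$snp, snps, "SNP")
  invisible(TRUE)
}

#' Simulate a full study cohort
#'
#' Draws genotypes from Hardy-Weinberg proportions at per-SNP allele
#' frequencies, gene counts from a negative binomial with log-normal library
#' sizes and planted log-scale effects, exon totals from a negative binomial
#' with inclusion reads binomial given the true PSI (with planted group and
#' genotype-interaction shifts), and allele-specific read counts at
#' heterozygous sites.  The same seed always yields the identical cohort;
#' each data layer uses its own derived generator so adding one effect class
#' does not perturb the others.
#'
#' @param config a \code{\link{cohort_config}}
#' @return object of class `StudyCohort`: list with elements `samples`,
#'   `genotypes`, `snps`, `gene_counts`, `genes`, `exon_usage` (list with
#'   `parts`, `inclusion`, `total`, `psi`), `allele_counts`, and `truth`
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  n <- cfg$n_cases + cfg$n_controls
  ids <- sprintf("smp%03d", seq_len(n))
  group <- factor(rep(c("case", "control"), c(cfg$n_cases, cfg$n_controls)),
                  levels = c("control", "case"))

  gids <- gene_ids(cfg$n_genes)
  sids <- snp_ids(cfg$n_snps)

  # gene models: spaced 2.5 Mb along one chromosome so each SNP is cis to
  # exactly one or two genes
  set.seed(child_seed(cfg$seed, "genes"))
  glen <- round(runif(cfg$n_genes, 2e3, 2e4))
  gstart <- 1e6 + (seq_len(cfg$n_genes) - 1L) * 2.5e6
  genes <- data.frame(gene = gids, chrom = "chr1", start = gstart,
                      end = gstart + glen, strand = "+", length = glen,
                      stringsAsFactors = FALSE)

  # exon parts tile each gene body
  set.seed(child_seed(cfg$seed, "exon_layout"))
  nex <- sample(seq(cfg$n_exons_per_gene[1], cfg$n_exons_per_gene[2]),
                cfg$n_genes, replace = TRUE)
  parts <- do.call(rbind, lapply(seq_len(cfg$n_genes), function(i) {
    k <- nex[i]
    bnd <- round(seq(genes$start[i], genes$end[i], length.out = k + 1L))
    data.frame(exon_id = sprintf("%s:E%02d", gids[i], seq_len(k)),
               gene = gids[i], chrom = "chr1",
               start = bnd[-(k + 1L)] + c(0L, rep(1L, k - 1L)), end = bnd[-1L],
               stringsAsFactors = FALSE)
  }))

  check_planted(cfg$effects, gids, sids, parts$exon_id)

  # covariates; all cases from one center (perfect group/center confounding)
  set.seed(child_seed(cfg$seed, "covariates"))
  conf <- cfg$covariate_confounding
  samples <- data.frame(
    id = ids, group = group,
    sex = factor(sample(c("m", "f"), n, replace = TRUE)),
    age = rnorm(n, 50 + conf * 12 * (group == "case"), 12),
    rin = pmin(10, pmax(5, rnorm(n, 8 - conf * 0.5 * (group == "case"), 0.5))),
    center = factor(ifelse(group == "case", "C1",
                           sample(c("C2", "C3"), n, replace = TRUE))),
    stringsAsFactors = FALSE)

  # genotypes: SNPs placed round-robin near genes, HWE at drawn MAF
  set.seed(child_seed(cfg$seed, "genotypes"))
  host <- rep(seq_len(cfg$n_genes), length.out = cfg$n_snps)
  pos <- round(genes$start[host] + runif(cfg$n_snps, -9e5, 9e5) + glen[host] / 2)
  maf <- runif(cfg$n_snps, cfg$maf_range[1], cfg$maf_range[2])
  geno <- vapply(seq_len(cfg$n_snps), function(k) {
    p <- maf[k]
    sample(0:2, n, replace = TRUE, prob = c((1 - p)^2, 2 * p * (1 - p), p^2))
  }, numeric(n))
  geno <- t(geno)
  dimnames(geno) <- list(sids, ids)
  snps <- data.frame(snp = sids, chrom = "chr1", pos = pos,
                     ref = "A", alt = "G", maf = maf, stringsAsFactors = FALSE)

  e <- cfg$effects
  is_case <- as.numeric(group == "case")

  # gene counts
  set.seed(child_seed(cfg$seed, "gene_counts"))
  lib <- rlnorm(n, 0, cfg$library_size_sd)
  base <- rlnorm(cfg$n_genes, 0, 1)
  logmu <- outer(log(cfg$nb_mean * base), log(lib), `+`)
  if (!is.null(e$de)) {
    for (r in seq_len(nrow(e$de))) {
      i <- match(e$de$gene[r], gids)
      logmu[i, ] <- logmu[i, ] + e$de$lfc[r] * is_case
    }
  }
  if (!is.null(e$eqtl)) {
    for (r in seq_len(nrow(e$eqtl))) {
      i <- match(e$eqtl$gene[r], gids)
      logmu[i, ] <- logmu[i, ] + e$eqtl$beta[r] * geno[e$eqtl$snp[r], ]
    }
  }
  if (!is.null(e$specific_eqtl)) {
    for (r in seq_len(nrow(e$specific_eqtl))) {
      i <- match(e$specific_eqtl$gene[r], gids)
      on <- if (e$specific_eqtl$group[r] == "case") is_case else 1 - is_case
      logmu[i, ] <- logmu[i, ] + e$specific_eqtl$beta[r] * geno[e$specific_eqtl$snp[r], ] * on
    }
  }
  counts <- matrix(rnbinom(cfg$n_genes * n, mu = exp(logmu), size = cfg$nb_size),
                   nrow = cfg$n_genes, dimnames = list(gids, ids))

  # exon usage: totals ~ NB, true PSI ~ U(0,1) with planted shifts,
  # inclusion ~ Binomial(total, PSI)
  set.seed(child_seed(cfg$seed, "exon_usage"))
  npart <- nrow(parts)
  total <- matrix(rnbinom(npart * n, mu = cfg$exon_nb_mean, size = cfg$exon_nb_size),
                  nrow = npart, dimnames = list(parts$exon_id, ids))
  psi0 <- runif(npart)
  psi <- matrix(psi0, npart, n, dimnames = list(parts$exon_id, ids))
  if (!is.null(e$dpsi)) {
    for (r in seq_len(nrow(e$dpsi))) {
      i <- match(e$dpsi$exon[r], parts$exon_id)
      psi[i, ] <- pmin(1, pmax(0, psi[i, ] + e$dpsi$delta[r] * is_case))
    }
  }
  if (!is.null(e$sqtl)) {
    for (r in seq_len(nrow(e$sqtl))) {
      i <- match(e$sqtl$exon[r], parts$exon_id)
      psi[i, ] <- pmin(1, pmax(0, psi[i, ] + e$sqtl$beta[r] * geno[e$sqtl$snp[r], ]))
    }
  }
  inclusion <- matrix(rbinom(npart * n, size = total, prob = psi),
                      nrow = npart, dimnames = list(parts$exon_id, ids))
  psi_obs <- inclusion / ifelse(total > 0, total, NA)

  # allele-specific counts at heterozygous samples of every SNP site
  set.seed(child_seed(cfg$seed, "ase"))
  rf <- stats::setNames(rep(cfg$ref_bias, cfg$n_snps), sids)
  if (!is.null(e$ase)) rf[e$ase$snp] <- e$ase$ref_fraction
  het <- which(geno == 1, arr.ind = TRUE)
  tot_reads <- rnbinom(nrow(het), mu = cfg$ase_coverage, size = 10) + 2L
  ref_reads <- rbinom(nrow(het), tot_reads, rf[het[, 1L]])
  allele_counts <- data.frame(
    sample = ids[het[, 2L]], site = sids[het[, 1L]],
    chrom = "chr1", pos = pos[het[, 1L]],
    ref_reads = ref_reads, alt_reads = tot_reads - ref_reads,
    phred = 37, stringsAsFactors = FALSE)

  structure(list(
    samples = samples, genotypes = geno, snps = snps,
    gene_counts = counts, genes = genes,
    exon_usage = list(parts = parts, inclusion = inclusion,
                      total = total, psi = psi_obs),
    allele_counts = allele_counts,
    truth = e, config = cfg), class = "StudyCohort")
}

#' Simulate GWA summary statistics over LD blocks
#'
#' Per-SNP p-values are uniform except in the designated enriched blocks,
#' where they are shifted down by `effect` decades on the -log10 scale.
#'
#' @param blocks an \code{\link{build_ld_blocks}} result (LdBlockSet)
#' @param enriched_block_ids block ids whose members receive the shift
#' @param effect shift on the -log10 p scale (decades; 0 = null)
#' @param seed integer seed
#' @return data.frame(snp, p)
#' @export
simulate_gwa_summary <- function(blocks, enriched_block_ids = character(),
                                 effect = 0, seed = 1L) {
  stopifnot(inherits(blocks, "LdBlockSet"), length(blocks$blocks) > 0L)
  unknown <- setdiff(as.character(enriched_block_ids), names(blocks$blocks))
  if (length(unknown)) stop("unknown block id(s): ", paste(unknown, collapse = ", "))
  set.seed(seed)
  snp <- unlist(blocks$blocks, use.names = FALSE)
  block_of <- rep(names(blocks$blocks), lengths(blocks$blocks))
  p <- runif(length(snp))
  hit <- block_of %in% enriched_block_ids
  p[hit] <- p[hit] * 10^(-effect)
  data.frame(snp = snp, p = p, stringsAsFactors = FALSE)
}
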
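#' Load a genotype dosage matrix from VCF or TSV
#'
#' VCF input uses the DS (dosage) FORMAT field when present, otherwise GT
#' converted to 0/1/2; multi-allelic records are skipped and counted.  TSV
#' input expects SNP row ids in the first column and one column per sample.
#'
#' @param path path to a `.vcf` (optionally gzipped) or dosage TSV file
#' @return list of class `GenotypeMatrix`: `dosages` (SNP x sample matrix in
#'   [0,2]), `snps` (data.frame snp, chrom, pos, ref, alt, maf),
#'   `n_skipped` multi-allelic records dropped
#' @export
load_genotypes <- function(path) {
  if (grepl("\\.vcf(\\.gz|\\.bgz)?$", path)) {
    vcf <- VariantAnnotation::readVcf(path)
    multi <- lengths(VariantAnnotation::alt(vcf)) != 1L
    n_skipped <- sum(multi)
    vcf <- vcf[!multi]
    gdat <- VariantAnnotation::geno(vcf)
    if ("DS" %in% names(gdat)) {
      dos <- gdat$DS
      mode(dos) <- "numeric"
    } else if ("GT" %in% names(gdat)) {
      gt <- gdat$GT
      dos <- matrix(vapply(gt, function(g) {
        if (g %in% c(".", "./.", ".|.")) return(NA_real_)
        sum(as.numeric(strsplit(g, "[/|]")[[1L]]))
      }, numeric(1)), nrow = nrow(gt), dimnames = dimnames(gt))
    } else stop("VCF has neither DS nor GT genotype fields")
    rr <- SummarizedExperiment::rowRanges(vcf)
    snps <- data.frame(
      snp = names(vcf),
      chrom = as.character(GenomicRanges::seqnames(rr)),
      pos = GenomicRanges::start(rr),
      ref = as.character(VariantAnnotation::ref(vcf)),
      alt = vapply(VariantAnnotation::alt(vcf),
                   function(a) as.character(a)[1L], character(1)),
      stringsAsFactors = FALSE)
  } else {
    tsv <- utils::read.delim(path, check.names = FALSE, comment.char = "#")
    dos <- as.matrix(tsv[, -1L, drop = FALSE])
    rownames(dos) <- tsv[[1L]]
    snps <- data.frame(snp = rownames(dos), chrom = NA_character_,
                       pos = NA_integer_, ref = NA_character_,
                       alt = NA_character_, stringsAsFactors = FALSE)
    n_skipped <- 0L
  }
  if (any(dos < 0 | dos > 2, na.rm = TRUE)) {
    stop("dosages outside [0, 2] in ", path)
  }
  af <- rowMeans(dos, na.rm = TRUE) / 2
  snps$maf <- pmin(af, 1 - af)
  structure(list(dosages = dos, snps = snps, n_skipped = n_skipped),
            class = "GenotypeMatrix")
}

#' Write a dosage matrix as a minimal VCF
#'
#' Emits one biallelic record per SNP with GT (rounded dosage) and DS
#' fields, so \code{\link{load_genotypes}} round-trips the dosages.
#'
#' @param dosages SNP x sample matrix in [0, 2]
#' @param snp_table data.frame(snp, chrom, pos, ref, alt)
#' @param path output path
#' @export
write_genotypes_vcf <- function(dosages, snp_table, path) {
  stopifnot(nrow(dosages) == nrow(snp_table))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", colnames(dosages)), collapse = "\t")),
             con)
  gt_of <- c("0/0", "0/1", "1/1")
  for (i in seq_len(nrow(dosages))) {
    cells <- sprintf("%s:%.6g", gt_of[round(dosages[i, ]) + 1L], dosages[i, ])
    writeLines(paste(c(snp_table$chrom[i], snp_table$pos[i], snp_table$snp[i],
                       snp_table$ref[i], snp_table$alt[i], ".", "PASS", ".",
                       "GT:DS", cells), collapse = "\t"), con)
  }
  invisible(path)
}

#' Load BED intervals
#'
#' Reads 0-based half-open BED (3+ columns; a 4th column is kept as label),
#' validates start < end with line numbers, and returns the intervals
#' sorted per chromosome alongside a GRanges (1-based) representation for
#' overlap queries.
#'
#' @param path BED file path
#' @return data.frame(chrom, start, end, label) sorted by (chrom, start),
#'   with attribute `granges`
#' @export
load_intervals <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  fields <- strsplit(lines[keep], "\t")
  lineno <- which(keep)
  n_col <- lengths(fields)
  if (any(n_col < 3L)) {
    stop("BED line ", lineno[which(n_col < 3L)[1L]], ": fewer than 3 columns")
  }
  d <- data.frame(
    chrom = vapply(fields, `[`, "", 1L),
    start = as.integer(vapply(fields, `[`, "", 2L)),
    end = as.integer(vapply(fields, `[`, "", 3L)),
    label = vapply(fields, function(f) if (length(f) >= 4L) f[4L] else NA_character_, ""),
    stringsAsFactors = FALSE)
  bad <- which(!is.finite(d$start) | !is.finite(d$end) | d$start >= d$end)
  if (length(bad)) {
    stop("BED line ", lineno[bad[1L]], ": start must be < end")
  }
  d <- d[order(d$chrom, d$start, d$end), , drop = FALSE]
  rownames(d) <- NULL
  attr(d, "granges") <- GenomicRanges::GRanges(
    d$chrom, IRanges::IRanges(d$start + 1L, d$end))
  d
}

#' Query positions against loaded intervals
#'
#' @param intervals a \code{\link{load_intervals}} result
#' @param chrom,pos 1-based query positions (vectorized)
#' @return logical: position covered by any interval
#' @export
positions_in_intervals <- function(intervals, chrom, pos) {
  gr <- attr(intervals, "granges")
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  GenomicRanges::countOverlaps(q, gr) > 0
}

write_result_tsv <- function(df, path, seed, stage) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cardioqtl %s | stage=%s | seed=%d",
                     as.character(utils::packageVersion("cardioqtl")),
                     stage, seed), con)
  utils::write.table(format(df, digits = 10, trim = TRUE), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the simulated end-to-end pipeline
#'
#' Generates a cohort from `config$cohort` (a \code{\link{cohort_config}}),
#' runs the requested stages in dependency order and writes one provenance-
#' stamped TSV per stage under `config$out_dir`.  Identical config and seed
#' give byte-identical outputs.
#'
#' Stages: `de` (Wilcoxon differential expression), `deu` (differential
#' exon usage), `eqtl` (cis scan), `eqtl_specific`, `sqtl`, `ase`,
#' `gwa_enrich`.
#'
#' @param config list: `cohort` (cohort_config), `out_dir`, `stages`
#'   (character subset, default all), `n_expression_pcs` (default 5),
#'   `cis_window` (default 1e6)
#' @return invisible list of written paths plus in-memory results
#' @export
run_pipeline <- function(config) {
  known <- c("de", "deu", "eqtl", "eqtl_specific", "sqtl", "ase", "gwa_enrich")
  stages <- config$stages %||% known
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  extra <- setdiff(names(config),
                   c("cohort", "out_dir", "stages", "n_expression_pcs",
                     "cis_window"))
  if (length(extra)) stop("unknown config key(s): ", paste(extra, collapse = ", "))
  stopifnot(inherits(config$cohort, "cohort_config"))
  out_dir <- config$out_dir %||% stop("config$out_dir is required")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- config$cohort$seed
  npc <- config$n_expression_pcs %||% 5L
  win <- config$cis_window %||% 1e6

  cohort <- simulate_cohort(config$cohort)
  results <- list()
  paths <- character()

  scaled <- scale_counts_quantile(cohort$gene_counts + 1)
  logexpr <- log2(scaled + 1)
  covars <- cohort$samples[, c("sex", "age", "rin", "center")]
  group <- cohort$samples$group

  emit <- function(df, stage) {
    p <- file.path(out_dir, paste0(stage, ".tsv"))
    write_result_tsv(df, p, seed, stage)
    paths[[stage]] <<- p
  }

  if ("de" %in% stages) {
    adj <- suppressWarnings(adjust_covariates(logexpr, covars))
    de <- wmw_differential_expression(adj, group)
    results$de <- de
    emit(de, "de")
  }
  if ("deu" %in% stages) {
    deu <- suppressWarnings(
      diff_exon_usage(cohort$exon_usage$psi, group, covariates = covars))
    results$deu <- deu
    emit(deu, "deu")
  }
  need_eqtl <- any(c("eqtl", "eqtl_specific", "gwa_enrich") %in% stages)
  if (need_eqtl) {
    lib <- colSums(cohort$gene_counts)
    rp <- rpkm(cohort$gene_counts, cohort$genes$length, lib)
    expressed <- filter_expressed(rp, 0, 0.5, fraction_strict = FALSE)
    qn <- quantile_normalize_samples(rp[expressed, , drop = FALSE])
    rin <- rank_inverse_normal(qn, seed = child_seed(seed, "rin"))
    pcs <- stats::prcomp(t(rin), rank. = npc)$x
    ecov <- suppressWarnings(cbind(covars, as.data.frame(pcs)))
    pairs <- cis_pairs(cohort$genes[cohort$genes$gene %in% expressed, ],
                       cohort$snps, window = win)
    eq <- suppressWarnings(cis_eqtl_scan(rin, cohort$genotypes, ecov, pairs))
    results$eqtl <- eq
    if ("eqtl" %in% stages) emit(eq, "eqtl")
  }
  if ("eqtl_specific" %in% stages) {
    adj <- suppressWarnings(adjust_covariates(logexpr, covars))
    top <- results$eqtl[order(results$eqtl$p), ][
      seq_len(min(20L, nrow(results$eqtl))), ]
    sp <- do.call(rbind, lapply(seq_len(nrow(top)), function(i) {
      f <- specific_eqtl_test(adj[top$gene[i], ],
                              cohort$genotypes[top$snp[i], ], group)
      data.frame(gene = top$gene[i], snp = top$snp[i], p = f$p.value,
                 armitage_p = f$armitage_p, call = f$call,
                 stringsAsFactors = FALSE)
    }))
    sp$fdr <- p.adjust(sp$p, "BH")
    results$eqtl_specific <- sp
    emit(sp, "eqtl_specific")
  }
  if ("sqtl" %in% stages) {
    eu <- cohort$exon_usage
    lg <- log2(eu$total + 1)
    qx <- quantile_normalize_exons_within_sample(lg)
    genes_multi <- names(which(table(eu$parts$gene) >= 2L))
    rows <- list()
    for (g in genes_multi) {
      pid <- eu$parts$exon_id[eu$parts$gene == g]
      gm <- cohort$genes[cohort$genes$gene == g, ]
      local_snps <- cis_pairs(gm, cohort$snps, window = win)$snp
      for (tp in pid) for (sk in head(local_snps, 3L)) {
        fit <- tryCatch(sqtl_interaction_test(qx[pid, , drop = FALSE], tp,
                                              cohort$genotypes[sk, ]),
                        error = function(e) NULL)
        if (is.null(fit)) next
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, exon = tp, snp = sk, statistic = fit$statistic,
          p = fit$p.value, stringsAsFactors = FALSE)
      }
    }
    sq <- do.call(rbind, rows)
    sq$fdr <- p.adjust(sq$p, "BH")
    results$sqtl <- sq
    emit(sq, "sqtl")
  }
  if ("ase" %in% stages) {
    flt <- filter_ase_sites(cohort$allele_counts)
    sc <- ase_scan(flt, seed = child_seed(seed, "ase_scan"))
    results$ase <- sc
    emit(sc, "ase")
  }
  if ("gwa_enrich" %in% stages) {
    # synthetic LD pairs linking consecutive SNPs near the same gene
    sids <- cohort$snps$snp
    host <- rep(seq_len(config$cohort$n_genes), length.out = length(sids))
    lp <- do.call(rbind, lapply(split(sids, host), function(s) {
      if (length(s) < 2L) return(NULL)
      data.frame(snp_a = s[-length(s)], snp_b = s[-1L], r2 = 0.9,
                 stringsAsFactors = FALSE)
    }))
    blocks <- build_ld_blocks(sids, lp)
    marked <- unique(results$eqtl$snp[results$eqtl$significant])
    if (length(marked) == 0L) {
      marked <- unique(results$eqtl$snp[order(results$eqtl$p)][1:5])
    }
    marked_blocks <- unique(blocks$membership[marked])
    gwa <- simulate_gwa_summary(blocks, marked_blocks, effect = 1.5,
                                seed = child_seed(seed, "gwa"))
    bt <- block_enrichment_test(blocks, marked, gwa)
    en <- data.frame(p = bt$p.value, n_marked = bt$n_marked,
                     n_unmarked = bt$n_unmarked)
    results$gwa_enrich <- en
    emit(en, "gwa_enrich")
  }
  invisible(list(paths = paths, results = results, cohort = cohort))
}
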
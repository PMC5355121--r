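#' Cis-eQTL scan over a genomic window
#'
#' Expression of one gene is regressed on additive variant-allele
#' dosage (0/1/2) SNP by SNP across a window (for NUDT15:
#' chr13:48,582,000-48,622,000, hg19, 1-based). Rare variants -- those
#' with fewer than `min_carriers` individuals carrying at least one
#' variant allele -- are removed before the scan. Missing dosages drop
#' the sample for that SNP only. Indels are treated like SNPs: any
#' non-reference allele counts toward the dosage.
#'
#' A genotype panel is a list with `samples` (character vector), `snps`
#' (tibble: `snp_id`, `chrom`, `pos`) and `dosage` (samples x snps
#' numeric matrix of 0/1/2/NA).
#'
#' @name eqtl
NULL

#' Assemble a genotype panel
#'
#' @param dosage Samples-by-variants numeric matrix (0/1/2/NA) with
#'   sample ids as rownames and variant ids as colnames.
#' @param snps Tibble with `snp_id`, `chrom`, `pos` (1-based bp)
#'   matching the dosage columns; positions may be `NA` when unknown.
#' @return A `genotype_panel` list.
#' @export
genotype_panel <- function(dosage, snps = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(snps)) {
    snps <- tibble(snp_id = colnames(dosage) %||%
                     paste0("snp", seq_len(ncol(dosage))),
                   chrom = NA_character_, pos = NA_real_)
  }
  if (nrow(snps) != ncol(dosage)) {
    abort("snps table and dosage columns disagree")
  }
  colnames(dosage) <- snps$snp_id
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- paste0("sample", seq_len(nrow(dosage)))
  }
  bad <- dosage[!is.na(dosage)]
  if (any(bad < 0 | bad > 2)) {
    abort("dosages must be 0, 1, 2 or NA")
  }
  structure(list(samples = rownames(dosage), snps = as_tibble(snps),
                 dosage = dosage),
            class = "genotype_panel")
}

#' Read a delimited dosage matrix
#'
#' Samples x variants TSV: first column sample ids, remaining columns
#' one variant each with cells 0/1/2 or empty.
#'
#' @param path TSV path.
#' @param snps Optional `snp_id`/`chrom`/`pos` table.
#' @return A `genotype_panel`.
#' @export
read_dosage_matrix <- function(path, snps = NULL) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_double(),
    sample_id = readr::col_character()), na = c("", "NA"),
    progress = FALSE)
  m <- as.matrix(tab[, -1])
  rownames(m) <- tab$sample_id
  genotype_panel(m, snps)
}

#' Read genotype dosages from a VCF
#'
#' Derives additive dosage from the GT field (count of non-reference
#' alleles, any ALT); needs the VariantAnnotation package.
#'
#' @param path VCF path (plain or bgzipped).
#' @return A `genotype_panel`.
#' @export
read_dosage_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    abort("read_dosage_vcf needs the VariantAnnotation package")
  }
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  count_alt <- function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
    alleles <- strsplit(g, "[/|]")[[1]]
    sum(alleles != "0" & alleles != ".")
  }
  dosage <- t(apply(gt, c(1, 2), count_alt))
  rr <- SummarizedExperiment::rowRanges(vcf)
  snps <- tibble(snp_id = rownames(gt),
                 chrom = as.character(GenomicRanges::seqnames(rr)),
                 pos = GenomicRanges::start(rr))
  genotype_panel(dosage, snps)
}

#' Read an expression vector
#'
#' Two-column delimited file: `sample_id`, `value`.
#'
#' @param path TSV path.
#' @return A named numeric vector.
#' @export
read_expression <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    value = readr::col_double()), progress = FALSE)
  setNames(tab$value, tab$sample_id)
}

#' Carrier filter for rare variants
#'
#' Retains variants carried (dosage >= 1) by at least `min_carriers`
#' individuals; missing dosages do not count as carriers.
#'
#' @param panel A `genotype_panel`.
#' @param min_carriers Minimum carrier count (default 3, the published
#'   threshold).
#' @return The filtered panel.
#' @export
filter_snps <- function(panel, min_carriers = 3) {
  carriers <- colSums(panel$dosage >= 1, na.rm = TRUE)
  keep <- carriers >= min_carriers
  genotype_panel(panel$dosage[, keep, drop = FALSE],
                 panel$snps[keep, ])
}

#' Additive-dosage regression of expression on one variant
#'
#' Ordinary least squares of expression on dosage with intercept;
#' two-sided t-test on the slope with n-2 df. Samples missing either
#' value are dropped pairwise.
#'
#' @param expression Numeric expression values.
#' @param dosage Numeric dosages (same order/length).
#' @param snp_id Label for the output row.
#' @return A one-row tibble: `snp_id`, `n`, `beta`, `se`, `t`, `p`,
#'   `neg_log10_p`; all-`NA` statistics (with `skipped = TRUE`) when
#'   dosage is constant or fewer than 3 pairs remain.
#' @export
eqtl_regress <- function(expression, dosage, snp_id = "snp") {
  ok <- !is.na(expression) & !is.na(dosage)
  x <- dosage[ok]
  y <- expression[ok]
  n <- length(x)
  if (n < 3 || stats::var(x) == 0) {
    return(tibble(snp_id = snp_id, n = n, beta = NA_real_,
                  se = NA_real_, t = NA_real_, p = NA_real_,
                  neg_log10_p = NA_real_, skipped = TRUE))
  }
  sxx <- sum((x - mean(x))^2)
  beta <- sum((x - mean(x)) * (y - mean(y))) / sxx
  resid <- y - mean(y) - beta * (x - mean(x))
  sigma2 <- sum(resid^2) / (n - 2)
  se <- sqrt(sigma2 / sxx)
  t <- beta / se
  p <- 2 * stats::pt(-abs(t), df = n - 2)
  tibble(snp_id = snp_id, n = n, beta = beta, se = se, t = t, p = p,
         neg_log10_p = -log10(p), skipped = FALSE)
}

#' Scan every variant of a panel against an expression vector
#'
#' Runs [eqtl_regress()] per variant (after aligning samples by id when
#' the expression vector is named) and returns results sorted by
#' ascending p-value, together with a plot-ready regional table.
#'
#' @param panel A `genotype_panel`, already carrier-filtered.
#' @param expression Numeric vector; if named, names are matched to
#'   panel samples (their intersection is used).
#' @param bh Add a Benjamini-Hochberg adjusted p column (`p_bh`).
#' @return A list with `results` (tibble sorted by p) and `regional`
#'   (tibble: chrom, pos, snp_id, p, neg_log10_p in position order).
#' @export
eqtl_scan <- function(panel, expression, bh = FALSE) {
  if (ncol(panel$dosage) == 0) {
    abort("empty panel")
  }
  if (!is.null(names(expression))) {
    common <- intersect(panel$samples, names(expression))
    if (length(common) == 0) {
      abort("no overlapping samples between panel and expression")
    }
    dos <- panel$dosage[common, , drop = FALSE]
    expr <- expression[common]
  } else {
    if (length(expression) != nrow(panel$dosage)) {
      abort("unnamed expression must match panel sample count")
    }
    dos <- panel$dosage
    expr <- expression
  }
  results <- purrr::map_dfr(seq_len(ncol(dos)), function(j) {
    eqtl_regress(expr, dos[, j], panel$snps$snp_id[j])
  })
  if (bh) {
    results$p_bh <- stats::p.adjust(results$p, method = "BH")
  }
  regional <- dplyr::left_join(panel$snps, results,
                               by = "snp_id")[, c("chrom", "pos",
                                                  "snp_id", "p",
                                                  "neg_log10_p")]
  regional <- dplyr::arrange(regional, .data$pos)
  list(results = dplyr::arrange(results, .data$p),
       regional = as_tibble(regional))
}

#' Regional association plot data rendered with ggplot2
#'
#' @param scan Output of [eqtl_scan()].
#' @return A ggplot of -log10(p) against position.
#' @export
plot_region <- function(scan) {
  ggplot2::ggplot(scan$regional,
                  ggplot2::aes(x = .data$pos, y = .data$neg_log10_p)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "position (bp)",
                  y = expression(-log[10](italic(p))))
}
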
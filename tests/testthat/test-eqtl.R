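test_that("regression recovers an exact linear relationship", {
  dosage <- c(0, 1, 2, 0, 1, 2, 0)
  res <- eqtl_regress(2 * dosage + 1, dosage)
  expect_equal(res$beta, 2)
  expect_equal(res$se, 0)
  expect_equal(res$n, 7)
})

test_that("regression equals base R lm and the two-sample t closed form", {
  set.seed(21)
  dosage <- rbinom(40, 2, 0.3)
  expr <- -0.4 * dosage + rnorm(40)
  res <- eqtl_regress(expr, dosage)
  fit <- summary(lm(expr ~ dosage))$coefficients
  expect_equal(res$beta, fit[2, 1])
  expect_equal(res$se, fit[2, 2])
  expect_equal(res$p, fit[2, 4])

  # binary dosage: slope is the difference of group means, t the
  # equal-variance two-sample t
  g <- rbinom(30, 1, 0.5)
  y <- 0.8 * g + rnorm(30)
  res2 <- eqtl_regress(y, g)
  expect_equal(res2$beta, mean(y[g == 1]) - mean(y[g == 0]))
  tt <- t.test(y[g == 1], y[g == 0], var.equal = TRUE)
  expect_equal(res2$t, unname(tt$statistic))
  expect_equal(res2$p, tt$p.value)
})

test_that("regression is equivariant under expression scaling", {
  set.seed(4)
  dosage <- rbinom(50, 2, 0.25)
  expr <- 0.3 * dosage + rnorm(50)
  a <- eqtl_regress(expr, dosage)
  b <- eqtl_regress(5 * expr, dosage)
  expect_equal(b$beta, 5 * a$beta)
  expect_equal(b$se, 5 * a$se)
  expect_equal(b$t, a$t)
  expect_equal(b$p, a$p)
})

test_that("missing and constant dosages are handled pairwise", {
  expr <- c(1, 2, 3, 4, 5)
  dosage <- c(0, 1, NA, 2, 1)
  res <- eqtl_regress(expr, dosage)
  expect_equal(res$n, 4)
  skipped <- eqtl_regress(expr, rep(1, 5))
  expect_true(skipped$skipped)
})

test_that("carrier filter applies the published threshold inclusively", {
  dosage <- cbind(two = c(1, 1, 0, 0, 0, 0),
                  three = c(1, 1, 1, 0, 0, 0),
                  mono = c(0, 0, 0, 0, 0, 0),
                  miss = c(1, 1, NA, 0, 0, 0))
  panel <- genotype_panel(dosage)
  kept <- filter_snps(panel, min_carriers = 3)
  expect_equal(kept$snps$snp_id, "three")
})

test_that("scan orders by p without losing or duplicating variants", {
  sim <- simulate_eqtl_panel(n_samples = 80, n_snps = 12, seed = 5)
  sc <- eqtl_scan(sim$panel, sim$expression)
  expect_setequal(sc$results$snp_id, sim$panel$snps$snp_id)
  expect_equal(sc$results$p, sort(sc$results$p))
  expect_equal(sc$regional$pos, sort(sc$regional$pos))
  expect_equal(sc$results$neg_log10_p, -log10(sc$results$p))

  # single-variant panel reduces to the single regression
  one <- genotype_panel(sim$panel$dosage[, 1, drop = FALSE],
                        sim$panel$snps[1, ])
  sc1 <- eqtl_scan(one, sim$expression)
  direct <- eqtl_regress(sim$expression, sim$panel$dosage[, 1],
                         sim$panel$snps$snp_id[1])
  expect_equal(sc1$results$beta, direct$beta)
  expect_s3_class(plot_region(sc), "ggplot")
})

test_that("a planted effect at the published panel size is recovered", {
  sim <- simulate_eqtl_panel(n_samples = 447, n_snps = 20,
                             causal_beta = -0.5, seed = 77)
  res <- eqtl_scan(sim$panel, sim$expression)$results
  causal <- res[res$snp_id == "causal", ]
  expect_lt(abs(causal$beta - (-0.5)), 2 * causal$se)

  # the causal variant tops the scan in at least 90% of replicates
  top <- vapply(1:100, function(r) {
    s <- simulate_eqtl_panel(n_samples = 447, n_snps = 20,
                             causal_beta = -0.5, seed = 300 + r)
    eqtl_scan(s$panel, s$expression)$results$snp_id[1] == "causal"
  }, logical(1))
  expect_gte(mean(top), 0.9)
})

test_that("null scans produce uniform minimum p-values", {
  m <- 40
  min_p <- vapply(1:200, function(r) {
    s <- simulate_eqtl_panel(n_samples = 60, n_snps = m,
                             causal_beta = 0, seed = 40000 + r)
    min(eqtl_scan(s$panel, s$expression)$results$p)
  }, numeric(1))
  # minimum of m independent uniforms is Beta(1, m); dosage columns are
  # independent so the comparison is exact up to t-vs-normal tails
  ks <- suppressWarnings(stats::ks.test(min_p, function(q) stats::pbeta(q, 1, m)))
  expect_gt(ks$p.value, 0.01)
})

test_that("delimited matrix and expression readers round-trip a panel", {
  sim <- simulate_eqtl_panel(n_samples = 10, n_snps = 4, seed = 9)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  tab <- tibble::as_tibble(sim$panel$dosage)
  tab <- dplyr::bind_cols(tibble::tibble(sample_id = sim$panel$samples),
                          tab)
  readr::write_tsv(tab, tmp)
  panel <- read_dosage_matrix(tmp, sim$panel$snps)
  expect_equal(panel$dosage, sim$panel$dosage)

  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(sample_id = names(sim$expression),
                                  value = unname(sim$expression)), tmp2)
  expect_equal(read_expression(tmp2), sim$expression)
})

test_that("VCF genotypes convert to additive dosages", {
  skip_if_not_installed("VariantAnnotation")
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=13>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", "s1", "s2", "s3"), collapse = "\t"),
    paste(c("13", "48582100", "rs1", "C", "T", ".", ".", ".", "GT",
            "0/1", "1/1", "0/0"), collapse = "\t"),
    paste(c("13", "48582200", "ins1", "A", "AGV", ".", ".", ".", "GT",
            "0|1", "0/0", "./."), collapse = "\t"))
  tmp <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, tmp)
  panel <- read_dosage_vcf(tmp)
  expect_equal(unname(panel$dosage[, "rs1"]), c(1, 2, 0))
  expect_equal(unname(panel$dosage[, "ins1"]), c(1, 0, NA))
  expect_equal(panel$snps$pos, c(48582100, 48582200))
})
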
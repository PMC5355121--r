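#' Seeded generators for simulated inputs
#'
#' Every stage of the pipeline can be exercised without external data:
#' case-control cohorts with a known allele-level odds ratio,
#' dose cohorts with a known carrier dose reduction, and
#' genotype-expression panels with one planted causal variant. All
#' generators are pure functions of their arguments including `seed`
#' (Mersenne-Twister, via `set.seed`), so outputs are reproducible
#' across platforms; the caller's RNG state is left untouched.
#'
#' @name synthetic_data
NULL

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed, kind = "Mersenne-Twister")
  code
}

#' Simulate case-control genotype cohorts
#'
#' Controls draw genotypes from Hardy-Weinberg proportions at the
#' control variant-allele frequency `maf`. Each study's log OR is drawn
#' from Normal(log(true_or), tau^2); the case allele frequency is the
#' control frequency tilted by that study OR on the odds scale
#' (p_case = maf OR / (1 - maf + maf OR)), and case genotypes are drawn
#' from Hardy-Weinberg at the tilted frequency -- so `true_or` is the
#' allele-level odds ratio the pooling step should recover.
#'
#' @param k Number of studies.
#' @param n_case,n_control Per-study arm sizes, recycled to length `k`.
#'   Defaults mirror the scale of the published myelotoxicity cohorts.
#' @param maf Control variant-allele frequency (published East Asian
#'   frequency is about 0.1).
#' @param true_or Allele-level odds ratio (the pooled estimate of the
#'   source analysis is about 8).
#' @param tau Between-study SD of the log OR (0 = homogeneous).
#' @param seed Integer seed.
#' @return A study-set tibble with both arms and a myelotoxicity
#'   endpoint.
#' @examples
#' simulate_meta_cohorts(k = 3, seed = 1)
#' @export
simulate_meta_cohorts <- function(k = 7, n_case = 100, n_control = 200,
                                  maf = 0.1, true_or = 8, tau = 0,
                                  seed = 1) {
  stopifnot(maf > 0, maf < 1, true_or > 0, tau >= 0, k >= 1)
  n_case <- rep_len(n_case, k)
  n_control <- rep_len(n_control, k)
  if (any(2 * pmin(n_case, n_control) * maf < 1)) {
    warn("expected variant-allele counts below 1 at requested sizes")
  }
  with_seed(seed, {
    rows <- purrr::map_dfr(seq_len(k), function(i) {
      lor <- stats::rnorm(1, log(true_or), tau)
      p_ctrl <- maf
      p_case <- p_ctrl * exp(lor) / (1 - p_ctrl + p_ctrl * exp(lor))
      draw <- function(n, p) {
        g <- stats::rbinom(n, 2, p)
        c(tt = sum(g == 2), ct = sum(g == 1), cc = sum(g == 0))
      }
      gc <- draw(n_case[i], p_case)
      g0 <- draw(n_control[i], p_ctrl)
      tibble(study_id = sprintf("sim-%02d", i),
             author = "simulated", year = 2026L,
             ethnicity = "simulated", disease = "IBD",
             endpoints = "myelotoxicity",
             tt_case = gc[["tt"]], ct_case = gc[["ct"]],
             cc_case = gc[["cc"]],
             tt_ctrl = g0[["tt"]], ct_ctrl = g0[["ct"]],
             cc_ctrl = g0[["cc"]])
    })
    for (col in setdiff(.all_cols, names(rows))) rows[[col]] <- NA_real_
    new_study_set(rows[, .all_cols],
                  provenance = sprintf("simulated (seed %d)", seed))
  })
}

#' Simulate dose cohorts with a known carrier dose reduction
#'
#' Per cohort, CC patients receive Gaussian doses around a nominal mean
#' and carriers around (1 - true_reduction) times it; raw samples are
#' summarized to mean +/- SD, and the normalized columns are filled by
#' [normalize_doses()] downstream of the raw summaries (the generator
#' leaves them to the pipeline).
#'
#' @param k Number of cohorts.
#' @param true_reduction Fractional carrier dose reduction in [0, 1);
#'   the source analysis reports about 0.28.
#' @param n_carrier,n_cc Group sizes, recycled.
#' @param nominal_dose CC mean daily dose, mg/m2 (60 is a typical ALL
#'   maintenance scale).
#' @param cv Coefficient of variation of individual doses (0.3,
#'   matching the spread of the published summaries).
#' @param seed Integer seed.
#' @return A study-set tibble of dose cohorts (raw dose summaries
#'   filled, normalized columns `NA`).
#' @examples
#' simulate_dose_studies(k = 3, seed = 1)
#' @export
simulate_dose_studies <- function(k = 13, true_reduction = 0.28,
                                  n_carrier = 20, n_cc = 100,
                                  nominal_dose = 60, cv = 0.3,
                                  seed = 1) {
  stopifnot(true_reduction >= 0, true_reduction < 1,
            all(n_carrier >= 2), all(n_cc >= 2))
  n_carrier <- rep_len(n_carrier, k)
  n_cc <- rep_len(n_cc, k)
  with_seed(seed, {
    rows <- purrr::map_dfr(seq_len(k), function(i) {
      cc <- stats::rnorm(n_cc[i], nominal_dose, cv * nominal_dose)
      car <- stats::rnorm(n_carrier[i],
                          (1 - true_reduction) * nominal_dose,
                          cv * nominal_dose)
      tibble(study_id = sprintf("sim-dose-%02d", i),
             author = "simulated", year = 2026L,
             ethnicity = "simulated", disease = "ALL",
             endpoints = "dose",
             dose_tcar_n = n_carrier[i], dose_tcar_mean = mean(car),
             dose_tcar_sd = stats::sd(car),
             dose_cc_n = n_cc[i], dose_cc_mean = mean(cc),
             dose_cc_sd = stats::sd(cc))
    })
    for (col in setdiff(.all_cols, names(rows))) rows[[col]] <- NA_real_
    rows <- rows[, .all_cols]
    rows <- normalize_doses(structure(as_tibble(rows),
                                      class = c("study_set",
                                                class(tibble()))))
    new_study_set(rows, provenance = sprintf("simulated (seed %d)", seed))
  })
}

#' Simulate a genotype-expression panel
#'
#' Genotypes per variant come from Hardy-Weinberg proportions at
#' frequencies drawn uniformly from `maf_range`; expression is
#' causal_beta times the causal variant's dosage plus Gaussian noise.
#'
#' @param n_samples Panel size (447 matches the published regression).
#' @param n_snps Number of variants in the window.
#' @param maf_range Variant-allele frequency range.
#' @param causal_beta Slope of the planted causal variant (0 for a null
#'   panel); the first variant is causal.
#' @param noise_sd Residual SD of expression.
#' @param seed Integer seed.
#' @return A list with `panel` (a `genotype_panel` spanning the NUDT15
#'   window coordinates) and `expression` (named numeric vector).
#' @examples
#' sim <- simulate_eqtl_panel(n_samples = 50, n_snps = 5, seed = 1)
#' @export
simulate_eqtl_panel <- function(n_samples = 447, n_snps = 100,
                                maf_range = c(0.05, 0.5),
                                causal_beta = -0.5, noise_sd = 1,
                                seed = 1) {
  stopifnot(n_samples >= 3, noise_sd > 0, n_snps >= 1)
  with_seed(seed, {
    mafs <- stats::runif(n_snps, maf_range[1], maf_range[2])
    dosage <- vapply(mafs, function(p) stats::rbinom(n_samples, 2, p),
                     numeric(n_samples))
    rownames(dosage) <- sprintf("s%03d", seq_len(n_samples))
    snps <- tibble(
      snp_id = c("causal", sprintf("null%03d", seq_len(n_snps - 1)))[
        seq_len(n_snps)],
      chrom = "13",
      pos = round(seq(48582000, 48622000, length.out = n_snps)))
    expr <- causal_beta * dosage[, 1] +
      stats::rnorm(n_samples, 0, noise_sd)
    list(panel = genotype_panel(dosage, snps),
         expression = setNames(expr, rownames(dosage)))
  })
}
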
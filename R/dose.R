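#' Dose conversion, normalization and carrier-group combination
#'
#' Published maintenance doses mix drugs (azathioprine and
#' 6-mercaptopurine) and units. The pipeline converts 6-MP doses to
#' azathioprine equivalents with a fixed multiplier (2.08), converts
#' per-kg doses to mg/m2 body-surface area with the Meeh-Rubner
#' allometric formula when needed, and then normalizes each study's
#' per-genotype mean +/- SD against that study's CC (homozygous
#' reference) group so studies with very different absolute dosing
#' remain comparable. The normalization makes the conversion factor
#' cancel within a study. Heterozygote and homozygous-variant summaries
#' are combined into a single T-carrier summary with the exact
#' pooled-sample formula before the dose meta-analysis.
#'
#' @name dose_normalization
NULL

#' Convert a thiopurine dose to its azathioprine equivalent
#'
#' @param dose Numeric dose (any unit: mg, mg/kg or mg/m2).
#' @param drug `"AZA"` (returned unchanged) or `"6MP"` (multiplied by
#'   `factor`).
#' @param factor 6-MP to AZA multiplier; 2.08 by convention.
#' @return Dose in the same unit, azathioprine-equivalent.
#' @examples
#' to_aza_equivalent(50, "6MP")
#' @export
to_aza_equivalent <- function(dose, drug = c("AZA", "6MP"), factor = 2.08) {
  drug <- match.arg(drug)
  stopifnot(all(dose >= 0), factor > 0)
  if (drug == "AZA") dose else dose * factor
}

#' Body surface area by the Meeh-Rubner formula
#'
#' A = k * W^(2/3) / 1e4 with W in grams and A in m2. The constant k is
#' not fixed by physiology alone; 10.1 is the customary human value.
#'
#' @param weight_kg Body weight in kilograms, > 0.
#' @param k Meeh-Rubner constant.
#' @return Body surface area in m2.
#' @examples
#' meeh_rubner_bsa(70)
#' @export
meeh_rubner_bsa <- function(weight_kg, k = 10.1) {
  stopifnot(k > 0)
  if (any(weight_kg <= 0)) {
    abort("weight must be positive")
  }
  k * (1000 * weight_kg)^(2 / 3) / 1e4
}

#' Normalize per-genotype dose summaries against the CC reference
#'
#' For every genotype group g of a study, norm_mean = mean_g / mean_CC
#' and norm_sd = sd_g / mean_CC, so the CC group has normalized mean
#' exactly 1. Operates on a study-set tibble and fills the
#' `dose_*_norm_mean` / `dose_*_norm_sd` columns from the raw
#' `dose_*_mean` / `dose_*_sd` columns; rows without a raw CC mean are
#' left untouched.
#'
#' @param studies A study-set tibble with raw dose columns.
#' @return The study set with normalized dose columns recomputed.
#' @examples
#' normalize_doses(table1_fixture())
#' @export
normalize_doses <- function(studies) {
  validate_studies(studies)
  ref <- studies$dose_cc_mean
  ok <- !is.na(ref) & ref > 0
  for (g in .dose_groups) {
    m <- paste0("dose_", g, "_mean")
    s <- paste0("dose_", g, "_sd")
    studies[[paste0("dose_", g, "_norm_mean")]][ok] <-
      studies[[m]][ok] / ref[ok]
    studies[[paste0("dose_", g, "_norm_sd")]][ok] <-
      studies[[s]][ok] / ref[ok]
  }
  studies
}

#' Combine two group summaries into one
#'
#' Exact pooled-sample combination: given (n1, m1, s1) and (n2, m2, s2)
#' summarizing two disjoint samples, returns the n, mean and SD of their
#' concatenation:
#' combined variance =
#' ((n1-1) s1^2 + (n2-1) s2^2 + n1 n2 (m1-m2)^2 / N) / (N - 1),
#' N = n1 + n2. For a singleton group (n2 = 1) the s2 term vanishes, so
#' the combination is exact even though a single observation has no SD.
#'
#' @param n1,mean1,sd1 First group summary.
#' @param n2,mean2,sd2 Second group summary; `sd2` may be `NA` when
#'   `n2 == 1`.
#' @return A list with `n`, `mean`, `sd`.
#' @examples
#' combine_summaries(10, 5, 1, 10, 5, 1)
#' @export
combine_summaries <- function(n1, mean1, sd1, n2, mean2, sd2) {
  stopifnot(n1 >= 1, n2 >= 1)
  if (is.na(sd1) && n1 > 1) abort("sd1 missing for a group with n1 > 1")
  if (is.na(sd2) && n2 > 1) abort("sd2 missing for a group with n2 > 1")
  s1 <- if (n1 > 1) sd1 else 0
  s2 <- if (n2 > 1) sd2 else 0
  n <- n1 + n2
  m <- (n1 * mean1 + n2 * mean2) / n
  v <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2 +
          n1 * n2 * (mean1 - mean2)^2 / n) / (n - 1)
  list(n = n, mean = m, sd = sqrt(v))
}

#' Per-study T-carrier vs CC dose table
#'
#' Builds the input of the dose meta-analysis: one row per dose cohort
#' with the T-carrier group (CT and TT combined, or the published
#' pre-combined carrier group) and the CC reference group on the
#' normalized scale.
#'
#' TT groups are folded into the carrier summary according to `policy`:
#' \describe{
#'   \item{singleton_exact (default)}{combine whenever the TT SD is
#'     known or n_TT == 1 (exact either way); TT groups with n >= 2 but
#'     no published SD cannot be combined honestly and the carrier group
#'     falls back to CT only.}
#'   \item{drop_sd_less}{combine only when the TT SD is known; any TT
#'     group without an SD is dropped.}
#'   \item{zero_sd}{combine always, treating a missing TT SD as 0.}
#' }
#'
#' @param studies A study-set tibble.
#' @param policy TT-folding policy, see above.
#' @return A tibble with one row per dose cohort: `study_id`, `disease`,
#'   `n_carrier`, `mean_carrier`, `sd_carrier`, `n_cc`, `mean_cc`,
#'   `sd_cc` (normalized scale), and `carrier_source` describing how the
#'   carrier group was formed.
#' @examples
#' carrier_dose_table(table1_fixture())
#' @export
carrier_dose_table <- function(studies,
                               policy = c("singleton_exact",
                                          "drop_sd_less", "zero_sd")) {
  policy <- match.arg(policy)
  validate_studies(studies)
  tab <- filter_endpoint(studies, "dose")
  if (nrow(tab) == 0) {
    abort("no dose cohorts with a CC reference")
  }
  args <- as.list(tab[, c(
    "study_id", "disease",
    "dose_ct_n", "dose_ct_norm_mean", "dose_ct_norm_sd",
    "dose_tt_n", "dose_tt_norm_mean", "dose_tt_norm_sd",
    "dose_tcar_n", "dose_tcar_norm_mean", "dose_tcar_norm_sd",
    "dose_cc_n", "dose_cc_norm_mean", "dose_cc_norm_sd")])
  names(args) <- c("study_id", "disease", "ct_n", "ct_m", "ct_s",
                   "tt_n", "tt_m", "tt_s", "tc_n", "tc_m", "tc_s",
                   "cc_n", "cc_m", "cc_s")
  purrr::pmap_dfr(args,
    function(study_id, disease, ct_n, ct_m, ct_s, tt_n, tt_m, tt_s,
             tc_n, tc_m, tc_s, cc_n, cc_m, cc_s) {
      if (!is.na(tc_m)) {
        car <- list(n = tc_n, mean = tc_m, sd = tc_s)
        src <- "published_carrier"
      } else if (is.na(ct_m)) {
        abort(paste0("dose cohort without CT or carrier summary: ",
                     study_id))
      } else {
        has_tt <- !is.na(tt_m) && !is.na(tt_n)
        fold <- has_tt && switch(policy,
          singleton_exact = !is.na(tt_s) || tt_n == 1,
          drop_sd_less = !is.na(tt_s),
          zero_sd = TRUE)
        if (fold) {
          s2 <- if (is.na(tt_s)) 0 else tt_s
          car <- combine_summaries(ct_n, ct_m, ct_s, tt_n, tt_m,
                                   if (tt_n > 1) s2 else tt_s %|NA|% 0)
          src <- "ct_plus_tt"
        } else {
          car <- list(n = ct_n, mean = ct_m, sd = ct_s)
          src <- "ct_only"
        }
      }
      tibble(study_id = study_id, disease = disease,
             n_carrier = car$n, mean_carrier = car$mean,
             sd_carrier = car$sd,
             n_cc = cc_n, mean_cc = cc_m, sd_cc = cc_s,
             carrier_source = src)
    })
}

`%|NA|%` <- function(a, b) if (is.na(a)) b else a
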
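#' Genetic-model contingency tables and carrier diagnostics
#'
#' The case-control studies are contrasted under the classical
#' single-SNP genetic models. With genotype counts (TT, CT, CC) per arm
#' and T the risk allele:
#' \describe{
#'   \item{allele}{T vs C allele counts; each individual contributes two
#'     alleles, so exposed = 2 TT + CT and unexposed = 2 CC + CT.}
#'   \item{dominant}{carriers (TT+CT) vs CC.}
#'   \item{recessive}{TT vs CT+CC.}
#'   \item{het}{heterozygote contrast CT vs TT+CC -- the comparison
#'     whose pooled OR the source meta-analysis reports for CT.}
#'   \item{ct_vs_cc, tt_vs_cc}{genotype contrasts restricted to the two
#'     named genotypes (individuals with the third genotype dropped).}
#' }
#'
#' @name genetic_models
NULL

#' Genetic models available for contingency construction
#' @export
model_kinds <- c("allele", "dominant", "recessive", "het",
                 "ct_vs_cc", "tt_vs_cc")

model_cells <- function(tt, ct, cc, model) {
  switch(model,
    allele    = c(2 * tt + ct, 2 * cc + ct),
    dominant  = c(tt + ct, cc),
    recessive = c(tt, ct + cc),
    het       = c(ct, tt + cc),
    ct_vs_cc  = c(ct, cc),
    tt_vs_cc  = c(tt, cc))
}

#' Build per-study exposure-by-outcome tables under a genetic model
#'
#' Converts genotype counts of every both-arm study into a 2x2 table
#' (`case_exposed`, `case_unexposed`, `control_exposed`,
#' `control_unexposed`) under the requested model. Tables are raw
#' integer counts; continuity correction is applied downstream by the
#' pooling functions. Studies whose exposed (or unexposed) margin is
#' zero in both arms carry no information about the odds ratio and are
#' flagged `degenerate` rather than dropped, so exclusion is an explicit
#' pooling-time decision.
#'
#' @param studies A study-set tibble; rows lacking either arm are
#'   skipped.
#' @param model One of [model_kinds].
#' @return A tibble with one row per contributing study: `study_id`,
#'   `model`, the four cells, and `degenerate`.
#' @examples
#' build_contrasts(table1_fixture(), "allele")
#' @export
build_contrasts <- function(studies, model = model_kinds) {
  model <- match.arg(model)
  validate_studies(studies)
  both <- stats::complete.cases(studies[, .count_cols])
  tab <- studies[both, ]
  if ("endpoints" %in% names(tab)) {
    tab <- tab[has_endpoint(tab, "myelotoxicity"), ]
  }
  if (nrow(tab) == 0) {
    return(tibble(study_id = character(0), model = character(0),
                  case_exposed = numeric(0), case_unexposed = numeric(0),
                  control_exposed = numeric(0),
                  control_unexposed = numeric(0),
                  degenerate = logical(0)))
  }
  cells <- purrr::pmap_dfr(
    list(tab$tt_case, tab$ct_case, tab$cc_case,
         tab$tt_ctrl, tab$ct_ctrl, tab$cc_ctrl),
    function(tc, cc_, ccc, tt0, ct0, cc0) {
      case <- model_cells(tc, cc_, ccc, model)
      ctrl <- model_cells(tt0, ct0, cc0, model)
      tibble(case_exposed = case[1], case_unexposed = case[2],
             control_exposed = ctrl[1], control_unexposed = ctrl[2])
    })
  out <- dplyr::bind_cols(tibble(study_id = tab$study_id, model = model),
                          cells)
  out$degenerate <-
    (out$case_exposed == 0 & out$control_exposed == 0) |
    (out$case_unexposed == 0 & out$control_unexposed == 0)
  out
}

#' Carrier-based diagnostic summary for myelotoxicity
#'
#' Treats T-carrier status (TT or CT) as a diagnostic test for
#' thiopurine-induced myelotoxicity and aggregates the case-control
#' studies: true positives are carriers among cases, true negatives
#' non-carriers among controls. Sensitivity = TP/(TP+FN), specificity =
#' TN/(TN+FP).
#'
#' @param studies A study-set tibble; only myelotoxicity rows with both
#'   arms contribute.
#' @return A one-row tibble: `tp`, `fn`, `tn`, `fp`, `sensitivity`,
#'   `specificity`.
#' @examples
#' carrier_diagnostics(table1_fixture())
#' @export
carrier_diagnostics <- function(studies) {
  validate_studies(studies)
  tab <- filter_endpoint(studies, "myelotoxicity")
  if (nrow(tab) == 0) {
    abort("no myelotoxicity studies with both arms")
  }
  tp <- sum(tab$tt_case + tab$ct_case)
  fn <- sum(tab$cc_case)
  tn <- sum(tab$cc_ctrl)
  fp <- sum(tab$tt_ctrl + tab$ct_ctrl)
  tibble(tp = tp, fn = fn, tn = tn, fp = fp,
         sensitivity = tp / (tp + fn),
         specificity = tn / (tn + fp))
}

#' Per-genotype adverse-event rates
#'
#' For each genotype, the pooled rate of myelotoxicity among all
#' genotyped patients of the case-control studies: cases with the
#' genotype over cases-plus-controls with the genotype. The CT rate is
#' additionally reported per study (ct_case / (ct_case + ct_ctrl)) with
#' min, max and median across studies; the median of an even number of
#' studies is the mean of the two central order statistics.
#'
#' @param studies A study-set tibble.
#' @return A list with `pooled` (tibble: genotype, events, total, rate;
#'   rate is `NA` where the genotype is absent everywhere) and
#'   `ct_by_study` (tibble: study_id, rate) plus `ct_summary`
#'   (min/max/median).
#' @examples
#' genotype_event_rates(table1_fixture())$pooled
#' @export
genotype_event_rates <- function(studies) {
  validate_studies(studies)
  tab <- filter_endpoint(studies, "myelotoxicity")
  if (nrow(tab) == 0) {
    abort("no myelotoxicity studies with both arms")
  }
  pooled <- purrr::map_dfr(c("tt", "ct", "cc"), function(g) {
    ev <- sum(tab[[paste0(g, "_case")]])
    tot <- ev + sum(tab[[paste0(g, "_ctrl")]])
    tibble(genotype = toupper(g), events = ev, total = tot,
           rate = if (tot > 0) ev / tot else NA_real_)
  })
  ct_by_study <- tibble(
    study_id = tab$study_id,
    rate = ifelse(tab$ct_case + tab$ct_ctrl > 0,
                  tab$ct_case / (tab$ct_case + tab$ct_ctrl), NA_real_))
  rates <- ct_by_study$rate[!is.na(ct_by_study$rate)]
  list(pooled = pooled,
       ct_by_study = ct_by_study,
       ct_summary = tibble(min = min(rates), max = max(rates),
                           median = stats::median(rates)))
}

#' Serialize contrasts for audit
#'
#' @param contrasts Output of [build_contrasts()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_contrasts <- function(contrasts, path) {
  readr::write_tsv(contrasts, path, na = "", progress = FALSE)
  invisible(path)
}
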
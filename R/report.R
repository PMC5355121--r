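#' Report assembly for the two published analyses
#'
#' Each `run_*` function ties the pipeline stages together the way the
#' published meta-analysis proceeds and, when `out_dir` is given,
#' writes human-readable TSVs plus a machine-readable JSON summary
#' (numbers at full precision; rounding is a display concern). All
#' outputs are deterministic functions of the input table.
#'
#' @name cli_report
NULL

write_report <- function(out_dir, name, tsvs, summary) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(tsvs)) {
    readr::write_tsv(tsvs[[nm]],
                     file.path(out_dir, paste0(name, "_", nm, ".tsv")),
                     na = "", progress = FALSE)
  }
  jsonlite::write_json(summary,
                       file.path(out_dir, paste0(name, "_summary.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}

#' Myelotoxicity susceptibility meta-analysis
#'
#' Builds per-study tables under `model`, pools (Mantel-Haenszel for
#' `pooling = "fixed"`, DerSimonian-Laird for `"random"`; `"auto"`
#' applies the I^2/p selection rule), and attaches heterogeneity,
#' Egger/Begg bias tests, leave-one-out results and the forest table.
#'
#' @param studies A study-set tibble (default: the packaged table).
#' @param model One of [model_kinds].
#' @param pooling `"auto"`, `"fixed"` or `"random"`.
#' @param out_dir Optional directory for TSV/JSON report files.
#' @return A list: `pooled` (`meta_pool`), `model_selected`,
#'   `heterogeneity`, `effects`, `forest`, `bias` (tibble of both
#'   tests), `leave_one_out`, `excluded`.
#' @examples
#' run_myelotoxicity(table1_fixture(), "allele")$pooled
#' @export
run_myelotoxicity <- function(studies = table1_fixture(),
                              model = model_kinds,
                              pooling = c("auto", "fixed", "random"),
                              out_dir = NULL) {
  model <- match.arg(model)
  pooling <- match.arg(pooling)
  contrasts <- build_contrasts(studies, model)
  if (sum(!contrasts$degenerate) < 2) {
    abort("need at least 2 usable studies")
  }
  effects <- log_odds_ratio(contrasts)
  het <- heterogeneity(effects)
  chosen <- if (pooling == "auto") select_model(het) else pooling
  pooled <- if (chosen == "fixed") pool_mh(contrasts) else
    pool_dl(effects, "OR")
  bias <- dplyr::bind_rows(tidy(eggers_test(effects)),
                           tidy(beggs_test(effects)))
  loo <- leave_one_out(contrasts, if (chosen == "fixed") "mh" else "dl")
  forest <- tidy(pooled)
  summary <- list(analysis = "myelotoxicity", model = model,
                  model_selected = chosen,
                  or = pooled$estimate, ci_low = pooled$ci_low,
                  ci_high = pooled$ci_high, z = pooled$z, p = pooled$p,
                  k = pooled$k, Q = het$Q, het_p = het$p, I2 = het$I2,
                  tau2 = het$tau2,
                  excluded = effects$study_id[effects$excluded])
  write_report(out_dir, paste0("myelotoxicity_", model),
               list(forest = forest, effects = effects, bias = bias,
                    leave_one_out = loo),
               summary)
  list(pooled = pooled, model_selected = chosen, heterogeneity = het,
       effects = effects, forest = forest, bias = bias,
       leave_one_out = loo,
       excluded = effects$study_id[effects$excluded])
}

#' Thiopurine intolerance-dose meta-analysis
#'
#' Normalized carrier-vs-CC mean differences pooled with
#' DerSimonian-Laird random effects (the published choice, justified by
#' the high between-study heterogeneity); optional disease subgroup.
#'
#' @param studies A study-set tibble.
#' @param policy TT-folding policy, see [carrier_dose_table()].
#' @param disease Optional subgroup (`"IBD"` or `"ALL"`).
#' @param pooling `"random"` (default, as published) or `"fixed"` (IV).
#' @param out_dir Optional directory for report files.
#' @return A list: `pooled`, `heterogeneity`, `dose_table`, `effects`,
#'   `forest`, `excluded`.
#' @examples
#' run_dose(table1_fixture())$pooled
#' @export
run_dose <- function(studies = table1_fixture(),
                     policy = "singleton_exact", disease = NULL,
                     pooling = c("random", "fixed"), out_dir = NULL) {
  pooling <- match.arg(pooling)
  dose_table <- carrier_dose_table(studies, policy)
  if (!is.null(disease)) {
    dose_table <- dose_table[dose_table$disease == disease, ]
  }
  if (nrow(dose_table) < 2) {
    abort("need at least 2 dose cohorts")
  }
  effects <- mean_difference(dose_table)
  het <- heterogeneity(effects)
  pooled <- if (pooling == "random") pool_dl(effects, "MD") else
    pool_iv(effects, "MD")
  forest <- tidy(pooled)
  summary <- list(analysis = "dose", policy = policy,
                  disease = disease %||% "all", pooling = pooling,
                  md = pooled$estimate, ci_low = pooled$ci_low,
                  ci_high = pooled$ci_high, p = pooled$p, k = pooled$k,
                  percent_reduction = 100 * abs(pooled$estimate),
                  Q = het$Q, het_p = het$p, I2 = het$I2,
                  tau2 = het$tau2)
  write_report(out_dir, paste0("dose_", disease %||% "all"),
               list(dose_table = dose_table, effects = effects,
                    forest = forest),
               summary)
  list(pooled = pooled, heterogeneity = het, dose_table = dose_table,
       effects = effects, forest = forest,
       excluded = effects$study_id[effects$excluded])
}

#' Carrier diagnostics and per-genotype event rates
#'
#' @param studies A study-set tibble.
#' @param out_dir Optional directory for report files.
#' @return A list: `diagnostics` (tibble), `rates`
#'   (per-genotype pooled rates), `ct_by_study`, `ct_summary`.
#' @examples
#' run_diagnostics(table1_fixture())$diagnostics
#' @export
run_diagnostics <- function(studies = table1_fixture(),
                            out_dir = NULL) {
  diag <- carrier_diagnostics(studies)
  rates <- genotype_event_rates(studies)
  summary <- list(analysis = "diagnostics",
                  sensitivity = diag$sensitivity,
                  specificity = diag$specificity,
                  tp = diag$tp, fn = diag$fn, tn = diag$tn,
                  fp = diag$fp,
                  ct_rate = rates$pooled$rate[rates$pooled$genotype == "CT"],
                  tt_rate = rates$pooled$rate[rates$pooled$genotype == "TT"],
                  ct_rate_median = rates$ct_summary$median)
  write_report(out_dir, "diagnostics",
               list(diagnostics = diag, rates = rates$pooled,
                    ct_by_study = rates$ct_by_study),
               summary)
  list(diagnostics = diag, rates = rates$pooled,
       ct_by_study = rates$ct_by_study, ct_summary = rates$ct_summary)
}
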
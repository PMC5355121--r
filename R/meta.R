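#' Effect sizes and fixed/random-effects pooling
#'
#' Per-study effects are log odds ratios (from 2x2 tables) or mean
#' differences (normalized dose scale). Pooling methods:
#' \describe{
#'   \item{MH_FIXED}{Mantel-Haenszel fixed-effect odds ratio,
#'     OR = sum(a d / n) / sum(b c / n), with the
#'     Robins-Breslow-Greenland variance for its log; the default for
#'     dichotomous outcomes (and the default of the era's meta-analysis
#'     software).}
#'   \item{IV_FIXED}{inverse-variance fixed effect, weights 1/se^2.}
#'   \item{DL_RANDOM}{DerSimonian-Laird random effects, tau^2 =
#'     max(0, (Q - df) / C) with C = sum(w) - sum(w^2)/sum(w), then
#'     inverse-variance pooling with weights 1/(se^2 + tau^2).}
#' }
#' Heterogeneity is Cochran's Q around the IV fixed estimate, with
#' I^2 = max(0, (Q - (k-1)) / Q) x 100.
#'
#' Zero cells: any 2x2 table containing a zero has 0.5 added to all four
#' cells (per-study Haldane correction, the convention of standard
#' meta-analysis software); tables with a zero exposed (or unexposed)
#' margin in both arms carry no odds-ratio information and are excluded.
#'
#' @name meta_engine
NULL

correct_cells <- function(a, b, c, d) {
  z <- a == 0 | b == 0 | c == 0 | d == 0
  add <- ifelse(z, 0.5, 0)
  list(a = a + add, b = b + add, c = c + add, d = d + add)
}

#' Per-study log odds ratios
#'
#' Computes the log OR and its standard error for each 2x2 table, after
#' the 0.5 continuity correction for tables containing a zero cell.
#' Degenerate tables (zero exposed or zero unexposed in both arms) are
#' returned with `excluded = TRUE` and `NA` effect.
#'
#' @param contrasts Output of [build_contrasts()] (or any tibble with
#'   `study_id` and the four cell columns).
#' @return An effects tibble: `study_id`, `effect` (log OR), `se`,
#'   `excluded`, `reason`.
#' @examples
#' log_odds_ratio(build_contrasts(table1_fixture(), "allele"))
#' @export
log_odds_ratio <- function(contrasts) {
  a <- contrasts$case_exposed
  b <- contrasts$case_unexposed
  c <- contrasts$control_exposed
  d <- contrasts$control_unexposed
  degenerate <- (a == 0 & c == 0) | (b == 0 & d == 0)
  cc <- correct_cells(a, b, c, d)
  eff <- log(cc$a * cc$d / (cc$b * cc$c))
  se <- sqrt(1 / cc$a + 1 / cc$b + 1 / cc$c + 1 / cc$d)
  tibble(study_id = contrasts$study_id,
         effect = ifelse(degenerate, NA_real_, eff),
         se = ifelse(degenerate, NA_real_, se),
         excluded = degenerate,
         reason = ifelse(degenerate, "zero margin in both arms",
                         NA_character_))
}

#' Per-study mean differences from a carrier dose table
#'
#' Effect = carrier normalized mean - CC normalized mean (= carrier mean
#' - 1), SE = sqrt(s1^2/n1 + s2^2/n2). Cohorts lacking an SD or with
#' fewer than 2 patients in either group are flagged excluded.
#'
#' @param dose_table Output of [carrier_dose_table()].
#' @return An effects tibble: `study_id`, `effect`, `se`, `excluded`,
#'   `reason`.
#' @examples
#' mean_difference(carrier_dose_table(table1_fixture()))
#' @export
mean_difference <- function(dose_table) {
  with(dose_table, {
    usable <- !is.na(sd_carrier) & !is.na(sd_cc) &
      !is.na(n_carrier) & !is.na(n_cc) & n_carrier >= 2 & n_cc >= 2
    tibble(study_id = study_id,
           effect = ifelse(usable, mean_carrier - mean_cc, NA_real_),
           se = ifelse(usable,
                       sqrt(sd_carrier^2 / n_carrier + sd_cc^2 / n_cc),
                       NA_real_),
           excluded = !usable,
           reason = ifelse(usable, NA_character_,
                           "missing sd or n < 2"))
  })
}

#' Heterogeneity of a set of effects
#'
#' Cochran's Q around the inverse-variance fixed pooled estimate, its
#' chi-square p-value on k-1 degrees of freedom, I^2 floored at zero,
#' and the DerSimonian-Laird tau^2.
#'
#' @param effects An effects tibble (excluded rows are dropped).
#' @return A one-row tibble: `Q`, `df`, `p`, `I2` (percent), `tau2`.
#' @export
heterogeneity <- function(effects) {
  eff <- effects[!effects$excluded, ]
  k <- nrow(eff)
  if (k < 2) {
    abort("heterogeneity needs at least 2 included studies")
  }
  w <- 1 / eff$se^2
  theta <- sum(w * eff$effect) / sum(w)
  Q <- sum(w * (eff$effect - theta)^2)
  df <- k - 1
  C <- sum(w) - sum(w^2) / sum(w)
  tibble(Q = Q, df = df,
         p = stats::pchisq(Q, df, lower.tail = FALSE),
         I2 = max(0, (Q - df) / Q * 100),
         tau2 = max(0, (Q - df) / C))
}

new_meta_pool <- function(method, scale, estimate, se_log, k, effects,
                          het, weights) {
  z <- estimate / se_log
  structure(list(
    method = method,
    scale = scale,
    estimate = if (scale == "OR") exp(estimate) else estimate,
    ci_low = if (scale == "OR") exp(estimate - 1.96 * se_log) else
      estimate - 1.96 * se_log,
    ci_high = if (scale == "OR") exp(estimate + 1.96 * se_log) else
      estimate + 1.96 * se_log,
    z = z,
    p = 2 * stats::pnorm(-abs(z)),
    k = k,
    het = het,
    effects = effects,
    weights = weights
  ), class = "meta_pool")
}

effects_het <- function(effects) {
  eff <- effects[!effects$excluded, ]
  if (nrow(eff) >= 2) heterogeneity(effects) else
    tibble(Q = NA_real_, df = 0L, p = NA_real_, I2 = NA_real_,
           tau2 = 0)
}

#' Mantel-Haenszel fixed-effect pooled odds ratio
#'
#' Pools 2x2 tables with the MH estimator on continuity-corrected cells
#' and the Robins-Breslow-Greenland variance for the log OR. Degenerate
#' tables (zero margin in both arms) are excluded. Heterogeneity is
#' computed from the per-study log ORs with inverse-variance weights.
#'
#' @param contrasts Output of [build_contrasts()].
#' @return A `meta_pool` object (OR scale); see [tidy.meta_pool()].
#' @examples
#' pool_mh(build_contrasts(table1_fixture(), "allele"))
#' @export
pool_mh <- function(contrasts) {
  effects <- log_odds_ratio(contrasts)
  keep <- !effects$excluded
  if (!any(keep)) {
    abort("all tables are degenerate; nothing to pool")
  }
  tab <- contrasts[keep, ]
  cc <- correct_cells(tab$case_exposed, tab$case_unexposed,
                      tab$control_exposed, tab$control_unexposed)
  n <- cc$a + cc$b + cc$c + cc$d
  R <- cc$a * cc$d / n
  S <- cc$b * cc$c / n
  or <- sum(R) / sum(S)
  # Robins-Breslow-Greenland variance of log(OR_MH)
  P <- (cc$a + cc$d) / n
  Qv <- (cc$b + cc$c) / n
  v <- sum(P * R) / (2 * sum(R)^2) +
    sum(P * S + Qv * R) / (2 * sum(R) * sum(S)) +
    sum(Qv * S) / (2 * sum(S)^2)
  w <- R / sum(R)
  new_meta_pool("MH_FIXED", "OR", log(or), sqrt(v), sum(keep),
                effects, effects_het(effects),
                setNames(w, tab$study_id))
}

#' Inverse-variance fixed-effect pooling
#'
#' @param effects An effects tibble ([log_odds_ratio()] or
#'   [mean_difference()] output).
#' @param scale `"OR"` to exponentiate back to the ratio scale, `"MD"`
#'   for mean differences.
#' @return A `meta_pool` object.
#' @export
pool_iv <- function(effects, scale = c("OR", "MD")) {
  scale <- match.arg(scale)
  eff <- effects[!effects$excluded, ]
  if (nrow(eff) == 0) {
    abort("no included effects to pool")
  }
  w <- 1 / eff$se^2
  theta <- sum(w * eff$effect) / sum(w)
  new_meta_pool("IV_FIXED", scale, theta, 1 / sqrt(sum(w)), nrow(eff),
                effects, effects_het(effects),
                setNames(w / sum(w), eff$study_id))
}

#' DerSimonian-Laird random-effects pooling
#'
#' Moment estimator of the between-study variance tau^2 from Cochran's
#' Q, then inverse-variance pooling with weights 1/(se^2 + tau^2). When
#' Q <= df, tau^2 = 0 and the result coincides with [pool_iv()].
#'
#' @inheritParams pool_iv
#' @return A `meta_pool` object.
#' @examples
#' pool_dl(mean_difference(carrier_dose_table(table1_fixture())), "MD")
#' @export
pool_dl <- function(effects, scale = c("OR", "MD")) {
  scale <- match.arg(scale)
  eff <- effects[!effects$excluded, ]
  if (nrow(eff) == 0) {
    abort("no included effects to pool")
  }
  het <- effects_het(effects)
  tau2 <- het$tau2
  w <- 1 / (eff$se^2 + tau2)
  theta <- sum(w * eff$effect) / sum(w)
  new_meta_pool("DL_RANDOM", scale, theta, 1 / sqrt(sum(w)), nrow(eff),
                effects, het, setNames(w / sum(w), eff$study_id))
}

#' Fixed-vs-random model selection rule
#'
#' Fixed effect when I^2 < 50 percent and the heterogeneity p-value
#' exceeds 0.1; random effects otherwise (boundary cases resolve to
#' random, the conservative choice).
#'
#' @param het A heterogeneity tibble from [heterogeneity()].
#' @return `"fixed"` or `"random"`.
#' @export
select_model <- function(het) {
  if (is.na(het$I2) || is.na(het$p)) return("fixed")
  if (het$I2 < 50 && het$p > 0.1) "fixed" else "random"
}

#' @export
print.meta_pool <- function(x, ...) {
  cat(sprintf("Pooled %s (%s), k = %d\n", x$scale, x$method, x$k))
  cat(sprintf("  estimate %.4f, 95%% CI [%.4f, %.4f], z = %.3f, p = %.3g\n",
              x$estimate, x$ci_low, x$ci_high, x$z, x$p))
  if (!is.na(x$het$Q)) {
    cat(sprintf("  heterogeneity: Q = %.3f (df %d, p = %.3f), I2 = %.1f%%, tau2 = %.4f\n",
                x$het$Q, x$het$df, x$het$p, x$het$I2, x$het$tau2))
  }
  invisible(x)
}

#' Tidy per-study rows of a pooled meta-analysis
#'
#' One row per study with effect, CI and percent weight, plus a final
#' pooled row -- the forest-plot table.
#'
#' @param x A `meta_pool` object.
#' @param ... Unused.
#' @return A tibble with `study_id`, `effect`, `ci_low`, `ci_high`,
#'   `weight_percent`, `pooled`.
#' @method tidy meta_pool
#' @export
tidy.meta_pool <- function(x, ...) {
  eff <- x$effects[!x$effects$excluded, ]
  est <- eff$effect
  lo <- eff$effect - 1.96 * eff$se
  hi <- eff$effect + 1.96 * eff$se
  if (x$scale == "OR") {
    est <- exp(est); lo <- exp(lo); hi <- exp(hi)
  }
  dplyr::bind_rows(
    tibble(study_id = eff$study_id, effect = est, ci_low = lo,
           ci_high = hi,
           weight_percent = 100 * unname(x$weights[eff$study_id]),
           pooled = FALSE),
    tibble(study_id = paste0("pooled (", x$method, ")"),
           effect = x$estimate, ci_low = x$ci_low, ci_high = x$ci_high,
           weight_percent = 100, pooled = TRUE))
}

#' One-row summary of a pooled meta-analysis
#'
#' @param x A `meta_pool` object.
#' @param ... Unused.
#' @return A one-row tibble with estimate, CI, z, p, k and the
#'   heterogeneity statistics.
#' @method glance meta_pool
#' @export
glance.meta_pool <- function(x, ...) {
  het <- x$het
  names(het) <- c("Q", "df", "het_p", "I2", "tau2")
  dplyr::bind_cols(
    tibble(method = x$method, scale = x$scale, estimate = x$estimate,
           ci_low = x$ci_low, ci_high = x$ci_high, z = x$z, p = x$p,
           k = x$k),
    het)
}

#' Forest plot of a pooled meta-analysis
#'
#' @param object A `meta_pool` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot meta_pool
#' @export
autoplot.meta_pool <- function(object, ...) {
  tab <- tidy(object)
  tab$study_id <- factor(tab$study_id, levels = rev(tab$study_id))
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$effect,
                                         y = .data$study_id)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$weight_percent,
                                     shape = .data$pooled),
                        show.legend = FALSE) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 15, `TRUE` = 18)) +
    ggplot2::labs(x = if (object$scale == "OR") "odds ratio" else
      "mean difference", y = NULL)
  if (object$scale == "OR") {
    p <- p + ggplot2::scale_x_log10() +
      ggplot2::geom_vline(xintercept = 1, linetype = "dashed")
  } else {
    p <- p + ggplot2::geom_vline(xintercept = 0, linetype = "dashed")
  }
  p
}
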
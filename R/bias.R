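#' Publication-bias tests and leave-one-out sensitivity analysis
#'
#' Small-study and reporting effects are probed two ways: Egger's
#' regression (the 1997 form: ordinary least squares of the
#' standardized effect theta/se on precision 1/se; the intercept
#' measures funnel asymmetry, tested with t on k-2 df) and the
#' Begg-Mazumdar rank correlation (Kendall tau-b between
#' variance-stabilized deviates from the fixed pooled effect and the
#' study variances, normal approximation with tie correction).
#' Robustness of the pooled effect is probed by re-pooling with each
#' study omitted.
#'
#' @name bias_sensitivity
NULL

new_bias_test <- function(method, statistic, se_or_z, p, k) {
  structure(list(method = method, statistic = statistic,
                 se_or_z = se_or_z, p = p, k = k),
            class = "bias_test")
}

#' Egger's regression test for funnel-plot asymmetry
#'
#' @param effects An effects tibble; at least 3 included studies.
#' @return A `bias_test` object: `statistic` is the regression
#'   intercept, `se_or_z` its standard error, `p` the two-sided t-test
#'   p-value on k-2 df.
#' @examples
#' eggers_test(log_odds_ratio(build_contrasts(table1_fixture(), "allele")))
#' @export
eggers_test <- function(effects) {
  eff <- effects[!effects$excluded, ]
  k <- nrow(eff)
  if (k < 3) {
    abort("Egger's test needs at least 3 included studies")
  }
  y <- eff$effect / eff$se
  x <- 1 / eff$se
  X <- cbind(1, x)
  xtx_inv <- solve(crossprod(X))
  beta <- drop(xtx_inv %*% crossprod(X, y))
  rss <- sum((y - drop(X %*% beta))^2)
  sigma2 <- rss / (k - 2)
  intercept <- unname(beta[1])
  se <- sqrt(sigma2 * xtx_inv[1, 1])
  t <- intercept / se
  new_bias_test("EGGER", intercept, se,
                2 * stats::pt(-abs(t), df = k - 2), k)
}

#' Begg-Mazumdar rank-correlation test
#'
#' Kendall tau-b between the variance-adjusted deviates
#' (theta_i - theta_fixed) / sqrt(v_i - 1/sum(w)) and the variances
#' v_i, with the tie-corrected normal approximation. For k <= 8 an
#' exact permutation p-value is available.
#'
#' @param effects An effects tibble; at least 3 included studies.
#' @param exact Use exact permutation of the (tie-free) Kendall
#'   statistic instead of the normal approximation; only for k <= 8.
#' @return A `bias_test` object: `statistic` is tau-b, `se_or_z` the
#'   normal z, `p` two-sided.
#' @export
beggs_test <- function(effects, exact = FALSE) {
  eff <- effects[!effects$excluded, ]
  k <- nrow(eff)
  if (k < 3) {
    abort("Begg's test needs at least 3 included studies")
  }
  v <- eff$se^2
  w <- 1 / v
  theta <- sum(w * eff$effect) / sum(w)
  vstar <- v - 1 / sum(w)
  dev <- (eff$effect - theta) / sqrt(pmax(vstar, .Machine$double.eps))
  tau <- kendall_tau_b(dev, v)
  if (exact) {
    if (k > 8) abort("exact permutation only for k <= 8")
    p <- kendall_exact_p(dev, v)
    return(new_bias_test("BEGG", tau$tau, NA_real_, p, k))
  }
  z <- tau$S / sqrt(tau$varS)
  new_bias_test("BEGG", tau$tau, z, 2 * stats::pnorm(-abs(z)), k)
}

# Kendall S, its tie-corrected null variance, and tau-b
kendall_tau_b <- function(x, y) {
  n <- length(x)
  pairs <- utils::combn(n, 2)
  dx <- sign(x[pairs[2, ]] - x[pairs[1, ]])
  dy <- sign(y[pairs[2, ]] - y[pairs[1, ]])
  S <- sum(dx * dy)
  tie_term <- function(v) {
    t <- table(v)
    t <- t[t > 1]
    c(sum(t * (t - 1) * (2 * t + 5)), sum(t * (t - 1)),
      sum(t * (t - 1) * (t - 2)))
  }
  tx <- tie_term(x)
  ty <- tie_term(y)
  n0 <- n * (n - 1) / 2
  varS <- (n * (n - 1) * (2 * n + 5) - tx[1] - ty[1]) / 18 +
    tx[2] * ty[2] / (4 * n0) +
    tx[3] * ty[3] / (9 * n * (n - 1) * (n - 2))
  denom <- sqrt((n0 - tx[2] / 2) * (n0 - ty[2] / 2))
  list(S = S, varS = varS, tau = S / denom)
}

kendall_exact_p <- function(x, y) {
  n <- length(x)
  S_obs <- abs(kendall_tau_b(x, y)$S)
  perms <- permutations_of(n)
  S_null <- apply(perms, 1, function(idx) abs(kendall_tau_b(x[idx], y)$S))
  mean(S_null >= S_obs - 1e-12)
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- permutations_of(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' @export
print.bias_test <- function(x, ...) {
  lbl <- if (x$method == "EGGER") "intercept" else "tau-b"
  cat(sprintf("%s test (k = %d): %s = %.4f, p = %.4f\n",
              x$method, x$k, lbl, x$statistic, x$p))
  invisible(x)
}

#' @method tidy bias_test
#' @export
tidy.bias_test <- function(x, ...) {
  tibble(method = x$method, statistic = x$statistic,
         se_or_z = x$se_or_z, p = x$p, k = x$k)
}

#' @method glance bias_test
#' @export
glance.bias_test <- function(x, ...) tidy(x)

#' Leave-one-out sensitivity analysis
#'
#' Re-pools with each study omitted. Accepts either a contrasts tibble
#' (pooled with [pool_mh()]) or an effects tibble (pooled with
#' [pool_iv()] or [pool_dl()]).
#'
#' @param x Contrasts or effects tibble with at least 2 included
#'   studies.
#' @param method `"mh"`, `"iv"` or `"dl"`.
#' @param scale Effect scale for `"iv"`/`"dl"`.
#' @return A tibble with one row per omitted study (`omitted`,
#'   `estimate`, `ci_low`, `ci_high`, `p`, `k`), carrying the stability
#'   range as attributes `range_low`/`range_high`.
#' @examples
#' leave_one_out(build_contrasts(table1_fixture(), "allele"))
#' @export
leave_one_out <- function(x, method = c("mh", "iv", "dl"),
                          scale = c("OR", "MD")) {
  method <- match.arg(method)
  scale <- match.arg(scale)
  ids <- if ("excluded" %in% names(x)) x$study_id[!x$excluded] else
    x$study_id[!x$degenerate]
  if (length(ids) < 2) {
    abort("leave-one-out needs at least 2 included studies")
  }
  out <- purrr::map_dfr(ids, function(id) {
    rest <- x[x$study_id != id, ]
    pooled <- switch(method,
      mh = pool_mh(rest),
      iv = pool_iv(rest, scale),
      dl = pool_dl(rest, scale))
    tibble(omitted = id, estimate = pooled$estimate,
           ci_low = pooled$ci_low, ci_high = pooled$ci_high,
           p = pooled$p, k = pooled$k)
  })
  attr(out, "range_low") <- min(out$estimate)
  attr(out, "range_high") <- max(out$estimate)
  out
}

#' Funnel-plot coordinates
#'
#' Study points (effect, se) plus the pseudo-95-percent-confidence
#' triangle around the pooled estimate, evaluated over the observed SE
#' range down to zero (the apex).
#'
#' @param effects An effects tibble.
#' @param pooled A `meta_pool` object for the centre line.
#' @return A list with `points` (study_id, effect, se) and `guides`
#'   (se, lower, upper) on the pooling scale (log OR for OR pools).
#' @export
funnel_data <- function(effects, pooled) {
  eff <- effects[!effects$excluded, ]
  if (nrow(eff) == 0) {
    abort("no included effects")
  }
  centre <- if (pooled$scale == "OR") log(pooled$estimate) else
    pooled$estimate
  se_grid <- seq(0, max(eff$se), length.out = 50)
  list(points = tibble(study_id = eff$study_id, effect = eff$effect,
                       se = eff$se),
       guides = tibble(se = se_grid,
                       lower = centre - 1.96 * se_grid,
                       upper = centre + 1.96 * se_grid))
}

#' Funnel plot
#'
#' @param effects An effects tibble.
#' @param pooled A `meta_pool` object.
#' @return A ggplot object (SE inverted on the y axis, as usual).
#' @export
plot_funnel <- function(effects, pooled) {
  fd <- funnel_data(effects, pooled)
  guides_long <- tidyr::pivot_longer(fd$guides, c("lower", "upper"),
                                     names_to = "side",
                                     values_to = "effect")
  ggplot2::ggplot(fd$points, ggplot2::aes(x = .data$effect,
                                          y = .data$se)) +
    ggplot2::geom_line(data = guides_long,
                       ggplot2::aes(group = .data$side),
                       linetype = "dotted") +
    ggplot2::geom_point() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = if (pooled$scale == "OR") "log odds ratio" else
      "mean difference", y = "standard error")
}
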
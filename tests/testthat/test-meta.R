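test_that("log odds ratio handles symmetry, zero cells and degeneracy", {
  sym <- log_odds_ratio(make_contrast(10, 10, 10, 10))
  expect_equal(sym$effect, 0)
  expect_equal(sym$se, sqrt(0.4))

  # zero cell: 0.5 added to all four cells of that study
  rec <- log_odds_ratio(make_contrast(14, 332, 0, 632))
  expect_equal(round(exp(rec$effect), 2), 55.17)
  expect_equal(rec$se, sqrt(1 / 14.5 + 1 / 332.5 + 1 / 0.5 + 1 / 632.5))

  # zero exposed in both arms carries no OR information
  dz <- log_odds_ratio(make_contrast(0, 46, 0, 5))
  expect_true(dz$excluded)
  expect_true(is.na(dz$effect))
})

test_that("inverse-variance fixed pooling matches closed forms", {
  # identical effects: pooled equals them, Q = 0
  eff <- make_effects(c(0.5, 0.5, 0.5), c(0.2, 0.2, 0.2))
  pooled <- pool_iv(eff, "MD")
  expect_equal(pooled$estimate, 0.5)
  expect_equal(heterogeneity(eff)$Q, 0)
  expect_equal(heterogeneity(eff)$I2, 0)

  # two equal-precision effects: midpoint, se sqrt(1/2)
  two <- pool_iv(make_effects(c(0, 2), c(1, 1)), "MD")
  expect_equal(two$estimate, 1)
  expect_equal((two$ci_high - two$estimate) / 1.96, sqrt(0.5))

  # convexity: pooled estimate inside the span of study effects
  for (seed in 1:5) {
    set.seed(seed)
    e <- make_effects(rnorm(6), runif(6, 0.1, 1))
    est <- pool_iv(e, "MD")$estimate
    expect_gte(est, min(e$effect))
    expect_lte(est, max(e$effect))
  }

  expect_error(pool_iv(make_effects(1, 1)[0, ]), "no included")
})

test_that("single-study pooling returns that study's estimate", {
  tab <- make_contrast(20, 80, 10, 90)
  single <- pool_mh(tab)
  expect_equal(single$estimate, (20 * 90) / (80 * 10))
  expect_equal(single$estimate, exp(log_odds_ratio(tab)$effect))
})

test_that("DL random effects reduces to fixed when Q <= df", {
  eff <- make_effects(c(0.48, 0.5, 0.52), c(0.3, 0.3, 0.3))
  expect_equal(heterogeneity(eff)$tau2, 0)
  dl <- pool_dl(eff, "MD")
  iv <- pool_iv(eff, "MD")
  expect_equal(dl$estimate, iv$estimate)
  expect_equal(dl$ci_low, iv$ci_low)
})

test_that("I2 floors at zero and approaches 100 for discrepant effects", {
  far <- heterogeneity(make_effects(c(0, 10), c(0.1, 0.1)))
  expect_gt(far$I2, 95)
  near <- heterogeneity(make_effects(c(0.1, 0.11, 0.09),
                                     c(0.5, 0.5, 0.5)))
  expect_equal(near$I2, 0)
  expect_error(heterogeneity(make_effects(1, 1)), "at least 2")
})

test_that("model selection follows the I2/p rule with conservative boundaries", {
  het <- function(I2, p) tibble::tibble(Q = 1, df = 1, p = p, I2 = I2,
                                        tau2 = 0)
  expect_equal(select_model(het(0, 0.68)), "fixed")
  expect_equal(select_model(het(80, 0.01)), "random")
  expect_equal(select_model(het(60, 0.2)), "random")
  expect_equal(select_model(het(30, 0.05)), "random")
})

test_that("mean difference uses the two-group normal SE", {
  tab <- tibble::tibble(study_id = c("a", "b", "c"), disease = "ALL",
                        n_carrier = c(25, 10, 1),
                        mean_carrier = c(0.7, 1, 0.5),
                        sd_carrier = c(0.3, 0.2, NA),
                        n_cc = c(100, 10, 50),
                        mean_cc = c(1, 1, 1),
                        sd_cc = c(0.4, 0.2, 0.3),
                        carrier_source = "ct_only")
  eff <- mean_difference(tab)
  expect_equal(eff$effect[1], -0.3)
  expect_equal(eff$se[1], sqrt(0.3^2 / 25 + 0.4^2 / 100))
  expect_equal(eff$effect[2], 0)
  expect_true(eff$excluded[3])
})

test_that("pooling is invariant to study order and id relabeling", {
  contrasts <- build_contrasts(table1_fixture(), "allele")
  shuffled <- contrasts[sample(nrow(contrasts)), ]
  shuffled$study_id <- paste0("x", seq_len(nrow(shuffled)))
  expect_equal(pool_mh(shuffled)$estimate, pool_mh(contrasts)$estimate)
  eff <- log_odds_ratio(contrasts)
  eff2 <- eff[rev(seq_len(nrow(eff))), ]
  expect_equal(pool_dl(eff2, "OR")$estimate, pool_dl(eff, "OR")$estimate)
})

test_that("inverting exposure columns inverts the pooled OR exactly", {
  contrasts <- build_contrasts(table1_fixture(), "recessive")
  inv <- contrasts
  inv[, c("case_exposed", "case_unexposed")] <-
    contrasts[, c("case_unexposed", "case_exposed")]
  inv[, c("control_exposed", "control_unexposed")] <-
    contrasts[, c("control_unexposed", "control_exposed")]
  expect_equal(pool_mh(inv)$estimate, 1 / pool_mh(contrasts)$estimate,
               tolerance = 1e-12)
})

test_that("MH and IV fixed effects agree closely on the published table", {
  for (model in c("allele", "dominant", "het")) {
    contrasts <- build_contrasts(table1_fixture(), model)
    mh <- pool_mh(contrasts)$estimate
    iv <- pool_iv(log_odds_ratio(contrasts), "OR")$estimate
    expect_lt(abs(mh - iv) / mh, 0.02)
  }
})

test_that("pooling recovers a known odds ratio with honest coverage", {
  # 200 simulated 7-study meta-analyses, fixture-scale arms, true OR 8
  n_case <- c(346, 34, 45, 65, 38, 28, 46)
  n_ctrl <- c(632, 101, 116, 188, 54, 54, 5)
  lors <- covered <- numeric(200)
  for (r in 1:200) {
    sim <- simulate_meta_cohorts(k = 7, n_case = n_case,
                                 n_control = n_ctrl, maf = 0.1,
                                 true_or = 8, tau = 0, seed = 5000 + r)
    pooled <- pool_mh(build_contrasts(sim, "allele"))
    lors[r] <- log(pooled$estimate)
    covered[r] <- pooled$ci_low <= 8 && 8 <= pooled$ci_high
  }
  mc_se <- sd(lors) / sqrt(length(lors))
  expect_lt(abs(mean(lors) - log(8)), 2 * mc_se + 0.02)
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.99)
})

test_that("DL tau2 estimate tracks the simulated between-study variance", {
  tau <- 0.3
  tau2_hat <- numeric(300)
  for (r in 1:300) {
    sim <- simulate_meta_cohorts(k = 10, n_case = 200, n_control = 400,
                                 maf = 0.15, true_or = 4, tau = tau,
                                 seed = 9000 + r)
    eff <- log_odds_ratio(build_contrasts(sim, "allele"))
    tau2_hat[r] <- heterogeneity(eff)$tau2
  }
  mc_se <- sd(tau2_hat) / sqrt(length(tau2_hat))
  expect_lt(abs(mean(tau2_hat) - tau^2), 2 * mc_se + 0.02)
})

test_that("forest table carries per-study rows plus a pooled row", {
  pooled <- pool_mh(build_contrasts(table1_fixture(), "allele"))
  tab <- tidy(pooled)
  expect_equal(nrow(tab), 8)
  expect_equal(sum(tab$pooled), 1)
  expect_equal(sum(tab$weight_percent[!tab$pooled]), 100)
  g <- glance(pooled)
  expect_equal(g$estimate, pooled$estimate)
  expect_s3_class(autoplot(pooled), "ggplot")
})
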
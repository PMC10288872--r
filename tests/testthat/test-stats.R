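test_that("noiseless cohorts are interpolated exactly by every model", {
  spec <- cohort_spec(n_control = 20, n_fas = 15, n_nsfasd = 0, seed = 21,
                      delta = -8)
  co <- simulate_cohort(spec, noise = FALSE)
  truth <- callosum:::cohort_true_coefficients(spec)
  for (l in c(2L, 5L)) {
    f <- fit_cc_model(co, 1, l)
    expect_equal(f$r_squared, 1, tolerance = 1e-10)
    est <- stats::setNames(f$coefficients$estimate, f$coefficients$term)
    expect_equal(est[["DIAG"]], truth$delta[l], tolerance = 1e-8)
    expect_equal(est[["SEX"]], truth$b_sex[l], tolerance = 1e-8)
    expect_equal(est[["AGE"]], truth$b_age[l], tolerance = 1e-8)
    expect_equal(est[["TCxS"]], truth$b_tcxs[l], tolerance = 1e-8)
  }
})

test_that("model machinery reproduces the printed one-tailed p-values", {
  ## printed t/df pairs pin the lower-tail convention for DIAG
  expect_equal(round(one_tailed_p(-2.75, 98), 3), 0.004)
  expect_equal(round(one_tailed_p(-1.72, 98), 3), 0.044)
  ## and a fitted model uses exactly that convention
  co <- simulate_cohort(cohort_spec(n_control = 30, n_fas = 30, n_nsfasd = 0,
                                    seed = 3, delta = -15))
  f <- fit_cc_model(co, 1, "postcentral", affected = "FAS")
  cf <- f$coefficients
  i <- match("DIAG", cf$term)
  expect_equal(cf$p[i], one_tailed_p(cf$t[i], f$df_res))
})

test_that("rank-deficient designs name the collinear column", {
  co <- simulate_cohort(cohort_spec(n_control = 12, n_fas = 12, n_nsfasd = 0,
                                    seed = 4))
  co$age_years <- 10           # constant -> collinear with intercept
  expect_error(fit_cc_model(co, 1, "parietal"), "AGE")
})

test_that("eta-squared equals the explicit sum-of-squares decomposition", {
  ## 8-subject hand-built dataset, brute-force SS arithmetic as the oracle
  co <- simulate_cohort(cohort_spec(n_control = 4, n_fas = 4, n_nsfasd = 0,
                                    seed = 8))
  y <- c(31, 28, 35, 30, 26, 24, 27, 22)
  co$ccps_precentral_mm2 <- y
  f <- fit_cc_model(co, 1, "precentral")
  X <- cbind(1, as.integer(co$group == "FAS"), co$sex, co$age_years,
             co$tcxs_cm2)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  rss_full <- sum((y - X %*% beta)^2)
  ## type-III: SS of dropping DIAG from the full model
  X0 <- X[, -2]
  beta0 <- solve(t(X0) %*% X0, t(X0) %*% y)
  ss_diag <- sum((y - X0 %*% beta0)^2) - rss_full
  ss_total <- sum((y - mean(y))^2)
  expect_equal(eta_squared(f), ss_diag / ss_total, tolerance = 1e-10)
  ## and the t-statistic identity eta^2 = t^2 (1 - R^2) / df_res
  i <- match("DIAG", f$coefficients$term)
  expect_equal(eta_squared(f),
               f$coefficients$t[i]^2 * (1 - f$r_squared) / f$df_res,
               tolerance = 1e-12)
})

test_that("eta-squared is 0 under an orthogonal null and always in [0,1]", {
  co <- simulate_cohort(cohort_spec(n_control = 4, n_fas = 4, n_nsfasd = 0,
                                    seed = 12), noise = FALSE)
  co$sex <- rep(0L, 8); co$age_years <- rep(10, 8)
  co$tcxs_cm2 <- rep(1900, 8)
  co$ccps_parietal_mm2 <- rep(c(50, 60), 4)  # identical across DIAG groups
  ## SEX/AGE/TCxS constant would be collinear; use a direct design instead
  X <- cbind(1, as.integer(co$group == "FAS"))
  y <- co$ccps_parietal_mm2
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(beta[2], 0, tolerance = 1e-12)  # DIAG orthogonal to response
  for (seed in 31:35) {
    cox <- simulate_cohort(cohort_spec(n_control = 15, n_fas = 15,
                                       n_nsfasd = 0, seed = seed))
    f <- fit_cc_model(cox, 1, "occipital")
    expect_gte(eta_squared(f), 0)
    expect_lte(eta_squared(f), 1)
  }
})

test_that("bh_fdr reproduces printed q-values and the step-up oracle", {
  ## model-1 p column: the 0.004 entry adjusts to 0.032, 0.064 to 0.093
  p1 <- c(0.030, 0.211, 0.070, 0.064, 0.044, 0.004, 0.445, 0.016)
  q1 <- bh_fdr(p1)
  expect_equal(round(q1[6], 3), 0.032)
  expect_equal(round(q1[4], 3), 0.093)
  ## identical p-values are their own q
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  ## random vectors against the definitional oracle
  set.seed(5)
  for (rep in 1:50) {
    p <- round(runif(sample(1:6, 1)), 3)
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.2, 1.3)), "\\[0, 1\\]")
})

test_that("bh_fdr is monotone; reapplication can only grow q-values", {
  ## note: BH adjustment is *not* idempotent (p = (0.01, 0.5) gives
  ## q = (0.02, 0.5) and re-adjusting gives (0.04, 0.5), also with
  ## stats::p.adjust); the checkable property is order preservation and
  ## that reapplication never shrinks a q-value
  set.seed(6)
  for (rep in 1:20) {
    p <- runif(8)
    q <- bh_fdr(p)
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # order-preserving
    expect_true(all(bh_fdr(q) >= q - 1e-12))
    expect_true(all(q >= p))
  }
})

test_that("welch_t matches the printed age comparison and hand arithmetic", {
  tt <- welch_t(11.17, 3.72, 37, 13.06, 4.97, 28)
  expect_lt(abs(tt$p - 0.098), 0.002)
  expect_identical(welch_t(5, 1, 10, 5, 1, 10)$statistic, 0)
  expect_equal(welch_t(5, 1, 10, 5, 1, 10)$p, 1)
  ## raw vectors against the textbook formula evaluated independently
  x <- c(3.1, 4.5, 2.2, 5.0, 3.8)
  y <- c(6.0, 4.9, 7.2, 5.5)
  tt2 <- welch_t_raw(x, y)
  v1 <- var(x) / 5; v2 <- var(y) / 4
  t_hand <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df_hand <- (v1 + v2)^2 / (v1^2 / 4 + v2^2 / 3)
  expect_equal(tt2$statistic, t_hand, tolerance = 1e-12)
  expect_equal(tt2$df, df_hand, tolerance = 1e-12)
  expect_equal(tt2$p, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-12)
})

test_that("yates_chi2 matches the printed sex table and direct arithmetic", {
  expect_equal(round(yates_chi2(17, 21, 32, 33)$p, 3), 0.813)
  expect_identical(yates_chi2(10, 20, 1, 2)$statistic, 0)  # ad = bc
  expect_equal(yates_chi2(10, 20, 1, 2)$p, 1)
  set.seed(9)
  for (rep in 1:20) {
    tab <- sample(1:30, 4, replace = TRUE)
    got <- yates_chi2(tab[1], tab[2], tab[3], tab[4])
    n <- sum(tab)
    x2 <- n * max(abs(tab[1] * tab[4] - tab[2] * tab[3]) - n / 2, 0)^2 /
      ((tab[1] + tab[2]) * (tab[3] + tab[4]) *
         (tab[1] + tab[3]) * (tab[2] + tab[4]))
    expect_equal(got$statistic, x2, tolerance = 1e-12)
    expect_equal(got$p, pchisq(x2, 1, lower.tail = FALSE), tolerance = 1e-12)
  }
  expect_error(yates_chi2(0, 0, 3, 4), "margin")
})

test_that("fisher_exact equals exhaustive hypergeometric enumeration", {
  expect_equal(fisher_exact(2, 4, 3, 6)$p, 1)     # proportional rows
  expect_equal(fisher_exact(0, 5, 0, 5)$p, 1)     # degenerate margin
  expect_equal(fisher_exact(3, 7, 9, 1)$p, oracle_fisher(3, 7, 9, 1),
               tolerance = 1e-12)
  set.seed(10)
  for (rep in 1:40) {
    tab <- sample(0:12, 4, replace = TRUE)
    expect_equal(fisher_exact(tab[1], tab[2], tab[3], tab[4])$p,
                 oracle_fisher(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-12)
  }
})

test_that("raw group comparison flags an injected deficit", {
  spec <- cohort_spec(n_control = 40, n_fas = 40, n_nsfasd = 0, seed = 14,
                      delta = c(0, 0, 0, 0, -25, 0, 0))
  co <- simulate_cohort(spec)
  res <- compare_groups_raw(co)
  expect_lt(res$q[res$surface == "postcentral"], 0.05)
  ## identical groups -> p = 1 everywhere
  co2 <- co[co$group == "control", , drop = FALSE]
  co2b <- co2; co2b$group <- "FAS"; co2b$subject_id <- paste0("X", co2$subject_id)
  res2 <- compare_groups_raw(rbind(co2, co2b))
  expect_true(all(res2$p == 1))
  ## single surface: q equals p
  res3 <- compare_groups_raw(co, surfaces = "occipital")
  expect_identical(res3$q, res3$p)
})
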
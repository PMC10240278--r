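test_that("with no mouse variance the fit reduces to ordinary least squares", {
  set.seed(1)
  d <- simulate_zonal_rows(zone_effects = c(0, 0.4, 0.9), mouse_sd = 0)
  fit <- fit_random_intercept(d)
  expect_lt(fit$var_mouse, 0.01 * fit$var_resid)
  ols <- stats::lm(log(median_intensity) ~ factor(zone), data = d)
  expect_equal(unname(fit$fixed_effects), unname(stats::coef(ols)),
    tolerance = 1e-6
  )
})

test_that("fit agrees with lme4 maximum likelihood on a random-effects dataset", {
  set.seed(2)
  d <- simulate_zonal_rows(zone_effects = c(0, 0.3, 0.7), mouse_sd = 0.4)
  fit <- fit_random_intercept(d)
  lmm <- lme4::lmer(log(median_intensity) ~ factor(zone) + (1 | mouse),
    data = d, REML = FALSE
  )
  expect_equal(fit$loglik_ml, as.numeric(stats::logLik(lmm)), tolerance = 1e-4)
  expect_equal(unname(fit$fixed_effects), unname(lme4::fixef(lmm)),
    tolerance = 1e-4
  )
  vc <- as.data.frame(lme4::VarCorr(lmm))
  expect_equal(fit$var_mouse, vc$vcov[vc$grp == "mouse"], tolerance = 1e-3)
  expect_equal(fit$var_resid, vc$vcov[vc$grp == "Residual"], tolerance = 1e-3)
  # null model too
  fit0 <- fit_random_intercept(d, include_zone = FALSE)
  lmm0 <- lme4::lmer(log(median_intensity) ~ 1 + (1 | mouse), data = d, REML = FALSE)
  expect_equal(fit0$loglik_ml, as.numeric(stats::logLik(lmm0)), tolerance = 1e-4)
})

test_that("parameter recovery across simulated lipids is within 15 percent", {
  set.seed(3)
  fits <- lapply(1:200, function(i) {
    d <- simulate_zonal_rows(
      zone_effects = c(0, 0.5, 1),
      mouse_sd = 0.3, resid_sd = 0.16
    )
    fit_random_intercept(d)
  })
  z2 <- mean(vapply(fits, function(f) f$fixed_effects[["Z2-Z1"]], numeric(1)))
  z3 <- mean(vapply(fits, function(f) f$fixed_effects[["Z3-Z1"]], numeric(1)))
  vm <- mean(vapply(fits, function(f) f$var_mouse, numeric(1)))
  vr <- mean(vapply(fits, function(f) f$var_resid, numeric(1)))
  expect_equal(z2, 0.5, tolerance = 0.15)
  expect_equal(z3, 1.0, tolerance = 0.15)
  expect_equal(vm, 0.09, tolerance = 0.15)
  expect_equal(vr, 0.16^2, tolerance = 0.15)
})

test_that("adding a constant on the log scale shifts only the intercept", {
  set.seed(4)
  d <- simulate_zonal_rows(zone_effects = c(0, 0.2, 0.5), mouse_sd = 0.3)
  f1 <- fit_random_intercept(d)
  d2 <- d
  d2$median_intensity <- d2$median_intensity * exp(1.7)
  f2 <- fit_random_intercept(d2)
  expect_equal(f2$fixed_effects[["(Intercept)"]],
    f1$fixed_effects[["(Intercept)"]] + 1.7,
    tolerance = 1e-6
  )
  expect_equal(f2$fixed_effects[-1], f1$fixed_effects[-1], tolerance = 1e-6)
  expect_equal(f2$var_mouse, f1$var_mouse, tolerance = 1e-6)
  expect_equal(f2$var_resid, f1$var_resid, tolerance = 1e-6)
})

test_that("likelihood-ratio test statistics and p values behave", {
  set.seed(5)
  d <- simulate_zonal_rows(zone_effects = c(0, 0, 0))
  full <- fit_random_intercept(d)
  null <- fit_random_intercept(d, include_zone = FALSE)
  out <- lrt_zone(full, null)
  expect_equal(out$df, 2)
  expect_gte(out$chisq, 0)
  # chisq = 0 gives p = 1; the 5.991 quantile gives p = 0.050
  expect_equal(stats::pchisq(0, 2, lower.tail = FALSE), 1)
  expect_equal(stats::pchisq(5.991, 2, lower.tail = FALSE), 0.05, tolerance = 1e-3)
  # scale invariance of the p value
  d7 <- d
  d7$median_intensity <- d7$median_intensity * 7
  out7 <- lrt_zone(
    fit_random_intercept(d7),
    fit_random_intercept(d7, include_zone = FALSE)
  )
  expect_equal(out7$p, out$p, tolerance = 1e-8)
  expect_error(lrt_zone(full, fit_random_intercept(d[1:18, ], include_zone = FALSE)))
})

test_that("BH adjustment matches the hand-computed step-up example", {
  expect_equal(bh_adjust(c(0.005, 0.011, 0.02, 0.04)),
    c(0.02, 0.022, 0.02 * 4 / 3, 0.04),
    tolerance = 1e-12
  )
  expect_equal(bh_adjust(0.73), 0.73)
  expect_error(bh_adjust(c(0.1, 0)), "p > 0")
})

test_that("BH adjustment equals the brute-force step-up on short vectors", {
  set.seed(6)
  for (n in 1:8) {
    for (rep in 1:5) {
      p <- runif(n)^2
      q <- bh_adjust(p)
      expect_equal(q, bh_brute(p), tolerance = 1e-12)
      expect_true(all(q >= p & q <= 1))
    }
  }
})

test_that("percent CV matches its definition and is scale invariant", {
  expect_equal(percent_cv(c(9, 10, 11)), 10)
  expect_equal(percent_cv(c(5, 5, 5)), 0)
  expect_equal(percent_cv(7 * c(9, 10, 11)), percent_cv(c(9, 10, 11)))
  expect_warning(out <- percent_cv(c(-1, 1)), "mean is zero")
  expect_true(is.na(out))
  expect_error(percent_cv(3))
})

test_that("test_zonation reports a coherent table and honours alpha", {
  set.seed(7)
  tabs <- lapply(1:30, function(i) {
    eff <- if (i <= 10) c(0, 0.7, 1.2) else c(0, 0, 0)
    d <- simulate_zonal_rows(zone_effects = eff)
    d$lipid_id <- sprintf("L%02d", i)
    d
  })
  tab <- dplyr::bind_rows(tabs)
  res <- test_zonation(tab)
  expect_s3_class(res, "zonation_test")
  expect_true(all(res$q >= res$p))
  expect_true(all(res$q <= 1))
  expect_true(all(res$lipid_id[res$significant] %in% sprintf("L%02d", 1:10)))
  expect_gte(sum(res$significant), 8)
  res0 <- test_zonation(tab, alpha = 0)
  expect_equal(sum(res0$significant), 0)
})

test_that("zeros are handled by the half-minimum pseudo-count policy", {
  set.seed(8)
  d <- simulate_zonal_rows(zone_effects = c(0, 0, 0))
  d$lipid_id <- "L1"
  d$median_intensity[1] <- 0
  expect_error(fit_random_intercept(d), "pseudo-count")
  expect_message(res <- test_zonation(d), "zero intensit")
  expect_equal(nrow(res), 1)
  expect_true(is.finite(res$p))
})
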
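test_that("memory scores and decline follow their defining formulas", {
  expect_equal(recognition_memory_score(0.8, 0.1), 0.7)
  expect_equal(recognition_memory_score(1, 0), 1)
  expect_equal(recognition_memory_score(0.4, 0.4), 0)
  expect_error(recognition_memory_score(1.2, 0), "0, 1")
  expect_equal(memory_decline(0.5, 0.4), 0.2)
  expect_equal(memory_decline(0.5, 0.5), 0)
  expect_equal(memory_decline(0.5, 0.6), -0.2)
  expect_error(memory_decline(0, 0.2), "baseline")
  # scale invariance
  expect_equal(memory_decline(0.3 * 7, 0.21 * 7), memory_decline(0.3, 0.21))
})

test_that("semi-partial R2 is monotone in F and maps onto [0, 1)", {
  expect_equal(semipartial_r2(0, 1, 50), 0)
  fs_ <- c(0.5, 1, 5, 20, 100, 1e6)
  vals <- semipartial_r2(fs_, 1, 96)
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals >= 0 & vals < 1))
  expect_equal(semipartial_r2(34.97, 1, 179.6), 34.97 / 179.6 / (1 + 34.97 / 179.6))
})

test_that("the mixed model reduces to OLS when subject variance is zero", {
  set.seed(61)
  n <- 60
  dat <- data.frame(subject_id = rep(sprintf("s%02d", 1:n), each = 2),
                    switcher = rep(c("slow", "fast"), n),
                    centiloid = rep(rlnorm(n, log(10), 0.5), each = 2),
                    age = rep(runif(n, 50, 70), each = 2))
  eps <- rnorm(n, 0, 0.1)   # perfectly anti-correlated within subject:
  dat$y <- -0.3 + 0.2 * (dat$switcher == "fast") +
    ifelse(dat$switcher == "slow", eps, -eps)  # subject variance estimates 0
  f_lmm <- suppressWarnings(
    fit_mixed_model(y ~ switcher + centiloid + age + (1 | subject_id), dat))
  f_ols <- stats::lm(y ~ switcher + centiloid + age, dat)
  expect_true(f_lmm$meta$singular_fallback || f_lmm$varcomp[["subject_id"]] < 1e-4)
  expect_equal(unname(f_lmm$coef[names(coef(f_ols))]), unname(coef(f_ols)),
               tolerance = 1e-6)
})

test_that("equal true slopes give a null interaction and matching post-hoc slopes", {
  co <- generate_cohort(cohort_truth(slope_slow = -0.005, slope_fast = -0.005,
                                     seed = 12))
  fit <- fit_primary_model(co$long)
  a <- fit$anova
  expect_gt(a$p[a$effect == "switcher:centiloid"], 0.05)
  ph <- posthoc_slopes(fit)
  expect_lt(abs(ph$slope[1] - ph$slope[2]), 3 * sum(ph$se))
  expect_lt(abs(mean(ph$slope) - (-0.005)), 0.005)
  no_int <- fit_mixed_model(
    mean_cos_phase ~ switcher + centiloid + (1 | subject_id), co$long)
  expect_error(posthoc_slopes(no_int), "interaction")
})

test_that("primary model recovers an injected slow-only association", {
  co <- generate_cohort(cohort_truth(slope_slow = -0.012, seed = 5))
  fit <- fit_primary_model(co$long)
  a <- fit$anova
  expect_lt(a$p[a$effect == "switcher:centiloid"], 0.05)
  ph <- posthoc_slopes(fit)
  expect_lt(ph$p_adj[ph$level == "slow"], 0.05)
  expect_gt(ph$p_adj[ph$level == "fast"], 0.05)
  expect_true(all(a$r2_beta_star >= 0 & a$r2_beta_star < 1))
  expect_error(fit_primary_model(co$long[1:10, ]), "20 subjects")
  expect_error(fit_primary_model(co$long[, -3]), "missing columns")
})

test_that("Cook's distances flag a gross outlier and nothing else", {
  co <- generate_cohort(cohort_truth(n_subjects = 40, n_followup = 40, seed = 9))
  fit <- fit_primary_model(co$long)
  cd <- cooks_check(fit)
  expect_true(all(cd$cooks_d < 1))
  expect_false(any(cd$flag))
  # inject a 10-SD outlier into one subject
  long2 <- co$long
  long2$mean_cos_phase[long2$subject_id == "s001"] <-
    long2$mean_cos_phase[long2$subject_id == "s001"] + 10 * 0.15
  long2$centiloid[long2$subject_id == "s001"] <- 60
  fit2 <- fit_primary_model(long2)
  cd2 <- cooks_check(fit2)
  expect_true(cd2$flag[cd2$subject == "s001"])
  # duplicating a subject's rows leaves its leave-one-out distance tiny
  dup <- rbind(co$long, transform(co$long[co$long$subject_id == "s002", ],
                                  subject_id = "s999"))
  fit3 <- fit_primary_model(dup)
  cd3 <- cooks_check(fit3)
  expect_lt(cd3$cooks_d[cd3$subject == "s999"], 0.15)
})

test_that("paired change test behaves at its boundaries", {
  x <- c(0.5, 0.6, 0.4, 0.7, 0.55)
  same <- paired_change_test(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  shifted <- paired_change_test(x, x - 0.1)
  expect_lt(shifted$p, 1e-10)
  expect_gt(shifted$mean_change, 0)
  expect_error(paired_change_test(x, x[-1]), "paired")
  expect_error(paired_change_test(c(1, 2), c(1, 2)), "3")
})

test_that("decline power at the design effect size matches the oracle", {
  # paired design, d ~ 0.27, n = 66: power of the paired t test
  oracle <- power.t.test(n = 66, delta = 0.27, sd = 1, sig.level = 0.05,
                         type = "paired")$power
  set.seed(44)
  hits <- replicate(400, {
    diffs <- rnorm(66, 0.27, 1)
    paired_change_test(diffs, numeric(66))$p < 0.05
  })
  expect_equal(mean(hits), oracle, tolerance = 0.06)
  expect_equal(oracle, 0.58, tolerance = 0.03)
})
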
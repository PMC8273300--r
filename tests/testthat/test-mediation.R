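test_that("Sobel test matches the closed-form evaluation", {
  s <- sobel_test(alpha = 0.5, alpha_se = 0.1, beta = 0.6,
                  beta_se = 0.2)
  expect_equal(s$se, sqrt(0.6^2 * 0.1^2 + 0.5^2 * 0.2^2),
               tolerance = 1e-12)
  expect_equal(s$se, 0.116619, tolerance = 1e-6)
  expect_equal(abs(0.5 * 0.6) / s$se, 2.572479, tolerance = 1e-6)
  expect_equal(s$p, 0.01009732, tolerance = 1e-6)
  expect_equal(round(s$p, 4), 0.0101)

  # zero product: z = 0, p = 1
  expect_equal(sobel_test(0, 0.1, 0.6, 0.2)$p, 1)

  # p strictly decreasing in |alpha*beta| at fixed SEs
  ps <- vapply(c(0.1, 0.3, 0.5),
               function(a) sobel_test(a, 0.1, 0.6, 0.2)$p, numeric(1))
  expect_true(all(diff(ps) < 0))

  # second-order variant adds the se_a^2 se_b^2 term
  s2 <- sobel_test(0.5, 0.1, 0.6, 0.2, second_order = TRUE)
  expect_equal(s2$se^2 - s$se^2, 0.1^2 * 0.2^2, tolerance = 1e-12)
  expect_error(sobel_test(0.5, 0, 0.6, 0.2), "positive")
})

test_that("joint test is the maximum of the path p-values", {
  expect_equal(joint_test(0.01, 0.03), 0.03)
  expect_equal(joint_test(1, 0.2), 1)
  pa <- runif(20)
  pb <- runif(20)
  pj <- joint_test(pa, pb)
  expect_true(all(pj >= pa & pj >= pb))
  expect_error(joint_test(1.2, 0.5), "p_alpha")
})

test_that("Bonferroni multiplies by |S2| and caps at one", {
  expect_equal(bonferroni_adjust(0.004, 5), 0.02)
  expect_equal(bonferroni_adjust(0.4, 5), 1)
  expect_equal(bonferroni_adjust(0.123, 1), 0.123)
  expect_error(bonferroni_adjust(0.1, 0), "s2_size")
})

test_that("indirect-effect hazard ratio and interval behave", {
  h0 <- indirect_hr(0, 0.1)
  expect_equal(h0$hr, 1)
  expect_equal(log(h0$upper), -log(h0$lower), tolerance = 1e-12)

  # product of the applied-analysis point estimates
  h <- indirect_hr((-0.06) * (-3.21), 0.05)
  expect_equal(h$hr, exp(0.1926), tolerance = 1e-6)
  expect_equal(round(h$hr, 4), 1.2124)

  w1 <- indirect_hr(0.2, 0.10)
  w2 <- indirect_hr(0.2, 0.05)
  expect_lt(w2$upper - w2$lower, w1$upper - w1$lower)
  expect_true(h$lower < h$hr && h$hr < h$upper)
})

test_that("alpha path is recovered by OLS and biased without adjustment", {
  ds <- generate_dataset(sim_config(50000L, 8L, c0 = 17, seed = 71))
  fit <- fit_propensity(ds$exposure, ds$confounders, form = "logit")
  adj <- attach_covariate(ds, "ps", fit = fit)
  a <- fit_alpha(ds, adj, k = 1)
  expect_lt(abs(a$alpha - 0.5), 0.03)
  # omitted confounders push alpha-hat far from truth
  an <- fit_alpha(ds, attach_covariate(ds, "naive"), k = 1)
  expect_gt(abs(an$alpha - 0.5), 3 * an$se)

  dsx <- ds
  dsx$exposure <- rep(0L, length(dsx$exposure))
  expect_error(fit_alpha(dsx, adj, 1), "variation")
})

test_that("beta refit recovers the outcome-path coefficients", {
  ds <- generate_dataset(sim_config(1000L, 8L, c0 = 17, seed = 72))
  adj <- attach_covariate(ds, "ps",
                          fit = fit_propensity(ds$exposure,
                                               ds$confounders,
                                               form = "logit"))
  rb <- refit_beta(ds, adj, S2 = c(1:4, 7:8))
  expect_lt(abs(rb$beta[["M1"]] - 0.6), 3 * rb$beta_se[["M1"]] + 0.05)
  # empty selection: direct-effect-only fit, no mediator records
  rb0 <- refit_beta(ds, adj, S2 = integer(0))
  expect_length(rb0$beta, 0)
  expect_true(is.finite(rb0$gamma))
  # adding a null mediator barely moves the others
  rb2 <- refit_beta(ds, adj, S2 = c(1:4, 7:8, 5))
  expect_lt(abs(rb2$beta[["M1"]] - rb$beta[["M1"]]),
            2 * rb$beta_se[["M1"]])
})

test_that("mediation_tests builds a coherent record table", {
  ds <- small_dataset(n = 300, p = 40, seed = 73)
  adj <- attach_covariate(ds, "ps",
                          fit = fit_propensity(ds$exposure,
                                               ds$confounders))
  rec <- mediation_tests(ds, adj, S2 = c(2, 1, 9))
  expect_equal(rec$mediator, c(1, 2, 9))
  expect_equal(rec$indirect, rec$alpha * rec$beta)
  expect_equal(rec$p_joint_raw, pmax(rec$p_alpha, rec$p_beta))
  expect_true(all(rec$p_sobel >= rec$p_sobel_raw))
  expect_true(all(rec$p_joint <= 1 & rec$p_sobel <= 1))
  expect_equal(rec$p_sobel, pmin(rec$p_sobel_raw * 3, 1))
  expect_true(all(rec$hr > 0 & rec$hr_lower < rec$hr &
                    rec$hr < rec$hr_upper))
  empty <- mediation_tests(ds, adj, S2 = integer(0))
  expect_equal(nrow(empty), 0L)
})

test_that("total effect exceeds the direct effect under the benchmark DGP", {
  ds <- generate_dataset(sim_config(5000L, 8L, c0 = 17, seed = 74))
  adj <- attach_covariate(ds, "ps",
                          fit = fit_propensity(ds$exposure,
                                               ds$confounders,
                                               form = "logit"))
  te <- estimate_total_effect(ds, adj)
  expect_gt(te$log_hr, 0.5)  # mediated paths add to gamma = 0.5
  expect_true(te$lower < te$hr && te$hr < te$upper)
  dsx <- ds
  dsx$exposure <- rep(1L, length(dsx$exposure))
  expect_error(estimate_total_effect(dsx, adj), "variation")
})

test_that("total-effect Wald interval has near-nominal null coverage", {
  cover <- 0L
  for (r in 1:100) {
    ds <- generate_dataset(null_config(n = 200, p = 4, seed = 750 + r))
    te <- estimate_total_effect(ds, attach_covariate(ds, "naive"))
    if (te$lower <= 1 && 1 <= te$upper) cover <- cover + 1L
  }
  expect_gte(cover, 88L)
  expect_lte(cover, 100L)
})
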
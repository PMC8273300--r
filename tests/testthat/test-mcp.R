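test_that("MCP value and derivative match the closed form", {
  v <- mcp_value_deriv(0, lambda = 1, a = 3)
  expect_equal(v$penalty, 0)
  expect_equal(v$deriv, 0)

  v <- mcp_value_deriv(1.5, lambda = 1, a = 3)
  expect_equal(v$penalty, 1.125)
  expect_equal(v$deriv, 0.5)

  # continuity and flatness at the knot |t| = a*lambda
  v <- mcp_value_deriv(3, lambda = 1, a = 3)
  expect_equal(v$penalty, 1.5)          # a*lambda^2/2
  expect_equal(v$deriv, 0)
  v <- mcp_value_deriv(-5, lambda = 1, a = 3)
  expect_equal(v$penalty, 1.5)
  expect_equal(v$deriv, 0)

  # negative side is the mirror image
  v <- mcp_value_deriv(-1.5, lambda = 1, a = 3)
  expect_equal(v$penalty, 1.125)
  expect_equal(v$deriv, -0.5)

  expect_error(mcp_value_deriv(1, lambda = 1, a = 1), "a > 1")
})

test_that("lambda = 0 reproduces the unpenalized Newton fit", {
  ds <- small_dataset(n = 200, p = 5, seed = 61)
  adj <- attach_covariate(ds, "ps",
                          fit = fit_propensity(ds$exposure,
                                               ds$confounders))
  mcp <- fit_mcp_cox(ds, adj, 1:5, lambda = 0)
  d <- cox_design(cbind(ds$exposure, adj, ds$mediators), ds$time,
                  ds$event)
  ref <- fit_cox(d)
  got <- c(mcp$unpenalized[, 1], mcp$beta[, 1])
  expect_lt(max(abs(got - unname(ref$coef))), 1e-5)
})

test_that("the head of the lambda path is the null model", {
  ds <- small_dataset(n = 200, p = 30, seed = 62)
  adj <- attach_covariate(ds, "ps",
                          fit = fit_propensity(ds$exposure,
                                               ds$confounders))
  mcp <- fit_mcp_cox(ds, adj, 1:30, nlambda = 20)
  expect_equal(mcp$df[1], 0)
  expect_true(all(mcp$beta[, 1] == 0))
  # grid is strictly decreasing
  expect_true(all(diff(mcp$lambda) < 0))
  # a lambda beyond lambda_max keeps everything at zero
  big <- fit_mcp_cox(ds, adj, 1:30, lambda = c(10 * mcp$lambda[1],
                                               mcp$lambda[1]))
  expect_length(big$selected, 0)
})

test_that("lambda_max from the score formula is tight", {
  ds <- small_dataset(n = 150, p = 20, seed = 63)
  adj <- attach_covariate(ds, "ps",
                          fit = fit_propensity(ds$exposure,
                                               ds$confounders))
  mcp <- fit_mcp_cox(ds, adj, 1:20, nlambda = 30,
                     bic_patience = Inf)
  # one grid step below lambda_max something must enter
  expect_equal(mcp$df[1], 0)
  expect_gt(max(mcp$df[2:4]), 0)
})

test_that("BIC at the null model is -2*loglik of the unpenalized fit", {
  ds <- small_dataset(n = 150, p = 15, seed = 64)
  adj <- attach_covariate(ds, "ps",
                          fit = fit_propensity(ds$exposure,
                                               ds$confounders))
  mcp <- fit_mcp_cox(ds, adj, 1:15, nlambda = 10)
  d0 <- cox_design(cbind(ds$exposure, adj), ds$time, ds$event)
  f0 <- fit_cox(d0)
  expect_equal(mcp$crit_value[1], -2 * f0$loglik, tolerance = 1e-5)
})

test_that("huge shape parameter approaches the lasso (glmnet oracle)", {
  library(glmnet)
  ds <- small_dataset(n = 250, p = 12, seed = 65)
  X <- ds$mediators
  lam <- 0.08
  mcp <- fit_mcp_cox(ds, matrix(numeric(0), 250, 0),
                     candidates = 1:12, lambda = lam, a = 1e6)
  # glmnet: exposure unpenalized via penalty.factor, same 1/n loss scale
  gl <- glmnet(cbind(ds$exposure, X),
               survival::Surv(ds$time, ds$event), family = "cox",
               lambda = lam * 12 / 13,  # glmnet rescales by nvars/sum(pf)
               penalty.factor = c(0, rep(1, 12)),
               standardize = TRUE, thresh = 1e-12)
  got <- unname(c(mcp$unpenalized[, 1], mcp$beta[, 1]))
  expect_equal(got, as.numeric(coef(gl)), tolerance = 5e-3)
})

test_that("BIC-chosen model drops pure-noise mediators", {
  # beta = 0 truth for every candidate: selection should stay near-empty
  sparse_hits <- 0L
  for (r in 1:10) {
    ds <- generate_dataset(sim_config(
      n_subjects = 300, n_mediators = 40,
      alpha_true = c(rep(0.5, 4), numeric(36)),
      beta_true = numeric(40), seed = 660 + r))
    adj <- attach_covariate(ds, "ps",
                            fit = fit_propensity(ds$exposure,
                                                 ds$confounders))
    mcp <- fit_mcp_cox(ds, adj, 1:40)
    if (length(mcp$selected) <= 2) sparse_hits <- sparse_hits + 1L
  }
  expect_gte(sparse_hits, 9L)
})

test_that("select_lambda handles a single-lambda path and cv runs", {
  ds <- small_dataset(n = 150, p = 10, seed = 67)
  adj <- attach_covariate(ds, "ps",
                          fit = fit_propensity(ds$exposure,
                                               ds$confounders))
  one <- fit_mcp_cox(ds, adj, 1:10, lambda = 0.05)
  expect_equal(one$lambda_index, 1L)
  cv <- fit_mcp_cox(ds, adj, 1:10, nlambda = 8, criterion = "cv",
                    cv_seed = 3)
  expect_true(cv$lambda_sel %in% cv$lambda)
  cv2 <- fit_mcp_cox(ds, adj, 1:10, nlambda = 8, criterion = "cv",
                     cv_seed = 3)
  expect_identical(cv$lambda_index, cv2$lambda_index)
})

test_that("degenerate penalized columns are rejected", {
  ds <- small_dataset(n = 100, p = 8, seed = 68)
  ds$mediators[, 3] <- 2
  adj <- attach_covariate(ds, "naive")
  expect_error(fit_mcp_cox(ds, adj, 1:8), "degenerate")
})
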
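test_that("confounders match their stated distributions at large n", {
  cfg <- sim_config(n_subjects = 10L, n_mediators = 8L)
  set.seed(1)
  Z <- generate_confounders(100000L, cfg)
  expect_equal(dim(Z), c(100000L, 10L))
  # binary block: Pr(Z_m = 1) = 0.3
  expect_true(all(abs(colMeans(Z[, 1:5]) - 0.3) < 0.01))
  # normal block: unit variance, pairwise correlation 0.3
  expect_true(all(abs(apply(Z[, 6:10], 2, sd) - 1) < 0.02))
  expect_lt(abs(cor(Z[, 6], Z[, 7]) - 0.3), 0.02)
  expect_lt(abs(cor(Z[, 8], Z[, 10]) - 0.3), 0.02)
  # minimal dimension
  expect_equal(dim(generate_confounders(1L, cfg)), c(1L, 10L))
  # non-positive-definite correlation rejected
  expect_error(sim_config(10, 8, normal_corr = -0.5), "positive-definite")
})

test_that("exposure follows the no-intercept logistic model", {
  cfg <- sim_config(10L, 8L)
  set.seed(2)
  Z <- generate_confounders(100000L, cfg)
  # theta = 0: every subject has P = 1/2
  X0 <- generate_exposure(Z, rep(0, 10))
  expect_lt(abs(mean(X0) - 0.5), 3 * sqrt(0.25 / 100000))
  # benchmark theta: empirical rate matches mean of 1/(1+exp(-theta'Z))
  X <- generate_exposure(Z, cfg$theta)
  pr <- plogis(drop(Z %*% cfg$theta))
  expect_lt(abs(mean(X) - mean(pr)),
            4 * sqrt(mean(pr * (1 - pr)) / 100000))
  # all-zero confounder row forces P = 0.5, i.e. theta-free
  expect_error(generate_exposure(Z, rep(0, 9)), "length")
})

test_that("mediator model has the stated structure", {
  # alpha = 0, phi = 0: pure N(c_k, 1) noise
  cfg0 <- sim_config(20000L, 5L, alpha_true = numeric(5),
                     beta_true = numeric(5), phi_mediator = numeric(10))
  set.seed(3)
  Z <- generate_confounders(20000L, cfg0)
  X <- generate_exposure(Z, cfg0$theta)
  M <- generate_mediators(X, Z, cfg0)
  v <- apply(M, 2, var)
  expect_true(all(abs(v - 1) < 0.05))
  ck <- attr(M, "c_k")
  expect_true(all(abs(colMeans(M) - ck) < 0.05))

  # OLS on (X, Z) recovers alpha_1 = 0.5 under the benchmark design
  cfg <- sim_config(50000L, 8L)
  set.seed(4)
  Z <- generate_confounders(50000L, cfg)
  X <- generate_exposure(Z, cfg$theta)
  M <- generate_mediators(X, Z, cfg)
  a1 <- coef(lm(M[, 1] ~ X + Z))[["X"]]
  expect_lt(abs(a1 - 0.5), 0.03)
})

test_that("null mediators share the benchmark pairwise correlation", {
  # nulls still load on the common confounder combination phi'Z
  cfg <- sim_config(5000L, 40L)
  set.seed(5)
  Z <- generate_confounders(5000L, cfg)
  X <- generate_exposure(Z, cfg$theta)
  M <- generate_mediators(X, Z, cfg)
  cc <- cor(M[, 9:40])
  med <- median(cc[upper.tri(cc)])
  expect_gt(med, 0.45)
  expect_lt(med, 0.65)
})

test_that("survival times are exponential with the stated hazard", {
  # flat linear predictor: D ~ Exp(0.5), mean 2
  cfg <- sim_config(100000L, 4L, alpha_true = numeric(4),
                    beta_true = numeric(4), phi_outcome = numeric(10),
                    gamma = 0, c0 = 1e9)
  set.seed(6)
  Z <- generate_confounders(100000L, cfg)
  X <- generate_exposure(Z, cfg$theta)
  M <- generate_mediators(X, Z, cfg)
  sv <- generate_survival(X, M, Z, cfg)
  expect_lt(abs(mean(sv$time) - 2), 4 * 2 / sqrt(100000))
  expect_true(all(sv$event == 1))  # c0 huge: nothing censored

  # delta = I(D <= C) by construction
  cfg2 <- sim_config(5000L, 4L, c0 = 2)
  set.seed(7)
  Z <- generate_confounders(5000L, cfg2)
  X <- generate_exposure(Z, cfg2$theta)
  M <- generate_mediators(X, Z, cfg2)
  sv2 <- generate_survival(X, M, Z, cfg2)
  expect_true(all(sv2$event %in% c(0, 1)))
  expect_true(all(sv2$time >= 0))
  expect_error(generate_survival(X, M, Z,
                                 sim_config(5000L, 4L)),
               "c0")
})

test_that("censoring calibration hits 15% and 30% and is monotone", {
  cfg <- sim_config(2000L, 16L)
  set.seed(8)
  c15 <- calibrate_censoring(cfg, target = 0.15)
  set.seed(8)
  c30 <- calibrate_censoring(cfg, target = 0.30)
  # heavier censoring needs a smaller uniform bound
  expect_lt(c30, c15)
  # fresh large sample reproduces the target within +-0.01
  for (tc in c(0.15, 0.30)) {
    cfg2 <- sim_config(20000L, 16L, target_censoring = tc,
                       c0 = if (tc == 0.15) c15 else c30, seed = 99L)
    ds <- generate_dataset(cfg2)
    expect_lt(abs(mean(ds$event == 0) - tc), 0.01)
  }
  expect_error(calibrate_censoring(cfg, target = 1.2), "target")
})

test_that("generate_dataset is deterministic with a correct truth manifest", {
  ds1 <- small_dataset(seed = 11)
  ds2 <- small_dataset(seed = 11)
  expect_identical(ds1, ds2)
  ds3 <- small_dataset(seed = 12)
  expect_false(identical(ds1$mediators, ds3$mediators))

  expect_equal(ds1$truth$true_indices, 1:4)
  expect_equal(ds1$truth$alpha_beta_products, c(0.30, 0.36, 0.25, 0.30))

  # benchmark dimensions
  cfg <- sim_config(300L, 10000L, c0 = 17, seed = 1L)
  ds <- generate_dataset(cfg)
  expect_equal(dim(ds$mediators), c(300L, 10000L))
  expect_equal(dim(ds$confounders), c(300L, 10L))
})

test_that("mediation_dataset validates its invariants", {
  expect_error(mediation_dataset(c(1, -2), c(1, 0), c(0, 1),
                                 matrix(0, 2, 3)), "nonnegative")
  expect_error(mediation_dataset(c(1, 2), c(2, 0), c(0, 1),
                                 matrix(0, 2, 3)), "event")
  expect_error(mediation_dataset(c(1, 2), c(1, 0), c(0, 3),
                                 matrix(0, 2, 3)), "exposure")
  expect_error(mediation_dataset(c(1, 2), c(1, 0), c(0, 1),
                                 matrix(0, 2, 3),
                                 truth = list(true_indices = 5)),
               "range")
})
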
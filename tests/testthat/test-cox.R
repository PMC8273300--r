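test_that("log partial likelihood matches hand-enumerated risk sets", {
  ts <- tiny_surv()
  d <- cox_design(ts$x, ts$time, ts$event)
  # risk sets of sizes 3, 2, 1 at coef 0: -(log 3 + log 2 + log 1)
  expect_equal(log_partial_likelihood(d, 0), -log(6), tolerance = 1e-12)
})

test_that("coef = 0 gives -sum over events of log risk-set size", {
  sc <- small_cox(seed = 2)
  d <- cox_design(sc$x, sc$time, sc$event)
  rs <- vapply(which(sc$event == 1),
               function(i) sum(sc$time >= sc$time[i]), numeric(1))
  expect_equal(log_partial_likelihood(d, numeric(3)), -sum(log(rs)),
               tolerance = 1e-10)
})

test_that("partial likelihood is invariant to location shift of a column", {
  sc <- small_cox(seed = 3)
  cf <- c(0.4, -0.2, 0.7)
  d1 <- cox_design(sc$x, sc$time, sc$event)
  x2 <- sc$x
  x2[, 2] <- x2[, 2] + 100
  d2 <- cox_design(x2, sc$time, sc$event)
  expect_equal(log_partial_likelihood(d1, cf),
               log_partial_likelihood(d2, cf), tolerance = 1e-6)
})

test_that("gradient matches central finite differences", {
  for (seed in 1:3) {
    sc <- small_cox(n = 40, q = 4, seed = seed)
    d <- cox_design(sc$x, sc$time, sc$event)
    set.seed(seed + 100)
    cf <- rnorm(4, sd = 0.3)
    gh <- cox_gradient_hessian(d, cf)
    eps <- 1e-6
    fd <- vapply(1:4, function(j) {
      e <- numeric(4); e[j] <- eps
      (log_partial_likelihood(d, cf + e) -
         log_partial_likelihood(d, cf - e)) / (2 * eps)
    }, numeric(1))
    expect_equal(gh$gradient, fd, tolerance = 1e-5)
  }
})

test_that("Hessian is symmetric negative semi-definite", {
  sc <- small_cox(n = 80, q = 4, seed = 5)
  d <- cox_design(sc$x, sc$time, sc$event)
  gh <- cox_gradient_hessian(d, c(0.2, -0.1, 0.3, 0))
  expect_equal(gh$hessian, t(gh$hessian), tolerance = 1e-10)
  expect_true(all(eigen(gh$hessian, symmetric = TRUE,
                        only.values = TRUE)$values < 1e-8))
})

test_that("no events means a flat likelihood and an error on fitting", {
  sc <- small_cox(seed = 6)
  d0 <- cox_design(sc$x, sc$time, rep(0, length(sc$time)))
  gh <- cox_gradient_hessian(d0, numeric(3))
  expect_equal(gh$gradient, numeric(3))
  expect_error(fit_cox(d0), "no events")
})

test_that("fit_cox agrees with survival::coxph (Breslow ties)", {
  library(survival)
  sc <- small_cox(n = 120, q = 3, seed = 7)
  # introduce ties to exercise the Breslow convention
  tt <- round(sc$time, 1)
  d <- cox_design(sc$x, tt, sc$event)
  ours <- fit_cox(d)
  ref <- coxph(Surv(tt, sc$event) ~ sc$x, ties = "breslow")
  expect_equal(unname(ours$coef), unname(coef(ref)), tolerance = 1e-4)
  expect_equal(unname(ours$se), unname(sqrt(diag(vcov(ref)))),
               tolerance = 1e-4)
  expect_equal(ours$loglik, ref$loglik[2], tolerance = 1e-6)
})

test_that("a binary covariate with true log-HR 0.5 is recovered", {
  set.seed(8)
  n <- 4000
  x <- rbinom(n, 1, 0.5)
  tm <- rexp(n, 0.5 * exp(0.5 * x))
  d <- cox_design(matrix(x), tm, rep(1, n))
  fit <- fit_cox(d)
  expect_lt(abs(fit$coef[1] - 0.5), 0.05)
})

test_that("identifiability guard rejects too many covariates", {
  sc <- small_cox(n = 10, q = 3, seed = 9)
  ev <- c(1, 1, rep(0, 8))
  d <- cox_design(sc$x, sc$time, ev)
  expect_error(fit_cox(d), "more covariates than events")
})

test_that("extreme linear predictors stay finite (log-sum-exp guard)", {
  # per-subject |eta| up to 700 log units, spread 1400 across risk sets
  set.seed(10)
  x <- matrix(seq(-700, 700, length.out = 50))
  d <- cox_design(x, runif(50), rbinom(50, 1, 0.7))
  ll <- log_partial_likelihood(d, 1)
  expect_true(is.finite(ll))
  ll2 <- log_partial_likelihood(d, -1)
  expect_true(is.finite(ll2))
})
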
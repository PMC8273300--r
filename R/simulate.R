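#' Simulation configuration for the benchmarking data-generating process
#'
#' Bundles every parameter of the simulation design used to benchmark the
#' mediation pipeline: ten baseline confounders (five Bernoulli(0.3), five
#' equicorrelated standard normals), a logistic exposure model on the
#' confounders, `n_mediators` correlated continuous mediators of which the
#' first four carry true indirect effects, exponential survival with a
#' log-linear hazard, and uniform censoring calibrated to a target rate.
#'
#' Defaults reproduce the benchmark design: `theta` the confounder-exposure
#' coefficients, `alpha_true` starting (0.5, 0.6, 0.5, 0.6, 0.5, 0.5, 0, 0),
#' `beta_true` starting (0.6, 0.6, 0.5, 0.5, 0, 0, 0.5, 0.5) (zeros
#' elsewhere), so exactly mediators 1-4 satisfy alpha_k * beta_k != 0;
#' `phi_mediator` and `phi_outcome` the confounder effects on mediators and
#' hazard; direct effect `gamma = 0.5`; constant baseline hazard
#' `baseline_hazard = 0.5`.
#'
#' @param n_subjects number of subjects n.
#' @param n_mediators number of candidate mediators p (benchmark 10,000).
#' @param theta length-10 confounder-to-exposure log-odds coefficients
#'   (no intercept in the generating model).
#' @param alpha_true length-p sparse exposure-to-mediator coefficients.
#' @param beta_true length-p sparse mediator-to-log-hazard coefficients.
#' @param phi_mediator length-10 confounder effects shared by every
#'   mediator (override per-mediator via `phi_by_k`).
#' @param phi_by_k optional p x 10 matrix of per-mediator confounder
#'   effects; default `NULL` repeats `phi_mediator` for all k.
#' @param phi_outcome length-10 confounder effects on the log hazard.
#' @param gamma scalar direct effect of exposure on the log hazard.
#' @param baseline_hazard constant baseline hazard lambda0 > 0.
#' @param bern_prob success probability of the binary confounders.
#' @param normal_corr common pairwise correlation of the normal confounders.
#' @param target_censoring desired fraction of censored subjects in [0, 1).
#' @param c0 upper bound of the uniform censoring distribution; `NULL`
#'   (default) means calibrate to `target_censoring` when generating.
#' @param seed integer seed controlling all randomness in
#'   [generate_dataset()].
#' @return an object of class `sim_config` (a validated list).
#' @seealso [generate_dataset()], [calibrate_censoring()]
#' @export
sim_config <- function(n_subjects,
                       n_mediators = 10000L,
                       theta = c(0.2, 0.3, 0.3, 0.5, 0.6,
                                 0.2, 0.3, 0.3, 0.5, 0.6),
                       alpha_true = NULL,
                       beta_true = NULL,
                       phi_mediator = c(0.3, 0, 0.4, 0.2, 0.5,
                                        0, 0.4, 0.2, 0.5, 0.3),
                       phi_by_k = NULL,
                       phi_outcome = c(0, 0.2, 0.2, 0.3, 0.2,
                                       0.3, 0, 0.2, 0.3, 0.2),
                       gamma = 0.5,
                       baseline_hazard = 0.5,
                       bern_prob = 0.3,
                       normal_corr = 0.3,
                       target_censoring = 0.15,
                       c0 = NULL,
                       seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  n_mediators <- as.integer(n_mediators)
  stopifnot(n_subjects >= 1L, n_mediators >= 1L)
  p <- n_mediators
  if (is.null(alpha_true)) {
    alpha_true <- numeric(p)
    alpha_true[seq_len(min(8L, p))] <-
      c(0.5, 0.6, 0.5, 0.6, 0.5, 0.5, 0, 0)[seq_len(min(8L, p))]
  }
  if (is.null(beta_true)) {
    beta_true <- numeric(p)
    beta_true[seq_len(min(8L, p))] <-
      c(0.6, 0.6, 0.5, 0.5, 0, 0, 0.5, 0.5)[seq_len(min(8L, p))]
  }
  if (length(alpha_true) != p || length(beta_true) != p)
    stop("alpha_true and beta_true must have length n_mediators")
  if (length(theta) != 10L || length(phi_mediator) != 10L ||
      length(phi_outcome) != 10L)
    stop("theta, phi_mediator and phi_outcome must have length 10")
  if (!is.null(phi_by_k) &&
      (!is.matrix(phi_by_k) || nrow(phi_by_k) != p || ncol(phi_by_k) != 10L))
    stop("phi_by_k must be a p x 10 matrix")
  if (!(bern_prob > 0 && bern_prob < 1))
    stop("bern_prob must lie in (0, 1)")
  # equicorrelation matrix of dimension 5 is positive definite iff
  # corr in (-1/4, 1)
  if (!(normal_corr > -0.25 && normal_corr < 1))
    stop("normal_corr yields a non-positive-definite covariance")
  if (!(baseline_hazard > 0)) stop("baseline_hazard must be positive")
  if (!(target_censoring >= 0 && target_censoring < 1))
    stop("target_censoring must lie in [0, 1)")
  if (!is.null(c0) && c0 <= 0) stop("c0 must be positive")
  cfg <- list(n_subjects = n_subjects, n_mediators = p, theta = theta,
              alpha_true = alpha_true, beta_true = beta_true,
              phi_mediator = phi_mediator, phi_by_k = phi_by_k,
              phi_outcome = phi_outcome, gamma = gamma,
              baseline_hazard = baseline_hazard, bern_prob = bern_prob,
              normal_corr = normal_corr,
              target_censoring = target_censoring, c0 = c0,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Draw the baseline confounder matrix
#'
#' Columns 1-5 are independent Bernoulli(`bern_prob`); columns 6-10 are
#' multivariate normal with unit variances and common covariance
#' `normal_corr`.
#'
#' @param n number of rows to draw.
#' @param cfg a [sim_config()].
#' @return an n x 10 numeric matrix with columns `Z1`..`Z10`.
#' @export
generate_confounders <- function(n, cfg) {
  stopifnot(n >= 1)
  Zb <- matrix(rbinom(n * 5L, 1L, cfg$bern_prob), nrow = n, ncol = 5L)
  Sigma <- matrix(cfg$normal_corr, 5L, 5L)
  diag(Sigma) <- 1
  R <- chol(Sigma)  # errors if not positive definite
  Zn <- matrix(rnorm(n * 5L), nrow = n, ncol = 5L) %*% R
  Z <- cbind(Zb, Zn)
  colnames(Z) <- paste0("Z", 1:10)
  Z
}

#' Draw the binary exposure from the logistic model on confounders
#'
#' `Pr(X_i = 1) = 1 / (1 + exp(-theta' Z_i))`; the generating model has no
#' intercept (an intercept is always included when *fitting* the
#' propensity model).
#'
#' @param Z confounder matrix (n x m).
#' @param theta length-m coefficient vector.
#' @return integer 0/1 vector of length n.
#' @export
generate_exposure <- function(Z, theta) {
  if (ncol(Z) != length(theta))
    stop("theta length must match the number of confounder columns")
  pr <- plogis(drop(Z %*% theta))
  rbinom(nrow(Z), 1L, pr)
}

#' Draw the mediator matrix
#'
#' `M_ki = c_k + alpha_k X_i + phi_k' Z_i + e_ki` with per-mediator
#' intercepts `c_k ~ U(0,1)` and noise `e_ki ~ N(0,1)`. With the shared
#' default `phi_k`, all mediators load on the same confounder combination,
#' which induces the strong (~0.5) pairwise correlation of the benchmark
#' design.
#'
#' @param X exposure vector (length n).
#' @param Z confounder matrix (n x 10).
#' @param cfg a [sim_config()].
#' @return an n x p matrix with columns `M1`..`Mp`; attribute `"c_k"`
#'   carries the drawn intercepts.
#' @export
generate_mediators <- function(X, Z, cfg) {
  n <- length(X)
  p <- cfg$n_mediators
  stopifnot(nrow(Z) == n)
  ck <- runif(p)
  M <- matrix(rnorm(n * p), nrow = n, ncol = p)
  if (is.null(cfg$phi_by_k)) {
    M <- M + drop(Z %*% cfg$phi_mediator)  # recycled down columns
  } else {
    M <- M + Z %*% t(cfg$phi_by_k)
  }
  nz <- which(cfg$alpha_true != 0)
  if (length(nz))
    M[, nz] <- M[, nz] + outer(X, cfg$alpha_true[nz])
  M <- sweep(M, 2L, ck, "+")
  colnames(M) <- paste0("M", seq_len(p))
  attr(M, "c_k") <- ck
  M
}

# hazard linear predictor gamma*X + beta'M + phi'Z (Z omitted when NULL,
# used by the pilot draws in calibrate_censoring)
hazard_lp <- function(X, M, Z, cfg, beta_idx = NULL) {
  lp <- cfg$gamma * X
  if (is.null(beta_idx)) beta_idx <- which(cfg$beta_true != 0)
  if (length(beta_idx))
    lp <- lp + drop(M %*% cfg$beta_true[beta_idx])
  if (!is.null(Z))
    lp <- lp + drop(Z %*% cfg$phi_outcome)
  lp
}

#' Draw survival and censoring times
#'
#' Death times are exponential with hazard
#' `lambda0 * exp(gamma X + beta'M + phi'Z)`, inverted analytically as
#' `D = -log(U) / rate`; censoring is `C ~ U(0, c0)`. The observed time is
#' `T = min(D, C)` and the event indicator `delta = I(D <= C)`.
#'
#' @param X exposure vector.
#' @param M mediator matrix (n x p).
#' @param Z confounder matrix (n x 10).
#' @param cfg a [sim_config()] whose `c0` is set (see
#'   [calibrate_censoring()]).
#' @return list with numeric `time` and integer `event`.
#' @export
generate_survival <- function(X, M, Z, cfg) {
  n <- length(X)
  if (is.null(cfg$c0)) stop("cfg$c0 is not set; run calibrate_censoring()")
  if (cfg$c0 <= 0) stop("c0 must be positive")
  nz <- which(cfg$beta_true != 0)
  lp <- hazard_lp(X, M[, nz, drop = FALSE], Z, cfg, beta_idx = nz)
  # log-space inversion keeps extreme linear predictors finite
  D <- exp(log(-log(runif(n))) - log(cfg$baseline_hazard) - lp)
  C <- runif(n, 0, cfg$c0)
  list(time = pmin(D, C), event = as.integer(D <= C))
}

#' Calibrate the uniform censoring bound to a target censoring rate
#'
#' Draws a pilot sample of death times from the configured hazard model and
#' root-finds the bound `c0` of `C ~ U(0, c0)`. Conditional on the pilot
#' draws the censoring fraction has the closed form
#' `E[min(D, c0)] / c0`, monotone decreasing in `c0`, so the root is found
#' with [uniroot()] to within `tol`.
#'
#' @param cfg a [sim_config()].
#' @param target desired censoring fraction in (0, 1); defaults to
#'   `cfg$target_censoring`.
#' @param pilot_n pilot sample size (default 100,000; calibration runs
#'   once per study, and the pilot error bounds how closely generated
#'   datasets hit the target rate).
#' @param tol calibration tolerance on the censoring fraction.
#' @return the calibrated scalar `c0`.
#' @export
calibrate_censoring <- function(cfg, target = cfg$target_censoring,
                                pilot_n = 100000L, tol = 0.005) {
  if (!(target > 0 && target < 1)) stop("target must lie in (0, 1)")
  Z <- generate_confounders(pilot_n, cfg)
  X <- generate_exposure(Z, cfg$theta)
  nz <- which(cfg$beta_true != 0)
  # only mediators entering the hazard are needed for the pilot
  ck <- runif(length(nz))
  Mnz <- matrix(rnorm(pilot_n * length(nz)), pilot_n, length(nz))
  if (length(nz)) {
    Mnz <- Mnz + drop(Z %*% cfg$phi_mediator)
    Mnz <- Mnz + outer(X, cfg$alpha_true[nz])
    Mnz <- sweep(Mnz, 2L, ck, "+")
  }
  lp <- hazard_lp(X, Mnz, Z, cfg, beta_idx = nz)
  D <- exp(log(-log(runif(pilot_n))) - log(cfg$baseline_hazard) - lp)
  cens_frac <- function(c0) mean(pmin(D, c0)) / c0
  lo <- min(D) / 2
  hi <- max(D) * 2
  it <- 0L
  while (cens_frac(lo) < target && it < 100L) { lo <- lo / 4; it <- it + 1L }
  while (cens_frac(hi) > target && it < 200L) { hi <- hi * 4; it <- it + 1L }
  if (it >= 200L || cens_frac(lo) < target || cens_frac(hi) > target)
    stop("censoring calibration failed to bracket the target rate")
  c0 <- uniroot(function(c0) cens_frac(c0) - target, c(lo, hi),
                tol = .Machine$double.eps^0.5)$root
  if (abs(cens_frac(c0) - target) > tol)
    stop("censoring calibration did not converge within tolerance")
  c0
}

#' Generate a complete mediation dataset
#'
#' Assembles confounders, exposure, mediators and survival outcome from a
#' [sim_config()], calibrating the censoring bound first when `cfg$c0` is
#' `NULL`. All randomness is governed by `cfg$seed`; the global RNG state
#' is restored on exit, and the same configuration always yields an
#' identical dataset.
#'
#' @param cfg a [sim_config()].
#' @return an object of class `mediation_dataset`: list with `time`,
#'   `event`, `exposure`, `mediators` (n x p), `confounders` (n x 10),
#'   `truth` (true indices, alpha*beta products, seed, c0) and `c0`.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed_(cfg$seed, {
    if (is.null(cfg$c0)) cfg$c0 <- calibrate_censoring(cfg)
    Z <- generate_confounders(cfg$n_subjects, cfg)
    X <- generate_exposure(Z, cfg$theta)
    M <- generate_mediators(X, Z, cfg)
    surv <- generate_survival(X, M, Z, cfg)
    truth_idx <- which(cfg$alpha_true * cfg$beta_true != 0)
    ds <- list(time = surv$time, event = surv$event, exposure = X,
               mediators = M, confounders = Z,
               truth = list(true_indices = truth_idx,
                            alpha_beta_products =
                              (cfg$alpha_true * cfg$beta_true)[truth_idx],
                            seed = cfg$seed, c0 = cfg$c0),
               c0 = cfg$c0)
    class(ds) <- "mediation_dataset"
    ds
  })
}

#' Assemble a mediation dataset from components
#'
#' Validates dimensions and value ranges and returns the container used by
#' the pipeline; `truth` is optional (absent for real data).
#'
#' @param time nonnegative observed times.
#' @param event 0/1 event indicators.
#' @param exposure 0/1 exposure vector.
#' @param mediators n x p mediator matrix.
#' @param confounders n x m confounder matrix (may be `NULL` when no
#'   confounders were measured).
#' @param truth optional list with `true_indices` and
#'   `alpha_beta_products`.
#' @return a `mediation_dataset`.
#' @export
mediation_dataset <- function(time, event, exposure, mediators,
                              confounders = NULL, truth = NULL) {
  n <- length(time)
  mediators <- as.matrix(mediators)
  if (length(event) != n || length(exposure) != n ||
      nrow(mediators) != n ||
      (!is.null(confounders) && nrow(confounders) != n))
    stop("inconsistent dimensions")
  if (any(!is.finite(time)) || any(time < 0))
    stop("time must be finite and nonnegative")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  if (!all(exposure %in% c(0, 1))) stop("exposure must be 0/1")
  if (!is.null(truth)) {
    if (!all(truth$true_indices %in% seq_len(ncol(mediators))))
      stop("truth indices out of mediator range")
  }
  ds <- list(time = as.numeric(time), event = as.integer(event),
             exposure = as.integer(exposure), mediators = mediators,
             confounders = if (is.null(confounders)) NULL
                           else as.matrix(confounders),
             truth = truth, c0 = NULL)
  class(ds) <- "mediation_dataset"
  ds
}

#' @export
print.mediation_dataset <- function(x, ...) {
  cat(sprintf("mediation_dataset: %d subjects, %d mediators, %s confounders\n",
              length(x$time), ncol(x$mediators),
              if (is.null(x$confounders)) "no"
              else ncol(x$confounders)))
  cat(sprintf("  events: %d (%.1f%% censored)\n", sum(x$event),
              100 * mean(x$event == 0)))
  if (!is.null(x$truth))
    cat("  true mediators:",
        paste(x$truth$true_indices, collapse = ", "), "\n")
  invisible(x)
}

# evaluate expr under a temporary seed, restoring the caller's RNG state
with_seed_ <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
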
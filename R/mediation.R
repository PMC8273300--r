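#' Exposure-to-mediator path estimate (alpha) for one mediator
#'
#' Ordinary least squares of `M_k` on intercept, exposure and the
#' adjustment covariate(s); `alpha_hat` is the exposure coefficient.
#'
#' @param dataset a `mediation_dataset`.
#' @param adjustment adjustment covariate matrix (possibly zero columns).
#' @param k mediator column index.
#' @return list with `alpha`, `se`.
#' @export
fit_alpha <- function(dataset, adjustment, k) {
  res <- fit_alpha_many(dataset, adjustment, k)
  list(alpha = res$alpha[[1L]], se = res$se[[1L]])
}

# vectorized OLS of several mediator columns on (1, X, adjustment)
fit_alpha_many <- function(dataset, adjustment, ks) {
  if (length(unique(dataset$exposure)) < 2L)
    stop("exposure has no variation; alpha path is not estimable")
  D <- cbind(1, exposure = dataset$exposure, as.matrix(adjustment))
  n <- nrow(D); q <- ncol(D)
  qrD <- qr(D)
  if (qrD$rank < q) stop("collinear design in the alpha-path regression")
  M <- dataset$mediators[, ks, drop = FALSE]
  cf <- qr.coef(qrD, M)
  res <- qr.resid(qrD, M)
  sigma2 <- colSums(res^2) / (n - q)
  unpiv <- order(qrD$pivot)
  xtxinv <- chol2inv(qr.R(qrD))[unpiv, unpiv]
  list(alpha = unname(cf[2L, ]), se = unname(sqrt(sigma2 * xtxinv[2L, 2L])))
}

#' Refit the outcome model on the selected mediators (beta)
#'
#' One unpenalized Cox fit with columns (exposure, adjustment, selected
#' mediators); per-mediator `beta_hat` and standard errors come from the
#' inverse observed information, alongside the direct effect of exposure.
#'
#' @param dataset a `mediation_dataset`.
#' @param adjustment adjustment covariate matrix.
#' @param S2 selected mediator indices (may be empty).
#' @return list with `beta`, `beta_se` (named by mediator id), `gamma`
#'   (direct-effect estimate), `gamma_se`, and the full `cox_fit`.
#' @export
refit_beta <- function(dataset, adjustment, S2) {
  adjustment <- as.matrix(adjustment)
  Xb <- cbind(exposure = dataset$exposure, adjustment,
              dataset$mediators[, S2, drop = FALSE])
  if (ncol(Xb) + 0L >= sum(dataset$event))
    stop("too few events to refit the selected model")
  fit <- fit_cox(cox_design(Xb, dataset$time, dataset$event))
  qa <- 1L + ncol(adjustment)
  idx <- qa + seq_along(S2)
  list(beta = setNames(fit$coef[idx], colnames(dataset$mediators)[S2]),
       beta_se = setNames(fit$se[idx], colnames(dataset$mediators)[S2]),
       gamma = unname(fit$coef[1L]), gamma_se = unname(fit$se[1L]),
       fit = fit)
}

#' Sobel test of the indirect effect
#'
#' First-order delta-method standard error of the product
#' `alpha_hat * beta_hat`:
#' `se = sqrt(beta^2 se_alpha^2 + alpha^2 se_beta^2)` (set
#' `second_order = TRUE` to add the `se_alpha^2 se_beta^2` term), with a
#' two-sided normal p-value for `H0: alpha_k beta_k = 0`.
#'
#' @param alpha,alpha_se exposure-to-mediator estimate and SE.
#' @param beta,beta_se mediator-to-outcome estimate and SE.
#' @param second_order add the second-order variance term.
#' @return list with `se` and `p`.
#' @export
sobel_test <- function(alpha, alpha_se, beta, beta_se,
                       second_order = FALSE) {
  if (any(alpha_se <= 0) || any(beta_se <= 0))
    stop("standard errors must be positive")
  v <- beta^2 * alpha_se^2 + alpha^2 * beta_se^2
  if (second_order) v <- v + alpha_se^2 * beta_se^2
  se <- sqrt(v)
  z <- abs(alpha * beta) / se
  list(se = se, p = 2 * pnorm(-z))
}

#' Joint significance test of the indirect effect
#'
#' The p-value is the maximum of the two path p-values: mediation is
#' declared only when both `alpha_k` and `beta_k` are individually
#' significant. Conservative under the composite null.
#'
#' @param p_alpha,p_beta two-sided path p-values.
#' @return the joint p-value(s).
#' @export
joint_test <- function(p_alpha, p_beta) {
  stopifnot(all(p_alpha >= 0 & p_alpha <= 1),
            all(p_beta >= 0 & p_beta <= 1))
  pmax(p_alpha, p_beta)
}

#' Bonferroni correction over the selected set
#'
#' `P_k = min(P_raw,k * |S2|, 1)` — the multiplier is the size of the
#' post-selection candidate set, not p or d.
#'
#' @param p_raw raw p-value(s).
#' @param s2_size number of selected mediators, at least 1.
#' @return adjusted p-value(s).
#' @export
bonferroni_adjust <- function(p_raw, s2_size) {
  stopifnot(all(p_raw >= 0 & p_raw <= 1), s2_size >= 1)
  pmin(p_raw * s2_size, 1)
}

#' Hazard ratio and confidence interval for an indirect effect
#'
#' `HR = exp(alpha_hat * beta_hat)` with a Wald interval on the log scale
#' using the Sobel standard error.
#'
#' @param indirect log-hazard indirect effect `alpha_hat * beta_hat`.
#' @param sobel_se its Sobel standard error.
#' @param level confidence level (default 0.95).
#' @return list with `hr`, `lower`, `upper`.
#' @export
indirect_hr <- function(indirect, sobel_se, level = 0.95) {
  zq <- qnorm(1 - (1 - level) / 2)
  list(hr = exp(indirect),
       lower = exp(indirect - zq * sobel_se),
       upper = exp(indirect + zq * sobel_se))
}

#' Total effect of exposure on the hazard
#'
#' Cox fit of the outcome on exposure and the adjustment covariate only
#' (no mediators); reports the exposure hazard ratio with a Wald
#' confidence interval.
#'
#' @param dataset a `mediation_dataset`.
#' @param adjustment adjustment covariate matrix.
#' @param level confidence level.
#' @return list with `log_hr`, `se`, `hr`, `lower`, `upper`.
#' @export
estimate_total_effect <- function(dataset, adjustment, level = 0.95) {
  if (length(unique(dataset$exposure)) < 2L)
    stop("exposure has no variation")
  Xb <- cbind(exposure = dataset$exposure, as.matrix(adjustment))
  fit <- fit_cox(cox_design(Xb, dataset$time, dataset$event))
  est <- unname(fit$coef[1L]); se <- unname(fit$se[1L])
  zq <- qnorm(1 - (1 - level) / 2)
  list(log_hr = est, se = se, hr = exp(est),
       lower = exp(est - zq * se), upper = exp(est + zq * se))
}

#' Per-mediator mediation records for a selected set (Step 3)
#'
#' For each mediator in `S2`: the OLS alpha path, the Cox-refit beta
#' path, the Sobel and joint tests with Bonferroni correction over
#' `|S2|`, and the indirect-effect hazard ratio with its interval.
#'
#' @param dataset a `mediation_dataset`.
#' @param adjustment adjustment covariate matrix.
#' @param S2 selected mediator indices.
#' @param second_order_sobel use the second-order Sobel variance.
#' @return a data.frame with one row per mediator in `S2`, columns
#'   `mediator`, `id`, `alpha`, `alpha_se`, `beta`, `beta_se`,
#'   `indirect`, `sobel_se`, `p_sobel_raw`, `p_alpha`, `p_beta`,
#'   `p_joint_raw`, `p_sobel`, `p_joint`, `hr`, `hr_lower`, `hr_upper`;
#'   plus attributes `gamma` and `gamma_se` (direct effect). Empty `S2`
#'   yields a zero-row frame.
#' @export
mediation_tests <- function(dataset, adjustment, S2,
                            second_order_sobel = FALSE) {
  cols <- c("mediator", "id", "alpha", "alpha_se", "beta", "beta_se",
            "indirect", "sobel_se", "p_sobel_raw", "p_alpha", "p_beta",
            "p_joint_raw", "p_sobel", "p_joint", "hr", "hr_lower",
            "hr_upper")
  if (length(S2) == 0L) {
    out <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)),
                                  cols))
    out$id <- character(0)
    return(out)
  }
  S2 <- sort(S2)
  al <- fit_alpha_many(dataset, adjustment, S2)
  be <- refit_beta(dataset, adjustment, S2)
  sob <- sobel_test(al$alpha, al$se, be$beta, be$beta_se,
                    second_order = second_order_sobel)
  p_alpha <- 2 * pnorm(-abs(al$alpha / al$se))
  p_beta <- 2 * pnorm(-abs(be$beta / be$beta_se))
  p_joint_raw <- joint_test(p_alpha, p_beta)
  s2n <- length(S2)
  ind <- al$alpha * be$beta
  hr <- indirect_hr(ind, sob$se)
  out <- data.frame(
    mediator = S2,
    id = colnames(dataset$mediators)[S2],
    alpha = al$alpha, alpha_se = al$se,
    beta = unname(be$beta), beta_se = unname(be$beta_se),
    indirect = ind, sobel_se = sob$se,
    p_sobel_raw = sob$p, p_alpha = p_alpha, p_beta = unname(p_beta),
    p_joint_raw = unname(p_joint_raw),
    p_sobel = bonferroni_adjust(sob$p, s2n),
    p_joint = bonferroni_adjust(unname(p_joint_raw), s2n),
    hr = hr$hr, hr_lower = hr$lower, hr_upper = hr$upper,
    row.names = NULL)
  attr(out, "gamma") <- be$gamma
  attr(out, "gamma_se") <- be$gamma_se
  out
}
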
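#' Minimax concave penalty value and derivative
#'
#' `P_lambda(t) = lambda |t| - t^2 / (2a)` for `|t| <= a lambda` and the
#' constant `a lambda^2 / 2` beyond; the derivative is
#' `(lambda - |t|/a) sign(t)` inside the knot and 0 beyond. The shape
#' parameter `a > 1` controls how fast the penalty levels off (larger `a`
#' approaches the lasso).
#'
#' @param t coefficient value(s).
#' @param lambda penalty level, `lambda >= 0`.
#' @param a shape parameter, `a > 1` (default 3).
#' @return list with vectors `penalty` and `deriv`.
#' @export
mcp_value_deriv <- function(t, lambda, a = 3) {
  stopifnot(a > 1, lambda >= 0)
  at <- abs(t)
  inside <- at <= a * lambda
  penalty <- ifelse(inside, lambda * at - t^2 / (2 * a), a * lambda^2 / 2)
  deriv <- ifelse(inside, (lambda - at / a) * sign(t), 0)
  list(penalty = penalty, deriv = deriv)
}

#' MCP-penalized Cox selection over screened mediators (Step 2)
#'
#' Maximizes the penalized log partial likelihood
#' `l_n(Q) - sum_k P_lambda(beta_k)` over the screened mediator block,
#' keeping the exposure and adjustment columns unpenalized. The solver is
#' outer iteratively-reweighted least squares on the diagonal-Hessian
#' surrogate with inner cyclic coordinate descent using the MCP
#' firm-thresholding update, warm-started along a descending log-spaced
#' lambda grid from `lambda_max` (the smallest lambda with all penalized
#' coefficients zero) down to `lambda_min_ratio * lambda_max`. Penalized
#' columns are standardized internally; coefficients are reported on the
#' original scale.
#'
#' The selected set `S2` consists of the mediators with nonzero
#' coefficients at the criterion-chosen lambda (see [select_lambda()]).
#'
#' @param dataset a `mediation_dataset`.
#' @param adjustment adjustment covariate matrix (from
#'   [attach_covariate()]).
#' @param candidates mediator indices entering the penalized block
#'   (typically `screening$selected`).
#' @param lambda optional user grid (descending); computed when `NULL`.
#' @param nlambda grid length (default 50).
#' @param lambda_min_ratio smallest grid value as a fraction of
#'   `lambda_max` (default 0.05).
#' @param a MCP shape parameter (default 3).
#' @param criterion lambda-selection criterion, `"bic"` (default,
#'   deterministic) or `"cv"` (K-fold cross-validated partial
#'   likelihood).
#' @param nfolds folds for `criterion = "cv"`.
#' @param cv_seed seed for the fold split.
#' @param tol convergence tolerance (maximum absolute coefficient
#'   change, standardized scale).
#' @param dfmax optional cap on the active-set size; the path stops once
#'   exceeded (`NULL` = no cap).
#' @param bic_patience under BIC selection, stop the path once BIC has
#'   been past its running minimum for this many grid points while the
#'   active set keeps growing (the skipped tail cannot contain the BIC
#'   optimum in practice; raise to `Inf` to disable).
#' @return an object of class `mcp_cox_fit`: `lambda` (grid), `beta`
#'   (p_cand x nlambda matrix, original scale, rownames the mediator
#'   ids), `unpenalized` (coefficients of exposure/adjustment per
#'   lambda), `df`, `loglik`, `criterion`, `crit_value` (per lambda),
#'   `lambda_index` (chosen), `selected` (S2, original mediator
#'   indices), `coef` (penalized coefficients at the chosen lambda),
#'   `nonconvex` flag.
#' @export
fit_mcp_cox <- function(dataset, adjustment, candidates,
                        lambda = NULL, nlambda = 50L,
                        lambda_min_ratio = 0.05, a = 3,
                        criterion = c("bic", "cv"), nfolds = 5L,
                        cv_seed = 1L, tol = 1e-7, dfmax = NULL,
                        bic_patience = 10L) {
  criterion <- match.arg(criterion)
  stopifnot(a > 1)
  n <- length(dataset$time)
  if (sum(dataset$event) < 2L) stop("need at least 2 events")
  Zu <- cbind(exposure = dataset$exposure, as.matrix(adjustment))
  Mc <- dataset$mediators[, candidates, drop = FALSE]

  ord <- order(dataset$time, method = "radix")
  tm <- dataset$time[ord]
  ev <- dataset$event[ord]
  Zo <- Zu[ord, , drop = FALSE]
  Mo <- Mc[ord, , drop = FALSE]

  ctr <- colMeans(Mo)
  scl <- apply(Mo, 2L, sd) * sqrt((n - 1) / n)
  if (any(scl < 1e-12))
    stop("degenerate (constant) penalized column in the MCP design")
  Xs <- sweep(sweep(Mo, 2L, ctr, "-"), 2L, scl, "/")

  null_fit <- cpp_cox_newton(Zo, ev, tm, numeric(ncol(Zo)))
  if (null_fit$singular || !null_fit$converged)
    stop("unpenalized null model failed to converge")
  b0 <- drop(null_fit$coef)

  if (is.null(lambda)) {
    eta0 <- drop(Zo %*% b0)
    g <- cpp_cox_eta_derivs(eta0, ev, tm)$g
    lambda_max <- max(abs(crossprod(Xs, g))) / n * 1.000001
    if (!is.finite(lambda_max) || lambda_max <= 0)
      stop("degenerate design: cannot compute lambda_max")
    stopifnot(nlambda >= 2L, lambda_min_ratio > 0, lambda_min_ratio < 1)
    lambda <- exp(seq(log(lambda_max), log(lambda_min_ratio * lambda_max),
                      length.out = nlambda))
  } else {
    lambda <- sort(as.numeric(lambda), decreasing = TRUE)
  }

  nev <- sum(ev)
  L <- length(lambda)
  B0 <- matrix(NA_real_, ncol(Zo), L)
  B <- matrix(NA_real_, ncol(Xs), L)
  ll <- df <- bic <- rep(NA_real_, L)
  b0_cur <- b0
  b_cur <- numeric(ncol(Xs))
  ncx <- FALSE
  used <- 0L
  for (l in seq_len(L)) {
    sol <- cpp_mcp_cox_solve(Zo, Xs, ev, tm, b0_cur, b_cur, lambda[l],
                             a = a, tol = tol)
    b0_cur <- drop(sol$b_unpen)
    b_cur <- drop(sol$b_pen)
    used <- l
    B0[, l] <- b0_cur
    B[, l] <- b_cur
    ll[l] <- sol$loglik
    df[l] <- sol$df
    ncx <- ncx || sol$nonconvex
    bic[l] <- -2 * sol$loglik + log(nev) * sol$df
    if (!is.null(dfmax) && df[l] > dfmax) break
    # once BIC has been past its minimum for `bic_patience` grid points
    # with a growing active set, the remainder of the path cannot win
    if (criterion == "bic" && l - which.min(bic[seq_len(l)]) >=
        bic_patience && df[l] > df[which.min(bic[seq_len(l)])]) break
  }
  keep <- seq_len(used)
  lambda <- lambda[keep]
  beta <- B[, keep, drop = FALSE] / scl  # back to the original scale
  rownames(beta) <- colnames(Mc)

  fit <- list(lambda = lambda, beta = beta,
              unpenalized = B0[, keep, drop = FALSE],
              df = df[keep], loglik = ll[keep],
              n_events = nev, candidates = candidates,
              nonconvex = ncx, a = a)
  sel <- select_lambda_impl(fit, criterion, dataset, adjustment,
                            nfolds, cv_seed, tol)
  fit$criterion <- criterion
  fit$crit_value <- sel$value
  fit$lambda_index <- sel$index
  fit$lambda_sel <- lambda[sel$index]
  nz <- which(beta[, sel$index] != 0)
  fit$selected <- sort(candidates[nz])
  fit$coef <- beta[nz, sel$index]
  names(fit$coef) <- colnames(Mc)[nz]
  class(fit) <- "mcp_cox_fit"
  fit
}

#' Choose lambda on a fitted MCP path
#'
#' Default is BIC on the partial likelihood,
#' `-2 l_n + log(#events) * #nonzero`, which is deterministic; the
#' alternative is K-fold cross-validated partial likelihood
#' (Verweij-van Houwelingen: `l(full at fold-free fit) - l(training at
#' fold-free fit)` summed over folds), seeded for reproducibility.
#'
#' @param fit an `mcp_cox_fit` (a path already carries its criterion; this
#'   helper recomputes for a different rule).
#' @param criterion `"bic"` or `"cv"`.
#' @param dataset,adjustment required for `"cv"` refits.
#' @param nfolds,cv_seed cross-validation controls.
#' @return list with `index` (position in the lambda grid), `lambda`, and
#'   `value` (criterion per grid point; smaller is better).
#' @export
select_lambda <- function(fit, criterion = c("bic", "cv"),
                          dataset = NULL, adjustment = NULL,
                          nfolds = 5L, cv_seed = 1L) {
  criterion <- match.arg(criterion)
  sel <- select_lambda_impl(fit, criterion, dataset, adjustment,
                            nfolds, cv_seed, tol = 1e-7)
  list(index = sel$index, lambda = fit$lambda[sel$index],
       value = sel$value)
}

select_lambda_impl <- function(fit, criterion, dataset, adjustment,
                               nfolds, cv_seed, tol) {
  if (criterion == "bic") {
    value <- -2 * fit$loglik + log(fit$n_events) * fit$df
    return(list(index = which.min(value), value = value))
  }
  if (is.null(dataset))
    stop("cross-validation requires the dataset and adjustment block")
  value <- cv_partial_likelihood(fit, dataset, adjustment, nfolds,
                                 cv_seed, tol)
  list(index = which.min(value), value = value)
}

# K-fold cross-validated partial likelihood deviance along the path
cv_partial_likelihood <- function(fit, dataset, adjustment, nfolds,
                                  cv_seed, tol) {
  n <- length(dataset$time)
  folds <- with_seed_(cv_seed, sample(rep_len(seq_len(nfolds), n)))
  Zu <- cbind(exposure = dataset$exposure, as.matrix(adjustment))
  Mc <- dataset$mediators[, fit$candidates, drop = FALSE]
  cvll <- numeric(length(fit$lambda))
  for (v in seq_len(nfolds)) {
    tr <- folds != v
    ordt <- order(dataset$time[tr], method = "radix")
    Zt <- Zu[tr, , drop = FALSE][ordt, , drop = FALSE]
    Mt <- Mc[tr, , drop = FALSE][ordt, , drop = FALSE]
    tmt <- dataset$time[tr][ordt]
    evt <- dataset$event[tr][ordt]
    ctr <- colMeans(Mt)
    scl <- apply(Mt, 2L, sd) * sqrt((sum(tr) - 1) / sum(tr))
    scl[scl < 1e-12] <- 1
    Xst <- sweep(sweep(Mt, 2L, ctr, "-"), 2L, scl, "/")
    nf <- cpp_cox_newton(Zt, evt, tmt, numeric(ncol(Zt)))
    # full-data and training-data likelihoods at the fold-free fit
    ordf <- order(dataset$time, method = "radix")
    Zf <- Zu[ordf, , drop = FALSE]
    Mf <- Mc[ordf, , drop = FALSE]
    Xsf <- sweep(sweep(Mf, 2L, ctr, "-"), 2L, scl, "/")
    b0_cur <- drop(nf$coef)
    b_cur <- numeric(ncol(Xst))
    for (l in seq_along(fit$lambda)) {
      sol <- cpp_mcp_cox_solve(Zt, Xst, evt, tmt, b0_cur, b_cur,
                               fit$lambda[l], a = fit$a, tol = tol)
      b0_cur <- drop(sol$b_unpen)
      b_cur <- drop(sol$b_pen)
      ll_full <- cpp_cox_eval(cbind(Zf, Xsf), dataset$event[ordf],
                              dataset$time[ordf], c(b0_cur, b_cur),
                              derivs = FALSE)$loglik
      cvll[l] <- cvll[l] + (ll_full - sol$loglik)
    }
  }
  -2 * cvll
}

#' @export
print.mcp_cox_fit <- function(x, ...) {
  cat(sprintf(
    "mcp_cox_fit: %d candidates, %d lambda values (%s-selected #%d)\n",
    length(x$candidates), length(x$lambda), x$criterion, x$lambda_index))
  cat("  S2 =", if (length(x$selected)) paste(x$selected, collapse = ", ")
                else "(empty)", "\n")
  invisible(x)
}
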
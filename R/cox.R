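#' Construct a Cox design (risk-set ordered)
#'
#' Stores the covariate matrix together with times and event indicators,
#' sorted once by increasing observed time so that risk sets
#' `R_i = {l : T_l >= T_i}` are suffixes of the sorted order. Tied event
#' times are handled with the Breslow convention throughout.
#'
#' @param covariates numeric matrix (n x q); may have zero columns.
#' @param time nonnegative observed times.
#' @param event 0/1 event indicators.
#' @return an object of class `cox_design`.
#' @export
cox_design <- function(covariates, time, event) {
  covariates <- as.matrix(covariates)
  n <- length(time)
  if (nrow(covariates) != n || length(event) != n)
    stop("inconsistent dimensions")
  if (any(!is.finite(time)) || any(time < 0))
    stop("times must be finite and nonnegative")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  ord <- order(time, method = "radix")
  d <- list(x = covariates[ord, , drop = FALSE],
            time = as.numeric(time[ord]),
            event = as.numeric(event[ord]),
            order = ord, n = n, n_events = sum(event))
  class(d) <- "cox_design"
  d
}

#' Cox log partial likelihood
#'
#' Evaluates `l_n(Q) = sum_{i: event} { eta_i - log sum_{l in R_i}
#' exp(eta_l) }` with `eta = x' Q`, Breslow tie handling, and a global
#' log-sum-exp shift guarding overflow.
#'
#' @param design a [cox_design()].
#' @param coef coefficient vector (length = number of columns).
#' @return the scalar log partial likelihood.
#' @export
log_partial_likelihood <- function(design, coef) {
  stopifnot(inherits(design, "cox_design"),
            length(coef) == ncol(design$x), all(is.finite(coef)))
  cpp_cox_eval(design$x, design$event, design$time, coef,
               derivs = FALSE)$loglik
}

#' Gradient and Hessian of the Cox log partial likelihood
#'
#' Analytic first and second derivatives; the Hessian (of the
#' log-likelihood) is symmetric negative semi-definite.
#'
#' @inheritParams log_partial_likelihood
#' @return list with `gradient` (vector) and `hessian` (matrix).
#' @export
cox_gradient_hessian <- function(design, coef) {
  stopifnot(inherits(design, "cox_design"),
            length(coef) == ncol(design$x), all(is.finite(coef)))
  ev <- cpp_cox_eval(design$x, design$event, design$time, coef,
                     derivs = TRUE)
  list(gradient = drop(ev$gradient), hessian = ev$hessian)
}

#' Fit an unpenalized Cox proportional-hazards model
#'
#' Newton-Raphson with step halving on the Breslow partial likelihood;
#' standard errors come from the inverse observed information. Used for
#' marginal screening fits, the post-selection refit and the total-effect
#' model.
#'
#' @param design a [cox_design()].
#' @param init optional starting coefficients (default zero).
#' @param maxit maximum Newton iterations.
#' @param tol relative log-likelihood convergence tolerance.
#' @return an object of class `cox_fit` with `coef`, `se`, `cov`,
#'   `loglik`, `converged`.
#' @export
fit_cox <- function(design, init = NULL, maxit = 100L, tol = 1e-9) {
  stopifnot(inherits(design, "cox_design"))
  q <- ncol(design$x)
  if (design$n_events == 0)
    stop("no events observed; the partial likelihood is flat")
  if (q >= design$n_events)
    stop("more covariates than events; fit is not identifiable")
  if (is.null(init)) init <- numeric(q)
  fit <- cpp_cox_newton(design$x, design$event, design$time, init,
                        maxit = maxit, tol = tol)
  if (fit$singular) stop("singular information matrix in Cox fit")
  if (!fit$converged)
    stop("Cox Newton iterations failed to converge")
  cov <- (fit$cov + t(fit$cov)) / 2
  cf <- drop(fit$coef)
  names(cf) <- colnames(design$x)
  out <- list(coef = cf, cov = cov, se = sqrt(pmax(diag(cov), 0)),
              loglik = fit$loglik, converged = fit$converged)
  class(out) <- "cox_fit"
  out
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("cox_fit: log partial likelihood =", format(x$loglik, digits = 6),
      "\n")
  print(data.frame(coef = x$coef, se = x$se,
                   z = x$coef / x$se,
                   p = 2 * pnorm(-abs(x$coef / x$se))))
  invisible(x)
}
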
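#' Estimate the propensity score (Step 0)
#'
#' Fits `logit Pr(X = 1) = theta0 + theta' Z` by maximum likelihood (an
#' intercept is always included) and returns the per-subject scores
#' `pi_i`. The fitted scores satisfy the logistic score equation
#' `sum(pi) = sum(X)` to solver tolerance. Either the score itself or its
#' logit can be carried downstream as the single adjustment covariate.
#'
#' @param X binary exposure vector with both arms represented.
#' @param Z confounder matrix (full column rank).
#' @param form which transform of the score to use as the adjustment
#'   covariate: `"score"` for `pi_i` or `"logit"` for
#'   `theta0 + theta' Z_i`.
#' @return an object of class `propensity_fit` with `theta0`, `theta`,
#'   `scores`, `linear_predictor`, `covariate` (per `form`) and `form`.
#' @export
fit_propensity <- function(X, Z, form = c("score", "logit")) {
  form <- match.arg(form)
  if (is.null(Z)) Z <- matrix(numeric(0), nrow = length(X), ncol = 0)
  Z <- as.matrix(Z)
  if (length(X) != nrow(Z)) stop("X and Z have inconsistent dimensions")
  if (!all(X %in% c(0, 1))) stop("exposure must be binary 0/1")
  if (length(unique(X)) < 2L)
    stop("both exposure arms must be present to fit a propensity model")
  if (qr(cbind(1, Z))$rank < ncol(Z) + 1L)
    stop("confounder matrix is rank deficient")
  # glm.fit's own fitted-probability warnings are superseded by the
  # explicit separation check below
  fit <- suppressWarnings(
    glm.fit(cbind(`(Intercept)` = 1, Z), X,
            family = binomial(), control = list(epsilon = 1e-10,
                                                maxit = 100L)))
  if (!fit$converged) stop("propensity logistic regression did not converge")
  cf <- fit$coefficients
  lp <- drop(cbind(1, Z) %*% cf)
  scores <- plogis(lp)
  if (any(abs(lp) > 30)) {
    warning("near-perfect separation detected in the propensity model; ",
            "scores clipped away from 0/1")
    scores <- pmin(pmax(scores, 1e-6), 1 - 1e-6)
  }
  out <- list(theta0 = unname(cf[1L]), theta = cf[-1L], scores = scores,
              linear_predictor = lp,
              covariate = if (form == "score") scores else lp,
              form = form)
  class(out) <- "propensity_fit"
  out
}

#' @export
print.propensity_fit <- function(x, ...) {
  cat(sprintf("propensity_fit (%s form): n = %d, mean score = %.3f\n",
              x$form, length(x$scores), mean(x$scores)))
  cat("  theta0 =", format(x$theta0, digits = 4), "\n")
  invisible(x)
}

#' Build the adjustment covariate block for a comparison mode
#'
#' Returns the covariate column(s) placed alongside exposure in every
#' downstream model: the propensity score (or its logit) in `"ps"` mode,
#' all raw confounder columns in `"z"` mode, and nothing in `"naive"`
#' mode (the confounder-ignoring comparison arm).
#'
#' @param dataset a `mediation_dataset`.
#' @param mode adjustment mode, one of `"ps"`, `"z"`, `"naive"`.
#' @param fit a `propensity_fit` (required for `"ps"`; fitted on the
#'   dataset's exposure and confounders when `NULL`).
#' @param form score form passed to [fit_propensity()] when it is fitted
#'   here.
#' @return an n x k numeric matrix (k = 0 for `"naive"`).
#' @export
attach_covariate <- function(dataset, mode = c("ps", "z", "naive"),
                             fit = NULL, form = c("score", "logit")) {
  mode <- match.arg(mode)
  n <- length(dataset$time)
  if (mode == "naive") return(matrix(numeric(0), nrow = n, ncol = 0))
  if (mode == "z") {
    if (is.null(dataset$confounders))
      stop("z mode requires measured confounders")
    return(as.matrix(dataset$confounders))
  }
  if (is.null(fit))
    fit <- fit_propensity(dataset$exposure, dataset$confounders,
                          form = match.arg(form))
  if (length(fit$covariate) != n)
    stop("propensity scores and dataset have different lengths")
  matrix(fit$covariate, ncol = 1L,
         dimnames = list(NULL, if (fit$form == "score") "ps" else "logit_ps"))
}
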
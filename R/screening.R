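#' Sure-independence-screening subset size
#'
#' `d = ceiling(2n / log(n))` with the natural logarithm; the factor 2
#' (rather than 1) raises the chance that a mediator whose alpha and beta
#' paths must *both* survive screening is retained.
#'
#' @param n sample size (must be at least 3 so that `log(n) > 1`).
#' @return integer subset size d.
#' @export
screening_size <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 3L) stop("screening size requires n >= 3")
  as.integer(ceiling(2 * n / log(n)))
}

#' Screen mediators by marginal association (Step 1)
#'
#' Ranks all p mediators by a marginal-association p-value and keeps the
#' `min(d, p)` smallest, `d = ceiling(2n/log n)`. Modes:
#'
#' * `"outcome"` — Wald p-value of `M_k` in the Cox model with covariates
#'   (exposure, adjustment block, `M_k`); the default for the outcome
#'   path.
#' * `"exposure"` — p-value of the exposure coefficient in the linear
#'   model `M_k ~ exposure + adjustment`, the exposure-to-mediator path
#'   (useful when that path dominates, as in methylation applications).
#' * `"union"` — alternate between the two rankings until d distinct
#'   mediators are collected.
#'
#' Non-convergent marginal fits are recorded with p-value 1, never
#' dropped. Ties are broken by lower mediator index, so screening is
#' deterministic and invariant to column order.
#'
#' @param dataset a `mediation_dataset`.
#' @param adjustment adjustment covariate matrix from
#'   [attach_covariate()] (zero columns for the naive arm).
#' @param mode screening mode.
#' @param d subset size; default [screening_size()] of the sample size.
#' @return an object of class `screening_result` with `selected` (ranked
#'   indices), `pvalue` (length p, per the primary mode ranking),
#'   `statistic`, `mode`, `d`.
#' @export
screen_mediators <- function(dataset, adjustment,
                             mode = c("outcome", "exposure", "union"),
                             d = NULL) {
  mode <- match.arg(mode)
  n <- length(dataset$time)
  p <- ncol(dataset$mediators)
  if (is.null(d)) d <- screening_size(n)
  d <- min(as.integer(d), p)
  adjustment <- as.matrix(adjustment)

  pv_out <- st_out <- pv_exp <- st_exp <- NULL
  if (mode %in% c("outcome", "union")) {
    mo <- marginal_outcome_pvalues(dataset, adjustment)
    pv_out <- mo$pvalue; st_out <- mo$statistic
  }
  if (mode %in% c("exposure", "union")) {
    me <- marginal_exposure_pvalues(dataset, adjustment)
    pv_exp <- me$pvalue; st_exp <- me$statistic
  }

  if (mode == "union") {
    r_out <- order(pv_out, seq_len(p), method = "radix")
    r_exp <- order(pv_exp, seq_len(p), method = "radix")
    sel <- integer(0)
    i <- 1L
    while (length(sel) < d) {
      sel <- unique(c(sel, r_out[i], r_exp[i]))
      i <- i + 1L
    }
    sel <- sel[seq_len(d)]
    pv <- pmin(pv_out, pv_exp)
    st <- ifelse(pv_out <= pv_exp, st_out, st_exp)
  } else {
    pv <- if (mode == "outcome") pv_out else pv_exp
    st <- if (mode == "outcome") st_out else st_exp
    sel <- order(pv, seq_len(p), method = "radix")[seq_len(d)]
  }
  out <- list(selected = sel, pvalue = pv, statistic = st,
              mode = mode, d = d)
  class(out) <- "screening_result"
  out
}

# Wald p-value of M_k in Cox(exposure, adjustment, M_k) for every k
marginal_outcome_pvalues <- function(dataset, adjustment) {
  A <- cbind(exposure = dataset$exposure, adjustment)
  ord <- order(dataset$time, method = "radix")
  Ao <- A[ord, , drop = FALSE]
  Mo <- dataset$mediators[ord, , drop = FALSE]
  ev <- dataset$event[ord]
  tm <- dataset$time[ord]
  # warm start from the adjustment-only model
  base <- cpp_cox_newton(Ao, ev, tm, numeric(ncol(Ao)))
  init <- if (base$converged && !base$singular) drop(base$coef)
          else numeric(ncol(Ao))
  sc <- cpp_cox_screen(Ao, Mo, ev, tm, init)
  z <- sc$est / sc$se
  pv <- 2 * pnorm(-abs(z))
  bad <- sc$converged == 0L | !is.finite(pv)
  pv[bad] <- 1
  z[bad] <- 0
  list(pvalue = pv, statistic = z)
}

# normal-theory p-value of the exposure coefficient in
# lm(M_k ~ exposure + adjustment), vectorized over all k by one QR
marginal_exposure_pvalues <- function(dataset, adjustment) {
  D <- cbind(1, exposure = dataset$exposure, adjustment)
  n <- nrow(D); q <- ncol(D)
  qrD <- qr(D)
  if (qrD$rank < q) stop("collinear screening design")
  cf <- qr.coef(qrD, dataset$mediators)
  res <- qr.resid(qrD, dataset$mediators)
  sigma2 <- colSums(res^2) / (n - q)
  unpiv <- order(qrD$pivot)
  xtxinv <- chol2inv(qr.R(qrD))[unpiv, unpiv]
  se <- sqrt(sigma2 * xtxinv[2L, 2L])
  z <- cf[2L, ] / se
  pv <- 2 * pnorm(-abs(z))
  bad <- !is.finite(pv)
  pv[bad] <- 1
  z[bad] <- 0
  list(pvalue = unname(pv), statistic = unname(z))
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("screening_result (%s mode): kept %d of %d mediators\n",
              x$mode, length(x$selected), length(x$pvalue)))
  invisible(x)
}
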
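#' Pipeline configuration
#'
#' Collects every tunable of the four-step procedure so that a run is
#' fully described by (dataset, config).
#'
#' @param mode confounder-adjustment mode: `"ps"` (propensity-score
#'   covariate), `"z"` (all confounders as covariates), `"naive"` (no
#'   adjustment anywhere).
#' @param test which significance test declares mediators: `"joint"`,
#'   `"sobel"`, or `"both"` (records carry both either way; this picks
#'   the declaration rule).
#' @param screen screening mode passed to [screen_mediators()].
#' @param alpha significance threshold on the Bonferroni-adjusted
#'   p-value (default 0.05).
#' @param covariate_form propensity covariate form, `"score"` or
#'   `"logit"`.
#' @param nlambda,lambda_min_ratio,mcp_a,criterion MCP path controls, see
#'   [fit_mcp_cox()].
#' @param second_order_sobel use the second-order Sobel variance.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("ps", "z", "naive"),
                            test = c("joint", "sobel", "both"),
                            screen = c("outcome", "exposure", "union"),
                            alpha = 0.05,
                            covariate_form = c("score", "logit"),
                            nlambda = 50L, lambda_min_ratio = 0.05,
                            mcp_a = 3, criterion = c("bic", "cv"),
                            second_order_sobel = FALSE) {
  stopifnot(alpha > 0, alpha < 1)
  cfg <- list(mode = match.arg(mode), test = match.arg(test),
              screen = match.arg(screen), alpha = alpha,
              covariate_form = match.arg(covariate_form),
              nlambda = as.integer(nlambda),
              lambda_min_ratio = lambda_min_ratio, mcp_a = mcp_a,
              criterion = match.arg(criterion),
              second_order_sobel = isTRUE(second_order_sobel))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the four-step mediation pipeline on one dataset
#'
#' Step 0 propensity adjustment (per `config$mode`), Step 1 sure
#' independence screening, Step 2 MCP-penalized Cox selection, Step 3
#' mediation tests with Bonferroni correction, plus the total-effect
#' model. Significant mediators are those in `S2` whose adjusted p-value
#' (per `config$test`) falls below `config$alpha`.
#'
#' @param dataset a `mediation_dataset`.
#' @param config a [pipeline_config()].
#' @return an object of class `pipeline_result`: `records` (the
#'   [mediation_tests()] frame), `s1`, `s2`, `significant` (indices per
#'   the declaration test), `significant_sobel`, `significant_joint`,
#'   `total_effect`, `screening`, `mcp`, `propensity` (NULL unless
#'   `mode = "ps"`), `counts` (p, |S1|, |S2|, #significant), `config`.
#' @export
run_pipeline <- function(dataset, config = pipeline_config()) {
  stopifnot(inherits(dataset, "mediation_dataset"),
            inherits(config, "pipeline_config"))
  ps <- NULL
  if (config$mode == "ps")
    ps <- fit_propensity(dataset$exposure, dataset$confounders,
                         form = config$covariate_form)
  adj <- attach_covariate(dataset, mode = config$mode, fit = ps)

  sr <- screen_mediators(dataset, adj, mode = config$screen)
  mcp <- fit_mcp_cox(dataset, adj, sr$selected,
                     nlambda = config$nlambda,
                     lambda_min_ratio = config$lambda_min_ratio,
                     a = config$mcp_a, criterion = config$criterion)
  records <- mediation_tests(dataset, adj, mcp$selected,
                             second_order_sobel = config$second_order_sobel)
  sig_sobel <- records$mediator[records$p_sobel < config$alpha]
  sig_joint <- records$mediator[records$p_joint < config$alpha]
  sig <- switch(config$test, sobel = sig_sobel, joint = sig_joint,
                both = sort(union(sig_sobel, sig_joint)))
  total <- estimate_total_effect(dataset, adj)
  out <- list(records = records, s1 = sr$selected, s2 = mcp$selected,
              significant = sig, significant_sobel = sig_sobel,
              significant_joint = sig_joint, total_effect = total,
              screening = sr, mcp = mcp, propensity = ps,
              counts = c(p = ncol(dataset$mediators),
                         s1 = length(sr$selected),
                         s2 = length(mcp$selected),
                         significant = length(sig)),
              config = config)
  class(out) <- "pipeline_result"
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "pipeline_result (%s mode, %s test): p=%d -> |S1|=%d -> |S2|=%d -> %d significant\n",
    x$config$mode, x$config$test, x$counts["p"], x$counts["s1"],
    x$counts["s2"], x$counts["significant"]))
  cat(sprintf("  total effect HR = %.4f (%.4f-%.4f)\n",
              x$total_effect$hr, x$total_effect$lower,
              x$total_effect$upper))
  invisible(x)
}

#' Selection accuracy of one replication
#'
#' `TP = |selected intersect truth|`, `FP = |selected \\ truth|`,
#' `TPR = TP / |truth|`, `FDP = FP / max(TP + FP, 1)` (so an empty
#' selection scores FDP 0).
#'
#' @param selected selected mediator indices.
#' @param truth true mediator indices (nonempty).
#' @return named numeric vector `tp`, `fp`, `tpr`, `fdp`.
#' @export
evaluate_selection <- function(selected, truth) {
  stopifnot(length(truth) > 0)
  tp <- length(intersect(selected, truth))
  fp <- length(setdiff(selected, truth))
  c(tp = tp, fp = fp, tpr = tp / length(truth),
    fdp = fp / max(tp + fp, 1))
}

#' Replicated simulation study of selection and estimation accuracy
#'
#' Generates `reps` independent datasets from the benchmark design and
#' runs the pipeline in each requested comparison mode on every dataset
#' (all modes see the same data). Reports, per mode and test, the mean
#' TPR / FP / FDP over replications, and per true-effect mediator the
#' mean and MSE of `alpha_hat * beta_hat` across the replications in
#' which that mediator entered `S2` (estimation is conditional on
#' selection, matching how sparse-selection studies tabulate it).
#'
#' The master `seed` spawns one substream seed per replication (and one
#' for the censoring calibration), so results are deterministic and
#' independent of any parallel scheduling.
#'
#' @param n subjects per replication.
#' @param p candidate mediators per replication.
#' @param censoring target censoring rate (e.g. 0.15 or 0.30).
#' @param reps number of replications.
#' @param modes subset of `c("ps", "z", "naive")`.
#' @param seed master seed.
#' @param covariate_form propensity covariate form for the `"ps"` arm;
#'   the benchmark design carries the logit of the score.
#' @param alpha significance threshold.
#' @param sim_args extra arguments to [sim_config()].
#' @param pipe_args extra arguments to [pipeline_config()].
#' @param verbose print a progress line every 25 replications.
#' @return an object of class `simulation_study`: `table1` (mode x test
#'   TPR/FP/FDP), `table2` (per-mediator conditional mean and MSE of the
#'   indirect effect, per mode), `detail` (per-replication rows), plus
#'   the run metadata (`n`, `p`, `censoring`, `reps`, `seed`, `c0`).
#' @export
run_simulation_study <- function(n, p = 10000L, censoring = 0.15,
                                 reps = 500L,
                                 modes = c("ps", "naive", "z"),
                                 seed = 1L,
                                 covariate_form = "logit",
                                 alpha = 0.05,
                                 sim_args = list(),
                                 pipe_args = list(),
                                 verbose = FALSE) {
  modes <- match.arg(modes, c("ps", "naive", "z"), several.ok = TRUE)
  seeds <- with_seed_(seed, sample.int(.Machine$integer.max - 1L,
                                       reps + 1L))
  cal_cfg <- do.call(sim_config,
                     c(list(n_subjects = n, n_mediators = p,
                            target_censoring = censoring,
                            seed = seeds[1L]), sim_args))
  c0 <- with_seed_(seeds[1L], calibrate_censoring(cal_cfg))

  truth <- NULL
  detail <- vector("list", reps * length(modes))
  est_rows <- vector("list", reps * length(modes))
  di <- 0L
  for (r in seq_len(reps)) {
    cfg <- do.call(sim_config,
                   c(list(n_subjects = n, n_mediators = p,
                          target_censoring = censoring, c0 = c0,
                          seed = seeds[r + 1L]), sim_args))
    ds <- generate_dataset(cfg)
    truth <- ds$truth$true_indices
    true_prod <- (cfg$alpha_true * cfg$beta_true)
    effect_idx <- which(cfg$alpha_true != 0 | cfg$beta_true != 0)
    for (mode in modes) {
      pc <- do.call(pipeline_config,
                    c(list(mode = mode, alpha = alpha,
                           covariate_form = covariate_form), pipe_args))
      res <- run_pipeline(ds, pc)
      mj <- evaluate_selection(res$significant_joint, truth)
      msb <- evaluate_selection(res$significant_sobel, truth)
      di <- di + 1L
      detail[[di]] <- data.frame(
        rep = r, mode = mode,
        tpr_joint = unname(mj["tpr"]), fp_joint = unname(mj["fp"]),
        fdp_joint = unname(mj["fdp"]),
        tpr_sobel = unname(msb["tpr"]), fp_sobel = unname(msb["fp"]),
        fdp_sobel = unname(msb["fdp"]),
        s1 = length(res$s1), s2 = length(res$s2), row.names = NULL)
      sel <- res$records$mediator
      keep <- sel[sel %in% effect_idx]
      if (length(keep)) {
        rows <- match(keep, res$records$mediator)
        est_rows[[di]] <- data.frame(
          rep = r, mode = mode, mediator = keep,
          alpha_true = cfg$alpha_true[keep],
          beta_true = cfg$beta_true[keep],
          product_true = true_prod[keep],
          estimate = res$records$indirect[rows], row.names = NULL)
      }
    }
    if (verbose && r %% 25L == 0L)
      message(sprintf("replication %d/%d done", r, reps))
  }
  detail <- do.call(rbind, detail)
  est <- do.call(rbind, est_rows[!vapply(est_rows, is.null, logical(1))])

  t1 <- do.call(rbind, lapply(modes, function(m) {
    dd <- detail[detail$mode == m, ]
    data.frame(mode = m,
               test = c("sobel", "joint"),
               tpr = c(mean(dd$tpr_sobel), mean(dd$tpr_joint)),
               fp = c(mean(dd$fp_sobel), mean(dd$fp_joint)),
               fdp = c(mean(dd$fdp_sobel), mean(dd$fdp_joint)),
               row.names = NULL)
  }))

  t2 <- NULL
  if (!is.null(est)) {
    key <- interaction(est$mode, est$mediator, drop = TRUE)
    t2 <- do.call(rbind, lapply(split(est, key), function(g) {
      data.frame(mode = g$mode[1L], mediator = g$mediator[1L],
                 alpha_true = g$alpha_true[1L],
                 beta_true = g$beta_true[1L],
                 product_true = g$product_true[1L],
                 n_selected = nrow(g),
                 mean_est = mean(g$estimate),
                 mse = mean((g$estimate - g$product_true)^2),
                 row.names = NULL)
    }))
    t2 <- t2[order(t2$mode, t2$mediator), ]
    rownames(t2) <- NULL
  }

  out <- list(table1 = t1, table2 = t2, detail = detail,
              estimates = est, truth = truth, n = n, p = p,
              censoring = censoring, reps = reps, seed = seed, c0 = c0)
  class(out) <- "simulation_study"
  out
}

#' @export
print.simulation_study <- function(x, ...) {
  cat(sprintf(
    "simulation_study: n=%d, p=%d, censoring=%.0f%%, %d replications\n",
    x$n, x$p, 100 * x$censoring, x$reps))
  print(x$table1, digits = 4)
  invisible(x)
}
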
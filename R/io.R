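#' Dataset column schema for delimited-text input
#'
#' Names the required columns of a subject-per-row table: observed time,
#' event indicator, binary exposure, a mediator column prefix (or an
#' explicit list), and confounder columns (prefix or explicit list).
#'
#' @param time,event,exposure column names.
#' @param mediator_prefix prefix shared by the mediator columns (used
#'   when `mediator_cols` is `NULL`).
#' @param mediator_cols explicit mediator column names, optional.
#' @param confounder_prefix prefix for confounder columns.
#' @param confounder_cols explicit confounder column names, optional.
#' @param delim field delimiter.
#' @param na_token missing-value token.
#' @return an object of class `dataset_schema`.
#' @export
dataset_schema <- function(time = "time", event = "event",
                           exposure = "exposure",
                           mediator_prefix = "M", mediator_cols = NULL,
                           confounder_prefix = "Z",
                           confounder_cols = NULL,
                           delim = "\t", na_token = "NA") {
  s <- list(time = time, event = event, exposure = exposure,
            mediator_prefix = mediator_prefix,
            mediator_cols = mediator_cols,
            confounder_prefix = confounder_prefix,
            confounder_cols = confounder_cols,
            delim = delim, na_token = na_token)
  class(s) <- "dataset_schema"
  s
}

match_prefix_cols <- function(nms, prefix) {
  hits <- grep(paste0("^", prefix, "[0-9]+$"), nms, value = TRUE)
  hits[order(as.integer(sub(paste0("^", prefix), "", hits)))]
}

#' Read a mediation dataset from delimited text
#'
#' Validates the schema before any computation: required columns present
#' exactly once, event values in \{0, 1\}, times numeric and
#' nonnegative, exposure binary. Rows with a missing required field
#' (time, event, exposure, or any confounder) are excluded with a
#' reported count; malformed values are rejected with their line
#' numbers, never coerced.
#'
#' @param path file path.
#' @param schema a [dataset_schema()].
#' @return a `mediation_dataset`; attribute `"n_excluded"` carries the
#'   number of dropped rows.
#' @export
read_mediation_dataset <- function(path, schema = dataset_schema()) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = schema$delim,
                          na.strings = schema$na_token,
                          data.table = FALSE, showProgress = FALSE)
  nms <- names(dt)
  for (col in c(schema$time, schema$event, schema$exposure)) {
    cnt <- sum(nms == col)
    if (cnt != 1L)
      stop("required column '", col, "' present ", cnt,
           " times (need exactly once)")
  }
  med_cols <- schema$mediator_cols %||%
    match_prefix_cols(nms, schema$mediator_prefix)
  if (length(med_cols) == 0L) stop("no mediator columns found")
  conf_cols <- schema$confounder_cols %||%
    match_prefix_cols(nms, schema$confounder_prefix)
  if (!all(med_cols %in% nms) || !all(conf_cols %in% nms))
    stop("schema names columns absent from the file")

  tm <- dt[[schema$time]]
  ev <- dt[[schema$event]]
  xp <- dt[[schema$exposure]]
  if (!is.numeric(tm)) stop("time column is not numeric")
  bad_ev <- which(!(ev %in% c(0, 1)) & !is.na(ev))
  if (length(bad_ev))
    stop("event column contains non-0/1 values at data rows: ",
         paste(head(bad_ev, 5L), collapse = ", "))
  bad_xp <- which(!(xp %in% c(0, 1)) & !is.na(xp))
  if (length(bad_xp))
    stop("exposure column contains non-binary values at data rows: ",
         paste(head(bad_xp, 5L), collapse = ", "))
  bad_tm <- which(tm < 0)
  if (length(bad_tm))
    stop("negative times at data rows: ",
         paste(head(bad_tm, 5L), collapse = ", "))

  req <- cbind(tm, ev, xp,
               if (length(conf_cols)) as.matrix(dt[conf_cols]))
  keep <- rowSums(is.na(req)) == 0L
  n_excluded <- sum(!keep)
  if (n_excluded > 0L)
    message(n_excluded,
            " row(s) excluded for missing required fields")
  if (!any(keep)) stop("no complete rows left after exclusions")

  ds <- mediation_dataset(
    time = tm[keep], event = ev[keep], exposure = xp[keep],
    mediators = as.matrix(dt[keep, med_cols, drop = FALSE]),
    confounders = if (length(conf_cols))
      as.matrix(dt[keep, conf_cols, drop = FALSE]) else NULL)
  attr(ds, "n_excluded") <- n_excluded
  ds
}

#' Write a mediation dataset (and truth manifest) as delimited text
#'
#' Subjects in rows; columns `time`, `event`, `exposure`, the confounder
#' block, then the mediator block. When the dataset carries a truth
#' manifest it is written as JSON next to the table (or to
#' `manifest_path`).
#'
#' @param dataset a `mediation_dataset`.
#' @param path output TSV path.
#' @param manifest_path optional path for the truth manifest JSON;
#'   default replaces the table extension with `.truth.json`.
#' @return invisibly, the paths written.
#' @export
write_mediation_dataset <- function(dataset, path, manifest_path = NULL) {
  df <- data.frame(time = dataset$time, event = dataset$event,
                   exposure = dataset$exposure)
  if (!is.null(dataset$confounders))
    df <- cbind(df, as.data.frame(dataset$confounders))
  df <- cbind(df, as.data.frame(dataset$mediators))
  data.table::fwrite(df, path, sep = "\t")
  paths <- path
  if (!is.null(dataset$truth)) {
    if (is.null(manifest_path))
      manifest_path <- paste0(sub("\\.[^.]*$", "", path), ".truth.json")
    jsonlite::write_json(dataset$truth, manifest_path,
                         auto_unbox = TRUE, digits = NA)
    paths <- c(paths, manifest_path)
  }
  invisible(paths)
}

#' Write per-mediator results and a run summary
#'
#' `records.tsv` mirrors the applied-analysis layout (mediator id, alpha,
#' beta, Sobel and joint p-values, hazard ratio with interval) at full
#' precision; `summary.json` carries the total effect and stage counts.
#'
#' @param result a `pipeline_result` (or a records data.frame).
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_results <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  records <- if (inherits(result, "pipeline_result")) result$records
             else result
  rp <- file.path(dir, "records.tsv")
  data.table::fwrite(records, rp, sep = "\t")
  paths <- rp
  if (inherits(result, "pipeline_result")) {
    sp <- file.path(dir, "summary.json")
    jsonlite::write_json(
      list(total_effect = result$total_effect,
           counts = as.list(result$counts),
           mode = result$config$mode, test = result$config$test,
           alpha = result$config$alpha,
           significant = result$significant),
      sp, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, sp)
  }
  invisible(paths)
}

#' Write the screening report
#'
#' One row per mediator: id, mode, statistic, p-value, selected flag.
#'
#' @param screening a `screening_result`.
#' @param path output TSV path.
#' @export
write_screening_report <- function(screening, path) {
  p <- length(screening$pvalue)
  df <- data.frame(mediator = seq_len(p), mode = screening$mode,
                   statistic = screening$statistic,
                   pvalue = screening$pvalue,
                   selected = seq_len(p) %in% screening$selected)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Write MCP path diagnostics
#'
#' One row per lambda: lambda, number of nonzero penalized coefficients,
#' log partial likelihood, criterion value, selected flag.
#'
#' @param fit an `mcp_cox_fit`.
#' @param path output TSV path.
#' @export
write_path_diagnostics <- function(fit, path) {
  df <- data.frame(lambda = fit$lambda, df = fit$df,
                   loglik = fit$loglik, criterion = fit$crit_value,
                   selected = seq_along(fit$lambda) == fit$lambda_index)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
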
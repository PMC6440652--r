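# Run reports ------------------------------------------------------------
#
# Every analysis result can be persisted as a JSON report plus CSV traces,
# together with the effective configuration and seed, which is sufficient
# to re-run the analysis bit-identically.

#' Write a result report to a directory
#'
#' Writes `report.json` (the result's numeric content plus the seed), CSV
#' files for any traces or curves the result carries, the effective
#' configuration (`config.yaml`, when supplied) and a timestamped
#' `run.log`.
#'
#' @param result An `oed_result`, `fim_result`, `sample_size_result`,
#'   `opt_result` or `fit_diagnostics` object.
#' @param out_dir Output directory (created if needed).
#' @param config Optional [run_config()] echoed alongside the report.
#' @return Invisibly, the vector of files written.
#' @export
write_report <- function(result, out_dir, config = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  payload <- report_payload(result)
  json_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(payload$json, json_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  files <- c(files, json_path)
  for (nm in names(payload$tables)) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    tab <- as.data.frame(payload$tables[[nm]])
    utils::write.csv(tab, p, row.names = FALSE)
    files <- c(files, p)
  }
  if (!is.null(config)) {
    p <- file.path(out_dir, "config.yaml")
    save_config(config, p)
    files <- c(files, p)
  }
  log_path <- file.path(out_dir, "run.log")
  cat(sprintf("[%s] INFO report written: %s (seed %s)\n",
              format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
              class(result)[1],
              payload$json$seed %||% "NA"),
      file = log_path, append = TRUE)
  files <- c(files, log_path)
  invisible(files)
}

report_payload <- function(result) {
  UseMethod("report_payload")
}

#' @export
report_payload.oed_result <- function(result) {
  list(
    json = list(
      type = "oed_result",
      u_star = result$u_star,
      p_star = as.list(result$p_star),
      criterion_star = result$criterion_star,
      free = result$free,
      model = result$model_name,
      seed = result$seed
    ),
    tables = list(
      outer_trace = tibble::tibble(
        iteration = seq_along(result$outer$trace),
        best_fitness = result$outer$trace
      ),
      candidate_levels = result$evaluations,
      inner_trace = tibble::tibble(
        iteration = seq_along(result$inner_trace),
        best_fitness = result$inner_trace
      )
    )
  )
}

#' @export
report_payload.fim_result <- function(result) {
  list(
    json = list(
      type = "fim_result",
      parameters = result$param_names,
      eigenvalues = result$eigenvalues,
      criteria = as.list(result$criteria),
      crlb = as.list(result$crlb),
      singular = result$singular,
      fisher_matrix = unname(apply(result$F, 1, as.numeric,
                                   simplify = FALSE)),
      seed = NULL
    ),
    tables = list(crlb_table = tidy.fim_result(result))
  )
}

#' @export
report_payload.sample_size_result <- function(result) {
  list(
    json = list(
      type = "sample_size_result",
      n_m_star = result$n_m_star,
      lambda = result$lambda,
      seed = result$seed
    ),
    tables = list(cost_curve = result$cost_curve)
  )
}

#' @export
report_payload.opt_result <- function(result) {
  list(
    json = list(
      type = "opt_result",
      method = result$method,
      best_par = as.numeric(result$best_par),
      best_value = result$best_value,
      evaluations = result$evaluations,
      seed = result$seed
    ),
    tables = list(fitness_trace = tidy.opt_result(result))
  )
}

#' @export
report_payload.fit_diagnostics <- function(result) {
  list(
    json = list(
      type = "fit_diagnostics",
      rmse = result$rmse,
      wrsse = result$wrsse,
      dof = result$dof,
      chi2_pvalue = result$chi2_pvalue,
      seed = NULL
    ),
    tables = c(
      list(residuals = tibble::tibble(residual = result$residuals)),
      if (!is.null(result$qq)) list(qq_pairs = result$qq)
    )
  )
}
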
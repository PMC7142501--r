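# One-command replication of the study workflow on synthetic or user
# data: summarise -> develop -> refit on the development split ->
# validate on the held-out split -> benchmark the literature registry ->
# residual-plot data, written as a report bundle with a manifest.

#' Configuration of a study-replica run
#'
#' @param data Either `"generate"` (synthetic data from
#'   `generator_config`) or the path of a trial-record CSV file.
#' @param generator A [generator_config()] used when `data` is
#'   `"generate"`.
#' @param split_fraction,split_seed Development-set fraction and the
#'   seed of the stratified split.
#' @param model_specs Tibble of model forms to develop (`id`, `response`,
#'   list column `predictors`); defaults to every form of the built-in
#'   whole-data registries (tables 2-5).
#' @param benchmark Registry (or built-in name) of literature equations
#'   to score on the held-out split; default `"table8"`.
#' @param random Candidate random factors for equation development.
#' @param residual_ids Ids (within the refit set) whose
#'   residual-versus-predicted series are exported; defaults to the
#'   first ME forms.
#' @return A `study_config` list.
#' @export
study_config <- function(data = "generate",
                         generator = generator_config(),
                         split_fraction = 2/3,
                         split_seed = 20161201L,
                         model_specs = NULL,
                         benchmark = "table8",
                         random = c("sheep", "season", "year"),
                         residual_ids = NULL) {
  if (is.null(model_specs)) {
    model_specs <- dplyr::bind_rows(purrr::map(
      c("table2", "table3", "table4", "table5"),
      ~ model_specs_from_registry(.x)))
  }
  if (split_fraction <= 0 || split_fraction >= 1) {
    stop("`split_fraction` must lie in (0, 1).", call. = FALSE)
  }
  if (nrow(model_specs) == 0) {
    stop("At least one model spec is required.", call. = FALSE)
  }
  structure(list(data = data, generator = generator,
                 split_fraction = split_fraction,
                 split_seed = split_seed,
                 model_specs = model_specs, benchmark = benchmark,
                 random = random, residual_ids = residual_ids),
            class = "study_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("Stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

develop_registry <- function(records, specs, random) {
  rows <- purrr::map(seq_len(nrow(specs)), function(i) {
    eq <- develop_equation(records, specs$response[i],
                           specs$predictors[[i]], random = random,
                           id = specs$id[i])
    attr(eq, "fit") <- NULL
    eq
  })
  dplyr::bind_rows(rows)
}

#' Run the full study-replica pipeline
#'
#' Executes the end-to-end internal-validation workflow: load or
#' generate trial records; summarise them; develop every configured
#' model form on the whole data; refit the same forms on the
#' development fraction of a trial-stratified split; validate the refits
#' on the held-out fraction; benchmark the literature registry on the
#' same held-out records; and export residual-versus-predicted series.
#' All outputs are written to `out_dir` as tab-separated tables plus a
#' `manifest.json` recording the effective configuration, seeds, record
#' counts and any per-equation benchmark errors. Outputs are
#' deterministic given the configuration.
#'
#' @param config A [study_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results: `records`,
#'   `summary`, `whole_data_equations`, `refit_equations`,
#'   `internal_validation`, `benchmark_validation`, `residuals`,
#'   `manifest`.
#' @export
run_study_replica <- function(config = study_config(), out_dir) {
  stopifnot(inherits(config, "study_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  records <- stage("data", {
    if (identical(config$data, "generate")) {
      generate_trial_data(config$generator)
    } else {
      read_trial_records(config$data)
    }
  })

  summary_tab <- stage("summarize", summarize_dataset(records))

  whole_eqs <- stage("develop",
                     develop_registry(records, config$model_specs,
                                      config$random))

  split <- stage("split",
                 split_trial_data(records, config$split_fraction,
                                  seed = config$split_seed))

  refit_specs <- config$model_specs
  refit_specs$id <- paste0(refit_specs$id, "'")
  refit_eqs <- stage("refit",
                     develop_registry(split$train, refit_specs,
                                      config$random))

  internal <- stage("validate", validate_equations(split$test, refit_eqs))
  bench <- stage("benchmark",
                 validate_equations(split$test, config$benchmark))

  resid_ids <- config$residual_ids %||%
    head(refit_eqs$id[refit_eqs$response == "ME"], 4)
  residuals <- if (length(resid_ids) == 0) {
    tibble(equation_id = character(), predicted = numeric(),
           residual = numeric())
  } else {
    stage("residuals",
          residual_plot_data(split$test, refit_eqs, id = resid_ids))
  }

  files <- c(summary = "summary.tsv",
             whole_data_equations = "equations_whole_data.tsv",
             refit_equations = "equations_refit.tsv",
             internal_validation = "validation_internal.tsv",
             benchmark_validation = "validation_benchmark.tsv",
             residuals = "residuals.tsv")
  writeLines(report_table(summary_tab, "summary"),
             file.path(out_dir, files["summary"]))
  writeLines(report_table(whole_eqs, "equations"),
             file.path(out_dir, files["whole_data_equations"]))
  writeLines(report_table(refit_eqs, "equations"),
             file.path(out_dir, files["refit_equations"]))
  writeLines(report_table(internal, "validation"),
             file.path(out_dir, files["internal_validation"]))
  writeLines(report_table(bench, "validation"),
             file.path(out_dir, files["benchmark_validation"]))
  writeLines(report_table(residuals, "residuals"),
             file.path(out_dir, files["residuals"]))

  manifest <- list(
    data = if (identical(config$data, "generate")) "generate"
           else as.character(config$data),
    generator_seed = if (identical(config$data, "generate"))
      config$generator$seed else NULL,
    split_fraction = config$split_fraction,
    split_seed = config$split_seed,
    n_records = nrow(records),
    n_train = nrow(split$train),
    n_test = nrow(split$test),
    n_model_specs = nrow(config$model_specs),
    random_candidates = config$random,
    benchmark_errors = stats::na.omit(bench$error),
    files = as.list(files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(records = records, summary = summary_tab,
                 whole_data_equations = whole_eqs,
                 refit_equations = refit_eqs,
                 internal_validation = internal,
                 benchmark_validation = bench,
                 residuals = residuals, manifest = manifest))
}

fmt <- function(x, digits) {
  ifelse(is.na(x), "", formatC(round(x, digits), format = "f",
                               digits = digits))
}

equation_text <- function(equations) {
  purrr::map_chr(seq_len(nrow(equations)), function(i) {
    eq <- equations[i, ]
    terms <- eq$terms[[1]]
    paste0(fmt(eq$intercept, 3),
           paste0(purrr::map_chr(seq_len(nrow(terms)), function(j) {
             cf <- terms$coefficient[j]
             paste0(ifelse(cf < 0, " - ", " + "), fmt(abs(cf), 3),
                    terms$predictor[j])
           }), collapse = ""))
  })
}

#' Format results as a report table
#'
#' Renders a result object as tab-separated text in the layout of the
#' corresponding published table: `"summary"` (variable, mean, SD, min,
#' max), `"equations"` (id, response, fitted equation, R^2, MPE),
#' `"validation"` (equation, response, predicted/actual means, MPE, SE,
#' R^2, Rc, then residual mean/SD/min/max) and `"residuals"` (equation,
#' predicted, residual). Display rounding: MPE and ratio-scale values to
#' 3 decimals, energy concentrations to 2.
#'
#' @param x A summary, registry, validation-report or residual tibble.
#' @param layout One of `"summary"`, `"equations"`, `"validation"`,
#'   `"residuals"`.
#' @return Character vector of tab-separated lines (header first).
#' @export
report_table <- function(x, layout = c("summary", "equations",
                                       "validation", "residuals")) {
  layout <- match.arg(layout)
  tsv <- function(df) {
    c(paste(names(df), collapse = "\t"),
      if (nrow(df)) apply(df, 1, function(r)
        paste(trimws(r), collapse = "\t")))
  }
  switch(layout,
    summary = {
      tsv(tibble(variable = x$variable,
                 mean = fmt(x$mean, 4), sd = fmt(x$sd, 4),
                 min = fmt(x$min, 4), max = fmt(x$max, 4)))
    },
    equations = {
      tsv(tibble(id = x$id, response = x$response,
                 equation = equation_text(x),
                 r2 = fmt(x$reported_r2, 3),
                 mpe = fmt(x$reported_mpe, 3)))
    },
    validation = {
      ratio <- grepl("/GE", x$response)
      mfmt <- function(v) ifelse(ratio, fmt(v, 3), fmt(v, 2))
      tsv(tibble(equation = x$equation_id, response = x$response,
                 predicted = mfmt(x$predicted_mean),
                 actual = mfmt(x$actual_mean),
                 mpe = fmt(x$mpe, 3), se = fmt(x$se, 3),
                 r2 = fmt(x$r2, 2), rc = fmt(x$rc, 2),
                 resid_mean = fmt(x$resid_mean, 3),
                 resid_sd = fmt(x$resid_sd, 3),
                 resid_min = fmt(x$resid_min, 3),
                 resid_max = fmt(x$resid_max, 3),
                 error = ifelse(is.na(x$error), "", x$error)))
    },
    residuals = {
      tsv(tibble(equation = x$equation_id,
                 predicted = fmt(x$predicted, 4),
                 residual = fmt(x$residual, 4)))
    })
}
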
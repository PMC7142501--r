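# Internal/external validation: data splitting, prediction-error
# statistics, concordance, residual summaries and report assembly.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Split trial records into development and validation subsets
#'
#' Random, reproducible partition of the dataset into a development
#' (train) and a validation (test) part. With trial stratification each
#' trial contributes its proportional share to the development set
#' (6 sheep at fraction 2/3 give 4 train / 2 test), preserving seasonal
#' balance between the subsets.
#'
#' @param records Data frame of trial records.
#' @param fraction Development-set fraction, in (0, 1); default 2/3.
#' @param seed Integer seed making the partition deterministic; the
#'   global RNG state is left untouched.
#' @param stratify_by_trial Stratify on `trial_id` (default `TRUE`).
#' @return A list with tibbles `train` and `test`; the two are disjoint
#'   and jointly exhaustive.
#' @export
split_trial_data <- function(records, fraction = 2/3, seed = NULL,
                             stratify_by_trial = TRUE) {
  records <- as_tibble(records)
  if (nrow(records) == 0) stop("No records to split.", call. = FALSE)
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    stop("`fraction` must lie strictly between 0 and 1.", call. = FALSE)
  }
  idx_train <- with_seed(seed, {
    if (stratify_by_trial) {
      if (!"trial_id" %in% names(records)) {
        stop("Stratified split requires a `trial_id` column.",
             call. = FALSE)
      }
      groups <- split(seq_len(nrow(records)), records$trial_id)
      sizes <- lengths(groups)
      if (any(sizes < 2)) {
        stop("Every trial must have at least 2 records for a stratified",
             " split.", call. = FALSE)
      }
      unlist(purrr::map(groups, function(ix) {
        k <- round(fraction * length(ix))
        k <- min(max(k, 1), length(ix) - 1)
        sample(ix, k)
      }), use.names = FALSE)
    } else {
      k <- round(fraction * nrow(records))
      k <- min(max(k, 1), nrow(records) - 1)
      sample(seq_len(nrow(records)), k)
    }
  })
  idx_train <- sort(idx_train)
  list(train = records[idx_train, ],
       test = records[setdiff(seq_len(nrow(records)), idx_train), ])
}

check_pa <- function(predicted, actual) {
  if (length(predicted) != length(actual)) {
    stop("`predicted` and `actual` must have equal length.", call. = FALSE)
  }
  if (length(predicted) == 0) {
    stop("Empty prediction/actual vectors.", call. = FALSE)
  }
  if (anyNA(predicted) || anyNA(actual)) {
    stop("Missing values in predicted/actual.", call. = FALSE)
  }
  invisible(NULL)
}

#' Mean square prediction error
#'
#' `MSPE = mean((P - A)^2)` over paired predicted and actual values.
#'
#' @param predicted,actual Numeric vectors of equal length.
#' @return MSPE, in squared response units.
#' @examples
#' mspe(c(1, 2), c(0, 0))
#' @export
mspe <- function(predicted, actual) {
  check_pa(predicted, actual)
  mean((predicted - actual)^2)
}

#' Mean prediction error
#'
#' The root of the mean square prediction error scaled by the mean
#' actual value: `MPE = sqrt(MSPE) / mean(A)`. Dimensionless, invariant
#' to rescaling both series by the same positive constant; typical
#' within-study values are 0.01-0.08.
#'
#' @inheritParams mspe
#' @return MPE (dimensionless).
#' @examples
#' mpe(c(11, 9), c(10, 10))
#' @export
mpe <- function(predicted, actual) {
  check_pa(predicted, actual)
  m <- mean(actual)
  if (m <= 0) {
    stop("MPE requires a strictly positive mean actual value.",
         call. = FALSE)
  }
  sqrt(mspe(predicted, actual)) / m
}

#' Lin's concordance correlation coefficient
#'
#' Agreement between predicted and actual values, penalising both
#' dispersion and location shifts:
#' `Rc = 2 cov(P, A) / (var(P) + var(A) + (mean(P) - mean(A))^2)`,
#' with population (1/n) moments. Always `|Rc| <= |r|` (Pearson), with
#' equality exactly when the two means and variances agree.
#'
#' @inheritParams mspe
#' @return Rc in \[-1, 1\].
#' @examples
#' lins_ccc(c(2, 3, 4), c(1, 2, 3))
#' @export
lins_ccc <- function(predicted, actual) {
  check_pa(predicted, actual)
  if (length(predicted) < 2) {
    stop("At least two pairs are required.", call. = FALSE)
  }
  n <- length(predicted)
  mp <- mean(predicted); ma <- mean(actual)
  vp <- mean((predicted - mp)^2)
  va <- mean((actual - ma)^2)
  cv <- mean((predicted - mp) * (actual - ma))
  denom <- vp + va + (mp - ma)^2
  if (denom == 0) {
    stop("Concordance is undefined: both series are constant with equal",
         " means.", call. = FALSE)
  }
  2 * cv / denom
}

#' Summary of signed residuals (predicted minus actual)
#'
#' @inheritParams mspe
#' @return Tibble with `mean`, `sd`, `min`, `max` of `P - A` (sample SD;
#'   0 for a single pair).
#' @export
residual_summary <- function(predicted, actual) {
  check_pa(predicted, actual)
  d <- predicted - actual
  tibble(mean = mean(d),
         sd = if (length(d) > 1) stats::sd(d) else 0,
         min = min(d), max = max(d))
}

actual_column <- function(response) {
  switch(response, "DE" = "de", "ME" = "me",
         "DE/GE" = "de_ge", "ME/GE" = "me_ge")
}

validate_one <- function(eq, records) {
  acol <- actual_column(eq$response)
  if (!acol %in% names(records) || anyNA(records[[acol]])) {
    stop("Records lack the actual response column '", acol,
         "' required to validate equation '", eq$id, "'.", call. = FALSE)
  }
  p <- evaluate_one(eq, records)
  a <- records[[acol]]
  rs <- residual_summary(p, a)
  d <- p - a
  tibble(equation_id = eq$id,
         response = eq$response,
         source = eq$source,
         n_test = length(a),
         predicted_mean = mean(p),
         actual_mean = mean(a),
         mpe = mpe(p, a),
         se = rs$sd / sqrt(length(d)),
         r2 = if (stats::sd(p) < 1e-12 || stats::sd(a) < 1e-12) 0
              else cor(p, a)^2,
         rc = lins_ccc(p, a),
         resid_mean = rs$mean, resid_sd = rs$sd,
         resid_min = rs$min, resid_max = rs$max,
         error = NA_character_)
}

#' Validate prediction equations against observed records
#'
#' Assembles one validation-report row per equation on a common test
#' set: predicted and actual means, mean prediction error, the standard
#' error of the paired differences, the squared predicted-actual
#' correlation, Lin's concordance, and the signed-residual summary.
#' Per-equation failures (e.g. a missing predictor) are collected in the
#' `error` column rather than aborting the benchmark, so a whole
#' registry can be scored in one call.
#'
#' @param records Data frame of test records carrying the predictors and
#'   the actual response of each equation.
#' @param equations Registry tibble or built-in name (a single-row
#'   registry validates one equation).
#' @return A validation-report tibble, one row per equation.
#' @examples
#' \donttest{
#' recs <- generate_trial_data(generator_config(seed = 1))
#' validate_equations(recs, "table8")
#' }
#' @export
validate_equations <- function(records, equations) {
  records <- as_tibble(records)
  equations <- as_registry(equations)
  purrr::map(seq_len(nrow(equations)), function(i) {
    eq <- equations[i, ]
    tryCatch(validate_one(eq, records), error = function(e) {
      tibble(equation_id = eq$id, response = eq$response,
             source = eq$source, n_test = nrow(records),
             predicted_mean = NA_real_, actual_mean = NA_real_,
             mpe = NA_real_, se = NA_real_, r2 = NA_real_, rc = NA_real_,
             resid_mean = NA_real_, resid_sd = NA_real_,
             resid_min = NA_real_, resid_max = NA_real_,
             error = conditionMessage(e))
    })
  }) |> list_rbind()
}

#' Average mean prediction error by response type
#'
#' Arithmetic mean of the per-equation MPE values within each response
#' (DE, ME, DE/GE, ME/GE), as used to compare equation families. The
#' `mpe_display` column applies the 3-decimal display rounding of the
#' report tables.
#'
#' @param reports A validation-report tibble (from [validate_equations()]
#'   or [reference_validation()]).
#' @return Tibble with `response`, `n_equations`, `mean_mpe`,
#'   `mpe_display`.
#' @examples
#' average_mpe_by_response(reference_validation("internal"))
#' @export
average_mpe_by_response <- function(reports) {
  if (nrow(reports) == 0) stop("No reports supplied.", call. = FALSE)
  reports |>
    filter(!is.na(.data$mpe)) |>
    group_by(.data$response) |>
    summarise(n_equations = dplyr::n(),
              mean_mpe = mean(.data$mpe), .groups = "drop") |>
    mutate(mpe_display = round(.data$mean_mpe, 3))
}

#' Residual-versus-predicted series for an equation
#'
#' The paired (predicted, predicted - actual) values underlying a
#' residual diagnostic plot. No fitting or smoothing is applied.
#'
#' @param records Test records.
#' @param equations Registry tibble or built-in name.
#' @param id Equation id within `equations` (required when the registry
#'   has several rows).
#' @return Tibble with columns `equation_id`, `predicted`, `residual`.
#' @export
residual_plot_data <- function(records, equations, id = NULL) {
  records <- as_tibble(records)
  equations <- as_registry(equations)
  if (!is.null(id)) equations <- equations[equations$id %in% id, ]
  if (nrow(equations) == 0) stop("No matching equation.", call. = FALSE)
  purrr::map(seq_len(nrow(equations)), function(i) {
    eq <- equations[i, ]
    acol <- actual_column(eq$response)
    p <- evaluate_one(eq, records)
    tibble(equation_id = eq$id, predicted = p,
           residual = p - records[[acol]])
  }) |> list_rbind()
}

#' Residual diagnostic plot for prediction equations
#'
#' Residual (predicted minus actual) against predicted values, one panel
#' per equation, with a zero reference line.
#'
#' @inheritParams residual_plot_data
#' @return A ggplot object.
#' @export
plot_residuals <- function(records, equations, id = NULL) {
  dat <- residual_plot_data(records, equations, id)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$predicted,
                                    y = .data$residual)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~equation_id, scales = "free_x") +
    ggplot2::labs(x = "Predicted energy concentration",
                  y = "Residual (predicted - actual)")
}
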
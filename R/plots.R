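# Plot methods.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Observed-versus-fitted plot for an energy model
#'
#' @param object An `energy_fit` object.
#' @param records The records the model was fitted to.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.energy_fit <- function(object, records, ...) {
  df <- fit_frame(records, object$response, object$predictors)
  X <- model.matrix(stats::as.formula(
    paste("~", if (length(object$predictors))
      paste(paste0("`", object$predictors, "`"), collapse = " + ")
      else "1")), df)
  dat <- tibble(observed = df$.y,
                fitted = as.vector(X %*% object$coefficients$estimate),
                season = df$.season)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$fitted, y = .data$observed,
                                    colour = .data$season)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = paste("Fitted", object$response),
                  y = paste("Observed", object$response),
                  colour = "Season")
}

#' Seasonal distribution plot of a trial dataset
#'
#' Boxplots of a chosen variable by season, a quick view of the
#' herbage-quality gradient a dataset carries.
#'
#' @param records Data frame of trial records.
#' @param variable Column to plot (default `"me"`).
#' @return A ggplot object.
#' @export
plot_seasonal_distribution <- function(records, variable = "me") {
  records <- as_tibble(records)
  if (!variable %in% names(records)) {
    stop("Unknown variable '", variable, "'.", call. = FALSE)
  }
  dat <- tibble(season = factor(records$season, levels = SEASONS),
                value = records[[variable]])
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$season, y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "Season", y = variable)
}
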
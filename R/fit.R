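# Equation development: linear models with trial-structure random
# intercepts fitted by residual maximum likelihood.
#
# Predictors are named in the registry vocabulary (DMD, N, GE, ...); the
# candidate random grouping factors are sheep, season and year. Fitting
# delegates to lme4; when every random term is dropped the restricted
# log-likelihood of the ordinary least-squares model is computed in closed
# form on lme4's deviance scale (identical to lme4::REMLcrit at zero
# variance), so nested deviance comparisons remain valid across the
# mixed/fixed boundary.

random_factor_columns <- c(sheep = "sheep_id", season = "season",
                           year = "year")

fit_frame <- function(records, response, predictors) {
  defs <- predictor_defaults()
  if (response %in% defs$predictor && response %in% predictors) {
    stop("Response cannot also be a predictor.", call. = FALSE)
  }
  if (anyDuplicated(predictors)) {
    stop("Predictor names must be unique.", call. = FALSE)
  }
  resp_col <- switch(response,
                     "DE" = "de", "ME" = "me",
                     "DE/GE" = "de_ge", "ME/GE" = "me_ge",
                     stop("Unknown response '", response, "'.",
                          call. = FALSE))
  idx <- match(predictors, defs$predictor)
  if (anyNA(idx)) {
    stop("Unknown predictor(s): ",
         paste(predictors[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  cols <- c(resp_col, defs$maps_to[idx])
  miss <- setdiff(c(cols, unname(random_factor_columns)), names(records))
  if (length(miss)) {
    stop("Records lack required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(records[cols])
  names(df) <- c(".y", predictors)
  df$.sheep <- factor(records$sheep_id)
  df$.season <- factor(records$season)
  df$.year <- factor(records$year)
  if (anyNA(df)) stop("Records contain missing values in the model",
                      " variables.", call. = FALSE)
  df
}

# -2 x restricted log-likelihood of an OLS fit, on lme4's REMLcrit scale.
reml_criterion_ols <- function(X, rss) {
  n <- nrow(X)
  p <- ncol(X)
  log(det(crossprod(X))) + (n - p) * (1 + log(2 * pi * rss / (n - p)))
}

check_design <- function(X, predictors) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("Design matrix is rank deficient; collinear term(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (nrow(X) <= ncol(X)) {
    stop("Too few observations for the number of fixed terms.",
         call. = FALSE)
  }
  invisible(X)
}

#' Fit an energy prediction model by REML
#'
#' Fits `response ~ predictors` as a linear model with random intercepts
#' for the requested trial-structure factors (any subset of `sheep`,
#' `season`, `year`), estimated by residual maximum likelihood. With an
#' empty random set the model is the ordinary least-squares fit and its
#' restricted deviance is computed in closed form on the same scale, so
#' [compare_random_structures()] can test any nested pair.
#'
#' @param records Data frame of trial records.
#' @param response `"DE"`, `"ME"`, `"DE/GE"` or `"ME/GE"`.
#' @param predictors Character vector of predictor names in the registry
#'   vocabulary (`DMD`, `OMD`, `DOMD`, `GED`, `N`, `GE`, `NDF`, `ADF`,
#'   `EE`, `Ash`, `DE`, `tdCP`, `tdNDF`, `CP`).
#' @param random Character vector, subset of
#'   `c("sheep", "season", "year")`; may be empty.
#' @return An object of class `energy_fit`: coefficient estimates with
#'   SEs and Wald statistics, variance components, residual variance,
#'   REML deviance, and R^2 (squared correlation of response and fitted
#'   values from the fixed effects).
#' @seealso [develop_equation()], [wald_test()],
#'   [compare_random_structures()]
#' @export
fit_reml <- function(records, response, predictors,
                     random = c("sheep", "season", "year")) {
  random <- unique(random)
  bad <- setdiff(random, names(random_factor_columns))
  if (length(bad)) {
    stop("Unknown random factor(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  df <- fit_frame(records, response, predictors)
  fixed_rhs <- if (length(predictors)) {
    paste(paste0("`", predictors, "`"), collapse = " + ")
  } else "1"
  X <- model.matrix(stats::as.formula(paste("~", fixed_rhs)), df)
  check_design(X, predictors)

  if (length(random) == 0) {
    fit <- lm(stats::as.formula(paste(".y ~", fixed_rhs)), data = df)
    est <- coef(fit)
    rss <- sum(resid(fit)^2)
    dfres <- nrow(df) - length(est)
    sigma2 <- rss / dfres
    se <- if (rss < 1e-12) rep(0, length(est)) else
      sqrt(diag(vcov(fit)))
    deviance <- reml_criterion_ols(X, max(rss, 1e-300))
    varcomp <- tibble(group = character(), variance = numeric())
    fitted_fixed <- as.vector(X %*% est)
    model <- fit
  } else {
    rand_rhs <- paste(sprintf("(1 | .%s)", random), collapse = " + ")
    form <- stats::as.formula(paste(".y ~", fixed_rhs, "+", rand_rhs))
    model <- lme4::lmer(form, data = df, REML = TRUE,
                        control = lme4::lmerControl(
                          optimizer = "bobyqa",
                          check.conv.singular = "ignore",
                          check.scaleX = "ignore",
                          check.nobs.vs.nlev = "ignore",
                          check.nobs.vs.nRE = "ignore"))
    est <- lme4::fixef(model)
    se <- sqrt(diag(as.matrix(vcov(model))))
    vc <- as.data.frame(lme4::VarCorr(model))
    sigma2 <- vc$vcov[vc$grp == "Residual"]
    varcomp <- tibble(group = sub("^\\.", "", vc$grp[vc$grp != "Residual"]),
                      variance = vc$vcov[vc$grp != "Residual"])
    varcomp <- varcomp[match(random, varcomp$group), ]
    deviance <- lme4::REMLcrit(model)
    fitted_fixed <- as.vector(X %*% est)
  }

  wald <- ifelse(se > 0, (est / se)^2, ifelse(est == 0, 0, Inf))
  y <- df$.y
  r2 <- if (stats::sd(fitted_fixed) < 1e-12 || stats::sd(y) < 1e-12) {
    if (all(abs(y - fitted_fixed) < 1e-12)) 1 else 0
  } else {
    cor(y, fitted_fixed)^2
  }

  structure(list(
    coefficients = tibble(
      term = c("(Intercept)", predictors),
      estimate = unname(est), se = unname(se),
      wald = unname(wald),
      p_value = unname(pchisq(wald, df = 1, lower.tail = FALSE))),
    varcomp = varcomp,
    sigma2 = sigma2,
    deviance = deviance,
    r2 = min(max(r2, 0), 1),
    n = nrow(df),
    response = response,
    predictors = predictors,
    random = random,
    model = model
  ), class = "energy_fit")
}

#' @export
print.energy_fit <- function(x, ...) {
  cat("Energy prediction model (REML): ", x$response, " ~ ",
      paste(x$predictors, collapse = " + "), "\n", sep = "")
  if (nrow(x$varcomp)) {
    cat("Random intercepts: ",
        paste(sprintf("%s (%.4g)", x$varcomp$group, x$varcomp$variance),
              collapse = ", "), "\n", sep = "")
  } else cat("No random terms (ordinary least squares)\n")
  cat(sprintf("n = %d, deviance = %.3f, residual variance = %.4g, R2 = %.3f\n",
              x$n, x$deviance, x$sigma2, x$r2))
  print(x$coefficients)
  invisible(x)
}

#' Tidy an energy model fit
#'
#' @param x An `energy_fit` object.
#' @param ... Unused.
#' @return Tibble with columns `term`, `estimate`, `se`, `wald`,
#'   `p_value`.
#' @export
tidy.energy_fit <- function(x, ...) x$coefficients

#' One-row summary of an energy model fit
#'
#' @param x An `energy_fit` object.
#' @param ... Unused.
#' @return Tibble with `r2`, `deviance`, `sigma2`, `n` and the retained
#'   random factors.
#' @export
glance.energy_fit <- function(x, ...) {
  tibble(r2 = x$r2, deviance = x$deviance, sigma2 = x$sigma2, n = x$n,
         random = paste(x$random, collapse = "+"))
}

#' Deviance comparison of nested random-effect structures
#'
#' Tests whether the random terms dropped from `full` to `reduced` are
#' supported: the change in REML deviance is referred to a chi-squared
#' distribution with degrees of freedom equal to the difference in the
#' number of variance components. Both fits must share the same fixed
#' model and data. The chi-squared reference ignores the
#' boundary-at-zero issue and is therefore conservative.
#'
#' @param full,reduced `energy_fit` objects; `reduced`'s random factors
#'   must be a subset of `full`'s.
#' @return Tibble with `statistic`, `df`, `p_value`.
#' @export
compare_random_structures <- function(full, reduced) {
  stopifnot(inherits(full, "energy_fit"), inherits(reduced, "energy_fit"))
  if (!identical(full$response, reduced$response) ||
      !identical(full$predictors, reduced$predictors) ||
      full$n != reduced$n) {
    stop("Fits must share the same fixed-effect model and data.",
         call. = FALSE)
  }
  if (!all(reduced$random %in% full$random)) {
    stop("`reduced`'s random factors must be nested in `full`'s.",
         call. = FALSE)
  }
  df <- length(full$random) - length(reduced$random)
  statistic <- max(reduced$deviance - full$deviance, 0)
  p <- if (df == 0) 1 else pchisq(statistic, df = df, lower.tail = FALSE)
  tibble(statistic = statistic, df = df, p_value = p)
}

#' Wald test of a fixed term
#'
#' The squared ratio of estimate to standard error, referred to a
#' chi-squared distribution with one degree of freedom.
#'
#' @param fit An `energy_fit` object.
#' @param term Term name (a predictor or `"(Intercept)"`).
#' @return Tibble with `term`, `statistic`, `p_value`.
#' @export
wald_test <- function(fit, term) {
  stopifnot(inherits(fit, "energy_fit"))
  i <- match(term, fit$coefficients$term)
  if (is.na(i)) {
    stop("Term '", term, "' is not in the fitted model.", call. = FALSE)
  }
  tibble(term = term,
         statistic = fit$coefficients$wald[i],
         p_value = fit$coefficients$p_value[i])
}

#' Develop a prediction equation with data-supported random structure
#'
#' Implements the study's equation-development procedure: fit with all
#' candidate random intercepts, then backward-eliminate each variance
#' component whose removal is not rejected by the nested deviance
#' chi-squared test at `alpha` (the least significant first), refit, and
#' package the fixed coefficients and SEs as a registry equation with
#' source `"refit"`.
#'
#' @inheritParams fit_reml
#' @param alpha Significance level for retaining a random component.
#' @param id Label for the returned equation.
#' @return A one-row registry tibble (see [energy_equation()]) carrying
#'   the final `energy_fit` in the attribute `"fit"`.
#' @export
develop_equation <- function(records, response, predictors,
                             random = c("sheep", "season", "year"),
                             alpha = 0.05, id = NULL) {
  remaining <- unique(random)
  fit <- fit_reml(records, response, predictors, remaining)
  while (length(remaining) > 0) {
    pvals <- vapply(remaining, function(fac) {
      red <- fit_reml(records, response, predictors,
                      setdiff(remaining, fac))
      compare_random_structures(fit, red)$p_value
    }, numeric(1))
    worst <- which.max(pvals)
    if (pvals[worst] < alpha) break
    remaining <- remaining[-worst]
    fit <- fit_reml(records, response, predictors, remaining)
  }
  cf <- fit$coefficients
  terms <- purrr::map(predictors, function(p) {
    j <- match(p, cf$term)
    equation_term(p, cf$estimate[j], cf$se[j])
  })
  eq <- energy_equation(
    id = id %||% paste0("refit:", gsub("/", "_", response), "~",
                        paste(predictors, collapse = "+")),
    response = response,
    intercept = cf$estimate[1], intercept_se = cf$se[1],
    terms = terms, source = "refit",
    reported_r2 = fit$r2)
  attr(eq, "fit") <- fit
  eq
}

#' Extract the model specifications encoded in a registry
#'
#' Turns each registry equation into the response/predictor set needed to
#' refit its form with [develop_equation()].
#'
#' @param equations Registry tibble or built-in name.
#' @return Tibble with columns `id`, `response` and a list column
#'   `predictors`.
#' @export
model_specs_from_registry <- function(equations) {
  equations <- as_registry(equations)
  tibble(id = equations$id,
         response = equations$response,
         predictors = purrr::map(equations$terms, ~ .x$predictor))
}
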
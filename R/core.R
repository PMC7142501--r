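# Core arithmetic on herbage composition, digestibility and energy.

#' Crude protein from nitrogen concentration
#'
#' Applies the conventional Kjeldahl factor: CP = 6.25 x N.
#'
#' @param n Nitrogen concentration, kg/kg DM (non-negative).
#' @return Crude protein concentration, kg/kg DM.
#' @examples
#' crude_protein_from_n(0.064)
#' @export
crude_protein_from_n <- function(n) {
  if (!is.numeric(n)) stop("`n` must be numeric.", call. = FALSE)
  if (any(n < 0, na.rm = TRUE)) {
    stop("Nitrogen concentration must be non-negative.", call. = FALSE)
  }
  6.25 * n
}

#' Digestible organic matter in dry matter from its components
#'
#' DOMD is digestible organic matter expressed per unit dry matter. Under
#' the idealisation that ash is completely indigestible and organic-matter
#' digestibility applies uniformly, DOMD = OMD x (1 - ash). On measured
#' data the identity holds only approximately; this constructor is used by
#' the synthetic generator and for consistency checks.
#'
#' @param omd Organic-matter digestibility, fraction in \[0, 1\].
#' @param ash Ash concentration, kg/kg DM in \[0, 1\].
#' @return DOMD, kg/kg.
#' @examples
#' domd_from_components(0.681, 0.062)
#' @export
domd_from_components <- function(omd, ash) {
  check_fraction(omd, "omd")
  check_fraction(ash, "ash")
  omd * (1 - ash)
}

#' Total digestible nutrient concentration
#'
#' Concentration times apparent digestibility, on the g/kg DM scale:
#' used for total digestible crude protein (tdCP) and total digestible
#' NDF (tdNDF) predictors.
#'
#' @param concentration Nutrient concentration, g/kg DM.
#' @param digestibility Apparent digestibility, fraction in \[0, 1\].
#' @return Total digestible concentration, g/kg DM.
#' @export
total_digestible <- function(concentration, digestibility) {
  if (any(concentration < 0, na.rm = TRUE)) {
    stop("`concentration` must be non-negative.", call. = FALSE)
  }
  check_fraction(digestibility, "digestibility")
  concentration * digestibility
}

check_fraction <- function(x, name) {
  if (any(x < 0 | x > 1, na.rm = TRUE)) {
    stop("`", name, "` must lie in [0, 1].", call. = FALSE)
  }
  invisible(x)
}

#' Fill in energy-to-gross-energy ratios
#'
#' Adds (or overwrites) the `de_ge` and `me_ge` columns, defined as DE/GE
#' and ME/GE on a per-record basis.
#'
#' @param records Data frame with `de`, `me` (MJ/kg DM) and `ge`
#'   (MJ/kg DM) columns.
#' @return The records as a tibble with `de_ge` and `me_ge` filled.
#' @export
derive_energy_ratios <- function(records) {
  records <- as_tibble(records)
  need <- setdiff(c("de", "me", "ge"), names(records))
  if (length(need)) {
    stop("Missing column(s): ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(records$ge <= 0, na.rm = TRUE)) {
    stop("Gross energy must be strictly positive.", call. = FALSE)
  }
  mutate(records, de_ge = .data$de / .data$ge, me_ge = .data$me / .data$ge)
}

#' Per-variable summary of a trial dataset
#'
#' Mean, sample (n - 1) SD, minimum and maximum for each numeric variable,
#' in the layout of a trial summary table.
#'
#' @param records Data frame of trial records (at least two rows).
#' @param variables Optional character vector of columns to summarise;
#'   defaults to every numeric column.
#' @return A tibble with columns `variable`, `mean`, `sd`, `min`, `max`.
#' @examples
#' recs <- tibble::tibble(de = c(8.03, 15.21))
#' summarize_dataset(recs)
#' @export
summarize_dataset <- function(records, variables = NULL) {
  records <- as_tibble(records)
  if (nrow(records) < 2) {
    stop("At least two records are required to summarise.", call. = FALSE)
  }
  if (is.null(variables)) {
    variables <- names(records)[vapply(records, is.numeric, logical(1))]
    variables <- setdiff(variables, "year")
  }
  miss <- setdiff(variables, names(records))
  if (length(miss)) {
    stop("Unknown variable(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  purrr::map(variables, function(v) {
    x <- records[[v]]
    tibble(variable = v, mean = mean(x), sd = stats::sd(x),
           min = min(x), max = max(x))
  }) |> list_rbind()
}

#' Max/min fold range of a variable
#'
#' The ratio of the maximum to the minimum observed value, used to express
#' seasonal spread (e.g. "the maximum DE was 1.9 times the minimum").
#'
#' @param records Data frame of trial records.
#' @param variable Column name.
#' @return A single ratio (dimensionless).
#' @examples
#' fold_range(tibble::tibble(de = c(8.03, 15.21)), "de")
#' @export
fold_range <- function(records, variable) {
  records <- as_tibble(records)
  if (!variable %in% names(records)) {
    stop("Unknown variable '", variable, "'.", call. = FALSE)
  }
  x <- records[[variable]]
  if (min(x) <= 0) {
    stop("Fold range requires a strictly positive minimum for '",
         variable, "'.", call. = FALSE)
  }
  max(x) / min(x)
}

# Invariant rules checked by validate_records(). Each rule returns a logical
# vector (TRUE = violated) over rows; rules referring to absent columns are
# skipped.
record_rules <- function() {
  frac_cols <- c("dm_fresh", "n", "ndf", "adf", "ee", "ash",
                 "dmd", "omd", "nd", "ndfd", "adfd", "ged", "domd")
  rules <- purrr::map(frac_cols, function(col) {
    list(field = col, rule = paste0(col, " in [0, 1]"), needs = col,
         check = function(r) r[[col]] < 0 | r[[col]] > 1)
  })
  c(rules, list(
    list(field = "ge", rule = "ge > 0", needs = "ge",
         check = function(r) r$ge <= 0),
    list(field = "me", rule = "0 < me <= de", needs = c("me", "de"),
         check = function(r) r$me <= 0 | r$me > r$de),
    list(field = "domd", rule = "domd <= omd", needs = c("domd", "omd"),
         check = function(r) r$domd > r$omd + 1e-9),
    list(field = "me_ge", rule = "me_ge <= de_ge <= 1",
         needs = c("me_ge", "de_ge"),
         check = function(r) r$me_ge > r$de_ge | r$de_ge > 1),
    list(field = "season", rule = "season is june/august/december",
         needs = "season",
         check = function(r) !(r$season %in% SEASONS))
  ))
}

#' Check trial records against their domain invariants
#'
#' Screens each record for violations of the physical and definitional
#' constraints of a digestibility trial: fractions within \[0, 1\],
#' positive gross energy, ME never exceeding DE, DOMD never exceeding OMD,
#' ME/GE <= DE/GE <= 1, and a recognised season label. Purely a reporting
#' operation: an empty result means every checked rule holds.
#'
#' @param records Data frame of trial records.
#' @return A tibble with columns `row`, `field`, `rule`; zero rows when
#'   all invariants hold.
#' @export
validate_records <- function(records) {
  records <- as_tibble(records)
  out <- purrr::map(record_rules(), function(rl) {
    if (!all(rl$needs %in% names(records))) return(NULL)
    bad <- rl$check(records)
    bad[is.na(bad)] <- FALSE
    if (!any(bad)) return(NULL)
    tibble(row = which(bad), field = rl$field, rule = rl$rule)
  }) |> list_rbind()
  if (nrow(out) == 0) {
    tibble(row = integer(), field = character(), rule = character())
  } else {
    arrange(out, .data$row, .data$field)
  }
}
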
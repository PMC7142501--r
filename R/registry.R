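# Prediction-equation registry: construction, evaluation, serialization.
#
# An equation is one row of a registry tibble:
#   id, response, response_unit, intercept, intercept_se,
#   terms (list column of tibbles: predictor, coefficient, se, unit,
#   maps_to), source, reported_r2, reported_mpe, note.
# `maps_to` is the trial-record column supplying the predictor value;
# values are converted from the column's storage unit to the term's unit
# before multiplying.

# Closed predictor vocabulary with default record column and unit.
predictor_defaults <- function() {
  tibble::tribble(
    ~predictor, ~maps_to, ~unit,
    "DMD",   "dmd",   "kg/kg",
    "OMD",   "omd",   "kg/kg",
    "DOMD",  "domd",  "kg/kg",
    "GED",   "ged",   "MJ/MJ",
    "N",     "n",     "kg/kg DM",
    "GE",    "ge",    "MJ/kg DM",
    "NDF",   "ndf",   "kg/kg DM",
    "ADF",   "adf",   "kg/kg DM",
    "EE",    "ee",    "kg/kg DM",
    "Ash",   "ash",   "kg/kg DM",
    "DE",    "de",    "MJ/kg DM",
    "tdCP",  "tdcp",  "g/kg DM",
    "tdNDF", "tdndf", "g/kg DM",
    "CP",    "cp",    "kg/kg DM"
  )
}

#' Construct a prediction-equation term
#'
#' @param predictor Predictor name from the closed vocabulary (`DMD`,
#'   `OMD`, `DOMD`, `GED`, `N`, `GE`, `NDF`, `ADF`, `EE`, `Ash`, `DE`,
#'   `tdCP`, `tdNDF`, `CP`).
#' @param coefficient,se Coefficient and its standard error.
#' @param unit Unit the predictor takes in this equation; defaults to the
#'   vocabulary default (fraction units).
#' @param maps_to Trial-record column supplying the value; defaults to
#'   the vocabulary default.
#' @return One-row tibble describing the term.
#' @export
equation_term <- function(predictor, coefficient, se = NA_real_,
                          unit = NULL, maps_to = NULL) {
  defs <- predictor_defaults()
  i <- match(predictor, defs$predictor)
  if (is.na(i)) {
    stop("Predictor '", predictor, "' is not in the closed vocabulary: ",
         paste(defs$predictor, collapse = ", "), call. = FALSE)
  }
  tibble(predictor = predictor,
         coefficient = coefficient,
         se = se,
         unit = unit %||% defs$unit[i],
         maps_to = maps_to %||% defs$maps_to[i])
}

#' Construct a linear prediction equation
#'
#' @param id Equation label (e.g. `"1a"`, `"2i"`, `"L"`, `"AQ"`).
#' @param response One of `"DE"`, `"ME"`, `"DE/GE"`, `"ME/GE"`.
#' @param intercept,intercept_se Intercept and its standard error.
#' @param terms A list of [equation_term()] rows (or a single bound
#'   tibble of terms).
#' @param source Provenance: `"this-study-whole-data"`,
#'   `"this-study-two-thirds"`, `"refit"`, or a literature citation key.
#' @param reported_r2,reported_mpe The R^2 / mean prediction error
#'   reported alongside the equation, if any.
#' @param note Free-text remark (unit resolution, transcription caveats).
#' @return A one-row registry tibble.
#' @export
energy_equation <- function(id, response, intercept, terms,
                            intercept_se = NA_real_,
                            source = "user",
                            reported_r2 = NA_real_,
                            reported_mpe = NA_real_,
                            note = NA_character_) {
  if (!response %in% c("DE", "ME", "DE/GE", "ME/GE")) {
    stop("Unknown response '", response, "'.", call. = FALSE)
  }
  if (is.data.frame(terms)) terms <- list(terms)
  terms <- dplyr::bind_rows(terms)
  if (anyDuplicated(terms$predictor)) {
    stop("Duplicate predictor in equation '", id, "'.", call. = FALSE)
  }
  tibble(id = id,
         response = response,
         response_unit = if (grepl("/GE", response)) "MJ/MJ" else "MJ/kg DM",
         intercept = intercept,
         intercept_se = intercept_se,
         terms = list(terms),
         source = source,
         reported_r2 = reported_r2,
         reported_mpe = reported_mpe,
         note = note)
}

#' Load a built-in equation registry
#'
#' The package ships the published equation sets of the source study as
#' frozen registries: `table2` (energy from a single digestibility
#' predictor), `table3` (digestibility plus chemical composition),
#' `table4` (ME from DE plus composition), `table5` (total digestible
#' nutrients), `table6` (the two-thirds-data refits A-AM used for
#' internal validation) and `table8` (thirteen literature equations
#' AN-AZ used for benchmarking). Coefficients are stored at full printed
#' precision; rows whose printed values carry known transcription caveats
#' say so in their `note`.
#'
#' @param name One of `"table2"`, `"table3"`, `"table4"`, `"table5"`,
#'   `"table6"`, `"table8"`.
#' @return A registry tibble (one row per equation).
#' @examples
#' load_builtin_registry("table4")
#' @export
load_builtin_registry <- function(name) {
  valid <- c("table2", "table3", "table4", "table5", "table6", "table8")
  if (length(name) != 1 || !name %in% valid) {
    stop("Unknown registry '", paste(name, collapse = ","),
         "'. Valid names: ", paste(valid, collapse = ", "), call. = FALSE)
  }
  if (is.null(the$builtins)) the$builtins <- builtin_registries()
  the$builtins[[name]]
}

term_value <- function(records, term, eq_id) {
  col <- term$maps_to
  if (!col %in% names(records)) {
    stop("Equation '", eq_id, "' requires predictor ", term$predictor,
         " (record column '", col, "'), which is absent.", call. = FALSE)
  }
  v <- records[[col]]
  if (anyNA(v)) {
    stop("Equation '", eq_id, "' requires predictor ", term$predictor,
         " but column '", col, "' has missing values.", call. = FALSE)
  }
  convert_predictor(v, column_units()[[col]], term$unit)
}

evaluate_one <- function(eq, records) {
  terms <- eq$terms[[1]]
  value <- rep(eq$intercept, nrow(records))
  for (i in seq_len(nrow(terms))) {
    value <- value + terms$coefficient[i] *
      term_value(records, terms[i, ], eq$id)
  }
  value
}

#' Evaluate prediction equations on trial records
#'
#' Computes `intercept + sum(coefficient x predictor)` for every record
#' and every equation, converting each predictor from its storage unit to
#' the unit the equation expects. Records lacking a required predictor
#' (missing column or missing values) raise an error naming it.
#'
#' @param records Data frame of trial records (internal units; see
#'   [read_trial_records()]).
#' @param equations A registry tibble ([energy_equation()] rows) or the
#'   name of a built-in registry.
#' @param id Optional equation id(s) to restrict to.
#' @return A tibble with one row per record x equation: `.row`,
#'   `equation_id`, `response`, `response_unit`, `predicted`.
#' @examples
#' predict_energy(reference_mean_record(), "table2", id = "1a")
#' @export
predict_energy <- function(records, equations, id = NULL) {
  records <- as_tibble(records)
  equations <- as_registry(equations)
  if (!is.null(id)) {
    miss <- setdiff(id, equations$id)
    if (length(miss)) {
      stop("Equation id(s) not in registry: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    equations <- equations[equations$id %in% id, ]
  }
  purrr::map(seq_len(nrow(equations)), function(i) {
    eq <- equations[i, ]
    tibble(.row = seq_len(nrow(records)),
           equation_id = eq$id,
           response = eq$response,
           response_unit = eq$response_unit,
           predicted = evaluate_one(eq, records))
  }) |> list_rbind()
}

as_registry <- function(equations) {
  if (is.character(equations)) return(load_builtin_registry(equations))
  if (!is.data.frame(equations) || !"terms" %in% names(equations)) {
    stop("`equations` must be a registry tibble or a built-in name.",
         call. = FALSE)
  }
  as_tibble(equations)
}

registry_fields <- c("id", "response", "response_unit", "intercept",
                     "intercept_se", "source", "reported_r2",
                     "reported_mpe", "note")
term_fields <- c("predictor", "coefficient", "se", "unit", "maps_to")

#' Serialize an equation registry to JSON text
#'
#' Lossless structured-text representation of a registry (coefficients,
#' SEs, units, provenance), with a stable field order so that identical
#' registries serialize to identical text. Round-trips through
#' [parse_registry()].
#'
#' @param equations Registry tibble or built-in name.
#' @return A JSON string.
#' @export
serialize_registry <- function(equations) {
  equations <- as_registry(equations)
  rows <- purrr::map(seq_len(nrow(equations)), function(i) {
    eq <- equations[i, ]
    row <- as.list(eq[registry_fields])
    row$terms <- purrr::map(seq_len(nrow(eq$terms[[1]])), function(j) {
      as.list(eq$terms[[1]][j, term_fields])
    })
    row
  })
  jsonlite::toJSON(rows, auto_unbox = TRUE, digits = NA, na = "null",
                   pretty = TRUE)
}

#' Parse an equation registry from JSON text
#'
#' @param text JSON produced by [serialize_registry()] or written by
#'   hand in the same dialect. Malformed documents (missing coefficients,
#'   unknown fields) raise an error naming the offending equation.
#' @return A registry tibble.
#' @export
parse_registry <- function(text) {
  rows <- tryCatch(jsonlite::fromJSON(text, simplifyVector = FALSE),
                   error = function(e) {
                     stop("Malformed registry document: ",
                          conditionMessage(e), call. = FALSE)
                   })
  purrr::map(seq_along(rows), function(i) {
    row <- rows[[i]]
    where <- paste0("registry entry ", i,
                    if (!is.null(row$id)) paste0(" ('", row$id, "')"))
    need <- c("id", "response", "intercept", "terms")
    miss <- setdiff(need, names(row))
    if (length(miss)) {
      stop("Malformed ", where, ": missing field(s) ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    terms <- purrr::map(row$terms, function(tm) {
      if (is.null(tm$predictor) || is.null(tm$coefficient)) {
        stop("Malformed ", where, ": a term lacks predictor/coefficient.",
             call. = FALSE)
      }
      equation_term(tm$predictor, as_num(tm$coefficient), as_num(tm$se),
                    unit = tm$unit, maps_to = tm$maps_to)
    })
    energy_equation(row$id, row$response,
                    intercept = as_num(row$intercept),
                    intercept_se = as_num(row$intercept_se),
                    terms = terms,
                    source = row$source %||% "user",
                    reported_r2 = as_num(row$reported_r2),
                    reported_mpe = as_num(row$reported_mpe),
                    note = row$note %||% NA_character_)
  }) |> list_rbind()
}

as_num <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)

#' Checksum of an equation registry
#'
#' MD5 hash of the canonical JSON serialization, used to assert that the
#' built-in registries are frozen.
#'
#' @param equations Registry tibble or built-in name.
#' @return A hex string.
#' @export
registry_checksum <- function(equations) {
  txt <- serialize_registry(equations)
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(txt, f, sep = "")
  unname(tools::md5sum(f))
}
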
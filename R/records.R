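# Trial-record schema, derived columns, delimited-text I/O and the
# built-in reference summary tables.

# Canonical CSV column -> internal column and unit. Internal storage is
# kg/kg (fractions) and MJ/kg DM (energies); files carry g/kg columns.
csv_schema <- function() {
  tibble::tribble(
    ~file_col,        ~col,        ~file_unit,     ~internal_unit,
    "dm_fresh_g_kg",  "dm_fresh",  "g/kg fresh",   "kg/kg fresh",
    "n_g_kg_dm",      "n",         "g/kg DM",      "kg/kg DM",
    "ndf_g_kg_dm",    "ndf",       "g/kg DM",      "kg/kg DM",
    "adf_g_kg_dm",    "adf",       "g/kg DM",      "kg/kg DM",
    "ee_g_kg_dm",     "ee",        "g/kg DM",      "kg/kg DM",
    "ash_g_kg_dm",    "ash",       "g/kg DM",      "kg/kg DM",
    "ge_mj_kg_dm",    "ge",        "MJ/kg DM",     "MJ/kg DM",
    "dmd",            "dmd",       "kg/kg",        "kg/kg",
    "omd",            "omd",       "kg/kg",        "kg/kg",
    "nd",             "nd",        "kg/kg",        "kg/kg",
    "ndfd",           "ndfd",      "kg/kg",        "kg/kg",
    "adfd",           "adfd",      "kg/kg",        "kg/kg",
    "ged",            "ged",       "MJ/MJ",        "MJ/MJ",
    "domd",           "domd",      "kg/kg",        "kg/kg",
    "de_mj_kg_dm",    "de",        "MJ/kg DM",     "MJ/kg DM",
    "me_mj_kg_dm",    "me",        "MJ/kg DM",     "MJ/kg DM"
  )
}

id_cols <- function() c("sheep_id", "trial_id", "season", "year")

#' Add derived nutrient and energy columns to trial records
#'
#' Fills `cp` (6.25 x N, kg/kg DM), `tdcp` and `tdndf` (concentration x
#' digestibility, g/kg DM) and the `de_ge`/`me_ge` ratios, wherever their
#' ingredient columns are present. Existing values are overwritten.
#'
#' @param records Data frame of trial records in internal units.
#' @return Tibble with derived columns added.
#' @export
add_derived_columns <- function(records) {
  records <- as_tibble(records)
  if ("n" %in% names(records)) {
    records$cp <- crude_protein_from_n(records$n)
  }
  if (all(c("n", "nd") %in% names(records))) {
    records$tdcp <- total_digestible(
      convert_predictor(records$n, "kg/kg DM", "g/kg DM"), records$nd)
  }
  if (all(c("ndf", "ndfd") %in% names(records))) {
    records$tdndf <- total_digestible(
      convert_predictor(records$ndf, "kg/kg DM", "g/kg DM"), records$ndfd)
  }
  if (all(c("de", "me", "ge") %in% names(records))) {
    records <- derive_energy_ratios(records)
  }
  records
}

#' Read digestibility-trial records from a delimited file
#'
#' Reads the canonical comma-separated schema (one row per sheep x trial,
#' header `sheep_id, trial_id, season, year, dm_fresh_g_kg, n_g_kg_dm,
#' ...`), converts the g/kg columns to the internal kg/kg convention and
#' adds the derived columns (`cp`, `tdcp`, `tdndf`, `de_ge`, `me_ge`).
#' Missing values are empty fields.
#'
#' @param path File path.
#' @param derive Add derived columns (default `TRUE`).
#' @return A tibble of trial records in internal units.
#' @seealso [write_trial_records()]
#' @export
read_trial_records <- function(path, derive = TRUE) {
  sch <- csv_schema()
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           sheep_id = readr::col_character(),
                           trial_id = readr::col_character(),
                           season = readr::col_character(),
                           year = readr::col_integer(),
                           .default = readr::col_double()))
  miss <- setdiff(id_cols(), names(raw))
  if (length(miss)) {
    stop("Input file lacks required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  out <- raw[intersect(id_cols(), names(raw))]
  for (i in seq_len(nrow(sch))) {
    fc <- sch$file_col[i]
    if (fc %in% names(raw)) {
      out[[sch$col[i]]] <- convert_predictor(raw[[fc]], sch$file_unit[i],
                                             sch$internal_unit[i])
    }
  }
  out <- as_tibble(out)
  if (derive) out <- add_derived_columns(out)
  out
}

#' Write digestibility-trial records to a delimited file
#'
#' Inverse of [read_trial_records()]: converts internal kg/kg storage back
#' to the g/kg file columns and writes comma-separated text. Derived
#' columns (`cp`, `tdcp`, `tdndf`, `de_ge`, `me_ge`) are not written; they
#' are recomputed on read.
#'
#' @param records Tibble of trial records in internal units.
#' @param path File path.
#' @return `records`, invisibly.
#' @export
write_trial_records <- function(records, path) {
  records <- as_tibble(records)
  sch <- csv_schema()
  out <- records[intersect(id_cols(), names(records))]
  for (i in seq_len(nrow(sch))) {
    cl <- sch$col[i]
    if (cl %in% names(records)) {
      out[[sch$file_col[i]]] <- convert_predictor(records[[cl]],
                                                  sch$internal_unit[i],
                                                  sch$file_unit[i])
    }
  }
  readr::write_csv(out, path, na = "")
  invisible(records)
}

extdata <- function(...) {
  system.file("extdata", ..., package = "herbenergy", mustWork = TRUE)
}

#' Reference dataset summary of the source digestibility study
#'
#' The printed per-variable summary (mean, SD, min, max over the 66
#' sheep x trial records of the 11-trial Qinghai-Tibet Plateau study) that
#' anchors the synthetic generator and the registry spot checks. Shipped
#' as plain text; the raw per-sheep data were never deposited.
#'
#' @param units `"printed"` returns the table in its published units
#'   (g/kg DM etc.); `"internal"` converts mean/SD/min/max to the package
#'   convention (kg/kg, MJ/kg DM).
#' @return Tibble with columns `variable`, `unit`, `mean`, `sd`, `min`,
#'   `max`.
#' @export
reference_summary <- function(units = c("internal", "printed")) {
  units <- match.arg(units)
  tab <- readr::read_tsv(extdata("reference_summary.tsv"),
                         show_col_types = FALSE)
  if (units == "printed") return(tab)
  targets <- column_units()
  for (i in seq_len(nrow(tab))) {
    to <- targets[[tab$variable[i]]]
    for (cl in c("mean", "sd", "min", "max")) {
      tab[[cl]][i] <- convert_predictor(tab[[cl]][i], tab$unit[i], to)
    }
    tab$unit[i] <- to
  }
  tab
}

#' Mean trial record of the reference study
#'
#' A single synthetic record holding every variable at the reference
#' summary mean (internal units), with derived predictors filled in. Used
#' to spot-check registry equations against published means.
#'
#' @return A one-row tibble of trial-record columns.
#' @export
reference_mean_record <- function() {
  tab <- reference_summary("internal")
  rec <- as_tibble(as.list(setNames(tab$mean, tab$variable)))
  rec <- tibble(sheep_id = "mean", trial_id = "reference",
                season = "august", year = 2013L) |>
    dplyr::bind_cols(rec)
  # keep the printed de_ge/me_ge/ged columns rather than re-deriving them:
  # the study reports them as independently measured
  derived <- add_derived_columns(rec[setdiff(names(rec),
                                             c("de_ge", "me_ge"))])
  derived$de_ge <- rec$de_ge
  derived$me_ge <- rec$me_ge
  derived
}

#' Published internal/external validation tables of the reference study
#'
#' The printed row-per-equation validation reports: `"internal"` holds the
#' study's own refit equations (A-AM) validated on the held-out third of
#' its data; `"literature"` holds the thirteen published equations
#' (AN-AZ) validated on the same held-out third. These printed rows are
#' inputs, e.g. for [average_mpe_by_response()].
#'
#' @param which `"internal"` or `"literature"`.
#' @return Tibble with columns `equation_id`, `response`,
#'   `predicted_mean`, `actual_mean`, `mpe`, `se`, `r2`, `rc`,
#'   `resid_mean`, `resid_sd`, `resid_min`, `resid_max` (plus `source`
#'   for the literature table).
#' @export
reference_validation <- function(which = c("internal", "literature")) {
  which <- match.arg(which)
  f <- if (which == "internal") "reference_validation_internal.tsv"
       else "reference_validation_literature.tsv"
  readr::read_tsv(extdata(f), show_col_types = FALSE)
}
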
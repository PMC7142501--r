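# Unit handling for predictors and record columns.
#
# Every quantity belongs to a unit family; conversions are exact linear
# rescalings and only defined within a family:
#   mass fraction of DM      : kg/kg DM, g/kg DM, % DM
#   mass fraction of fresh   : kg/kg fresh, g/kg fresh
#   digestibility coefficient: kg/kg, g/g, %
#   energy ratio             : MJ/MJ
#   energy density           : MJ/kg DM

unit_table <- function() {
  tibble::tribble(
    ~unit,          ~family,       ~scale,
    "kg/kg DM",     "mass_dm",     1,
    "g/kg DM",      "mass_dm",     1000,
    "% DM",         "mass_dm",     100,
    "kg/kg fresh",  "mass_fresh",  1,
    "g/kg fresh",   "mass_fresh",  1000,
    "kg/kg",        "digestibility", 1,
    "g/g",          "digestibility", 1,
    "%",            "digestibility", 100,
    "MJ/MJ",        "energy_ratio", 1,
    "MJ/kg DM",     "energy_density", 1
  )
}

unit_info <- function(unit) {
  tab <- unit_table()
  i <- match(unit, tab$unit)
  if (is.na(i)) {
    stop("Unknown unit '", unit, "'. Known units: ",
         paste(tab$unit, collapse = ", "), call. = FALSE)
  }
  tab[i, ]
}

#' Convert a predictor value between registered units
#'
#' Exact linear rescaling within a unit family (e.g. `g/kg DM` to
#' `kg/kg DM` or `% DM`). Conversion across families (say a mass fraction
#' to an energy density) is refused.
#'
#' @param value Numeric vector.
#' @param from,to Unit strings; see Details for the registered set.
#'
#' @details Registered units: `kg/kg DM`, `g/kg DM`, `% DM` (mass fractions
#'   of dry matter); `kg/kg fresh`, `g/kg fresh` (fractions of fresh
#'   weight); `kg/kg`, `g/g`, `%` (digestibility coefficients); `MJ/MJ`
#'   (energy ratios); `MJ/kg DM` (energy densities).
#'
#' @return `value` rescaled to `to`.
#' @examples
#' convert_predictor(64, "g/kg DM", "kg/kg DM")
#' convert_predictor(0.329, "kg/kg DM", "% DM")
#' @export
convert_predictor <- function(value, from, to) {
  fi <- unit_info(from)
  ti <- unit_info(to)
  if (fi$family != ti$family) {
    stop("No registered conversion from '", from, "' to '", to,
         "' (different unit families).", call. = FALSE)
  }
  value * ti$scale / fi$scale
}

# Internal storage units of trial-record columns.
column_units <- function() {
  c(dm_fresh = "kg/kg fresh",
    n = "kg/kg DM", ndf = "kg/kg DM", adf = "kg/kg DM",
    ee = "kg/kg DM", ash = "kg/kg DM", cp = "kg/kg DM",
    ge = "MJ/kg DM", de = "MJ/kg DM", me = "MJ/kg DM",
    dmd = "kg/kg", omd = "kg/kg", nd = "kg/kg", ndfd = "kg/kg",
    adfd = "kg/kg", domd = "kg/kg",
    ged = "MJ/MJ", de_ge = "MJ/MJ", me_ge = "MJ/MJ",
    tdcp = "g/kg DM", tdndf = "g/kg DM")
}
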
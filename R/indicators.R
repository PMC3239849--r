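#' The twelve neighbourhood gender-inequality indicators
#'
#' Returns the fixed catalogue of census indicators used throughout the
#' package: eleven sex-specific proportions and one mean value (average
#' employment income), grouped into five dimensions of gender inequality.
#' The catalogue drives the census column schema, scoring, and every
#' downstream report.
#'
#' Columns:
#' \describe{
#'   \item{indicator}{machine identifier, used as the column-name stem in
#'     census tables (e.g. \code{divorce_num_f}).}
#'   \item{label}{human-readable name as printed in report tables.}
#'   \item{dimension}{one of \code{demographic_household}, \code{education},
#'     \code{income}, \code{work_leisure}, \code{political}.}
#'   \item{kind}{\code{"proportion"} or \code{"mean_value"}; exactly one
#'     indicator (average employment income) is a mean value.}
#'   \item{age_floor}{minimum age of the indicator's census universe, in
#'     years (informational; denominators in the input are assumed to
#'     already embody it).}
#'   \item{requires_labour_force}{indicators undefined for neighbourhoods
#'     with nobody in the labour force (labour force participation and the
#'     employment rate); such DAs are excluded from these indicators only.}
#'   \item{sampling}{\code{"full"} for 100\%-sample demographic items,
#'     \code{"sample20"} for items collected from 20\% of households.}
#' }
#'
#' @return A 12-row tibble, one row per indicator.
#' @export
#' @examples
#' indicator_definitions()
indicator_definitions <- function() {
  tibble::tribble(
    ~indicator,        ~label,                       ~dimension,               ~kind,        ~age_floor, ~requires_labour_force, ~sampling,
    "divorce",         "Divorce",                    "demographic_household",  "proportion", 20L,        FALSE,                  "full",
    "single_headed",   "Single-headed households",   "demographic_household",  "proportion", NA_integer_, FALSE,                 "full",
    "university",      "University certification",   "education",              "proportion", 20L,        FALSE,                  "sample20",
    "no_high_school",  "No high school diploma",     "education",              "proportion", 20L,        FALSE,                  "sample20",
    "income",          "Average employment income",  "income",                 "mean_value", 15L,        FALSE,                  "sample20",
    "labour_force",    "Labour force participation", "work_leisure",           "proportion", 15L,        TRUE,                   "sample20",
    "employment_rate", "Employment rate",            "work_leisure",           "proportion", 15L,        TRUE,                   "sample20",
    "managerial",      "Managerial positions",       "work_leisure",           "proportion", 15L,        FALSE,                  "sample20",
    "elderly_care",    "Unpaid elderly care",        "work_leisure",           "proportion", 25L,        FALSE,                  "sample20",
    "child_care",      "Unpaid child care",          "work_leisure",           "proportion", 25L,        FALSE,                  "sample20",
    "housework",       "Unpaid housework",           "work_leisure",           "proportion", 25L,        FALSE,                  "sample20",
    "decision_making", "Decision-making positions",  "political",              "proportion", 15L,        FALSE,                  "sample20"
  )
}

#' @keywords internal
proportion_indicators <- function(definitions = indicator_definitions()) {
  definitions$indicator[definitions$kind == "proportion"]
}

# Resolve an indicator argument (name or one-row definition) to one row of
# the catalogue; errors on unknown names.
#' @keywords internal
resolve_indicator <- function(indicator, definitions = indicator_definitions()) {
  if (is.data.frame(indicator)) {
    stopifnot(nrow(indicator) == 1L)
    return(indicator)
  }
  row <- definitions[definitions$indicator == indicator, ]
  if (nrow(row) != 1L) {
    stop("unknown indicator: ", indicator, call. = FALSE)
  }
  row
}

#' Column names the census table must carry for an indicator
#' @keywords internal
indicator_columns <- function(ind, kind) {
  if (kind == "mean_value") {
    c("income_mean_f", "income_mean_m")
  } else {
    paste0(ind, c("_num_f", "_num_m", "_den_f", "_den_m"))
  }
}

#' Full census CSV column schema
#' @keywords internal
census_schema <- function(definitions = indicator_definitions()) {
  cols <- c("da_id", "area_type", "pop_f", "pop_m")
  for (i in seq_len(nrow(definitions))) {
    cols <- c(cols,
              indicator_columns(definitions$indicator[i], definitions$kind[i]))
  }
  unique(cols)
}
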
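#' Apply the global DA exclusion rules
#'
#' Removes dissemination areas that cannot be scored at all: DAs with
#' missing required fields, and DAs whose population is exclusively female
#' or male (no gender comparison is possible). DAs with nobody in the
#' labour force are retained but flagged, and are skipped only for the
#' indicators that require a labour force (labour force participation and
#' the employment rate).
#'
#' Flags are derived from the data, never trusted from the input:
#' \itemize{
#'   \item \emph{missing data}: any NA among fields required for a sex with
#'     nonzero population (sex-specific fields of an empty sex are
#'     structurally absent, not missing);
#'   \item \emph{single sex}: \code{pop_f == 0} or \code{pop_m == 0};
#'   \item \emph{zero labour force}: no labour-force members of either sex.
#' }
#' When a DA qualifies for both exclusion reasons, missing data takes
#' precedence, so the per-reason counts decompose deterministically.
#'
#' @param table Census table (schema of [generate_census()]).
#' @param definitions Indicator catalogue.
#' @return List with \code{retained} (the filtered table, plus a derived
#'   logical \code{zero_labour_force} column) and \code{log} (tibble of
#'   \code{da_id}, \code{reason} for every excluded DA).
#' @export
filter_das <- function(table, definitions = indicator_definitions()) {
  if (anyDuplicated(table$da_id)) {
    stop("input error: duplicate da_id values: ",
         paste(unique(table$da_id[duplicated(table$da_id)])[1:5],
               collapse = ", "), call. = FALSE)
  }
  n <- nrow(table)
  no_f <- is.na(table$pop_f) | table$pop_f == 0L
  no_m <- is.na(table$pop_m) | table$pop_m == 0L

  required_na <- is.na(table$pop_f) | is.na(table$pop_m)
  for (i in seq_len(nrow(definitions))) {
    cols <- indicator_columns(definitions$indicator[i], definitions$kind[i])
    fcols <- grep("_f$", cols, value = TRUE)
    mcols <- grep("_m$", cols, value = TRUE)
    f_na <- Reduce(`|`, lapply(table[fcols], is.na))
    m_na <- Reduce(`|`, lapply(table[mcols], is.na))
    required_na <- required_na | (f_na & !no_f) | (m_na & !no_m)
  }

  missing_flag <- required_na
  single_flag <- (no_f | no_m) & !missing_flag  # missing-data precedence

  log <- dplyr::bind_rows(
    tibble::tibble(da_id = table$da_id[missing_flag], reason = "missing_data"),
    tibble::tibble(da_id = table$da_id[single_flag], reason = "single_sex")
  )
  retained <- table[!(missing_flag | single_flag), , drop = FALSE]
  retained$zero_labour_force <-
    (retained$labour_force_num_f + retained$labour_force_num_m) == 0L
  stopifnot(nrow(retained) + nrow(log) == n)
  list(retained = retained, log = log)
}

#' Sex-specific proportion of an indicator in each DA
#'
#' @param table Census table (one or more rows).
#' @param indicator Indicator name or one-row definition; must be a
#'   proportion indicator.
#' @param sex \code{"female"} or \code{"male"}.
#' @return Numeric vector of numerator/denominator per DA; \code{NA} where
#'   the sex's denominator is zero (undefined proportion — the caller
#'   decides how to treat the cell).
#' @export
sex_proportion <- function(table, indicator, sex = c("female", "male")) {
  sex <- match.arg(sex)
  def <- resolve_indicator(indicator)
  if (def$kind != "proportion") {
    stop("sex_proportion is defined for proportion indicators only",
         call. = FALSE)
  }
  sfx <- if (sex == "female") "_f" else "_m"
  num <- table[[paste0(def$indicator, "_num", sfx)]]
  den <- table[[paste0(def$indicator, "_den", sfx)]]
  ifelse(!is.na(den) & den > 0, num / den, NA_real_)
}

#' Overall (both-sex) level of an indicator in each DA
#'
#' For proportion indicators, the combined proportion
#' (num_f + num_m)/(den_f + den_m); for average employment income, the
#' population-weighted mean of the two sex-specific mean incomes.
#'
#' @inheritParams sex_proportion
#' @return Numeric vector per DA; \code{NA} where undefined (zero combined
#'   denominator or population).
#' @export
overall_proportion <- function(table, indicator) {
  def <- resolve_indicator(indicator)
  if (def$kind == "mean_value") {
    pf <- table$pop_f
    pm <- table$pop_m
    tot <- pf + pm
    out <- (pf * table$income_mean_f + pm * table$income_mean_m) / tot
    # single-sex DAs: the overall mean is the present sex's mean
    out <- ifelse(pf == 0L, table$income_mean_m, out)
    out <- ifelse(pm == 0L, table$income_mean_f, out)
    ifelse(!is.na(tot) & tot > 0, out, NA_real_)
  } else {
    num <- table[[paste0(def$indicator, "_num_f")]] +
      table[[paste0(def$indicator, "_num_m")]]
    den <- table[[paste0(def$indicator, "_den_f")]] +
      table[[paste0(def$indicator, "_den_m")]]
    ifelse(!is.na(den) & den > 0, num / den, NA_real_)
  }
}
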
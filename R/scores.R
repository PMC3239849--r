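#' Gender inequality score
#'
#' The score of a neighbourhood-level indicator is
#' \deqn{s = f / (f + m)}
#' where \eqn{f} and \eqn{m} are the female and male values (sex-specific
#' proportions, or mean employment incomes in thousand CAD). A score of 0.5
#' is perfect gender equality; scores below 0.5 indicate male dominance and
#' above 0.5 female dominance, with larger deviations meaning more
#' inequality. When both values are exactly zero there is, by definition,
#' no gender difference, and the score is attributed as 0.5.
#'
#' @param female,male Nonnegative numeric vectors (recycled).
#' @return Numeric vector of scores in \[0, 1\].
#' @export
#' @examples
#' inequality_score(0.3, 0.3)   # equality
#' inequality_score(0, 0)       # attributed 0.5
#' inequality_score(0.112, 0.101)
inequality_score <- function(female, male) {
  if (any(female < 0, na.rm = TRUE) || any(male < 0, na.rm = TRUE)) {
    stop("domain error: inequality_score requires nonnegative values",
         call. = FALSE)
  }
  total <- female + male
  out <- ifelse(total > 0, female / total, 0.5)
  out[is.na(total)] <- NA_real_
  out
}

#' Score every eligible (DA, indicator) cell
#'
#' Computes the gender inequality score of each indicator in each DA of a
#' filtered census table. Labour-force indicators are skipped for DAs with
#' an empty labour force. Proportion cells where exactly one sex has a zero
#' denominator (its proportion is undefined while the other sex's is not)
#' emit no score and are logged; cells where both sex values are exactly
#' zero score 0.5 under the both-zero attribution. Income scores are
#' computed from the sex-specific mean incomes.
#'
#' @param table Filtered census table (see [filter_das()]).
#' @param definitions Indicator catalogue (subset to score fewer
#'   indicators).
#' @return Tidy tibble \code{(da_id, indicator, score,
#'   convention_applied)} with \code{convention_applied} in
#'   \code{c("none", "both_zero")}. Dropped cells are recorded in the
#'   \code{"dropped"} attribute as \code{(da_id, indicator, reason)}.
#' @export
score_table <- function(table, definitions = indicator_definitions()) {
  zero_lab <- if ("zero_labour_force" %in% names(table)) {
    table$zero_labour_force
  } else {
    (table$labour_force_num_f + table$labour_force_num_m) == 0L
  }

  pieces <- vector("list", nrow(definitions))
  dropped <- vector("list", nrow(definitions))
  for (i in seq_len(nrow(definitions))) {
    def <- definitions[i, ]
    ind <- def$indicator
    eligible <- rep(TRUE, nrow(table))
    if (def$requires_labour_force) {
      eligible <- eligible & !zero_lab
    }
    if (def$kind == "mean_value") {
      f <- table$income_mean_f
      m <- table$income_mean_m
      undef <- is.na(f) | is.na(m)
    } else {
      f <- sex_proportion(table, def, "female")
      m <- sex_proportion(table, def, "male")
      undef <- is.na(f) | is.na(m)
    }
    drop <- eligible & undef
    keep <- eligible & !undef
    s <- inequality_score(f[keep], m[keep])
    pieces[[i]] <- tibble::tibble(
      da_id = table$da_id[keep],
      indicator = ind,
      score = s,
      convention_applied = ifelse(f[keep] == 0 & m[keep] == 0,
                                  "both_zero", "none")
    )
    dropped[[i]] <- tibble::tibble(
      da_id = table$da_id[drop],
      indicator = ind,
      reason = "undefined_proportion"
    )
  }
  out <- dplyr::bind_rows(pieces)
  attr(out, "dropped") <- dplyr::bind_rows(dropped)
  out
}

#' Summarize score distributions per indicator
#'
#' Mean, standard deviation (n-1 denominator), median and quartiles of the
#' gender inequality scores of each indicator, as in a descriptive report
#' table. Quartiles use the median-unbiased linear-interpolation rule
#' (\code{stats::quantile} type 8) so interquartile ranges are reproducible
#' bit for bit.
#'
#' @param scores Tidy score table from [score_table()].
#' @return Tibble \code{(indicator, n_das, mean, sd, median, q1, q3)}; an
#'   empty indicator group is omitted with a warning.
#' @export
summarize_scores <- function(scores) {
  if (nrow(scores) == 0L) {
    warning("no scores to summarize")
    return(tibble::tibble(indicator = character(), n_das = integer(),
                          mean = double(), sd = double(), median = double(),
                          q1 = double(), q3 = double()))
  }
  scores |>
    dplyr::group_by(.data$indicator) |>
    dplyr::summarise(
      n_das = dplyr::n(),
      mean = mean(.data$score),
      sd = stats::sd(.data$score),
      median = stats::median(.data$score),
      q1 = stats::quantile(.data$score, 0.25, type = 8, names = FALSE),
      q3 = stats::quantile(.data$score, 0.75, type = 8, names = FALSE),
      .groups = "drop"
    )
}
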
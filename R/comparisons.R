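#' Kruskal-Wallis omnibus test
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square p-value on k-1 degrees
#' of freedom (via [stats::kruskal.test()]). The degenerate case where the
#' pooled data are constant carries no rank variation and is reported as
#' H = 0, p = 1.
#'
#' @param groups List of two or more nonempty numeric vectors.
#' @return List \code{(H, df, p)}.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("input error: need at least 2 groups", call. = FALSE)
  }
  if (any(vapply(groups, length, integer(1)) == 0L)) {
    stop("input error: empty group", call. = FALSE)
  }
  x <- unlist(groups, use.names = FALSE)
  if (length(x) < 3L) {
    stop("input error: total n must be at least 3", call. = FALSE)
  }
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(x)) == 1L) {
    return(list(H = 0, df = length(groups) - 1L, p = 1))
  }
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = unname(kt$p.value))
}

#' Pairwise Mann-Whitney U tests with Bonferroni adjustment
#'
#' All pairwise two-sided Mann-Whitney (Wilcoxon rank-sum) tests between
#' the groups, using the tie-corrected normal approximation without
#' continuity correction (appropriate at the thousands-of-DAs scale this
#' package targets). Adjusted p-values multiply the raw p by the number of
#' pairs, capped at 1. A pair whose pooled values are all tied has no rank
#' information and is reported with p = 1.
#'
#' @param groups Named list of numeric vectors (typically three area
#'   types).
#' @return Tibble \code{(group1, group2, U, p_raw, p_adj)} with \code{U}
#'   the statistic of \code{group1}.
#' @export
pairwise_mwu_bonferroni <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("input error: need at least 2 groups", call. = FALSE)
  }
  if (any(vapply(groups, length, integer(1)) == 0L)) {
    stop("input error: empty group", call. = FALSE)
  }
  nms <- names(groups)
  if (is.null(nms)) nms <- paste0("group", seq_along(groups))
  pairs <- utils::combn(seq_along(groups), 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    x <- groups[[i1]]; y <- groups[[i2]]
    if (length(unique(c(x, y))) == 1L) {
      U <- length(x) * length(y) / 2
      p <- 1
    } else {
      wt <- suppressWarnings(
        stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
      )
      U <- unname(wt$statistic)
      p <- unname(wt$p.value)
      if (is.nan(p)) p <- 1
    }
    tibble::tibble(group1 = nms[i1], group2 = nms[i2], U = U,
                   p_raw = p, p_adj = min(1, m * p))
  })
  dplyr::bind_rows(rows)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (ties share their mean rank).
#'
#' @param x,y Numeric vectors of equal length, at least 3.
#' @return Correlation in \[-1, 1\].
#' @export
spearman_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("input error: x and y must have equal length >= 3", call. = FALSE)
  }
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) {
    stop("input error: fewer than 3 complete pairs", call. = FALSE)
  }
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    stop("undefined correlation: constant input vector", call. = FALSE)
  }
  stats::cor(x, y, method = "spearman")
}

#' Indicators whose score is most correlated with its overall level
#'
#' Applies the |r| >= threshold gate used to pick indicators for tertile
#' stratification. The magnitude is compared because strong negative
#' correlations (e.g. income, unpaid housework) mark an indicator as
#' level-dependent just as strong positive ones do.
#'
#' @param correlations Named numeric vector of per-indicator Spearman r.
#' @param threshold Inclusive magnitude cutoff (default 0.4).
#' @return Character vector of selected indicator names.
#' @export
select_correlated_indicators <- function(correlations, threshold = 0.4) {
  sel <- !is.na(correlations) & abs(correlations) >= threshold
  names(correlations)[sel]
}

#' Population-weighted tertiles of the overall indicator level
#'
#' Sorts DAs by the overall (both-sex) level of the indicator, accumulates
#' population, and cuts at the DAs whose cumulative population first
#' reaches one third and two thirds of the total, so each stratum holds
#' about a third of the population (within one DA's population). A DA
#' straddling a cut goes to the lower tertile; ties in level are broken by
#' \code{da_id} for determinism. DAs with an undefined overall level are
#' excluded and logged in the \code{"excluded"} attribute.
#'
#' @param table Filtered census table (at least 3 eligible DAs).
#' @param indicator Indicator name or one-row definition.
#' @return Tibble \code{(da_id, indicator, tertile, overall_level)} with
#'   \code{tertile} an ordered factor low < intermediate < high;
#'   attributes \code{"boundaries"} (the two cut levels) and
#'   \code{"excluded"}.
#' @export
population_weighted_tertiles <- function(table, indicator) {
  def <- resolve_indicator(indicator)
  level <- overall_proportion(table, def)
  elig <- !is.na(level)
  if (def$requires_labour_force) {
    zl <- if ("zero_labour_force" %in% names(table)) {
      table$zero_labour_force
    } else {
      (table$labour_force_num_f + table$labour_force_num_m) == 0L
    }
    elig <- elig & !zl
  }
  excluded <- tibble::tibble(da_id = table$da_id[!elig],
                             reason = "undefined_overall_level")
  if (sum(elig) < 3L) {
    stop("cannot stratify: fewer than 3 DAs with a defined overall level",
         call. = FALSE)
  }
  tab <- table[elig, , drop = FALSE]
  level <- level[elig]
  ord <- order(level, tab$da_id)
  tab <- tab[ord, , drop = FALSE]
  level <- level[ord]
  pop <- tab$pop_f + tab$pop_m
  cum <- cumsum(as.numeric(pop))
  total <- cum[length(cum)]
  i1 <- which(cum >= total / 3)[1]
  i2 <- which(cum >= 2 * total / 3)[1]
  tertile <- rep("high", nrow(tab))
  tertile[seq_len(i2)] <- "intermediate"
  tertile[seq_len(i1)] <- "low"
  out <- tibble::tibble(
    da_id = tab$da_id,
    indicator = def$indicator,
    tertile = factor(tertile, levels = c("low", "intermediate", "high"),
                     ordered = TRUE),
    overall_level = level
  )
  attr(out, "boundaries") <- c(level[i1], level[i2])
  attr(out, "excluded") <- excluded
  out
}

#' Mean scores per tertile and area type, with per-area tests
#'
#' Crosses the population-weighted tertiles of one indicator with the
#' geographic area types: mean gender inequality score in each of the 3x3
#' cells, plus one Kruskal-Wallis p-value per area type comparing its
#' tertiles. An area with fewer than two nonempty tertiles carries no
#' contrast and is reported with NA p and a warning.
#'
#' @param scores Tidy score table restricted (or restrictable) to the
#'   indicator of the assignments.
#' @param assignments Output of [population_weighted_tertiles()].
#' @param table Census table supplying \code{da_id} to \code{area_type}.
#' @return List with \code{grid} (tibble \code{area_type}, \code{tertile},
#'   \code{n}, \code{mean_score}), \code{tests} (tibble \code{area_type},
#'   \code{H}, \code{p}) and \code{boundaries}.
#' @export
tertile_score_summary <- function(scores, assignments, table) {
  ind <- assignments$indicator[1]
  sc <- scores[scores$indicator == ind, c("da_id", "score")]
  df <- dplyr::inner_join(sc, assignments, by = "da_id") |>
    dplyr::inner_join(table[, c("da_id", "area_type")], by = "da_id")
  grid <- df |>
    dplyr::group_by(.data$area_type, .data$tertile) |>
    dplyr::summarise(n = dplyr::n(), mean_score = mean(.data$score),
                     .groups = "drop")
  tests <- lapply(split(df, df$area_type), function(d) {
    gs <- split(d$score, droplevels(d$tertile))
    gs <- gs[lengths(gs) > 0L]
    if (length(gs) < 2L) {
      warning("area ", d$area_type[1],
              ": fewer than 2 nonempty tertiles, Kruskal-Wallis skipped")
      return(tibble::tibble(area_type = d$area_type[1],
                            H = NA_real_, p = NA_real_))
    }
    kw <- kruskal_wallis(gs)
    tibble::tibble(area_type = d$area_type[1], H = kw$H, p = kw$p)
  })
  list(grid = grid, tests = dplyr::bind_rows(tests),
       boundaries = attr(assignments, "boundaries"))
}

#' Between-area comparison of gender inequality scores
#'
#' For each indicator: per-area-type sample size, mean and SD of the
#' scores; a Kruskal-Wallis omnibus test across the area types; and, where
#' the omnibus p falls below \code{alpha} (or always, when the gate is
#' disabled), all pairwise Mann-Whitney tests with Bonferroni adjustment.
#'
#' @param scores Tidy score table.
#' @param table Census table supplying \code{area_type}.
#' @param alpha Omnibus significance gate for pairwise testing.
#' @param gate_pairwise Set \code{FALSE} to run pairwise tests regardless
#'   of the omnibus result.
#' @return List of tibbles: \code{summary} \code{(indicator, area_type, n,
#'   mean, sd)}, \code{omnibus} \code{(indicator, H, df, p)},
#'   \code{pairwise} \code{(indicator, group1, group2, U, p_raw, p_adj)}.
#' @export
between_area_comparison <- function(scores, table, alpha = 0.05,
                                    gate_pairwise = TRUE) {
  df <- dplyr::inner_join(scores, table[, c("da_id", "area_type")],
                          by = "da_id")
  summary <- df |>
    dplyr::group_by(.data$indicator, .data$area_type) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$score),
                     sd = stats::sd(.data$score), .groups = "drop")
  omni <- list()
  pairw <- list()
  for (ind in unique(df$indicator)) {
    d <- df[df$indicator == ind, ]
    gs <- split(d$score, d$area_type)
    gs <- gs[lengths(gs) > 0L]
    if (length(gs) < 2L) next
    kw <- kruskal_wallis(gs)
    omni[[ind]] <- tibble::tibble(indicator = ind, H = kw$H, df = kw$df,
                                  p = kw$p)
    if (!gate_pairwise || kw$p < alpha) {
      pw <- pairwise_mwu_bonferroni(gs)
      pw$indicator <- ind
      pairw[[ind]] <- pw[, c("indicator", "group1", "group2", "U",
                             "p_raw", "p_adj")]
    }
  }
  list(summary = summary,
       omnibus = dplyr::bind_rows(omni),
       pairwise = dplyr::bind_rows(pairw))
}

#' Correlation of each indicator's score with its overall level
#'
#' Spearman correlation between the gender inequality score and the
#' overall (both-sex) level of the same indicator across DAs, together
#' with descriptive statistics of the overall level (percent for
#' proportion indicators, thousand CAD for income).
#'
#' @param scores Tidy score table.
#' @param table Filtered census table.
#' @param definitions Indicator catalogue.
#' @return Tibble \code{(indicator, n, overall_mean, overall_sd,
#'   overall_median, spearman_r)}; an indicator with constant scores or
#'   levels gets NA r with a warning.
#' @export
score_level_correlations <- function(scores, table,
                                     definitions = indicator_definitions()) {
  rows <- lapply(seq_len(nrow(definitions)), function(i) {
    def <- definitions[i, ]
    level <- overall_proportion(table, def)
    lv <- tibble::tibble(da_id = table$da_id, level = level)
    sc <- scores[scores$indicator == def$indicator, c("da_id", "score")]
    d <- dplyr::inner_join(sc, lv, by = "da_id")
    d <- d[!is.na(d$level), ]
    scale <- if (def$kind == "mean_value") 1 else 100
    r <- tryCatch(spearman_r(d$score, d$level), error = function(e) {
      warning("indicator ", def$indicator, ": ", conditionMessage(e))
      NA_real_
    })
    tibble::tibble(
      indicator = def$indicator,
      n = nrow(d),
      overall_mean = mean(d$level) * scale,
      overall_sd = stats::sd(d$level) * scale,
      overall_median = stats::median(d$level) * scale,
      spearman_r = r
    )
  })
  dplyr::bind_rows(rows)
}
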
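#' Read a DA census table from CSV
#'
#' Validates the documented schema (da_id, area_type, per-sex populations,
#' four count columns per proportion indicator, two income means); empty
#' cells become NA and are later treated as missing data by
#' [filter_das()]. Basic count consistency (nonnegative counts, numerator
#' not above denominator) is checked on read.
#'
#' @param path CSV path.
#' @param definitions Indicator catalogue.
#' @return Census tibble.
#' @export
read_census_csv <- function(path, definitions = indicator_definitions()) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  schema <- census_schema(definitions)
  missing_cols <- setdiff(schema, names(tab))
  if (length(missing_cols)) {
    stop("input error: census CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  count_cols <- setdiff(grep("^pop_|_num_|_den_", schema, value = TRUE),
                        c("income_mean_f", "income_mean_m"))
  for (cc in count_cols) tab[[cc]] <- as.integer(tab[[cc]])
  validate_census(tab, definitions)
  tab[, schema]
}

#' Write a DA census table to CSV
#'
#' @param table Census tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_census_csv <- function(table, path) {
  readr::write_csv(table, path, na = "")
  invisible(path)
}

#' @keywords internal
validate_census <- function(table, definitions = indicator_definitions()) {
  bad <- character()
  for (ind in proportion_indicators(definitions)) {
    for (sfx in c("_f", "_m")) {
      num <- table[[paste0(ind, "_num", sfx)]]
      den <- table[[paste0(ind, "_den", sfx)]]
      viol <- which(!is.na(num) & !is.na(den) & (num < 0 | den < 0 | num > den))
      if (length(viol)) {
        bad <- c(bad, sprintf("%s%s (rows %s)", ind, sfx,
                              paste(utils::head(viol, 3), collapse = ",")))
      }
    }
  }
  if (length(bad)) {
    stop("input error: inconsistent counts (numerator > denominator or negative) in: ",
         paste(bad, collapse = "; "), call. = FALSE)
  }
  invisible(table)
}

#' Format p-values the way report tables print them
#'
#' Raw p-values are kept in machine-readable CSVs; rendered tables use
#' threshold notation ("< 0.001", "< 0.01") below the cutoffs and two
#' decimals otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
format_pvalue <- function(p) {
  out <- sprintf("%.2f", p)
  out[p < 0.01] <- "< 0.01"
  out[p < 0.001] <- "< 0.001"
  out[is.na(p)] <- NA_character_
  out
}

#' Pipeline run configuration
#'
#' @param input \code{"synthetic"} to generate data with
#'   \code{generator}, or the path of a census CSV.
#' @param generator A [generator_config()] (synthetic input only).
#' @param replicates Monte Carlo null replicates per indicator (>= 19).
#' @param seed Master seed; stage substreams are spawned from it.
#' @param alpha Significance level for the pairwise-test gate.
#' @param r_threshold Magnitude cutoff of the score-level correlation gate
#'   for tertile stratification.
#' @param out_dir Output directory for all CSV artifacts (NULL: write
#'   nothing).
#' @return List of class \code{"run_config"}.
#' @export
run_config <- function(input = "synthetic",
                       generator = generator_config(),
                       replicates = 999L,
                       seed = 1L,
                       alpha = 0.05,
                       r_threshold = 0.4,
                       out_dir = NULL) {
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 19L) {
    stop("configuration error: replicates must be at least 19", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) {
    stop("configuration error: alpha must be in (0, 1)", call. = FALSE)
  }
  structure(list(input = input, generator = generator,
                 replicates = replicates, seed = as.integer(seed),
                 alpha = alpha, r_threshold = r_threshold,
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full neighbourhood gender-inequality pipeline
#'
#' Executes, in order: census input (synthetic generation or CSV read),
#' DA filtering, per-DA scoring, descriptive summaries, Monte Carlo
#' heterogeneity tests, between-area comparisons, score-level
#' correlations, and population-weighted tertile stratification for the
#' indicators passing the correlation gate. All stages draw from
#' independent substreams of the master seed, so the bundle is
#' reproducible bit for bit from the configuration alone.
#'
#' @param config A [run_config()].
#' @return List of class \code{"report_bundle"}: \code{census},
#'   \code{retained}, \code{exclusion_log}, \code{scores},
#'   \code{descriptives} (12-indicator table with sex-specific percentages
#'   and score summaries), \code{heterogeneity}, \code{between_area},
#'   \code{correlations}, \code{selected_indicators}, \code{tertiles}
#'   (per selected indicator: grid, tests, boundaries), and
#'   \code{manifest}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  defs <- indicator_definitions()
  set.seed(config$seed)
  stage_seeds <- sample.int(2147483646L, 2L)  # heterogeneity, spare

  census <- if (identical(config$input, "synthetic")) {
    generate_census(config$generator)
  } else {
    read_census_csv(config$input, defs)
  }
  message("census: ", nrow(census), " DAs")

  filt <- filter_das(census, defs)
  message("filter: retained ", nrow(filt$retained), ", excluded ",
          nrow(filt$log), " (",
          sum(filt$log$reason == "missing_data"), " missing data, ",
          sum(filt$log$reason == "single_sex"), " single sex); ",
          sum(filt$retained$zero_labour_force),
          " zero-labour DAs flagged for labour-force indicators")

  scores <- score_table(filt$retained, defs)
  descriptives <- build_descriptives(filt$retained, scores, defs)

  het <- heterogeneity_test_all(filt$retained, defs,
                                R = config$replicates,
                                seed = stage_seeds[1])
  descriptives <- dplyr::left_join(
    descriptives, het[, c("indicator", "p_value")], by = "indicator")

  between <- between_area_comparison(scores, filt$retained,
                                     alpha = config$alpha)
  correlations <- score_level_correlations(scores, filt$retained, defs)
  r <- stats::setNames(correlations$spearman_r, correlations$indicator)
  selected <- select_correlated_indicators(r, config$r_threshold)
  message("correlation gate |r| >= ", config$r_threshold, ": ",
          if (length(selected)) paste(selected, collapse = ", ") else "none")

  tertiles <- lapply(selected, function(ind) {
    assign <- population_weighted_tertiles(filt$retained, ind)
    tertile_score_summary(scores, assign, filt$retained)
  })
  names(tertiles) <- selected

  manifest <- c(
    sprintf("input: %s", if (identical(config$input, "synthetic"))
      "synthetic" else config$input),
    sprintf("n_das_input: %d", nrow(census)),
    sprintf("n_das_retained: %d", nrow(filt$retained)),
    sprintf("replicates: %d", config$replicates),
    sprintf("seed: %d", config$seed),
    sprintf("alpha: %g", config$alpha),
    sprintf("r_threshold: %g", config$r_threshold),
    if (identical(config$input, "synthetic"))
      sprintf("generator_seed: %d", config$generator$seed),
    sprintf("package_version: %s",
            as.character(utils::packageVersion("gendineq")))
  )

  bundle <- structure(
    list(census = census, retained = filt$retained,
         exclusion_log = filt$log, scores = scores,
         descriptives = descriptives, heterogeneity = het,
         between_area = between, correlations = correlations,
         selected_indicators = selected, tertiles = tertiles,
         manifest = manifest),
    class = "report_bundle"
  )
  if (!is.null(config$out_dir)) {
    write_bundle(bundle, config$out_dir)
  }
  bundle
}

# Descriptive table: sex-specific percentages (income in thousand CAD)
# plus score mean/SD/median/IQR per indicator.
#' @keywords internal
build_descriptives <- function(retained, scores, defs) {
  sex_rows <- lapply(seq_len(nrow(defs)), function(i) {
    def <- defs[i, ]
    if (def$kind == "mean_value") {
      f <- retained$income_mean_f
      m <- retained$income_mean_m
      scale <- 1
    } else {
      f <- sex_proportion(retained, def, "female")
      m <- sex_proportion(retained, def, "male")
      scale <- 100
    }
    tibble::tibble(
      indicator = def$indicator,
      female_mean = mean(f, na.rm = TRUE) * scale,
      female_sd = stats::sd(f, na.rm = TRUE) * scale,
      female_median = stats::median(f, na.rm = TRUE) * scale,
      male_mean = mean(m, na.rm = TRUE) * scale,
      male_sd = stats::sd(m, na.rm = TRUE) * scale,
      male_median = stats::median(m, na.rm = TRUE) * scale
    )
  })
  summ <- summarize_scores(scores)
  out <- dplyr::left_join(dplyr::bind_rows(sex_rows), summ, by = "indicator")
  # keep catalogue order
  out[match(defs$indicator, out$indicator), ]
}

#' Write every table of a report bundle as CSV
#'
#' Raw (unrounded) values go to the CSVs; a companion
#' \code{report_rendered.txt} prints the descriptive table with the
#' conventional rounding (scores to 2 decimals, percentages to 1,
#' threshold notation for p-values).
#'
#' @param bundle A \code{report_bundle}.
#' @param out_dir Directory (created if needed).
#' @return \code{out_dir}, invisibly.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, name) {
    readr::write_csv(x, file.path(out_dir, name), na = "")
  }
  w(bundle$exclusion_log, "exclusion_log.csv")
  w(bundle$scores, "scores.csv")
  w(bundle$descriptives, "descriptives.csv")
  w(bundle$heterogeneity, "heterogeneity.csv")
  w(bundle$between_area$summary, "between_area_summary.csv")
  w(bundle$between_area$omnibus, "between_area_omnibus.csv")
  if (nrow(bundle$between_area$pairwise)) {
    w(bundle$between_area$pairwise, "between_area_pairwise.csv")
  }
  w(bundle$correlations, "correlations.csv")
  if (length(bundle$tertiles)) {
    grids <- dplyr::bind_rows(
      lapply(names(bundle$tertiles), function(ind) {
        g <- bundle$tertiles[[ind]]$grid
        g$indicator <- ind
        b <- bundle$tertiles[[ind]]$boundaries
        g$boundary_low_intermediate <- b[1]
        g$boundary_intermediate_high <- b[2]
        g
      }))
    tests <- dplyr::bind_rows(
      lapply(names(bundle$tertiles), function(ind) {
        t <- bundle$tertiles[[ind]]$tests
        t$indicator <- ind
        t
      }))
    w(grids, "tertile_grid.csv")
    w(tests, "tertile_tests.csv")
  }
  writeLines(bundle$manifest, file.path(out_dir, "manifest.txt"))

  d <- bundle$descriptives
  rendered <- c(
    "Descriptive statistics and heterogeneity p-values by indicator",
    sprintf("%-16s %14s %14s %18s %10s %8s",
            "indicator", "female mean(SD)", "male mean(SD)",
            "score mean(SD)", "IQR", "P"),
    sprintf("%-16s %8.1f (%.1f) %8.1f (%.1f) %10.2f (%.2f) %5.2f-%.2f %8s",
            d$indicator, d$female_mean, d$female_sd, d$male_mean, d$male_sd,
            d$mean, d$sd, d$q1, d$q3, format_pvalue(d$p_value))
  )
  writeLines(rendered, file.path(out_dir, "report_rendered.txt"))
  invisible(out_dir)
}
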
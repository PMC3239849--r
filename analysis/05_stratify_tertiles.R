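#!/usr/bin/env Rscript
# Stage 5: population-weighted tertile stratification.
#
# Indicators whose score is most correlated with its own overall level
# (|r| >= 0.4) are stratified into population-weighted tertiles of that
# level; mean scores are reported per tertile and area type, with a
# Kruskal-Wallis test across tertiles within each area.

suppressPackageStartupMessages(library(gendineq))
dir.create("results", showWarnings = FALSE)

filt <- filter_das(read_census_csv("scratch/census.csv"))
scores <- score_table(filt$retained)
correl <- score_level_correlations(scores, filt$retained)
r <- stats::setNames(correl$spearman_r, correl$indicator)
selected <- select_correlated_indicators(r, 0.4)
cat("Correlation gate |r| >= 0.4 selects:",
    if (length(selected)) paste(selected, collapse = ", ") else "none", "\n")

grids <- list(); tests <- list()
for (ind in selected) {
  assign <- population_weighted_tertiles(filt$retained, ind)
  s <- tertile_score_summary(scores, assign, filt$retained)
  g <- s$grid
  g$indicator <- ind
  g$boundary_low_intermediate <- s$boundaries[1]
  g$boundary_intermediate_high <- s$boundaries[2]
  grids[[ind]] <- g
  t <- s$tests
  t$indicator <- ind
  tests[[ind]] <- t
  cat("\n", ind, " (tertile boundaries ",
      sprintf("%.3f / %.3f", s$boundaries[1], s$boundaries[2]), "):\n", sep = "")
  print(as.data.frame(tidyr::pivot_wider(s$grid[, c("area_type", "tertile", "mean_score")],
                                         names_from = "tertile",
                                         values_from = "mean_score")),
        digits = 3)
}
if (length(grids)) {
  readr::write_csv(dplyr::bind_rows(grids), "results/table_tertile_grid.csv")
  readr::write_csv(dplyr::bind_rows(tests), "results/table_tertile_tests.csv")
}
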
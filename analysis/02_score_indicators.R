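#!/usr/bin/env Rscript
# Stage 2: filter the DA universe and compute gender inequality scores.
#
# Applies the global exclusion rules (missing data, single-sex DAs), flags
# zero-labour-force DAs for the labour-force indicators, scores every
# eligible (DA, indicator) cell with female/(female+male), and writes the
# descriptive table (sex-specific percentages and score summaries).

suppressPackageStartupMessages(library(gendineq))
dir.create("results", showWarnings = FALSE)

census <- read_census_csv("scratch/census.csv")
filt <- filter_das(census)
readr::write_csv(filt$log, "results/exclusion_log.csv")

cat("Input DAs:", nrow(census), "\n")
cat("Excluded :", sum(filt$log$reason == "missing_data"), "missing data,",
    sum(filt$log$reason == "single_sex"), "single-sex\n")
cat("Retained :", nrow(filt$retained), "DAs;",
    sum(filt$retained$zero_labour_force),
    "flagged zero-labour (skipped for labour-force indicators)\n")

scores <- score_table(filt$retained)
readr::write_csv(summarize_scores(scores), "results/table_descriptives_scores.csv")

both_zero <- table(scores$indicator[scores$convention_applied == "both_zero"])
cat("\nBoth-zero cells attributed 0.5, by indicator:\n")
print(both_zero)

summ <- summarize_scores(scores)
male_dom <- summ$indicator[summ$mean < 0.48]
female_dom <- summ$indicator[summ$mean > 0.52]
cat("\nMale-dominant indicators (mean score < 0.48):",
    paste(male_dom, collapse = ", "), "\n")
cat("Female-dominant indicators (mean score > 0.52):",
    paste(female_dom, collapse = ", "), "\n")
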
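#!/usr/bin/env Rscript
# Stage 1: simulate the dissemination-area census.
#
# Builds a synthetic aggregate census at the scale of the 2001 Québec DA
# universe: 11,612 DAs of 400-700 residents across three area types, with
# sex-specific indicator rates at the observed provincial means, moderate
# between-DA heterogeneity, and the documented data pathologies (12 DAs
# with missing fields, 36 single-sex DAs, 15 DAs with no labour force).
# The full table is large and intermediate, so it goes to scratch/.

suppressPackageStartupMessages(library(gendineq))

cfg <- generator_config(
  n_das = 11612,
  n_missing = 12,
  n_single_sex = 36,
  n_zero_labour = 15,
  seed = 2001
)

census <- generate_census(cfg)
dir.create("scratch", showWarnings = FALSE)
write_census_csv(census, "scratch/census.csv")

cat("Simulated", nrow(census), "DAs ->", "scratch/census.csv\n")
cat("Area types:", paste(capture.output(table(census$area_type)), collapse = " "), "\n")
cat("Population range:",
    paste(range(census$pop_f + census$pop_m, na.rm = TRUE), collapse = "-"),
    "residents per DA\n")
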
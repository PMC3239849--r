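test_that("the indicator catalogue has the expected structure", {
  defs <- indicator_definitions()
  expect_equal(nrow(defs), 12L)
  expect_equal(sum(defs$kind == "mean_value"), 1L)
  expect_equal(defs$indicator[defs$kind == "mean_value"], "income")
  expect_setequal(defs$indicator[defs$requires_labour_force],
                  c("labour_force", "employment_rate"))
  expect_setequal(unique(defs$dimension),
                  c("demographic_household", "education", "income",
                    "work_leisure", "political"))
})

test_that("a table with no pathologies passes the filter unchanged", {
  cen <- small_census(n = 30, seed = 2)
  f <- filter_das(cen)
  expect_equal(nrow(f$retained), 30L)
  expect_equal(nrow(f$log), 0L)
  expect_false(any(f$retained$zero_labour_force))
})

test_that("exclusion reasons are exhaustive, exclusive, and correctly counted", {
  cen <- small_census(n = 100, seed = 9, n_missing = 5, n_single_sex = 7,
                      n_zero_labour = 4)
  f <- filter_das(cen)
  expect_equal(nrow(f$retained) + nrow(f$log), 100L)
  expect_equal(sum(f$log$reason == "missing_data"), 5L)
  expect_equal(sum(f$log$reason == "single_sex"), 7L)
  expect_equal(nrow(f$retained), 88L)
  expect_equal(sum(f$retained$zero_labour_force), 4L)
  expect_false(anyDuplicated(f$log$da_id) > 0)
})

test_that("missing-data precedence applies when a DA qualifies for both reasons", {
  cen <- small_census(n = 10, seed = 4)
  cen$pop_m[1] <- 0L  # single-sex ...
  mcols <- grep("(_num_m|_den_m)$", names(cen), value = TRUE)
  cen[1, mcols] <- 0L
  cen$income_mean_m[1] <- NA_real_
  cen$divorce_num_f[1] <- NA_integer_  # ... and missing a required female field
  f <- filter_das(cen)
  expect_equal(f$log$reason[f$log$da_id == cen$da_id[1]], "missing_data")
})

test_that("filtering is idempotent and zero-labour DAs stay in the table", {
  cen <- small_census(n = 40, seed = 12, n_missing = 2, n_single_sex = 2,
                      n_zero_labour = 3)
  f1 <- filter_das(cen)
  f2 <- filter_das(f1$retained)
  expect_identical(f1$retained, f2$retained)
  expect_equal(nrow(f2$log), 0L)
  # 40 - 4 excluded retained globally; labour-force indicators see 3 fewer
  expect_equal(nrow(f1$retained), 36L)
  scores <- score_table(f1$retained)
  expect_equal(sum(scores$indicator == "labour_force"), 33L)
  expect_equal(sum(scores$indicator == "divorce"), 36L)
})

test_that("duplicate DA identifiers are rejected", {
  cen <- small_census(n = 5, seed = 1)
  cen$da_id[2] <- cen$da_id[1]
  expect_error(filter_das(cen), "duplicate da_id")
})

test_that("sex-specific proportions are plain ratios, undefined at zero denominators", {
  tab <- tiny_table(num_f = c(10L, 0L, 57L), den_f = c(100L, 100L, 100L),
                    num_m = c(30L, 5L, 50L), den_m = c(100L, 100L, 0L))
  expect_equal(sex_proportion(tab, "divorce", "female"), c(0.10, 0.0, 0.57))
  expect_equal(sex_proportion(tab, "divorce", "male"), c(0.30, 0.05, NA))
  expect_error(sex_proportion(tab, "income", "female"), "proportion")
})

test_that("overall proportion is the combined ratio and sits between the sex proportions", {
  tab <- tiny_table(num_f = 10L, den_f = 100L, num_m = 30L, den_m = 100L)
  expect_equal(overall_proportion(tab, "divorce"), 0.20)

  # weighted-mean property on random mixed-sex tables
  set.seed(42)
  for (rep in 1:20) {
    den_f <- sample(10:200, 1)
    den_m <- sample(10:200, 1)
    tab <- tiny_table(num_f = rbinom(1, den_f, 0.4), den_f = den_f,
                      num_m = rbinom(1, den_m, 0.2), den_m = den_m)
    pf <- sex_proportion(tab, "divorce", "female")
    pm <- sex_proportion(tab, "divorce", "male")
    ov <- overall_proportion(tab, "divorce")
    expect_true(ov >= min(pf, pm) - 1e-12 && ov <= max(pf, pm) + 1e-12)
  }

  # equal sex proportions are invariant
  tab <- tiny_table(num_f = 20L, den_f = 100L, num_m = 10L, den_m = 50L)
  expect_equal(overall_proportion(tab, "divorce"), 0.2)
})

test_that("overall income is the population-weighted mean of the sex means", {
  tab <- tibble::tibble(da_id = "DA1", pop_f = 300L, pop_m = 300L,
                        income_mean_f = 20.0, income_mean_m = 30.0)
  expect_equal(overall_proportion(tab, "income"), 25.0)
  tab2 <- tibble::tibble(da_id = "DA1", pop_f = 100L, pop_m = 300L,
                         income_mean_f = 20.0, income_mean_m = 30.0)
  expect_equal(overall_proportion(tab2, "income"), 27.5)
})
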
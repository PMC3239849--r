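#' Default underlying sex-specific indicator rates
#'
#' Ground-truth female and male rates for the eleven proportion indicators,
#' anchored at the province-wide mean sex-specific percentages observed in
#' the 2001 Québec census aggregates (e.g. divorce 11.2\% vs 10.1\%, labour
#' force participation 57.0\% vs 69.8\%). These are the generator's
#' defaults; any subset can be overridden.
#'
#' @return Named list; each element is \code{c(p_female, p_male)}.
#' @export
default_sex_rates <- function() {
  list(
    divorce         = c(p_female = 0.112, p_male = 0.101),
    single_headed   = c(p_female = 0.137, p_male = 0.034),
    university      = c(p_female = 0.147, p_male = 0.165),
    no_high_school  = c(p_female = 0.311, p_male = 0.308),
    labour_force    = c(p_female = 0.570, p_male = 0.698),
    employment_rate = c(p_female = 0.933, p_male = 0.920),
    managerial      = c(p_female = 0.065, p_male = 0.114),
    elderly_care    = c(p_female = 0.081, p_male = 0.045),
    child_care      = c(p_female = 0.345, p_male = 0.257),
    housework       = c(p_female = 0.798, p_male = 0.591),
    decision_making = c(p_female = 0.023, p_male = 0.017)
  )
}

# Fraction of a sex's population in each indicator's denominator universe
# (age floors are embodied in the input denominators, so the generator only
# needs a plausible share per universe: >=15y, >=20y, >=25y, households,
# labour force members for the employment rate).
.age_universe_share <- c(
  divorce = 0.75, single_headed = 0.40, university = 0.75,
  no_high_school = 0.75, labour_force = 0.80, managerial = 0.80,
  elderly_care = 0.68, child_care = 0.68, housework = 0.68,
  decision_making = 0.80
)

#' Configuration for the synthetic census generator
#'
#' Bundles and validates every knob of [generate_census()]. Defaults
#' emulate Québec dissemination areas: populations of 400--700 residents,
#' three area types, sex-specific rates near the observed provincial means,
#' and 20\%-household sampling for the non-demographic items.
#'
#' @param n_das Number of dissemination areas to generate.
#' @param population_range Integer interval for DA total population
#'   (persons); lower bound must be at least 2.
#' @param area_type_shares Nonnegative weights over
#'   \code{c(metropolitan, mid_sized, rural)}, summing to 1.
#' @param sex_rates Named list of \code{c(p_female, p_male)} underlying
#'   rates per proportion indicator; entries override
#'   [default_sex_rates()].
#' @param heterogeneity_sd Between-DA standard deviation, on the logit
#'   scale, of the female rate of every proportion indicator. 0 gives the
#'   homogeneous-inequality null in which all score variation is sampling
#'   noise.
#' @param income_params Named numeric vector with elements \code{mean_f},
#'   \code{mean_m} (DA-level mean employment income per sex, thousand CAD),
#'   \code{sd_f}, \code{sd_m} (person-level income SDs, thousand CAD) and
#'   \code{sd_between} (additional between-DA SD of the sex-specific mean).
#'   \code{sd_between = 0} gives the income null.
#' @param n_missing Count of DAs emitted with absent (NA) required fields.
#' @param n_single_sex Count of DAs with an exclusively female or male
#'   population (alternating).
#' @param n_zero_labour Count of DAs with nobody in the labour force.
#' @param sampling_fraction_20pct Fraction in (0, 1] by which denominators
#'   of 20\%-sample items are shrunk before binomial draws, emulating the
#'   extra sampling noise of items collected from 20\% of households.
#' @param seed Integer seed; identical configuration and seed reproduce the
#'   census bit for bit.
#'
#' @return A validated list of class \code{"generator_config"}.
#' @export
#' @examples
#' cfg <- generator_config(n_das = 50, seed = 1)
#' census <- generate_census(cfg)
generator_config <- function(n_das = 1000L,
                             population_range = c(400L, 700L),
                             area_type_shares = c(metropolitan = 0.55,
                                                  mid_sized = 0.15,
                                                  rural = 0.30),
                             sex_rates = list(),
                             heterogeneity_sd = 0.3,
                             income_params = c(mean_f = 22.0, mean_m = 32.9,
                                               sd_f = 15.0, sd_m = 25.0,
                                               sd_between = 2.0),
                             n_missing = 0L,
                             n_single_sex = 0L,
                             n_zero_labour = 0L,
                             sampling_fraction_20pct = 0.2,
                             seed = 1L) {
  n_das <- as.integer(n_das)
  if (is.na(n_das) || n_das < 0L) {
    stop("configuration error: n_das must be a nonnegative count", call. = FALSE)
  }
  if (length(population_range) != 2L || any(is.na(population_range)) ||
      population_range[1] > population_range[2]) {
    stop("configuration error: population_range must be a valid interval",
         call. = FALSE)
  }
  if (population_range[1] < 2) {
    stop("configuration error: population_range lower bound must be >= 2",
         call. = FALSE)
  }
  if (length(area_type_shares) != 3L || any(area_type_shares < 0) ||
      abs(sum(area_type_shares) - 1) > 1e-9) {
    stop("configuration error: area_type_shares must be 3 nonnegative weights summing to 1",
         call. = FALSE)
  }
  rates <- utils::modifyList(default_sex_rates(), as.list(sex_rates))
  extra <- setdiff(names(rates), proportion_indicators())
  if (length(extra)) {
    stop("configuration error: sex_rates for unknown indicator(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  for (nm in names(rates)) {
    r <- rates[[nm]]
    if (length(r) != 2L || any(is.na(r)) || any(r < 0) || any(r > 1)) {
      stop("configuration error: sex_rates$", nm,
           " must be two probabilities in [0,1]", call. = FALSE)
    }
  }
  if (length(heterogeneity_sd) != 1L || is.na(heterogeneity_sd) ||
      heterogeneity_sd < 0) {
    stop("configuration error: heterogeneity_sd must be a nonnegative real",
         call. = FALSE)
  }
  need <- c("mean_f", "mean_m", "sd_f", "sd_m", "sd_between")
  if (!all(need %in% names(income_params)) ||
      any(income_params[c("sd_f", "sd_m", "sd_between")] < 0)) {
    stop("configuration error: income_params needs nonnegative ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  n_missing <- as.integer(n_missing)
  n_single_sex <- as.integer(n_single_sex)
  n_zero_labour <- as.integer(n_zero_labour)
  if (any(c(n_missing, n_single_sex, n_zero_labour) < 0L) ||
      n_missing + n_single_sex + n_zero_labour > n_das) {
    stop("configuration error: pathology counts (n_missing, n_single_sex, n_zero_labour) must be nonnegative and fit within n_das",
         call. = FALSE)
  }
  if (sampling_fraction_20pct <= 0 || sampling_fraction_20pct > 1) {
    stop("configuration error: sampling_fraction_20pct must be in (0, 1]",
         call. = FALSE)
  }
  structure(
    list(n_das = n_das,
         population_range = as.integer(population_range),
         area_type_shares = area_type_shares,
         sex_rates = rates,
         heterogeneity_sd = heterogeneity_sd,
         income_params = income_params,
         n_missing = n_missing,
         n_single_sex = n_single_sex,
         n_zero_labour = n_zero_labour,
         sampling_fraction_20pct = sampling_fraction_20pct,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

# DA-level female rate around the configured rate, logit-normal dispersion.
# Degenerate configured rates (0 or 1) stay fixed regardless of sd.
.disperse_rate <- function(p, sd, n) {
  if (sd == 0 || p <= 0 || p >= 1) {
    rep(p, n)
  } else {
    stats::plogis(stats::qlogis(p) + stats::rnorm(n, 0, sd))
  }
}

#' Generate a synthetic dissemination-area census table
#'
#' Draws a seeded table of DA-level aggregate counts. Total population is
#' uniform on the configured range and split between the sexes as
#' Binomial(pop, 1/2). For every proportion indicator, each sex's
#' denominator is the sex population scaled by the indicator's universe
#' share (and by \code{sampling_fraction_20pct} for 20\%-sample items), and
#' the numerator is Binomial(denominator, rate); the female rate varies
#' between DAs with logit-normal dispersion \code{heterogeneity_sd} while
#' the male rate stays fixed, so \code{heterogeneity_sd = 0} is the
#' homogeneous null. The employment-rate denominator is the labour-force
#' count. Per-sex mean incomes are Normal with between-DA and
#' within-DA (person-level, shrinking as 1/sqrt(pop)) components, truncated
#' at zero. The first \code{n_missing} DAs get NA required fields, the next
#' \code{n_single_sex} are single-sex, the next \code{n_zero_labour} have
#' an empty labour force.
#'
#' @param config A [generator_config()].
#' @return Tibble with one row per DA and the documented census schema
#'   (\code{da_id}, \code{area_type}, \code{pop_f}, \code{pop_m}, four
#'   count columns per proportion indicator, \code{income_mean_f},
#'   \code{income_mean_m}).
#' @export
generate_census <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_das
  defs <- indicator_definitions()
  set.seed(config$seed)

  pop <- sample(seq(config$population_range[1], config$population_range[2]),
                n, replace = TRUE)
  pop_f <- stats::rbinom(n, pop, 0.5)
  pop_m <- pop - pop_f

  idx_missing <- seq_len(config$n_missing)
  idx_single <- config$n_missing + seq_len(config$n_single_sex)
  idx_zero_lab <- config$n_missing + config$n_single_sex +
    seq_len(config$n_zero_labour)

  # single-sex DAs alternate female-only / male-only
  if (length(idx_single)) {
    female_only <- idx_single[seq_along(idx_single) %% 2L == 1L]
    male_only <- setdiff(idx_single, female_only)
    pop_f[male_only] <- 0L
    pop_m[male_only] <- pop[male_only]
    pop_m[female_only] <- 0L
    pop_f[female_only] <- pop[female_only]
  }

  tab <- tibble::tibble(
    da_id = sprintf("DA%06d", seq_len(n)),
    area_type = NA_character_,
    pop_f = as.integer(pop_f),
    pop_m = as.integer(pop_m)
  )

  frac20 <- config$sampling_fraction_20pct
  lf_num <- list()  # employment-rate denominators come from here
  for (i in seq_len(nrow(defs))) {
    ind <- defs$indicator[i]
    if (defs$kind[i] != "proportion") next
    rates <- config$sex_rates[[ind]]
    scale20 <- if (defs$sampling[i] == "sample20") frac20 else 1
    if (ind == "employment_rate") {
      den_f <- lf_num$f
      den_m <- lf_num$m
    } else {
      share <- .age_universe_share[[ind]]
      den_f <- as.integer(round(tab$pop_f * share * scale20))
      den_m <- as.integer(round(tab$pop_m * share * scale20))
    }
    rate_f <- .disperse_rate(rates[["p_female"]], config$heterogeneity_sd, n)
    num_f <- stats::rbinom(n, den_f, rate_f)
    num_m <- stats::rbinom(n, den_m, rates[["p_male"]])
    if (ind == "labour_force" && length(idx_zero_lab)) {
      num_f[idx_zero_lab] <- 0L
      num_m[idx_zero_lab] <- 0L
    }
    tab[[paste0(ind, "_num_f")]] <- as.integer(num_f)
    tab[[paste0(ind, "_num_m")]] <- as.integer(num_m)
    tab[[paste0(ind, "_den_f")]] <- as.integer(den_f)
    tab[[paste0(ind, "_den_m")]] <- as.integer(den_m)
    if (ind == "labour_force") {
      lf_num <- list(f = as.integer(num_f), m = as.integer(num_m))
    }
  }

  ip <- config$income_params
  sd_f_da <- sqrt(ip[["sd_between"]]^2 + ip[["sd_f"]]^2 / pmax(tab$pop_f, 1))
  sd_m_da <- sqrt(ip[["sd_between"]]^2 + ip[["sd_m"]]^2 / pmax(tab$pop_m, 1))
  tab$income_mean_f <- pmax(stats::rnorm(n, ip[["mean_f"]], sd_f_da), 0)
  tab$income_mean_m <- pmax(stats::rnorm(n, ip[["mean_m"]], sd_m_da), 0)

  # zero out the empty sex of single-sex DAs
  fcols <- grep("(_num_f|_den_f)$", names(tab), value = TRUE)
  mcols <- grep("(_num_m|_den_m)$", names(tab), value = TRUE)
  no_f <- tab$pop_f == 0L
  no_m <- tab$pop_m == 0L
  tab[no_f, fcols] <- 0L
  tab[no_m, mcols] <- 0L
  tab$income_mean_f[no_f] <- NA_real_
  tab$income_mean_m[no_m] <- NA_real_

  # missing-data DAs: absent fields, not zeros
  if (length(idx_missing)) {
    tab$no_high_school_num_f[idx_missing] <- NA_integer_
    tab$income_mean_m[idx_missing] <- NA_real_
  }

  area_seed <- sample.int(2147483646L, 1L)
  tab <- tab[, census_schema(defs)]
  assign_area_types(tab, config$area_type_shares, seed = area_seed)
}

#' Assign geographic area types to DAs
#'
#' Labels each DA independently as metropolitan, mid-sized city, or rural
#' with the given probabilities, so realized shares converge to the weights
#' as the table grows.
#'
#' @param table Census table (any tibble with one row per DA).
#' @param shares Three nonnegative weights over
#'   \code{c(metropolitan, mid_sized, rural)} summing to 1.
#' @param seed Integer seed for the assignment.
#' @return The table with its \code{area_type} column (re)filled.
#' @export
assign_area_types <- function(table, shares, seed = 1L) {
  if (length(shares) != 3L || any(shares < 0) || abs(sum(shares) - 1) > 1e-9) {
    stop("configuration error: area_type_shares must be 3 nonnegative weights summing to 1",
         call. = FALSE)
  }
  table$area_type <- character(nrow(table))
  if (nrow(table) == 0L) {
    return(table)
  }
  set.seed(seed)
  table$area_type <- sample(c("metropolitan", "mid_sized", "rural"),
                            nrow(table), replace = TRUE, prob = shares)
  table
}
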
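#' Pool null parameters for the homogeneous-inequality scenario
#'
#' Under the null hypothesis every DA shares the same underlying
#' sex-specific rates, and all between-DA variation in gender inequality
#' scores is sampling noise. For proportion indicators the pooled rates are
#' the ratio of summed numerators to summed denominators per sex across
#' all eligible DAs. For average employment income the pooled parameters
#' are the population-weighted mean of the DA sex means and the
#' person-level SD sigma estimated by
#' \eqn{\hat\sigma^2 = \sum_i n_i (\bar x_i - \hat\mu)^2 / (N - 1)},
#' which is unbiased when DA means are Normal(mu, sigma/sqrt(n_i)).
#'
#' @param table Filtered census table.
#' @param indicator Indicator name or one-row definition.
#' @return List of class \code{"null_params"}: \code{indicator},
#'   \code{kind}, and either \code{p_f}, \code{p_m} or \code{mu_f},
#'   \code{mu_m}, \code{sigma_f}, \code{sigma_m}; plus \code{da_id} of the
#'   eligible DAs.
#' @export
pooled_null_params <- function(table, indicator) {
  def <- resolve_indicator(indicator)
  elig <- .eligible_rows(table, def)
  if (sum(elig) < 2L) {
    stop("cannot test: fewer than 2 eligible DAs for indicator ",
         def$indicator, call. = FALSE)
  }
  tab <- table[elig, , drop = FALSE]
  if (def$kind == "mean_value") {
    mu_f <- stats::weighted.mean(tab$income_mean_f, tab$pop_f)
    mu_m <- stats::weighted.mean(tab$income_mean_m, tab$pop_m)
    n <- nrow(tab)
    sigma_f <- sqrt(sum(tab$pop_f * (tab$income_mean_f - mu_f)^2) / (n - 1))
    sigma_m <- sqrt(sum(tab$pop_m * (tab$income_mean_m - mu_m)^2) / (n - 1))
    structure(list(indicator = def$indicator, kind = def$kind,
                   mu_f = mu_f, mu_m = mu_m,
                   sigma_f = sigma_f, sigma_m = sigma_m,
                   da_id = tab$da_id),
              class = "null_params")
  } else {
    den_f <- sum(tab[[paste0(def$indicator, "_den_f")]])
    den_m <- sum(tab[[paste0(def$indicator, "_den_m")]])
    if (den_f == 0 || den_m == 0) {
      stop("cannot test: zero pooled denominator for indicator ",
           def$indicator, call. = FALSE)
    }
    structure(list(indicator = def$indicator, kind = def$kind,
                   p_f = sum(tab[[paste0(def$indicator, "_num_f")]]) / den_f,
                   p_m = sum(tab[[paste0(def$indicator, "_num_m")]]) / den_m,
                   da_id = tab$da_id),
              class = "null_params")
  }
}

# Rows of the table that contribute a score for this indicator: not
# zero-labour for labour-force indicators, and both sex values defined.
# Matches score_table's eligibility exactly so observed and null variances
# run on the same DA set.
.eligible_rows <- function(table, def) {
  elig <- rep(TRUE, nrow(table))
  if (def$requires_labour_force) {
    zl <- if ("zero_labour_force" %in% names(table)) {
      table$zero_labour_force
    } else {
      (table$labour_force_num_f + table$labour_force_num_m) == 0L
    }
    elig <- elig & !zl
  }
  if (def$kind == "mean_value") {
    elig & !is.na(table$income_mean_f) & !is.na(table$income_mean_m)
  } else {
    den_f <- table[[paste0(def$indicator, "_den_f")]]
    den_m <- table[[paste0(def$indicator, "_den_m")]]
    elig & !is.na(den_f) & !is.na(den_m) & den_f > 0 & den_m > 0
  }
}

#' Simulate one null replicate and return its score variance
#'
#' Redraws each eligible DA's counts under the pooled null — female and
#' male numerators as Binomial(denominator, pooled rate) for proportion
#' indicators, or sex mean incomes as Normal(pooled mean,
#' sigma/sqrt(population)) truncated at zero for income — scores the
#' simulated table with the same conventions as the observed data
#' (including the both-zero attribution of 0.5), and returns the sample
#' variance (n-1) of the simulated scores.
#'
#' @param params [pooled_null_params()] output.
#' @param table Filtered census table carrying the per-DA denominators.
#' @param seed Integer seed for this replicate.
#' @return Scalar variance of the simulated scores.
#' @export
simulate_null_replicate <- function(params, table, seed) {
  stopifnot(inherits(params, "null_params"))
  tab <- table[match(params$da_id, table$da_id), , drop = FALSE]
  set.seed(seed)
  n <- nrow(tab)
  if (params$kind == "mean_value") {
    f <- pmax(stats::rnorm(n, params$mu_f, params$sigma_f / sqrt(tab$pop_f)), 0)
    m <- pmax(stats::rnorm(n, params$mu_m, params$sigma_m / sqrt(tab$pop_m)), 0)
  } else {
    den_f <- tab[[paste0(params$indicator, "_den_f")]]
    den_m <- tab[[paste0(params$indicator, "_den_m")]]
    f <- stats::rbinom(n, den_f, params$p_f) / den_f
    m <- stats::rbinom(n, den_m, params$p_m) / den_m
  }
  stats::var(inequality_score(f, m))
}

#' Monte Carlo heterogeneity test for one indicator
#'
#' Tests whether the across-DA variance of an indicator's gender
#' inequality scores exceeds what sampling noise alone would produce if
#' inequality were homogeneous across neighbourhoods. The observed sample
#' variance of the DA scores is compared with \code{R} null replicate
#' variances from [simulate_null_replicate()], and the p-value uses the
#' add-one rule \eqn{p = (1 + \#\{null \ge observed\}) / (R + 1)}, so
#' \eqn{1/(R+1) \le p \le 1}.
#'
#' DAs are processed in \code{da_id} order and each replicate draws from
#' its own substream spawned from the master seed, so the result is
#' invariant to row order and reproducible bit for bit.
#'
#' @param table Filtered census table.
#' @param indicator Indicator name or one-row definition.
#' @param R Number of null replicates (at least 19; default 999).
#' @param seed Master seed.
#' @return Object of class \code{"heterogeneity_result"}: a list with
#'   \code{indicator}, \code{observed_variance}, \code{null_variances},
#'   \code{p_value}, \code{n_replicates}, \code{n_das}, \code{seed}.
#' @export
heterogeneity_pvalue <- function(table, indicator, R = 999L, seed = 1L) {
  R <- as.integer(R)
  if (is.na(R) || R < 19L) {
    stop("R must be at least 19", call. = FALSE)
  }
  def <- resolve_indicator(indicator)
  table <- table[order(table$da_id), , drop = FALSE]

  scores <- score_table(table, def)
  if (nrow(scores) < 2L) {
    stop("cannot test: fewer than 2 scored DAs for indicator ",
         def$indicator, call. = FALSE)
  }
  observed <- stats::var(scores$score)
  params <- pooled_null_params(table, def)

  set.seed(seed)
  replicate_seeds <- sample.int(2147483646L, R)
  null_vars <- vapply(replicate_seeds, simulate_null_replicate,
                      numeric(1), params = params, table = table)
  p <- (1 + sum(null_vars >= observed)) / (R + 1)
  structure(
    list(indicator = def$indicator,
         observed_variance = observed,
         null_variances = null_vars,
         p_value = p,
         n_replicates = R,
         n_das = nrow(scores),
         seed = as.integer(seed)),
    class = "heterogeneity_result"
  )
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat("Monte Carlo heterogeneity test —", x$indicator, "\n")
  cat(sprintf("  observed score variance: %.6g over %d DAs\n",
              x$observed_variance, x$n_das))
  cat(sprintf("  null replicates: %d (seed %d), mean null variance %.6g\n",
              x$n_replicates, x$seed, mean(x$null_variances)))
  cat(sprintf("  p-value (add-one rule): %.4g\n", x$p_value))
  invisible(x)
}

#' Heterogeneity tests for every indicator
#'
#' Runs [heterogeneity_pvalue()] for each indicator in the catalogue, with
#' an independent seed substream per indicator spawned from the master
#' seed.
#'
#' @param table Filtered census table.
#' @param definitions Indicator catalogue.
#' @param R Null replicates per indicator.
#' @param seed Master seed.
#' @return Tibble \code{(indicator, n_das, observed_variance, p_value,
#'   n_replicates, seed)}.
#' @export
heterogeneity_test_all <- function(table, definitions = indicator_definitions(),
                                   R = 999L, seed = 1L) {
  set.seed(seed)
  seeds <- sample.int(2147483646L, nrow(definitions))
  rows <- lapply(seq_len(nrow(definitions)), function(i) {
    res <- heterogeneity_pvalue(table, definitions[i, ], R = R, seed = seeds[i])
    tibble::tibble(indicator = res$indicator, n_das = res$n_das,
                   observed_variance = res$observed_variance,
                   p_value = res$p_value, n_replicates = res$n_replicates,
                   seed = res$seed)
  })
  dplyr::bind_rows(rows)
}
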
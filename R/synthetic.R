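#' Synthetic-input configuration
#'
#' Settings for the seeded generators that stand in for the external data
#' the model consumes: a single-year-age demographic projection, 10-year
#' age-band cancer incidence rates, and annual macroeconomic series. The
#' defaults emulate an upper-middle-income country over 2005-2070: ~45M
#' people growing 0.9%/yr with a median age drifting upward, a crude cancer
#' incidence around 180 per 100,000/yr concentrated at older ages, 4%
#' annual inflation and 3% real GDP growth.
#'
#' @param seed Integer seed (generators are deterministic given the
#'   config; the seed is recorded for manifests).
#' @param years Calendar span.
#' @param base_population Total population in the first year.
#' @param pop_growth Annual total-population growth rate.
#' @param mean_age0 Mean of the age distribution in the first year.
#' @param mean_age_drift Upward drift of the mean age (years per calendar
#'   year), emulating population aging.
#' @param age_sd Spread of the age distribution.
#' @param crude_incidence_per_100k Target crude annual incidence.
#' @param incidence_gradient Log-linear increase of the band rate per
#'   10-year age band.
#' @param inflation Constant annual inflation.
#' @param gdp_real_growth Constant real GDP growth.
#' @param base_gdp Nominal GDP in the first year (currency).
#' @return A list of class `"oncopolicy_synth_config"`.
#' @export
synthetic_config <- function(seed = 1L, years = 2005:2070,
                             base_population = 4.5e7, pop_growth = 0.009,
                             mean_age0 = 30, mean_age_drift = 0.25,
                             age_sd = 20,
                             crude_incidence_per_100k = 180,
                             incidence_gradient = 0.55,
                             inflation = 0.04, gdp_real_growth = 0.03,
                             base_gdp = 3.4e14) {
  structure(as.list(environment()), class = "oncopolicy_synth_config")
}

#' Synthetic demographic projection
#'
#' A smooth parametric age pyramid per calendar year: single-year ages
#' 0..100+ weighted by a gamma density whose mean drifts upward over time
#' (population aging), scaled to an exponentially growing annual total.
#' Population is constant within a calendar year. Deterministic given the
#' config.
#'
#' @param config An `"oncopolicy_synth_config"`.
#' @return Data frame `year, age, population`.
#' @export
make_demography <- function(config = synthetic_config()) {
  ages <- 0:100
  out <- lapply(seq_along(config$years), function(i) {
    y <- config$years[i]
    mu <- config$mean_age0 + config$mean_age_drift * (i - 1)
    shape <- (mu / config$age_sd)^2
    rate <- mu / config$age_sd^2
    w <- stats::dgamma(ages + 0.5, shape = shape, rate = rate)
    w[length(w)] <- w[length(w)] +
      stats::pgamma(100, shape = shape, rate = rate, lower.tail = FALSE)
    w <- w / sum(w)
    total <- config$base_population * (1 + config$pop_growth)^(i - 1)
    data.frame(year = y, age = ages, population = total * w)
  })
  do.call(rbind, out)
}

#' Synthetic age-band incidence schedule
#'
#' 10-year age-band annual incidence rates increasing log-linearly with
#' age (cancer being an age-related disease), scaled so the crude annual
#' incidence over the config's first-year pyramid matches the requested
#' rate. Deterministic given the config.
#'
#' @param config An `"oncopolicy_synth_config"`.
#' @return Data frame `band_start, band_end, rate_per_100k_year`.
#' @export
make_incidence <- function(config = synthetic_config()) {
  band_start <- seq(0, 100, by = 10)
  band_end <- c(seq(9, 99, by = 10), 100)
  raw <- exp(config$incidence_gradient * seq_along(band_start))
  demo <- make_demography(config)
  first <- demo[demo$year == config$years[1], ]
  band_of <- pmin(first$age %/% 10 + 1, length(band_start))
  band_pop <- tapply(first$population, band_of, sum)
  crude_raw <- sum(raw[as.integer(names(band_pop))] * band_pop) /
    sum(band_pop)
  rate <- raw * config$crude_incidence_per_100k / crude_raw
  data.frame(band_start = band_start, band_end = band_end,
             rate_per_100k_year = rate)
}

#' Synthetic macroeconomic series
#'
#' Constant-inflation, constant-real-growth annual series: inflation and
#' nominal GDP (growing at `(1 + inflation) * (1 + gdp_real_growth) - 1`).
#' Deterministic given the config.
#'
#' @param config An `"oncopolicy_synth_config"`.
#' @return Data frame `year, inflation, gdp`.
#' @export
make_macro <- function(config = synthetic_config()) {
  n <- length(config$years)
  nominal_growth <- (1 + config$inflation) * (1 + config$gdp_real_growth) - 1
  data.frame(year = config$years,
             inflation = rep(config$inflation, n),
             gdp = config$base_gdp * (1 + nominal_growth)^(seq_len(n) - 1))
}
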
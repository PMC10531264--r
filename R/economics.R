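#' Net present value
#'
#' Discounts a vector of annual flows at the given rate with the
#' end-of-period convention: the first flow is at `t = 0` (undiscounted).
#'
#' @param flows Numeric vector of annual flows.
#' @param rate Discount rate per year (> -1).
#' @return Scalar NPV.
#' @export
npv <- function(flows, rate) {
  if (rate <= -1) stop("rate must exceed -1")
  sum(flows / (1 + rate)^(seq_along(flows) - 1))
}

#' Compound annual growth rate between two years
#'
#' @param series Named numeric vector (names = years) or data frame with
#'   `year` and a value column.
#' @param year_a,year_b Endpoint years (both present in the series).
#' @param value Column name when `series` is a data frame.
#' @return Annual proportional growth rate
#'   `(v_b / v_a)^(1 / (year_b - year_a)) - 1`.
#' @examples
#' growth_rate(c("2022" = 68.4, "2040" = 92.4), 2022, 2040)
#' @export
growth_rate <- function(series, year_a, year_b, value = NULL) {
  if (is.data.frame(series)) {
    series <- stats::setNames(series[[value]], series$year)
  }
  ya <- as.character(year_a)
  yb <- as.character(year_b)
  if (!all(c(ya, yb) %in% names(series))) stop("both years must be in series")
  va <- series[[ya]]
  vb <- series[[yb]]
  if (va <= 0 || vb <= 0) stop("growth rate needs positive endpoints")
  (vb / va)^(1 / (year_b - year_a)) - 1
}

#' Elasticity of a scenario relative to the baseline
#'
#' The ratio of relative mortality-growth change to relative cost-growth
#' change: `(grMR_s / grMR_bl) / (grCE_s / grCE_bl)`.
#'
#' @param grMR_s,grMR_bl Mortality-rate growth, scenario and baseline.
#' @param grCE_s,grCE_bl Cost (share of GDP) growth, scenario and baseline.
#' @return Scalar elasticity.
#' @export
elasticity <- function(grMR_s, grMR_bl, grCE_s, grCE_bl) {
  if (grMR_bl == 0 || grCE_bl == 0 || grCE_s == 0) {
    stop("elasticity undefined: zero denominator")
  }
  (grMR_s / grMR_bl) / (grCE_s / grCE_bl)
}

#' Financing ratio of a scenario
#'
#' Relative difference between the discounted expenditure of a scenario and
#' the baseline: `FR = (NPV_s - NPV_bl) / NPV_bl`, with flows discounted at
#' the social discount rate.
#'
#' @param CE_s,CE_bl Equal-length annual expenditure flows.
#' @param rate Social discount rate (default 0.09).
#' @return Scalar financing ratio (0.10 means the scenario needs 10% more
#'   discounted funding than the baseline).
#' @export
financing_ratio <- function(CE_s, CE_bl, rate = 0.09) {
  if (length(CE_s) != length(CE_bl)) stop("flows must have equal length")
  nb <- npv(CE_bl, rate)
  if (nb == 0) stop("baseline NPV is zero")
  (npv(CE_s, rate) - nb) / nb
}

#' Internal rate of return of expenditure differences
#'
#' Finds the discount rate(s) zeroing the NPV of the savings flows
#' `Delta_CE_t = CE_baseline_t - CE_scenario_t` by bracketed root search on
#' `(-0.99, 10)`. Flows must change sign at least once, otherwise the IRR
#' is undefined and an error is raised. When the NPV polynomial has several
#' roots, all bracketed roots are reported and the smallest is returned as
#' `irr`.
#'
#' @param delta_flows Annual difference flows (investment negative, returns
#'   positive), first flow at `t = 0`.
#' @return List with `irr` (scalar) and `roots` (all bracketed roots).
#' @examples
#' irr(c(-100, 110))$irr  # 0.10
#' @export
irr <- function(delta_flows) {
  if (all(delta_flows >= 0) || all(delta_flows <= 0)) {
    stop("IRR undefined: flows never change sign")
  }
  f <- function(r) npv(delta_flows, r)
  grid <- c(seq(-0.99, 1, by = 0.01), seq(1.05, 10, by = 0.05))
  vals <- vapply(grid, f, numeric(1))
  sgn <- sign(vals)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  roots <- vapply(idx, function(i) {
    stats::uniroot(f, lower = grid[i], upper = grid[i + 1], tol = 1e-10)$root
  }, numeric(1))
  roots <- unique(c(roots, grid[vals == 0]))
  if (!length(roots)) stop("no IRR found in (-0.99, 10)")
  list(irr = min(roots), roots = sort(roots))
}

#' Economic summary of policy scenarios
#'
#' Compares simulated scenarios against the baseline over the analysis
#' horizons: annualised cancer expenditure as a share of GDP (CE) and
#' mortality per 100,000 (MR) per year, percentage changes at the horizon
#' years relative to the reference year, compound growth rates, elasticity
#' of each scenario versus the baseline, the NPV-based financing ratio per
#' horizon, and the IRR of the expenditure-difference flows per horizon
#' (reported as NA, with a note, when the flows never change sign).
#'
#' @param baseline An `"oncopolicy_sim"` for the baseline.
#' @param scenarios Named list of `"oncopolicy_sim"` objects.
#' @param ref_year Reference year for levels and growth (default 2022).
#' @param horizons Named list of horizon end years (default
#'   `list(h2030 = 2030, h2040 = 2040)`).
#' @param discount_rate Social discount rate (default 0.09).
#' @return An object of class `"oncopolicy_econ"`: list with `annual`
#'   (per-scenario annual CE/MR table), `impact` (levels, % changes,
#'   growth, elasticity) and `financial` (FR and IRR per horizon).
#' @export
summarize_economics <- function(baseline, scenarios, ref_year = 2022L,
                                horizons = list(h2030 = 2030L, h2040 = 2040L),
                                discount_rate = 0.09) {
  sims <- c(list(baseline = baseline), scenarios)
  ann <- lapply(sims, annualize)
  span <- ann[[1]]$year
  if (!all(vapply(ann, function(a) identical(a$year, span), logical(1)))) {
    stop("simulation spans are misaligned")
  }
  if (!ref_year %in% span) stop("reference year outside the simulated span")

  annual <- do.call(rbind, lapply(names(ann), function(nm) {
    cbind(scenario = nm, ann[[nm]][, c("year", "G", "X", "ce_gdp",
                                       "mortality_per_100k")])
  }))

  pick <- function(a, year, col) a[[col]][match(year, a$year)]
  impact <- do.call(rbind, lapply(names(ann), function(nm) {
    a <- ann[[nm]]
    rows <- lapply(names(horizons), function(h) {
      yr <- horizons[[h]]
      ce0 <- pick(a, ref_year, "ce_gdp")
      mr0 <- pick(a, ref_year, "mortality_per_100k")
      ce1 <- pick(a, yr, "ce_gdp")
      mr1 <- pick(a, yr, "mortality_per_100k")
      data.frame(scenario = nm, horizon = yr,
                 ce_gdp = ce1, mr_per_100k = mr1,
                 ce_pct_change = 100 * (ce1 / ce0 - 1),
                 mr_pct_change = 100 * (mr1 / mr0 - 1),
                 gr_ce = growth_rate(stats::setNames(a$ce_gdp, a$year),
                                     ref_year, yr),
                 gr_mr = growth_rate(stats::setNames(a$mortality_per_100k,
                                                     a$year), ref_year, yr))
    })
    do.call(rbind, rows)
  }))
  bl <- impact[impact$scenario == "baseline", ]
  impact$elasticity <- NA_real_
  for (i in seq_len(nrow(impact))) {
    b <- bl[bl$horizon == impact$horizon[i], ]
    impact$elasticity[i] <- tryCatch(
      elasticity(impact$gr_mr[i], b$gr_mr, impact$gr_ce[i], b$gr_ce),
      error = function(e) NA_real_)
  }

  abl <- ann[["baseline"]]
  financial <- do.call(rbind, lapply(setdiff(names(ann), "baseline"),
                                     function(nm) {
    a <- ann[[nm]]
    rows <- lapply(names(horizons), function(h) {
      yrs <- ref_year:horizons[[h]]
      ce_s <- pick(a, yrs, "G")
      ce_b <- pick(abl, yrs, "G")
      fr <- financing_ratio(ce_s, ce_b, discount_rate)
      delta <- ce_b - ce_s
      irr_val <- tryCatch(irr(delta)$irr, error = function(e) NA_real_)
      data.frame(scenario = nm, horizon = horizons[[h]],
                 financing_ratio = fr, irr = irr_val)
    })
    do.call(rbind, rows)
  }))

  structure(list(annual = annual, impact = impact, financial = financial,
                 ref_year = ref_year, discount_rate = discount_rate),
            class = "oncopolicy_econ")
}

#' @export
print.oncopolicy_econ <- function(x, ...) {
  cat("<oncopolicy_econ> reference year ", x$ref_year, ", discount rate ",
      100 * x$discount_rate, "%\n", sep = "")
  cat("\nImpact:\n")
  print(cbind(x$impact[, c("scenario", "horizon")],
              signif(x$impact[, c("ce_gdp", "mr_per_100k", "ce_pct_change",
                                  "mr_pct_change", "elasticity")], 4)),
        row.names = FALSE)
  cat("\nFinancial:\n")
  print(cbind(x$financial[, c("scenario", "horizon")],
              signif(x$financial[, c("financing_ratio", "irr")], 4)),
        row.names = FALSE)
  invisible(x)
}
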
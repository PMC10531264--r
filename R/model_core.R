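#' Empty disease state
#'
#' Creates the age-structured occupancy containers of the model: `N`, an
#' `n_ages x 4` matrix of undiagnosed patients by single-year age and stage,
#' and `D`, an `n_ages x 4 x 3` array of diagnosed patients by age, stage
#' and treatment tier. Ages run 0..100 with the last group absorbing (100+).
#'
#' @param n_ages Number of single-year age groups (default 101 = ages
#'   0..100+).
#' @return An object of class `"oncopolicy_state"`.
#' @export
disease_state <- function(n_ages = 101L) {
  structure(list(
    N = matrix(0, n_ages, 4, dimnames = list(NULL, paste0("s", 1:4))),
    D = array(0, c(n_ages, 4, 3),
              dimnames = list(NULL, paste0("s", 1:4), paste0("T", 1:3)))
  ), class = "oncopolicy_state")
}

state_total <- function(state) sum(state$N) + sum(state$D)

#' Marginal treatment-tier probabilities
#'
#' Converts the conditional tier-assignment probabilities under the
#' hierarchy T1 > T2 > T3 into marginal probabilities: a newly diagnosed
#' patient receives T1 with probability `lambda_T1`, otherwise T2 with
#' conditional probability `lambda_T2`, otherwise T3.
#'
#' @param lambda_T1,lambda_T2 Conditional probabilities in `[0, 1]`.
#' @return Named length-3 vector `(T1, T2, T3)` summing to 1.
#' @examples
#' assign_treatment(0.196, 0.260)  # published tier shares 19.6/20.9/59.5%
#' @export
assign_treatment <- function(lambda_T1, lambda_T2) {
  if (any(!is.finite(c(lambda_T1, lambda_T2))) ||
      lambda_T1 < 0 || lambda_T1 > 1 || lambda_T2 < 0 || lambda_T2 > 1) {
    stop("lambda values must lie in [0, 1]")
  }
  p1 <- lambda_T1
  p2 <- (1 - lambda_T1) * lambda_T2
  c(T1 = p1, T2 = p2, T3 = 1 - p1 - p2)
}

# 4 x 3 matrix of marginal tier probabilities per detection stage.
lambda_marginals <- function(lambda) {
  t(apply(lambda, 1, function(l) assign_treatment(l[1], l[2])))
}

#' Advance the disease state by one month
#'
#' Applies the model's process hierarchy in order: (1) recovery from
#' diagnosed compartments (`gamma`); (2) detection of undiagnosed patients
#' (`delta`; stage-IV undiagnosed are fully detected) with treatment-tier
#' assignment; (3) stage progression (`alphaU` undiagnosed, `alphaD`
#' diagnosed) and stage-IV death; (4) incidence inflow, split by the
#' very-early detection probability `delta_s0`. Patients detected this month
#' incur the diagnosis cost; treatment spending accrues on the end-of-month
#' diagnosed occupancy.
#'
#' @param state An `"oncopolicy_state"`.
#' @param params An `"oncopolicy_params"`.
#' @param inflow Per-age incident cases this month (scalar or length
#'   `n_ages`).
#' @param price_index Multiplier applied to all costs (inflation indexation;
#'   1 = 2012 prices).
#' @return A list with the updated `state` and the step outputs `R`
#'   (recovered), `X` (deaths), `G` (spending, currency) and
#'   `new_diagnoses`.
#' @export
step_state <- function(state, params, inflow, price_index = 1) {
  n_ages <- nrow(state$N)
  if (length(inflow) == 1L) inflow <- rep(inflow, n_ages)
  if (length(inflow) != n_ages) stop("inflow length must match the age grid")
  if (any(inflow < 0)) stop("inflow must be non-negative")
  N <- state$N
  D <- state$D

  # (1) recovery takes precedence over every other flow
  R <- 0
  for (k in 1:3) {
    Dk <- matrix(D[, , k], n_ages, 4)
    rec <- sweep(Dk, 2, params$gamma[, k], `*`)
    R <- R + sum(rec)
    D[, , k] <- Dk - rec
  }

  # (2) detection; undiagnosed stage IV is fully detected (Assumption 10)
  det <- cbind(N[, 1] * params$delta["s1"],
               N[, 2] * params$delta["s2"],
               N[, 3] * params$delta["s3"],
               N[, 4])
  N[, 1:3] <- sweep(N[, 1:3, drop = FALSE], 2,
                    1 - params$delta[c("s1", "s2", "s3")], `*`)
  N[, 4] <- 0
  lm <- lambda_marginals(params$lambda)

  # (3) progression / death among the non-recovered, non-detected; patients
  # detected this month enter their compartments afterwards, so they first
  # recover/progress/die the month after diagnosis
  for (s in 3:1) {
    move <- N[, s] * params$alphaU[s]
    N[, s] <- N[, s] - move
    N[, s + 1] <- N[, s + 1] + move
  }
  X <- 0
  for (k in 1:3) {
    for (s in 3:1) {
      move <- D[, s, k] * params$alphaD[s, k]
      D[, s, k] <- D[, s, k] - move
      D[, s + 1, k] <- D[, s + 1, k] + move
    }
    die <- D[, 4, k] * params$alphaD[4, k]
    D[, 4, k] <- D[, 4, k] - die
    X <- X + sum(die)
  }
  for (s in 1:4) for (k in 1:3) D[, s, k] <- D[, s, k] + det[, s] * lm[s, k]

  # (4) incidence inflow with very-early detection split
  early <- inflow * params$delta["s0"]
  N[, 1] <- N[, 1] + inflow - early
  for (k in 1:3) D[, 1, k] <- D[, 1, k] + early * lm[1, k]

  if (min(N) < -1e-9 || min(D) < -1e-9) {
    stop("internal error: negative occupancy after update")
  }
  new_diag <- sum(det) + sum(early)
  state$N <- N
  state$D <- D
  G <- spending(state, params, new_diagnoses = new_diag,
                price_index = price_index)
  list(state = state, R = R, X = X, G = G, new_diagnoses = new_diag)
}

#' Monthly spending for a disease state
#'
#' Treatment spending is the diagnosed occupancy weighted by the per
#' stage/tier monthly cost, corrected by `epsilon` (the factor mapping
#' breast-cancer-derived costs to the all-cancer average) and indexed to
#' current prices; each new diagnosis additionally incurs the diagnosis cost
#' `C_diag` (not epsilon-corrected, being an all-cancer average already).
#'
#' @inheritParams step_state
#' @param new_diagnoses Number of diagnosis events this month.
#' @return Spending in currency units.
#' @export
spending <- function(state, params, new_diagnoses = 0, price_index = 1) {
  if (new_diagnoses < 0 || price_index < 0) stop("inputs must be non-negative")
  occ <- apply(state$D, c(2, 3), sum)
  treat <- sum(occ * params$cost) * params$epsilon
  (treat + new_diagnoses * params$cost_diag) * price_index
}

#' Stationary detection shares of the undiagnosed model
#'
#' Closed-form stationary solution of the undiagnosed subsystem under
#' constant inflow: the long-run fraction of all detections occurring at the
#' very start (`delta_s0` applied to the inflow), and at stages I-IV (stage
#' IV detections are the whole stage-IV occupancy each step). At
#' stationarity total detections equal the inflow, so the shares sum to 1.
#'
#' @param delta Length-4 detection probabilities, or an
#'   `"oncopolicy_params"` object (its `delta`/`alphaU` are used).
#' @param alphaU Length-3 undiagnosed progression probabilities.
#' @return Named length-5 share vector.
#' @examples
#' p <- builtin_constants("table1_nominal")
#' stationary_undiagnosed_shares(p[1:4], p[5:7])
#' @export
stationary_undiagnosed_shares <- function(delta, alphaU = NULL) {
  if (inherits(delta, "oncopolicy_params")) {
    alphaU <- delta$alphaU
    delta <- delta$delta
  }
  d <- as.numeric(delta)
  a <- as.numeric(alphaU)
  stopifnot(length(d) == 4L, length(a) == 3L)
  denom <- 1 - (1 - d[2:4]) * (1 - a)
  if (any(denom < 1e-12)) {
    stop("degenerate parameters: a stage retains its occupancy indefinitely")
  }
  N1 <- (1 - d[1]) / denom[1]
  N2 <- (1 - d[2]) * a[1] * N1 / denom[2]
  N3 <- (1 - d[3]) * a[2] * N2 / denom[3]
  N4 <- (1 - d[4]) * a[3] * N3
  det <- c(d[1], d[2] * N1, d[3] * N2, d[4] * N3, N4)
  stats::setNames(det / sum(det),
                  c("very_start", "stage1", "stage2", "stage3", "stage4"))
}

#' Simulated detection shares of the undiagnosed model
#'
#' Brute-force counterpart of [stationary_undiagnosed_shares()]: iterates
#' the undiagnosed subsystem with constant inflow and returns the detection
#' shares at the final step. Used as the independent oracle for the closed
#' form and inside the calibration objective's validation.
#'
#' @inheritParams stationary_undiagnosed_shares
#' @param months Number of monthly steps (default 120, past the >90-month
#'   stationarity horizon).
#' @param inflow Constant monthly inflow of new cases.
#' @return Named length-5 share vector.
#' @export
undiagnosed_shares_sim <- function(delta, alphaU = NULL, months = 120L,
                                   inflow = 1e5) {
  if (inherits(delta, "oncopolicy_params")) {
    alphaU <- delta$alphaU
    delta <- delta$delta
  }
  d <- as.numeric(delta)
  a <- as.numeric(alphaU)
  N <- numeric(4)
  det <- numeric(5)
  for (t in seq_len(months)) {
    det <- c(inflow * d[1], N[1] * d[2], N[2] * d[3], N[3] * d[4], N[4])
    N[1:3] <- N[1:3] * (1 - d[2:4])
    N[4] <- 0
    move <- N[1:3] * a
    N[1:3] <- N[1:3] - move
    N[2:4] <- N[2:4] + move
    N[1] <- N[1] + inflow * (1 - d[1])
  }
  stats::setNames(det / sum(det),
                  c("very_start", "stage1", "stage2", "stage3", "stage4"))
}

#' Simulate the full model
#'
#' Runs the age-structured model monthly over a calendar horizon. Incidence
#' inflow for age `a` in year `y` is `pop[y, a] * phi[a] / 12` (annual
#' age-band rates divided evenly across months); compartment age labels
#' advance at each calendar-year boundary with 100+ absorbing; treatment
#' costs are indexed from their 2012 anchor by the inflation series. An
#' optional scenario makes overridden parameters (and prevention) time
#' dependent after the break-point month via the transition function
#' `beta(tau)`.
#'
#' @param params An `"oncopolicy_params"`.
#' @param demography Data frame `year, age, population` covering the
#'   simulated span (see [make_demography()]).
#' @param incidence Data frame `band_start, band_end, rate_per_100k_year`
#'   (see [make_incidence()]).
#' @param macro Data frame `year, inflation, gdp` (see [make_macro()]).
#' @param start_year First simulated calendar year (January).
#' @param months Simulation horizon in months.
#' @param scenario Optional `"oncopolicy_scenario"` (see [scenario_spec()]).
#' @param cost_base_year Calendar year of the cost anchor (default 2012).
#' @return An object of class `"oncopolicy_sim"`: a list with `series` (a
#'   monthly data frame of `t, year, month, R, X, G, P, new_diagnoses,
#'   mortality_per_100k, undiagnosed, diagnosed`), the final `state`, and
#'   the call inputs.
#' @export
simulate_cancer <- function(params, demography, incidence, macro,
                            start_year, months, scenario = NULL,
                            cost_base_year = 2012L) {
  years_needed <- start_year + (months - 1) %/% 12
  pop <- demography_matrix(demography)
  if (!all(as.character(start_year:years_needed) %in% rownames(pop))) {
    stop("demography does not cover the simulated calendar span")
  }
  phi <- incidence_by_age(incidence, n_ages = ncol(pop))
  idx <- price_index_series(macro, cost_base_year)
  gdp <- stats::setNames(macro$gdp, macro$year)

  if (!is.null(scenario)) {
    base_vals <- flatten_params(params)[names(scenario$overrides)]
  }

  n_ages <- ncol(pop)
  state <- disease_state(n_ages)
  out <- matrix(NA_real_, months, 6,
                dimnames = list(NULL, c("R", "X", "G", "P", "new_diagnoses",
                                        "price_index")))
  occ <- matrix(NA_real_, months, 2,
                dimnames = list(NULL, c("undiagnosed", "diagnosed")))
  for (t in seq_len(months)) {
    year <- start_year + (t - 1) %/% 12
    if (t > 1 && (t - 1) %% 12 == 0) state <- age_state(state)
    p_t <- params
    phi_t <- phi
    if (!is.null(scenario) && t > scenario$t_star) {
      w <- transition_weight(t - scenario$t_star, scenario$beta1,
                             scenario$beta2)
      if (length(scenario$overrides)) {
        targets <- unlist(scenario$overrides)
        p_t <- set_params(p_t, base_vals + (targets - base_vals) * w)
      }
      if (scenario$eta > 0) phi_t <- phi / (1 + scenario$eta * w)
    }
    inflow <- pop[as.character(year), ] * phi_t / 12
    st <- step_state(state, p_t, inflow,
                     price_index = idx[as.character(year)])
    state <- st$state
    out[t, ] <- c(st$R, st$X, st$G, sum(pop[as.character(year), ]),
                  st$new_diagnoses, idx[as.character(year)])
    occ[t, ] <- c(sum(state$N), sum(state$D))
  }
  series <- data.frame(
    t = seq_len(months),
    year = start_year + (seq_len(months) - 1) %/% 12,
    month = (seq_len(months) - 1) %% 12 + 1,
    out, occ)
  series$mortality_per_100k <- series$X / series$P * 1e5
  structure(list(series = series, state = state, params = params,
                 scenario = scenario, start_year = start_year,
                 macro = macro),
            class = "oncopolicy_sim")
}

# Shift compartment age labels by one year; 100+ is absorbing.
age_state <- function(state) {
  n <- nrow(state$N)
  top <- state$N[n, ]
  state$N[2:n, ] <- state$N[1:(n - 1), ]
  state$N[1, ] <- 0
  state$N[n, ] <- state$N[n, ] + top
  topD <- state$D[n, , ]
  state$D[2:n, , ] <- state$D[1:(n - 1), , ]
  state$D[1, , ] <- 0
  state$D[n, , ] <- state$D[n, , ] + topD
  state
}

demography_matrix <- function(demography) {
  stopifnot(all(c("year", "age", "population") %in% names(demography)))
  if (any(demography$population < 0)) stop("population must be non-negative")
  pop <- tapply(demography$population, list(demography$year, demography$age),
                sum)
  pop <- pop[, order(as.integer(colnames(pop))), drop = FALSE]
  if (anyNA(pop)) stop("demography table has missing year/age combinations")
  pop
}

# Expand 10-year-band annual rates (per 100k) to per-person rates per
# single-year age. The 100+ band inherits the 90-99 band when absent.
incidence_by_age <- function(incidence, n_ages = 101L) {
  stopifnot(all(c("band_start", "band_end", "rate_per_100k_year")
                %in% names(incidence)))
  if (any(incidence$rate_per_100k_year < 0)) stop("rates must be non-negative")
  phi <- rep(NA_real_, n_ages)
  for (i in seq_len(nrow(incidence))) {
    lo <- incidence$band_start[i] + 1L
    hi <- min(incidence$band_end[i] + 1L, n_ages)
    phi[lo:hi] <- incidence$rate_per_100k_year[i] / 1e5
  }
  if (is.na(phi[n_ages])) phi[n_ages] <- phi[n_ages - 1L]
  if (anyNA(phi)) stop("incidence bands do not cover all ages")
  phi
}

# Cumulative inflation index relative to the cost anchor year.
price_index_series <- function(macro, base_year = 2012L) {
  stopifnot(all(c("year", "inflation") %in% names(macro)))
  macro <- macro[order(macro$year), ]
  lg <- cumsum(log1p(macro$inflation))
  if (base_year %in% macro$year) {
    ref <- lg[match(base_year, macro$year)]
  } else {
    ref <- 0
  }
  stats::setNames(exp(lg - ref), macro$year)
}

#' Annual aggregates of a simulation
#'
#' Sums monthly spending and deaths per calendar year, and derives the
#' annual mortality rate per 100,000 and cancer spending as a share of
#' nominal GDP.
#'
#' @param sim An `"oncopolicy_sim"`.
#' @return Data frame `year, G, X, R, P, mortality_per_100k, ce_gdp`.
#' @export
annualize <- function(sim) {
  s <- sim$series
  agg <- do.call(rbind, lapply(split(s, s$year), function(d) {
    data.frame(year = d$year[1], G = sum(d$G), X = sum(d$X), R = sum(d$R),
               P = mean(d$P))
  }))
  agg$mortality_per_100k <- agg$X / agg$P * 1e5
  gdp <- stats::setNames(sim$macro$gdp, sim$macro$year)
  agg$ce_gdp <- agg$G / gdp[as.character(agg$year)] * 100
  rownames(agg) <- NULL
  agg
}

#' @export
print.oncopolicy_sim <- function(x, ...) {
  s <- x$series
  cat("<oncopolicy_sim> ", nrow(s), " months from Jan ", x$start_year,
      if (!is.null(x$scenario)) paste0(" [scenario: ", x$scenario$name, "]"),
      "\n", sep = "")
  cat("  final month: X =", signif(s$X[nrow(s)], 4),
      " G =", signif(s$G[nrow(s)], 4),
      " mortality/100k =", signif(s$mortality_per_100k[nrow(s)], 4), "\n")
  invisible(x)
}
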
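#' Filter multi-start estimates and derive intervals
#'
#' Keeps the lowest-loss fraction of a multi-start estimation and returns
#' per-parameter `[min, max]`
#' intervals over the kept rows, the best-fit (nominal) vector, and a
#' dispersion diagnostic (interval width over |nominal|) used to judge
#' practical identifiability: estimates of an identifiable parameter
#' concentrate, so its dispersion is small.
#'
#' Losses within `tie_tol` of the cutoff loss count as ties and are all
#' kept: restarts whose losses differ by less than numerical noise have
#' converged to the same optimum (or to the same optimal manifold) and
#' carry the same evidence.
#'
#' @param estimates Matrix (restart x parameter) of estimates.
#' @param losses Numeric vector of losses, one per restart.
#' @param top_fraction Fraction in (0, 1] of restarts to keep.
#' @param tie_tol Absolute loss tolerance for ties at the cutoff.
#' @return An object of class `"oncopolicy_fit"`: list with `estimates`,
#'   `losses`, `kept` (logical), `intervals` (2 x p), `nominal`,
#'   `dispersion`, `top_fraction`.
#' @export
filter_and_intervals <- function(estimates, losses, top_fraction = 0.1,
                                 tie_tol = 1e-12) {
  estimates <- as.matrix(estimates)
  if (nrow(estimates) == 0L) stop("no estimates to filter")
  if (length(losses) != nrow(estimates)) {
    stop("losses must have one entry per restart")
  }
  if (top_fraction <= 0 || top_fraction > 1) {
    stop("top_fraction must lie in (0, 1]")
  }
  n_keep <- max(1L, ceiling(top_fraction * nrow(estimates)))
  cutoff <- sort(losses)[n_keep]
  kept <- losses <= cutoff + tie_tol
  intervals <- apply(estimates[kept, , drop = FALSE], 2, range)
  rownames(intervals) <- c("min", "max")
  best <- which.min(losses)
  nominal <- estimates[best, ]
  dispersion <- (intervals["max", ] - intervals["min", ]) /
    ifelse(abs(nominal) > 0, abs(nominal), 1)
  structure(list(estimates = estimates, losses = losses, kept = kept,
                 intervals = intervals, nominal = nominal,
                 loss_nominal = losses[best], dispersion = dispersion,
                 top_fraction = top_fraction),
            class = "oncopolicy_fit")
}

#' @export
print.oncopolicy_fit <- function(x, ...) {
  cat("<oncopolicy_fit> ", nrow(x$estimates), " restarts, kept ",
      sum(x$kept), " (top ", 100 * x$top_fraction, "%), best loss ",
      signif(x$loss_nominal, 4), "\n", sep = "")
  tab <- rbind(nominal = x$nominal, x$intervals, dispersion = x$dispersion)
  print(signif(t(tab), 4))
  invisible(x)
}

# Multi-start bounded MSE minimisation shared by both calibration fits.
multistart_fit <- function(objective, lower, upper, n_restarts, top_fraction,
                           seed, par_names) {
  stopifnot(n_restarts >= 1)
  set.seed(seed)
  k <- length(lower)
  starts <- matrix(stats::runif(n_restarts * k, min = rep(lower, each = n_restarts),
                                max = rep(upper, each = n_restarts)),
                   nrow = n_restarts)
  estimates <- matrix(NA_real_, n_restarts, k,
                      dimnames = list(NULL, par_names))
  losses <- numeric(n_restarts)
  for (i in seq_len(n_restarts)) {
    fit <- stats::optim(starts[i, ], objective, method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(maxit = 1000, factr = 10))
    estimates[i, ] <- fit$par
    losses[i] <- fit$value
  }
  filter_and_intervals(estimates, losses, top_fraction)
}

#' Detection-share trajectory of the undiagnosed model
#'
#' Iterates the undiagnosed subsystem from an empty state under constant
#' inflow and returns, per month, the composition of that month's
#' detections (very start, stages I-IV). The trajectory starts at
#' `(1, 0, 0, 0, 0)` and converges to [stationary_undiagnosed_shares()]
#' well before month 90.
#'
#' @inheritParams stationary_undiagnosed_shares
#' @param months Number of monthly steps.
#' @param inflow Constant monthly inflow.
#' @return `months x 5` matrix of detection shares.
#' @export
undiagnosed_share_trajectory <- function(delta, alphaU = NULL, months = 120L,
                                         inflow = 1e5) {
  if (inherits(delta, "oncopolicy_params")) {
    alphaU <- delta$alphaU
    delta <- delta$delta
  }
  d <- as.numeric(delta)
  a <- as.numeric(alphaU)
  out <- matrix(NA_real_, months, 5,
                dimnames = list(NULL, c("very_start", "stage1", "stage2",
                                        "stage3", "stage4")))
  N <- numeric(4)
  for (t in seq_len(months)) {
    det <- c(inflow * d[1], N[1] * d[2], N[2] * d[3], N[3] * d[4], N[4])
    tot <- sum(det)
    out[t, ] <- if (tot > 0) det / tot else c(1, 0, 0, 0, 0)
    N[1:3] <- N[1:3] * (1 - d[2:4])
    N[4] <- 0
    move <- N[1:3] * a
    N[1:3] <- N[1:3] - move
    N[2:4] <- N[2:4] + move
    N[1] <- N[1] + inflow * (1 - d[1])
  }
  out
}

#' Calibrate the undiagnosed model to detection shares
#'
#' Estimates the four detection probabilities and three undiagnosed
#' progression probabilities by bounded multi-start minimisation of the MSE
#' between the model's post-burn-in (stationary) detection shares under
#' constant inflow and the observed target shares (e.g. the 2021 national
#' registry shares, `builtin_constants("cac2021_shares")`). The stationary
#' shares are computed in closed form ([stationary_undiagnosed_shares()],
#' verified against the iterated model past the >90-month stationarity
#' threshold). The stationary composition pins `delta_s0` exactly but
#' constrains the remaining six parameters only up to a solution manifold:
#' their filtered intervals are correspondingly wide, which is precisely
#' the practical-identifiability signal the dispersion diagnostic reports.
#'
#' Because the model's shares sum to one exactly while reported shares may
#' not (the published vector sums to 0.9998), the fit distributes the
#' residual mass: that is why the calibrated `delta_s0` (0.0875) differs
#' slightly from the raw very-start share (0.0874).
#'
#' @param shares Length-5 target share vector (very start, stages I-IV);
#'   must sum to 1 within 0.01.
#' @param n_restarts Number of random multi-starts (default 1000).
#' @param top_fraction Fraction of best fits kept for intervals.
#' @param seed Integer seed for the start points.
#' @return An `"oncopolicy_fit"` over parameters
#'   `delta_s0..delta_s3, alpha_s1..alpha_s3`.
#' @export
fit_undiagnosed <- function(shares, n_restarts = 1000L, top_fraction = 0.1,
                            seed = 1L) {
  shares <- as.numeric(shares)
  if (length(shares) != 5L || any(shares < 0)) {
    stop("shares must be 5 non-negative values")
  }
  if (abs(sum(shares) - 1) > 0.01) stop("shares must sum to ~1")
  objective <- function(theta) {
    denom <- 1 - (1 - theta[2:4]) * (1 - theta[5:7])
    if (any(denom < 1e-10)) return(1e6)
    m <- stationary_undiagnosed_shares(theta[1:4], theta[5:7])
    mean((m - shares)^2)
  }
  multistart_fit(objective, lower = rep(0, 7), upper = rep(1, 7),
                 n_restarts = n_restarts, top_fraction = top_fraction,
                 seed = seed,
                 par_names = c(paste0("delta_s", 0:3),
                               paste0("alpha_s", 1:3)))
}

#' Cohort model of diagnosed patients
#'
#' Simulates four independent cohorts of patients diagnosed at stages I-IV
#' under a single treatment tier. Each month, recovery (`gamma`) takes
#' precedence; non-recovered patients progress to the next stage with
#' probability `alphaD` (at stage IV, `alphaD[4]` is death).
#'
#' @param gamma Length-4 monthly recovery probabilities per stage.
#' @param alphaD Length-4 monthly progression probabilities (element 4 =
#'   death at stage IV).
#' @param initial_cohorts Length-4 initial cohort sizes (patients detected
#'   at stages I-IV).
#' @param months Number of monthly steps.
#' @return List with `recovered` and `deaths` (months x 4 matrices of
#'   cumulative counts per detection-stage cohort, columns `det1..det4`).
#' @examples
#' cohort_model(rep(1, 4), rep(0.5, 4), rep(100, 4), 3)$recovered
#' @export
cohort_model <- function(gamma, alphaD, initial_cohorts = rep(1000, 4),
                         months = 12L) {
  gamma <- as.numeric(gamma)
  alphaD <- as.numeric(alphaD)
  stopifnot(length(gamma) == 4L, length(alphaD) == 4L,
            all(gamma >= 0 & gamma <= 1), all(alphaD >= 0 & alphaD <= 1),
            length(initial_cohorts) == 4L)
  rec <- matrix(0, months, 4, dimnames = list(NULL, paste0("det", 1:4)))
  dth <- matrix(0, months, 4, dimnames = list(NULL, paste0("det", 1:4)))
  for (s0 in 1:4) {
    occ <- numeric(4)
    occ[s0] <- initial_cohorts[s0]
    R <- 0
    X <- 0
    for (t in seq_len(months)) {
      recovered <- gamma * occ
      occ <- occ - recovered
      R <- R + sum(recovered)
      move <- alphaD[1:3] * occ[1:3]
      die <- alphaD[4] * occ[4]
      occ[1:3] <- occ[1:3] - move
      occ[2:4] <- occ[2:4] + move
      occ[4] <- occ[4] - die
      X <- X + die
      rec[t, s0] <- R
      dth[t, s0] <- X
    }
  }
  list(recovered = rec, deaths = dth)
}

#' Calibrate recovery and diagnosed progression for one treatment tier
#'
#' Estimates `gamma[s1..s4]`, the diagnosed progression probabilities
#' `alpha[s1..s3]` (bounded above by the calibrated undiagnosed progression
#' nominals, since treated patients should not deteriorate faster than
#' untreated ones) and the stage-IV death probability `alpha[s4]`, by
#' multi-start MSE fit of the cohort model's 12-month cumulative-recovered
#' trajectories to linear target ramps rising from 99% to 100% of the
#' expected survivors (`survival_target * cohort size`) — the 1% allowance
#' accommodates treatment continuing into a second year.
#'
#' @param survival_targets Length-4 five-year survival per detection stage
#'   for this tier (e.g. the case-weighted means or an extreme-scenario
#'   bound of the survival table).
#' @param alpha_upper_bounds Length-3 upper bounds for diagnosed progression
#'   (default: Table-1-style undiagnosed nominals).
#' @param n_restarts Number of random multi-starts (default 500).
#' @param top_fraction Fraction of best fits kept.
#' @param seed Integer seed.
#' @param cohort_size Initial patients per detection-stage cohort.
#' @param target_trajectories Optional `months x 4` matrix of cumulative
#'   recovered targets replacing the linear ramps (e.g. trajectories
#'   produced by [cohort_model()] for recovery studies).
#' @return An `"oncopolicy_fit"` over
#'   `gamma_s1..gamma_s4, alpha_s1..alpha_s4`.
#' @export
fit_diagnosed <- function(survival_targets,
                          alpha_upper_bounds = builtin_constants("table1_nominal")[5:7],
                          n_restarts = 500L, top_fraction = 0.1, seed = 1L,
                          cohort_size = 1000, target_trajectories = NULL) {
  survival_targets <- as.numeric(survival_targets)
  if (length(survival_targets) != 4L ||
      any(survival_targets < 0 | survival_targets > 1)) {
    stop("survival_targets must be 4 probabilities")
  }
  alpha_upper_bounds <- as.numeric(alpha_upper_bounds)
  if (length(alpha_upper_bounds) != 3L) {
    stop("alpha_upper_bounds must have length 3")
  }
  months <- 12L
  if (is.null(target_trajectories)) {
    ramp <- sapply(survival_targets * cohort_size, function(S) {
      S * seq(0.99, 1.00, length.out = months)
    })
  } else {
    ramp <- as.matrix(target_trajectories)
    if (!all(dim(ramp) == c(months, 4L))) {
      stop("target_trajectories must be a 12 x 4 matrix")
    }
  }
  objective <- function(theta) {
    traj <- cohort_model(theta[1:4], theta[5:8],
                         initial_cohorts = rep(cohort_size, 4),
                         months = months)$recovered
    mean((traj - ramp)^2)
  }
  multistart_fit(objective, lower = rep(0, 8),
                 upper = c(rep(1, 4), alpha_upper_bounds, 1),
                 n_restarts = n_restarts, top_fraction = top_fraction,
                 seed = seed,
                 par_names = c(paste0("gamma_s", 1:4),
                               paste0("alpha_s", 1:4)))
}

#' Case-weighted five-year survival per stage
#'
#' Aggregates per-cancer-type five-year survival into a single per-stage
#' survival using the number of cases as weights.
#'
#' @param table Data frame with columns `stage1..stage4` and `cases` (see
#'   `builtin_constants("table2_survival")`).
#' @return Named length-4 vector of weighted mean survivals.
#' @examples
#' weighted_survival(builtin_constants("table2_survival"))
#' @export
weighted_survival <- function(table) {
  cols <- paste0("stage", 1:4)
  stopifnot(all(c(cols, "cases") %in% names(table)), nrow(table) > 0)
  if (sum(table$cases) <= 0) stop("total cases must be positive")
  surv <- as.matrix(table[, cols])
  if (any(surv < 0 | surv > 1)) stop("survivals must lie in [0, 1]")
  stats::setNames(colSums(surv * table$cases) / sum(table$cases), cols)
}

#' Tier-specific survival targets
#'
#' Maps the survival table to the three treatment-quality tiers: the lowest
#' tier (T1) is assigned the lower extreme-scenario bound, the middle tier
#' (T2) the case-weighted mean, and the best tier (T3) the upper extreme
#' bound — mirroring the assumption that domestic quality variation matches
#' the variation observed across the reference country cluster, with
#' quality ordered by cost.
#'
#' @param table Survival data frame as in [weighted_survival()].
#' @param extremes 2 x 4 matrix of lower/upper extreme survival bounds.
#' @return 3 x 4 matrix (tier x stage) of survival targets.
#' @export
tier_survival_targets <- function(table = builtin_constants("table2_survival"),
                                  extremes = builtin_constants("table2_extremes")) {
  rbind(T1 = extremes["lower", ],
        T2 = weighted_survival(table),
        T3 = extremes["upper", ])
}
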
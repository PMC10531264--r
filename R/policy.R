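#' Policy transition weight
#'
#' The transition function `beta(tau) = beta1^(1 / (beta2 * tau))` that
#' blends a parameter from its old to its new value after a policy
#' break-point. `beta1` controls the abruptness of the change (the weight at
#' small `tau`), `beta2` the time horizon; the weight is non-decreasing in
#' `tau` and tends to 1.
#'
#' @param tau Months elapsed since the break-point (integer >= 1).
#' @param beta1 Abruptness parameter in `[0, 1]`.
#' @param beta2 Speed parameter (> 0).
#' @return Weight in `[0, 1]`.
#' @examples
#' transition_weight(1, 0.2, 1)   # 0.2
#' transition_weight(1000, 0.2, 1)
#' @export
transition_weight <- function(tau, beta1, beta2) {
  if (any(tau < 1)) stop("tau must be >= 1 (months elapsed after the break-point)")
  if (beta1 < 0 || beta1 > 1) stop("beta1 must lie in [0, 1]")
  if (beta2 <= 0) stop("beta2 must be positive")
  beta1^(1 / (beta2 * tau))
}

#' Time-dependent effective parameter
#'
#' Piecewise definition of a policy-shifted parameter: the base value up to
#' and including the break-point month, then
#' `base + (target - base) * beta(t - t_star)`.
#'
#' @param base,target Parameter value before the policy and its new target.
#' @param t Current month index.
#' @param spec An `"oncopolicy_scenario"` supplying `t_star`, `beta1`,
#'   `beta2`.
#' @return Effective value at month `t`.
#' @export
effective_parameter <- function(base, target, t, spec) {
  if (t <= spec$t_star) return(base)
  base + (target - base) * transition_weight(t - spec$t_star, spec$beta1,
                                             spec$beta2)
}

#' Prevention-modified incidence rates
#'
#' After the break-point, all age-specific incidence rates are divided by
#' `1 + eta * beta(t - t_star)`; at full effect `eta = 3/7` yields a 30%
#' reduction in total incidence (the WHO lower bound for preventable
#' cancers).
#'
#' @param phi_base Non-negative per-age annual incidence rates.
#' @param t Current month index.
#' @param spec An `"oncopolicy_scenario"` supplying `eta`, `t_star`,
#'   `beta1`, `beta2`.
#' @return Modified rate vector.
#' @export
effective_incidence <- function(phi_base, t, spec) {
  if (any(phi_base < 0)) stop("phi must be non-negative")
  if (t <= spec$t_star || spec$eta == 0) return(phi_base)
  phi_base / (1 + spec$eta * transition_weight(t - spec$t_star, spec$beta1,
                                               spec$beta2))
}

#' Scenario specification
#'
#' A declarative policy scenario: the break-point month `t_star` (the
#' transition acts for `t > t_star`), transition parameters, a prevention
#' parameter, and named parameter overrides in [flatten_params()] notation
#' (stage-specific `lambda_s.T.` overrides are supported even though the
#' calibrated baseline is stage-independent).
#'
#' @param name Scenario label.
#' @param t_star Break-point month index (default 204: December of year 17
#'   of a 2005-start simulation, so the transition acts from January 2022).
#' @param overrides Named numeric vector/list of parameter targets.
#' @param beta1,beta2 Transition parameters.
#' @param eta Prevention parameter (>= 0).
#' @return An object of class `"oncopolicy_scenario"`.
#' @export
scenario_spec <- function(name = "custom", t_star = 204L, overrides = c(),
                          beta1 = 0.2, beta2 = 1, eta = 0) {
  if (beta1 < 0 || beta1 > 1) stop("beta1 must lie in [0, 1]")
  if (beta2 <= 0) stop("beta2 must be positive")
  if (eta < 0) stop("eta must be non-negative")
  overrides <- as.list(overrides)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), c(param_names(), "lambda_T1", "lambda_T2"))
    if (length(bad)) {
      stop("overrides reference unknown parameters: ",
           paste(bad, collapse = ", "))
    }
  }
  structure(list(name = name, t_star = as.integer(t_star),
                 overrides = overrides, beta1 = beta1, beta2 = beta2,
                 eta = eta),
            class = "oncopolicy_scenario")
}

#' Built-in policy scenarios
#'
#' The baseline (no overrides) and the three published policy scenarios,
#' all with a rapid transition (`beta1 = 0.2`, `beta2 = 1`):
#' \describe{
#'   \item{scenario1}{Universal early detection: `delta_s0 -> 1`.}
#'   \item{scenario2}{Scenario 1 plus better treatment for stage-I patients:
#'     `lambda_s1T1 -> 0.1`, `lambda_s1T2 -> 0.2` (more stage-I patients
#'     reach the best tier T3).}
#'   \item{scenario3}{Scenario 2 plus a more effective and faster best-tier
#'     stage-I treatment: `gamma_s1T3 -> 0.6`, `alpha_s1T3 -> 0.3`.}
#' }
#'
#' @param t_star Break-point month passed to every scenario.
#' @return Named list of `"oncopolicy_scenario"` objects.
#' @export
builtin_scenarios <- function(t_star = 204L) {
  list(
    baseline = scenario_spec("baseline", t_star = t_star),
    scenario1 = scenario_spec("scenario1", t_star = t_star,
                              overrides = c(delta_s0 = 1)),
    scenario2 = scenario_spec("scenario2", t_star = t_star,
                              overrides = c(delta_s0 = 1, lambda_s1T1 = 0.1,
                                            lambda_s1T2 = 0.2)),
    scenario3 = scenario_spec("scenario3", t_star = t_star,
                              overrides = c(delta_s0 = 1, lambda_s1T1 = 0.1,
                                            lambda_s1T2 = 0.2,
                                            gamma_s1T3 = 0.6,
                                            alpha_s1T3 = 0.3))
  )
}

#' @export
print.oncopolicy_scenario <- function(x, ...) {
  cat("<oncopolicy_scenario> ", x$name, ": t_star=", x$t_star,
      " beta1=", x$beta1, " beta2=", x$beta2, " eta=", x$eta, "\n", sep = "")
  if (length(x$overrides)) {
    cat("  overrides:",
        paste(names(x$overrides), unlist(x$overrides), sep = "=",
              collapse = ", "), "\n")
  }
  invisible(x)
}
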
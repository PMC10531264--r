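#' Model parameter set
#'
#' Builds the complete parameter set of the cancer healthcare-system model:
#' detection probabilities `delta_s0..delta_s3`, undiagnosed monthly
#' progression `alpha_s1..alpha_s3`, per-stage/per-tier recovery `gamma` and
#' diagnosed progression/death `alpha` (stage IV's diagnosed "progression" is
#' death), per-stage conditional treatment-tier assignment `lambda[stage,
#' T1/T2]` (T3 is the remainder under the hierarchy T1 > T2 > T3), monthly
#' treatment costs (2012 currency) and the per-diagnosis cost, the cost
#' correction factor `epsilon`, and the policy levers (`eta`, `beta1`,
#' `beta2`, `t_star`).
#'
#' Defaults are the published calibrated values (see [builtin_constants()]).
#' The baseline tier assignment is stage-independent; scenarios may override
#' it per stage.
#'
#' @param delta Length-4 detection probabilities (very start, stages I-III).
#' @param alphaU Length-3 undiagnosed stage-progression probabilities.
#' @param gamma 4 x 3 recovery probabilities (stage x tier).
#' @param alphaD 4 x 3 diagnosed progression probabilities; row 4 is the
#'   monthly death probability at stage IV.
#' @param lambda Either a length-2 vector `(lambda_T1, lambda_T2)` applied to
#'   all stages, or a 4 x 2 matrix of per-stage conditional probabilities.
#' @param cost 4 x 3 monthly treatment cost matrix (currency, 2012 prices).
#' @param cost_diag Cost per diagnosis event.
#' @param epsilon Cost-correction factor in (0, 1].
#' @param eta Prevention parameter (>= 0).
#' @param beta1,beta2 Policy-transition parameters (`beta1` in `[0,1]`,
#'   `beta2 > 0`).
#' @param t_star Break-point month index; policy transitions act for
#'   `t > t_star`.
#' @return An object of class `"oncopolicy_params"` (a named list).
#' @examples
#' p <- default_parameters()
#' p$delta
#' @export
default_parameters <- function(delta = builtin_constants("table1_nominal")[1:4],
                               alphaU = builtin_constants("table1_nominal")[5:7],
                               gamma = builtin_constants("table3_nominal")$gamma,
                               alphaD = builtin_constants("table3_nominal")$alpha,
                               lambda = builtin_constants("lambda"),
                               cost = builtin_constants("table4_costs"),
                               cost_diag = attr(builtin_constants("table4_costs"), "C_diag"),
                               epsilon = builtin_constants("epsilon"),
                               eta = 0, beta1 = 0.2, beta2 = 1,
                               t_star = 204L) {
  stages <- paste0("s", 1:4)
  tiers <- paste0("T", 1:3)
  if (length(lambda) == 2L) {
    lambda <- matrix(rep(as.numeric(lambda), each = 4), nrow = 4,
                     dimnames = list(stages, c("T1", "T2")))
  }
  p <- structure(list(
    delta = stats::setNames(as.numeric(delta), paste0("s", 0:3)),
    alphaU = stats::setNames(as.numeric(alphaU), stages[1:3]),
    gamma = `dimnames<-`(as.matrix(gamma), list(stages, tiers)),
    alphaD = `dimnames<-`(as.matrix(alphaD), list(stages, tiers)),
    lambda = `dimnames<-`(as.matrix(lambda), list(stages, c("T1", "T2"))),
    cost = `dimnames<-`(matrix(as.numeric(cost), 4, 3), list(stages, tiers)),
    cost_diag = as.numeric(cost_diag),
    epsilon = as.numeric(epsilon),
    eta = as.numeric(eta),
    beta1 = as.numeric(beta1),
    beta2 = as.numeric(beta2),
    t_star = as.integer(t_star)
  ), class = "oncopolicy_params")
  validate_parameters(p)
  p
}

#' Validate a parameter set
#'
#' Checks ranges (probabilities in `[0,1]`, non-negative costs,
#' `epsilon` in (0,1], `beta2 > 0`) and the tier-assignment identity
#' `lambda_T1 + (1 - lambda_T1) * lambda_T2 <= 1`.
#'
#' @param p An `"oncopolicy_params"` object.
#' @return `p`, invisibly; errors on violation.
#' @export
validate_parameters <- function(p) {
  prob_ok <- function(x) all(is.finite(x)) && all(x >= 0) && all(x <= 1)
  if (!prob_ok(p$delta)) stop("delta probabilities must lie in [0, 1]")
  if (!prob_ok(p$alphaU)) stop("alphaU probabilities must lie in [0, 1]")
  if (!prob_ok(p$gamma)) stop("gamma probabilities must lie in [0, 1]")
  if (!prob_ok(p$alphaD)) stop("alphaD probabilities must lie in [0, 1]")
  if (!prob_ok(p$lambda)) stop("lambda probabilities must lie in [0, 1]")
  if (any(p$cost < 0) || p$cost_diag < 0) stop("costs must be non-negative")
  if (!(p$epsilon > 0 && p$epsilon <= 1)) stop("epsilon must lie in (0, 1]")
  if (p$eta < 0) stop("eta must be non-negative")
  if (p$beta1 < 0 || p$beta1 > 1) stop("beta1 must lie in [0, 1]")
  if (p$beta2 <= 0) stop("beta2 must be positive")
  marg <- p$lambda[, 1] + (1 - p$lambda[, 1]) * p$lambda[, 2]
  if (any(marg > 1 + 1e-12)) stop("lambda hierarchy exceeds total probability")
  invisible(p)
}

# Canonical scalar parameter names (the model's 55-parameter census):
# 4 delta + 3 undiagnosed alpha + 12 gamma + 12 diagnosed alpha +
# 8 per-stage lambda + 12 treatment costs + C_diag + eta + beta1 + beta2.
param_names <- function() {
  stages <- paste0("s", 1:4)
  tiers <- paste0("T", 1:3)
  c(paste0("delta_s", 0:3),
    paste0("alpha_", stages[1:3]),
    paste0("gamma_", outer(stages, tiers, paste0)),
    paste0("alpha_", outer(stages, tiers, paste0)),
    paste0("lambda_", outer(stages, c("T1", "T2"), paste0)),
    paste0("C_", outer(stages, tiers, paste0)),
    "C_diag", "eta", "beta1", "beta2")
}

#' Flatten a parameter set to a named vector
#'
#' Scalar names follow the published `[stage, tier]` notation, e.g.
#' `delta_s0`, `alpha_s2` (undiagnosed), `gamma_s4T3`, `alpha_s1T3`
#' (diagnosed), `lambda_s1T1`, `C_s2T2`, `C_diag`, `eta`, `beta1`, `beta2`.
#' `epsilon` and `t_star` are structural constants and are not part of the
#' flattened vector.
#'
#' @param p An `"oncopolicy_params"` object.
#' @return Named numeric vector of length 55.
#' @export
flatten_params <- function(p) {
  v <- c(p$delta, p$alphaU, as.vector(p$gamma), as.vector(p$alphaD),
         as.vector(p$lambda), as.vector(p$cost), p$cost_diag,
         p$eta, p$beta1, p$beta2)
  stats::setNames(v, param_names())
}

#' Set named scalar parameters
#'
#' Applies named overrides (in [flatten_params()] notation) to a parameter
#' set. `lambda_T1`/`lambda_T2` (without a stage) set all stages at once.
#'
#' @param p An `"oncopolicy_params"` object.
#' @param values Named numeric vector of overrides.
#' @return The modified parameter set.
#' @examples
#' p <- set_params(default_parameters(), c(delta_s0 = 1))
#' @export
set_params <- function(p, values) {
  stopifnot(is.numeric(values), !is.null(names(values)))
  for (nm in names(values)) {
    val <- as.numeric(values[[nm]])
    if (nm %in% c("lambda_T1", "lambda_T2")) {
      p$lambda[, sub("lambda_", "", nm)] <- val
    } else if (grepl("^delta_s[0-3]$", nm)) {
      p$delta[sub("delta_", "", nm)] <- val
    } else if (grepl("^alpha_s[1-3]$", nm)) {
      p$alphaU[sub("alpha_", "", nm)] <- val
    } else if (grepl("^gamma_s[1-4]T[1-3]$", nm)) {
      p$gamma[substr(nm, 7, 8), substr(nm, 9, 10)] <- val
    } else if (grepl("^alpha_s[1-4]T[1-3]$", nm)) {
      p$alphaD[substr(nm, 7, 8), substr(nm, 9, 10)] <- val
    } else if (grepl("^lambda_s[1-4]T[12]$", nm)) {
      p$lambda[substr(nm, 8, 9), substr(nm, 10, 11)] <- val
    } else if (grepl("^C_s[1-4]T[1-3]$", nm)) {
      p$cost[substr(nm, 3, 4), substr(nm, 5, 6)] <- val
    } else if (nm %in% c("C_diag", "eta", "beta1", "beta2", "epsilon")) {
      p[[sub("^C_diag$", "cost_diag", nm)]] <- val
    } else if (nm == "t_star") {
      p$t_star <- as.integer(val)
    } else {
      stop("unknown parameter name: '", nm, "'")
    }
  }
  validate_parameters(p)
  p
}

#' @export
print.oncopolicy_params <- function(x, ...) {
  cat("<oncopolicy_params>\n")
  cat("  delta:", paste(signif(x$delta, 4), collapse = " "), "\n")
  cat("  alphaU:", paste(signif(x$alphaU, 4), collapse = " "), "\n")
  cat("  lambda (marginal tiers, stage I):",
      paste(signif(assign_treatment(x$lambda[1, 1], x$lambda[1, 2]), 4),
            collapse = " "), "\n")
  cat("  epsilon:", x$epsilon, " eta:", x$eta,
      " beta1:", x$beta1, " beta2:", x$beta2, " t_star:", x$t_star, "\n")
  invisible(x)
}
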
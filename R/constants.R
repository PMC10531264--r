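#' Built-in calibration constants
#'
#' Named bundles of the published calibration inputs and results that the
#' model consumes: the 2021 national high-cost-account (CAC) detection
#' shares, the five-year survival table with case counts and extreme
#' country-cluster scenarios, the calibrated detection/progression and
#' recovery/death probabilities, 2012-anchored monthly treatment costs, the
#' breast-cancer cost-correction factor, and the treatment-tier assignment
#' probabilities.
#'
#' Available keys:
#' \describe{
#'   \item{`cac2021_shares`}{Detection shares (very start, stages I-IV) among
#'     staged incident cases, 2021.}
#'   \item{`table1_nominal`}{Nominal detection (`delta_s0..delta_s3`) and
#'     undiagnosed progression (`alpha_s1..alpha_s3`) probabilities.}
#'   \item{`table1_intervals`}{Filtered estimation intervals for the same
#'     seven parameters (2 x 7 matrix, rows `min`/`max`).}
#'   \item{`table2_survival`}{Five-year survival by cancer type and detection
#'     stage with case counts (data.frame).}
#'   \item{`table2_weighted_mean`}{Case-weighted five-year survival per stage.}
#'   \item{`table2_extremes`}{Extreme-scenario survival bounds per stage
#'     (2 x 4 matrix, rows `lower`/`upper`).}
#'   \item{`table3_nominal`}{Recovery `gamma[stage, tier]` and diagnosed
#'     progression/death `alpha[stage, tier]` probabilities (list of two
#'     4 x 3 matrices).}
#'   \item{`table4_costs`}{Monthly treatment cost per stage and tier
#'     (4 x 3 matrix, 2012 COP) plus attribute `C_diag`.}
#'   \item{`epsilon`}{Cost-correction factor from breast-cancer to all-cancer
#'     average spending.}
#'   \item{`lambda`}{Conditional tier-assignment probabilities
#'     (`lambda_T1`, `lambda_T2`).}
#' }
#'
#' @param key Character; one of the keys above.
#' @return The requested bundle (vector, matrix, list or data.frame).
#' @examples
#' builtin_constants("cac2021_shares")
#' builtin_constants("epsilon")
#' @export
builtin_constants <- function(key) {
  stages <- paste0("s", 1:4)
  tiers <- paste0("T", 1:3)
  bundles <- list(
    cac2021_shares = c(very_start = 0.0874, stage1 = 0.1876, stage2 = 0.2469,
                       stage3 = 0.2365, stage4 = 0.2414),
    table1_nominal = c(delta_s0 = 0.0875, delta_s1 = 0.1422, delta_s2 = 0.2525,
                       delta_s3 = 0.3489, alpha_s1 = 0.6398, alpha_s2 = 0.6532,
                       alpha_s3 = 0.5479),
    table1_intervals = matrix(
      c(0.0875, 0.0875, 0.1315, 0.1538, 0.2169, 0.2587, 0.3175, 0.3852,
        0.5849, 0.7017, 0.5357, 0.6749, 0.4756, 0.6405),
      nrow = 2,
      dimnames = list(c("min", "max"),
                      c("delta_s0", "delta_s1", "delta_s2", "delta_s3",
                        "alpha_s1", "alpha_s2", "alpha_s3"))),
    table2_survival = data.frame(
      type = c("Breast", "Prostate", "Colon & rectal", "Stomach", "Lung"),
      stage1 = c(0.902, 0.828, 0.672, 0.458, 0.350),
      stage2 = c(0.885, 0.783, 0.665, 0.440, 0.249),
      stage3 = c(0.789, 0.725, 0.563, 0.360, 0.231),
      stage4 = c(0.676, 0.618, 0.443, 0.214, 0.088),
      cases = c(24460, 13190, 9330, 4218, 2027)),
    table2_weighted_mean = c(stage1 = 0.787, stage2 = 0.762,
                             stage3 = 0.678, stage4 = 0.562),
    table2_extremes = matrix(
      c(0.707, 0.867, 0.662, 0.861, 0.576, 0.780, 0.376, 0.747),
      nrow = 2,
      dimnames = list(c("lower", "upper"),
                      c("stage1", "stage2", "stage3", "stage4"))),
    table3_nominal = list(
      gamma = matrix(c(0.088, 0.141, 0.204, 0.122,
                       0.070, 0.186, 0.164, 0.181,
                       0.031, 0.273, 0.076, 0.250),
                     nrow = 4, dimnames = list(stages, tiers)),
      alpha = matrix(c(0.640, 0.653, 0.548, 0.230,
                       0.640, 0.653, 0.548, 0.172,
                       0.640, 0.653, 0.548, 0.114),
                     nrow = 4, dimnames = list(stages, tiers))),
    table4_costs = structure(
      matrix(c(747500.000, 3966666.667, 4666666.667, 9083333.333,
               782500.000, 4325000.000, 5325000.000, 12000000.000,
               1008333.333, 6783333.333, 8666666.667, 12416666.667),
             nrow = 4, dimnames = list(stages, tiers)),
      C_diag = 916000.000),
    epsilon = 0.642,
    lambda = c(lambda_T1 = 0.196, lambda_T2 = 0.260)
  )
  if (!key %in% names(bundles)) {
    stop("unknown constant key: '", key, "'; available: ",
         paste(names(bundles), collapse = ", "))
  }
  bundles[[key]]
}
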
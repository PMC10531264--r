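#' Efficiency target output
#'
#' The scalar efficiency series `T(t) = (G/P) * (X/P)`: per-capita cancer
#' spending times the per-capita death rate, approximately the extra cost
#' borne by each individual because of cancer deaths. Lower values indicate
#' a more efficient system.
#'
#' @param sim Either an `"oncopolicy_sim"` or a data frame/list with
#'   numeric `G`, `X`, `P` series.
#' @return Numeric series `T`.
#' @export
efficiency_target <- function(sim) {
  s <- if (inherits(sim, "oncopolicy_sim")) sim$series else sim
  if (!all(c("G", "X", "P") %in% names(s))) stop("sim must carry G, X, P")
  if (any(s$P <= 0)) stop("population must be positive")
  s$G * s$X / s$P^2
}

#' Latin-hypercube sample of a parameter box
#'
#' Stratified design with one sample per equal-probability stratum per
#' parameter, scaled to the supplied ranges. Seeded and reproducible.
#'
#' @param ranges 2 x k matrix (rows `min`, `max`) or a list of length-2
#'   ranges; column/element names name the parameters.
#' @param n Number of samples (>= 2).
#' @param seed Integer seed.
#' @return An object of class `"oncopolicy_design"`: list with `samples`
#'   (n x k named matrix), `ranges`, `n`, `seed`.
#' @export
lhs_sample <- function(ranges, n, seed = 1L) {
  ranges <- as_range_matrix(ranges)
  if (n < 2) stop("n must be at least 2")
  set.seed(seed)
  u <- lhs::randomLHS(n, ncol(ranges))
  samples <- sweep(sweep(u, 2, ranges[2, ] - ranges[1, ], `*`),
                   2, ranges[1, ], `+`)
  colnames(samples) <- colnames(ranges)
  structure(list(samples = samples, ranges = ranges, n = n, seed = seed),
            class = "oncopolicy_design")
}

as_range_matrix <- function(ranges) {
  if (is.list(ranges)) {
    ranges <- sapply(ranges, function(r) as.numeric(r)[1:2])
  }
  ranges <- as.matrix(ranges)
  if (nrow(ranges) != 2L) stop("ranges must be a 2 x k matrix (min, max)")
  if (any(!is.finite(ranges)) || any(ranges[2, ] < ranges[1, ])) {
    stop("malformed ranges: need finite min <= max")
  }
  rownames(ranges) <- c("min", "max")
  ranges
}

#' Sensitivity-analysis ranges for the model parameters
#'
#' Builds the uncertainty box used for sensitivity and uncertainty
#' analysis: every varied parameter ranges over 50% to 150% of its nominal
#' value (capped at 1 for probabilities), except the prevention parameter
#' `eta` (0 up to `3/7`, the effort that asymptotically removes 30% of
#' incidence — the WHO lower bound for preventable cancers) and the
#' transition parameters `beta1`, `beta2` (`[0.1, 0.3]` around a nominal
#' 0.2). Cost-per-stage/tier parameters are excluded (kept fixed at
#' nominal), leaving 43 varied parameters.
#'
#' @param params An `"oncopolicy_params"` supplying the nominal values.
#' @param subset Optional character vector restricting the returned columns.
#' @return 2 x k range matrix with attribute `nominal`.
#' @export
sa_ranges <- function(params = default_parameters(), subset = NULL) {
  v <- flatten_params(params)
  varied <- setdiff(names(v), paste0("C_", outer(paste0("s", 1:4),
                                                 paste0("T", 1:3), paste0)))
  nom <- v[varied]
  lo <- 0.5 * nom
  hi <- 1.5 * nom
  probs <- !varied %in% c("C_diag", "eta", "beta1", "beta2")
  hi[probs] <- pmin(hi[probs], 1)
  lo["eta"] <- 0
  hi["eta"] <- 3 / 7
  nom["eta"] <- 0
  lo[c("beta1", "beta2")] <- 0.1
  hi[c("beta1", "beta2")] <- 0.3
  nom[c("beta1", "beta2")] <- 0.2
  out <- rbind(min = lo, max = hi)
  if (!is.null(subset)) {
    missing <- setdiff(subset, colnames(out))
    if (length(missing)) stop("unknown parameters: ",
                              paste(missing, collapse = ", "))
    out <- out[, subset, drop = FALSE]
    nom <- nom[subset]
  }
  attr(out, "nominal") <- nom
  out
}

#' Monte-Carlo filtering of sampled trajectories
#'
#' Splits sampled parameter vectors by whether the time-sum of their output
#' trajectory reaches the baseline's (membership `xi = 1` when
#' `sum_t T(t, theta) >= sum_t T(t, theta_hat)`), and contrasts, per
#' parameter, the empirical CDFs of the higher set, the lower set and the
#' full sample (the prior). A large separation between the conditional
#' eCDFs flags a parameter that drives the output.
#'
#' @param samples n x k named matrix of sampled parameter vectors.
#' @param trajectories n x T matrix of output trajectories (rows aligned
#'   with `samples`).
#' @param baseline_trajectory Length-T output of the nominal parameter
#'   vector.
#' @return An object of class `"oncopolicy_filter"`: list with `xi`
#'   (0/1 membership), `higher`/`lower` (row indices), and `separation`
#'   (per-parameter max distance between the two conditional eCDFs;
#'   NA when either set is empty).
#' @export
mc_filter <- function(samples, trajectories, baseline_trajectory) {
  samples <- as.matrix(samples)
  trajectories <- as.matrix(trajectories)
  if (nrow(samples) != nrow(trajectories)) {
    stop("trajectories must align with samples")
  }
  if (is.null(baseline_trajectory)) stop("baseline trajectory is required")
  if (length(baseline_trajectory) != ncol(trajectories)) {
    stop("baseline trajectory length must match the sampled trajectories")
  }
  totals <- rowSums(trajectories)
  xi <- as.integer(totals >= sum(baseline_trajectory))
  hi <- which(xi == 1L)
  lo <- which(xi == 0L)
  separation <- apply(samples, 2, function(x) {
    if (!length(hi) || !length(lo)) return(NA_real_)
    grid <- sort(unique(x))
    f1 <- stats::ecdf(x[hi])
    f0 <- stats::ecdf(x[lo])
    max(abs(f1(grid) - f0(grid)))
  })
  structure(list(xi = xi, higher = hi, lower = lo, samples = samples,
                 totals = totals, separation = separation),
            class = "oncopolicy_filter")
}

#' @export
print.oncopolicy_filter <- function(x, ...) {
  cat("<oncopolicy_filter> n =", length(x$xi), "; higher set:",
      length(x$higher), "; lower set:", length(x$lower), "\n")
  print(signif(sort(x$separation, decreasing = TRUE), 3))
  invisible(x)
}

#' Variance-based total-order sensitivity indices
#'
#' Estimates per-parameter total-order indices for a (possibly
#' vector-valued) model output with a covariance-decomposition
#' generalisation of the Jansen estimator: two independent Latin-hypercube
#' base matrices A and B are drawn, the model is evaluated on A, B and on
#' each hybrid matrix `AB_i` (A with column i replaced from B), and
#'
#' \deqn{ST_i = \frac{\sum_t \frac{1}{2n}\sum_j (f(A)_{jt} - f(AB_i)_{jt})^2}
#'              {\sum_t \widehat{Var}(f_t)}}
#'
#' i.e. componentwise Jansen numerators summed over the output dimensions
#' and normalised by the trace of the output covariance. Small negative
#' estimates are clipped to zero with a warning. The cost is
#' `n_base * (k + 2)` model evaluations.
#'
#' @param evaluator Function mapping a named parameter vector to a numeric
#'   output vector (a trajectory or a scalar).
#' @param ranges 2 x k range matrix (see [sa_ranges()]).
#' @param n_base Number of base samples (>= 8).
#' @param seed Integer seed.
#' @return An object of class `"oncopolicy_sa"`: list with `indices` (raw
#'   total-order estimates), `pct_sst` (share of the summed indices, %),
#'   `n_base`, `evaluations`.
#' @export
total_order_indices <- function(evaluator, ranges, n_base = 64L, seed = 1L) {
  ranges <- as_range_matrix(ranges)
  if (n_base < 8) stop("n_base must be at least 8")
  k <- ncol(ranges)
  nms <- colnames(ranges)
  A <- lhs_sample(ranges, n_base, seed = seed)$samples
  B <- lhs_sample(ranges, n_base, seed = seed + 1L)$samples
  eval_mat <- function(M) {
    out <- apply(M, 1, function(row) {
      as.numeric(evaluator(stats::setNames(row, nms)))
    })
    if (is.matrix(out)) t(out) else matrix(out, ncol = 1L)
  }
  fA <- eval_mat(A)
  fB <- eval_mat(B)
  vtot <- sum(apply(rbind(fA, fB), 2, stats::var))
  if (vtot <= 0) stop("output variance is zero over the sampled box")
  st <- numeric(k)
  for (i in seq_len(k)) {
    ABi <- A
    ABi[, i] <- B[, i]
    fABi <- eval_mat(ABi)
    st[i] <- sum(colMeans((fA - fABi)^2) / 2) / vtot
  }
  names(st) <- nms
  if (any(st < 0)) {
    warning("negative total-order estimates clipped to zero")
    st <- pmax(st, 0)
  }
  structure(list(indices = st, pct_sst = 100 * st / sum(st),
                 n_base = n_base, evaluations = n_base * (k + 2L),
                 seed = seed),
            class = "oncopolicy_sa")
}

#' @export
print.oncopolicy_sa <- function(x, ...) {
  cat("<oncopolicy_sa> total-order indices (", x$evaluations,
      " model evaluations)\n", sep = "")
  ord <- order(x$indices, decreasing = TRUE)
  print(data.frame(ST = signif(x$indices[ord], 3),
                   pct_SST = signif(x$pct_sst[ord], 3)))
  invisible(x)
}

#' Simulation-based evaluator for sensitivity analysis
#'
#' Builds the evaluator used by [total_order_indices()] and [mc_filter()]
#' on the full model: a sampled parameter vector is applied to the nominal
#' parameter set, the policy levers (`eta`, `beta1`, `beta2`) are routed
#' into a scenario starting at `t_star`, the model is simulated and the
#' efficiency target `T(t)` over the post-break-point months is returned.
#'
#' @param params Nominal `"oncopolicy_params"`.
#' @param demography,incidence,macro Model inputs (see [simulate_cancer()]).
#' @param start_year First simulated year.
#' @param months Simulation horizon.
#' @param t_star Policy break-point month for the sampled `eta`/`beta`.
#' @return Function: named parameter vector -> efficiency trajectory.
#' @export
make_sa_evaluator <- function(params, demography, incidence, macro,
                              start_year, months, t_star = params$t_star) {
  force(params)
  function(theta) {
    policy <- intersect(names(theta), c("eta", "beta1", "beta2"))
    p <- set_params(params, theta)
    sc <- scenario_spec("sa", t_star = t_star,
                        beta1 = p$beta1, beta2 = p$beta2, eta = p$eta)
    sim <- simulate_cancer(p, demography, incidence, macro,
                           start_year = start_year, months = months,
                           scenario = sc)
    ef <- efficiency_target(sim)
    ef[(t_star + 1):months]
  }
}
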
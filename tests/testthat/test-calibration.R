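test_that("case-weighted survival aggregation matches direct computation", {
  t2 <- builtin_constants("table2_survival")
  wm <- weighted_survival(t2)
  # independent oracle: explicit weighted sum on the raw rows
  manual <- colSums(as.matrix(t2[, paste0("stage", 1:4)]) * t2$cases) /
    sum(t2$cases)
  expect_equal(unname(wm), unname(manual))
  # single-type table returns its own row
  one <- t2[2, ]
  expect_equal(unname(weighted_survival(one)),
               unname(unlist(one[paste0("stage", 1:4)])))
  expect_error(weighted_survival(transform(t2, cases = 0)), "cases")
})

test_that("loss filtering keeps the best restarts and honours ties", {
  set.seed(5)
  est <- matrix(runif(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  losses <- runif(100)
  f <- filter_and_intervals(est, losses, 0.1)
  # sort oracle
  expect_equal(which(f$kept), sort(order(losses)[1:10]))
  expect_equal(f$nominal, est[which.min(losses), ])
  expect_true(all(f$intervals["min", ] <= f$nominal &
                  f$nominal <= f$intervals["max", ]))
  # single restart: degenerate interval
  f1 <- filter_and_intervals(est[1, , drop = FALSE], losses[1], 0.5)
  expect_equal(f1$intervals["min", ], f1$intervals["max", ])
  # identical losses: everything kept at any fraction
  fe <- filter_and_intervals(est, rep(0.3, 100), 0.01)
  expect_true(all(fe$kept))
  expect_error(filter_and_intervals(est[0, ], numeric(0)), "no estimates")
  expect_error(filter_and_intervals(est, losses, 0), "top_fraction")
})

test_that("the cohort model reproduces geometric-absorption closed forms", {
  # gamma = 1: everyone recovers in the first month
  r <- cohort_model(rep(1, 4), rep(0.5, 4), rep(100, 4), 3)
  expect_true(all(r$recovered == 100))
  expect_true(all(r$deaths == 0))
  # single stage-IV chain: eventual recovered fraction gamma/(gamma+(1-gamma)alpha)
  g4 <- 0.122
  a4 <- 0.23
  r <- cohort_model(c(0, 0, 0, g4), c(0, 0, 0, a4), c(0, 0, 0, 1), 600)
  expect_equal(unname(r$recovered[600, 4]), g4 / (g4 + (1 - g4) * a4),
               tolerance = 1e-9)
  expect_equal(unname(r$deaths[600, 4]), 1 - g4 / (g4 + (1 - g4) * a4),
               tolerance = 1e-9)
  # trajectories are cumulative and monotone
  expect_true(all(diff(r$recovered[, 4]) >= 0))
})

test_that("undiagnosed calibration pins delta_s0 and reproduces the shares", {
  shares <- builtin_constants("cac2021_shares")
  fit <- fit_undiagnosed(shares, n_restarts = 40, seed = 3)
  expect_equal(unname(fit$nominal["delta_s0"]), 0.0874, tolerance = 2e-3)
  # every kept estimate reproduces the target composition
  expect_lt(max(fit$losses[fit$kept]), 1e-6)
  # stationarity identity: detections equal inflow at the fitted optimum,
  # so shares sum to one even though the target sums to 0.9998
  m <- stationary_undiagnosed_shares(fit$nominal[1:4], fit$nominal[5:7])
  expect_equal(sum(m), 1, tolerance = 1e-12)
  # dispersion diagnostic: delta_s0 pinned, progression directions loose
  expect_lt(fit$dispersion["delta_s0"], 1e-3)
  expect_gt(max(fit$dispersion[5:7]), 0.05)
  # degenerate target: everything detected at the very start
  fd <- fit_undiagnosed(c(1, 0, 0, 0, 0), n_restarts = 20, seed = 4)
  expect_equal(unname(fd$nominal["delta_s0"]), 1, tolerance = 1e-4)
  expect_error(fit_undiagnosed(c(0.5, 0.5, 0.2, 0, 0)), "sum")
})

test_that("diagnosed calibration recovers known parameters from its own trajectories", {
  g0 <- c(0.2, 0.25, 0.3, 0.2)
  a0 <- c(0.5, 0.5, 0.4, 0.2)
  traj <- cohort_model(g0, a0, rep(1000, 4), 12)$recovered
  fit <- fit_diagnosed(rep(0.5, 4), alpha_upper_bounds = c(1, 1, 1),
                       n_restarts = 60, seed = 3,
                       target_trajectories = traj)
  # loss -> 0 (targets are in patient counts, cohorts of 1000)
  expect_lt(fit$loss_nominal, 1e-3)
  expect_equal(unname(fit$nominal), c(g0, a0), tolerance = 1e-2)
})

test_that("diagnosed calibration reproduces survival ordering across stages", {
  wm <- builtin_constants("table2_weighted_mean")
  fit <- fit_diagnosed(wm, n_restarts = 40, seed = 2)
  surv24 <- cohort_model(fit$nominal[1:4], fit$nominal[5:8],
                         rep(1, 4), 24)$recovered[24, ]
  # five-year survival decreases with detection stage; so must the fit
  expect_true(all(diff(surv24) < 0))
  # progression bounds from the undiagnosed nominals are respected
  ub <- builtin_constants("table1_nominal")[5:7]
  expect_true(all(fit$nominal[5:7] <= ub + 1e-9))
  # all-survive targets force high recovery probabilities
  f1 <- fit_diagnosed(rep(1, 4), n_restarts = 20, seed = 1)
  expect_true(all(f1$nominal[1:4] > 0.9))
  expect_error(fit_diagnosed(c(0.5, 0.5)), "4 probabilities")
  expect_error(fit_diagnosed(rep(0.5, 4), alpha_upper_bounds = c(1, 1)),
               "length 3")
})

test_that("tier survival targets bracket the weighted means", {
  tg <- tier_survival_targets()
  expect_equal(dim(tg), c(3, 4))
  expect_true(all(tg["T1", ] < tg["T2", ]))
  expect_true(all(tg["T2", ] < tg["T3", ]))
  expect_equal(round(unname(tg["T2", ]), 3),
               unname(builtin_constants("table2_weighted_mean")))
})
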
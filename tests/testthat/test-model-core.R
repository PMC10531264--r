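test_that("treatment-tier hierarchy yields valid marginal probabilities", {
  expect_equal(assign_treatment(0, 0), c(T1 = 0, T2 = 0, T3 = 1))
  expect_equal(assign_treatment(1, 0.3), c(T1 = 1, T2 = 0, T3 = 0))
  expect_equal(assign_treatment(1, 0.9), c(T1 = 1, T2 = 0, T3 = 0))
  # published conditional values give the published tier shares
  m <- assign_treatment(0.196, 0.260)
  expect_equal(unname(m), c(0.196, 0.20904, 0.59496), tolerance = 1e-12)
  set.seed(1)
  for (i in 1:20) {
    m <- assign_treatment(runif(1), runif(1))
    expect_equal(sum(m), 1, tolerance = 1e-12)
    expect_true(all(m >= 0))
  }
  expect_error(assign_treatment(-0.1, 0.5), "lambda")
  expect_error(assign_treatment(0.5, 1.2), "lambda")
})

test_that("a monthly step follows the recovery > detection > progression hierarchy", {
  p0 <- default_parameters(delta = rep(0, 4), alphaU = rep(0, 3),
                           gamma = matrix(0, 4, 3), alphaD = matrix(0, 4, 3))
  st <- random_state(3)
  st$N[, 4] <- 0  # stage-IV undiagnosed move regardless of probabilities
  r <- step_state(st, p0, inflow = 0)
  # identity case: nothing moves, only occupancy-driven costs accrue
  expect_equal(r$state$N, st$N)
  expect_equal(r$state$D, st$D)
  expect_equal(r$R, 0)
  expect_equal(r$X, 0)
  expect_equal(r$G, spending(st, p0))

  # hand-evaluated hierarchy algebra for one diagnosed stage-IV patient:
  # recovery first (gamma), then death among the non-recovered (alphaD)
  p <- default_parameters()
  st <- disease_state(1)
  st$D[1, 4, 1] <- 1
  r <- step_state(st, p, inflow = 0)
  expect_equal(r$state$D[1, 4, 1], (1 - 0.122) * (1 - 0.23), tolerance = 1e-12)
  expect_equal(r$X, (1 - 0.122) * 0.23, tolerance = 1e-12)
  expect_equal(r$R, 0.122, tolerance = 1e-12)
})

test_that("undiagnosed stage-IV patients are fully diagnosed the next step", {
  p <- default_parameters()
  st <- disease_state(1)
  st$N[1, 4] <- 1
  r <- step_state(st, p, inflow = 0)
  expect_equal(sum(r$state$N), 0)
  expect_equal(r$X, 0)  # arrivals only start flowing the month after
  expect_equal(unname(r$state$D[1, 4, ]),
               unname(assign_treatment(p$lambda[4, 1], p$lambda[4, 2])),
               tolerance = 1e-12)
  expect_equal(r$new_diagnoses, 1)
})

test_that("every step conserves persons and preserves non-negativity", {
  set.seed(42)
  for (i in 1:20) {
    p <- random_valid_params()
    st <- random_state(5)
    inflow <- runif(5, 0, 50)
    tot0 <- sum(st$N) + sum(st$D)
    r <- step_state(st, p, inflow)
    tot1 <- sum(r$state$N) + sum(r$state$D)
    expect_equal(sum(inflow), tot1 - tot0 + r$R + r$X,
                 tolerance = 1e-9 * max(1, tot0))
    expect_true(min(r$state$N) >= 0 && min(r$state$D) >= 0)
  }
})

test_that("the update is linear in occupancies and inflow (superposition)", {
  set.seed(7)
  p <- random_valid_params()
  s1 <- random_state(4)
  s2 <- random_state(4)
  i1 <- runif(4, 0, 10)
  i2 <- runif(4, 0, 10)
  both <- disease_state(4)
  both$N <- s1$N + s2$N
  both$D <- s1$D + s2$D
  r1 <- step_state(s1, p, i1)
  r2 <- step_state(s2, p, i2)
  rb <- step_state(both, p, i1 + i2)
  expect_equal(rb$state$N, r1$state$N + r2$state$N, tolerance = 1e-12)
  expect_equal(rb$state$D, r1$state$D + r2$state$D, tolerance = 1e-12)
  expect_equal(rb$R, r1$R + r2$R, tolerance = 1e-12)
  expect_equal(rb$X, r1$X + r2$X, tolerance = 1e-12)
})

test_that("closed-form stationary detection shares match the iterated model", {
  p <- builtin_constants("table1_nominal")
  cf <- stationary_undiagnosed_shares(p[1:4], p[5:7])
  expect_equal(sum(cf), 1, tolerance = 1e-12)
  sim <- undiagnosed_shares_sim(p[1:4], p[5:7], months = 120)
  expect_equal(cf, sim, tolerance = 1e-9)
  # burn-in claim: stationary well before 120 months
  sim90 <- undiagnosed_shares_sim(p[1:4], p[5:7], months = 91)
  expect_lt(max(abs(cf - sim90)), 1e-6)
  # the share trajectory converges to the same limit
  traj <- undiagnosed_share_trajectory(p[1:4], p[5:7], months = 120)
  expect_equal(unname(traj[120, ]), unname(cf), tolerance = 1e-9)
  # moderate random parameterizations agree too, given enough steps
  set.seed(11)
  for (i in 1:5) {
    d <- runif(4, 0.05, 0.95)
    a <- runif(3, 0.05, 0.95)
    expect_equal(stationary_undiagnosed_shares(d, a),
                 undiagnosed_shares_sim(d, a, months = 3000),
                 tolerance = 1e-9)
  }
  expect_equal(unname(stationary_undiagnosed_shares(c(1, 0.5, 0.5, 0.5),
                                                    rep(0.5, 3))),
               c(1, 0, 0, 0, 0))
  expect_error(stationary_undiagnosed_shares(rep(0, 4), rep(0, 3)),
               "degenerate")
})

test_that("spending prices diagnosed occupancy with the epsilon correction", {
  p1 <- default_parameters(epsilon = 1)
  st <- disease_state(1)
  expect_equal(spending(st, p1), 0)
  st$D[1, 1, 1] <- 1
  expect_equal(spending(st, p1), 747500)
  p <- default_parameters()  # epsilon = 0.642
  st <- disease_state(1)
  st$D[1, 4, 3] <- 1
  expect_equal(spending(st, p), 12416666.667 * 0.642, tolerance = 1e-9)
  # the diagnosis cost is not epsilon-corrected
  expect_equal(spending(disease_state(1), p, new_diagnoses = 2),
               2 * 916000)
  # price index scales everything
  expect_equal(spending(st, p, new_diagnoses = 1, price_index = 1.5),
               1.5 * (12416666.667 * 0.642 + 916000), tolerance = 1e-9)
})

test_that("full simulation behaves: zero incidence, stationarity, conservation", {
  w <- constant_world
  p <- default_parameters()
  inc0 <- w$incidence
  inc0$rate_per_100k_year <- 0
  sim0 <- simulate_cancer(p, w$demography, inc0, w$macro, 2005, 24)
  expect_true(all(sim0$series$X == 0))
  expect_true(all(sim0$series$G == 0))

  sim <- simulate_cancer(p, w$demography, w$incidence, w$macro, 2005, 240)
  s <- sim$series
  # constant demography + rates: monthly deaths and spending become constant
  expect_equal(s$X[240], s$X[216], tolerance = 1e-6)
  expect_equal(s$G[240], s$G[216], tolerance = 1e-6)
  # series lengths and population bookkeeping
  expect_equal(nrow(s), 240)
  expect_equal(s$P[1], sum(w$demography$population[w$demography$year == 2005]))
  expect_equal(s$mortality_per_100k, s$X / s$P * 1e5)
  # whole-horizon person conservation: cumulative inflow = occupancy + R + X
  pop2005 <- w$demography$population[w$demography$year == 2005]
  phi <- rep(w$incidence$rate_per_100k_year / 1e5, each = 10)[1:101]
  inflow_total <- 240 * sum(pop2005 * phi / 12)
  final_occ <- sum(sim$state$N) + sum(sim$state$D)
  expect_equal(inflow_total, final_occ + sum(s$R) + sum(s$X),
               tolerance = 1e-9 * inflow_total)
  expect_error(simulate_cancer(p, w$demography, w$incidence, w$macro,
                               2005, 12 * 80),
               "span")
})

test_that("all incident cases are eventually absorbed when recovery is impossible", {
  # gamma = 0 and certain stage-IV death: every case must reach X
  p <- default_parameters(gamma = matrix(0, 4, 3),
                          alphaD = rbind(matrix(builtin_constants("table3_nominal")$alpha[1:3, ], 3, 3),
                                         rep(1, 3)))
  st <- disease_state(1)
  r <- step_state(st, p, inflow = 1)  # single pulse of one case
  deaths <- r$X
  for (t in 1:600) {
    r <- step_state(r$state, p, inflow = 0)
    deaths <- deaths + r$X
  }
  expect_equal(deaths, 1, tolerance = 1e-6)
  expect_lt(sum(r$state$N) + sum(r$state$D), 1e-6)
})

test_that("parameter container validates and round-trips scalar names", {
  p <- default_parameters()
  v <- flatten_params(p)
  expect_length(v, 55)
  expect_equal(unname(v["gamma_s4T3"]), 0.25)
  expect_equal(unname(v["C_s2T2"]), 4325000)
  p2 <- set_params(p, c(delta_s0 = 1, gamma_s1T3 = 0.6, lambda_s1T1 = 0.1))
  expect_equal(unname(p2$delta["s0"]), 1)
  expect_equal(p2$gamma["s1", "T3"], 0.6)
  expect_equal(p2$lambda["s1", "T1"], 0.1)
  expect_equal(p2$lambda["s2", "T1"], 0.196)  # other stages untouched
  expect_error(set_params(p, c(nonsense = 1)), "unknown parameter")
  expect_error(default_parameters(delta = c(-0.1, 0, 0, 0)), "\\[0, 1\\]")
  expect_error(default_parameters(beta2 = 0), "beta2")
  expect_error(default_parameters(epsilon = 0), "epsilon")
})
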
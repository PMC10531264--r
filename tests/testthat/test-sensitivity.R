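test_that("the efficiency target is per-capita spending times per-capita deaths", {
  s <- data.frame(G = c(1e6, 2e6), X = c(10, 0), P = c(1e5, 1e5))
  expect_equal(efficiency_target(s), c(1e6 * 10 / 1e10, 0))
  s2 <- transform(s, G = 2 * G)
  expect_equal(efficiency_target(s2), 2 * efficiency_target(s))  # linear in G
  expect_error(efficiency_target(data.frame(G = 1, X = 1, P = 0)), "positive")
})

test_that("Latin hypercube sampling stratifies every margin and is reproducible", {
  rng <- rbind(min = c(a = 0, b = 10), max = c(a = 1, b = 30))
  d <- lhs_sample(rng, 2, seed = 1)
  expect_equal(dim(d$samples), c(2, 2))
  # one point in each half of [0, 1]
  expect_equal(sort(findInterval(d$samples[, "a"], c(0, 0.5, 1))), c(1, 2))
  # general stratification: exactly one point per 1/n stratum per column
  d100 <- lhs_sample(rng, 100, seed = 2)
  u <- (d100$samples[, "b"] - 10) / 20
  expect_equal(sort(ceiling(u * 100)), 1:100)
  # determinism and range containment
  expect_identical(lhs_sample(rng, 50, seed = 9)$samples,
                   lhs_sample(rng, 50, seed = 9)$samples)
  expect_true(all(d100$samples[, "b"] >= 10 & d100$samples[, "b"] <= 30))
  expect_error(lhs_sample(rng, 1), "at least 2")
  expect_error(lhs_sample(rbind(c(1, 0), c(0, 1)), 10), "malformed")
})

test_that("the uncertainty box spans 50-150% of nominal with the stated exceptions", {
  rng <- sa_ranges()
  expect_equal(ncol(rng), 43)  # costs fixed, 43 varied parameters
  expect_false(any(grepl("^C_s", colnames(rng))))
  nom <- attr(rng, "nominal")
  expect_equal(unname(rng[, "gamma_s4T3"]), c(0.125, 0.375))
  expect_equal(unname(rng[, "delta_s0"]), c(0.04375, 0.13125))
  expect_equal(unname(rng[, "C_diag"]), c(458000, 1374000))
  expect_equal(unname(rng[, "eta"]), c(0, 3 / 7))
  expect_equal(unname(rng[, "beta1"]), c(0.1, 0.3))
  expect_equal(unname(nom["beta2"]), 0.2)
  # probabilities never exceed 1
  probs <- setdiff(colnames(rng), c("C_diag", "eta", "beta1", "beta2"))
  expect_true(all(rng["max", probs] <= 1))
})

test_that("MC filtering splits by the baseline total and flags driving parameters", {
  # 1-parameter toy T = theta: split exactly at the baseline value
  rng <- rbind(min = c(th = 0), max = c(th = 1))
  d <- lhs_sample(rng, 200, seed = 3)
  traj <- matrix(d$samples[, 1], ncol = 1)
  fl <- mc_filter(d$samples, traj, baseline_trajectory = 0.5)
  expect_equal(fl$xi, as.integer(d$samples[, 1] >= 0.5))
  expect_equal(fl$separation[["th"]], 1, tolerance = 0.05)
  # baseline evaluated on itself belongs to the higher set (>= with equality)
  fl0 <- mc_filter(matrix(0.5), matrix(0.5), 0.5)
  expect_equal(fl0$xi, 1L)
  # a parameter the output ignores separates ever less as n grows
  rng2 <- rbind(min = c(used = 0, unused = 0), max = c(used = 1, unused = 1))
  d2 <- lhs_sample(rng2, 500, seed = 4)
  fl2 <- mc_filter(d2$samples, matrix(d2$samples[, "used"], ncol = 1), 0.5)
  expect_lt(fl2$separation[["unused"]], 0.15)
  expect_gt(fl2$separation[["used"]], 0.9)
  expect_error(mc_filter(d2$samples, matrix(1, 10, 1), 0.5), "align")
})

test_that("total-order indices match analytic values on known test functions", {
  # additive linear model: share of X1 is a^2 V1 / (a^2 V1 + b^2 V2)
  rng <- rbind(min = c(x1 = 0, x2 = 0), max = c(x1 = 1, x2 = 1))
  f <- function(th) 2 * th[["x1"]] + 1 * th[["x2"]]
  sa <- total_order_indices(f, rng, n_base = 1024, seed = 2)
  expect_equal(unname(sa$pct_sst), c(80, 20), tolerance = 0.05)
  # dummy parameter has a vanishing index
  rng3 <- cbind(rng, dummy = c(0, 1))
  sa3 <- total_order_indices(function(th) 2 * th[["x1"]] + th[["x2"]],
                             rng3, n_base = 1024, seed = 2)
  expect_lt(sa3$indices[["dummy"]], 0.02)
  # interacting 3-parameter function with known total-order indices
  A <- 7
  B <- 0.1
  ish <- function(th) A * sin(th[["x2"]])^2 +
    (1 + B * th[["x3"]]^4) * sin(th[["x1"]])
  rngI <- rbind(min = rep(-pi, 3), max = rep(pi, 3))
  colnames(rngI) <- c("x1", "x2", "x3")
  V1 <- 0.5 * (1 + B * pi^4 / 5)^2
  V2 <- A^2 / 8
  V13 <- B^2 * pi^8 * (1 / 18 - 1 / 50)
  V <- V1 + V2 + V13
  truth <- c((V1 + V13) / V, V2 / V, V13 / V)
  saI <- total_order_indices(ish, rngI, n_base = 4096, seed = 5)
  expect_equal(unname(saI$indices), truth, tolerance = 0.1)
  expect_error(total_order_indices(f, rng, n_base = 4), "n_base")
})

test_that("eCDF separation and total-order indices rank parameters alike", {
  rng <- rbind(min = c(big = 0, small = 0), max = c(big = 1, small = 1))
  f <- function(th) 3 * th[["big"]] + 0.2 * th[["small"]]
  sa <- total_order_indices(f, rng, n_base = 256, seed = 6)
  d <- lhs_sample(rng, 300, seed = 7)
  traj <- matrix(apply(d$samples, 1, function(r) f(as.list(r))), ncol = 1)
  fl <- mc_filter(d$samples, traj, f(list(big = 0.5, small = 0.5)))
  expect_equal(order(sa$indices), order(fl$separation))
  expect_gt(stats::cor(sa$indices, fl$separation, method = "spearman"), 0)
})
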
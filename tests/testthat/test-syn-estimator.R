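test_that("weight-to-activation reconstruction matches an explicit double loop", {
  H <- test_H(3, 25, seed = 2)
  expect_true(all(activations_from_weights(matrix(0, 4, 3), H) == 0))
  a1 <- activations_from_weights(matrix(0.6, 1, 1), test_H(1, 25, seed = 3))
  expect_equal(max(a1), 0.6)
  set.seed(5)
  w <- matrix(runif(4 * 3), 4, 3)
  a <- activations_from_weights(w, H)
  oracle <- matrix(0, 25, 4)
  for (t in 1:25) for (i in 1:4) for (s in 1:3) {
    oracle[t, i] <- oracle[t, i] + w[i, s] * H[s, t]
  }
  expect_equal(a, oracle, tolerance = 1e-12)
  expect_error(activations_from_weights(w, test_H(2, 25)),
               class = "argument_error")
  expect_error(activations_from_weights(-w, H), class = "argument_error")
})

test_that("cost terms match direct summation oracles on random cases", {
  set.seed(8)
  M1 <- matrix(rnorm(12), 4, 3); M2 <- matrix(rnorm(12), 4, 3)
  expect_equal(cost_moment_tracking(M1, M2, 5),
               sum(((M1 - M2) / 5)^2) / 12, tolerance = 1e-12)
  a <- matrix(runif(4 * 6), 4, 6)
  expect_equal(cost_activation(a, 0.5), sum((a / 0.5)^2) / 24,
               tolerance = 1e-12)
  expect_equal(cost_activation(matrix(0.5, 1, 1), 0.25), 4)
  groups <- list(g1 = 1:2, g2 = 3:6)
  direct <- 0
  for (g in groups) {
    sub <- a[, g, drop = FALSE]
    for (t in 1:4) for (i in seq_along(g)) {
      direct <- direct + ((sub[t, i] - mean(sub[t, ])) / 0.05)^2 /
        (4 * length(g))
    }
  }
  expect_equal(cost_activation_deviation(a, groups, 0.05), direct,
               tolerance = 1e-12)
  w <- matrix(runif(6 * 3), 6, 3)
  direct_w <- 0
  for (g in groups) {
    sub <- w[g, , drop = FALSE]
    for (s in 1:3) for (i in seq_along(g)) {
      direct_w <- direct_w + ((sub[i, s] - mean(sub[, s])) / 0.05)^2 /
        (3 * length(g))
    }
  }
  expect_equal(cost_weight_deviation(w, groups, 0.05), direct_w,
               tolerance = 1e-12)
  expect_error(cost_activation_deviation(a, list(integer(0))),
               class = "argument_error")
  expect_error(cost_moment_tracking(M1, matrix(NaN, 4, 3)),
               class = "data_error")
})

test_that("cost terms hit their calibration points", {
  M <- matrix(rnorm(9), 3, 3)
  expect_equal(cost_moment_tracking(M, M), 0)
  expect_equal(cost_moment_tracking(M + 5, M, allow_dM = 5), 1)
  expect_equal(cost_activation(matrix(0, 3, 2)), 0)
  expect_equal(cost_activation(matrix(0.5, 3, 2), allow_a = 0.5), 1)
  # one group, 2 heads, nPt = 1, a = {0.5, 0.6}: deviations are +/- 0.05
  expect_equal(cost_activation_deviation(matrix(c(0.5, 0.6), 1), list(1:2),
                                         allow_da = 0.05), 1)
  expect_equal(cost_weight_deviation(matrix(c(0.10, 0.20), 2, 1), list(1:2),
                                     allow_dw = 0.05), 1)
  expect_equal(cost_activation_deviation(matrix(0.4, 5, 4),
                                         list(1:2, 3:4), 0.05), 0)
})

test_that("the tiny-instance optimum matches an exhaustive grid search", {
  # 2 MTUs (one group), 1 synergy, 1 DoF, 3 samples
  model <- const_model(matrix(c(0.04, 0.06), 2, 1), fmo = c(400, 300))
  model$mtus$fmo <- c(400, 300)
  H <- matrix(c(1, 0.5, 0.25), 1)
  M_ref <- matrix(c(8, 4, 2), 3, 1)
  fit <- syn_estimate(model, M_ref, H)
  gains <- c(0.04 * 400, 0.06 * 300)     # lnorm = 1 so dM/da = r * FMo
  grid <- seq(0, 1, by = 0.005)
  obj <- outer(grid, grid, function(w1, w2) {
    jm <- ja <- jad <- 0
    for (t in 1:3) {
      a1 <- w1 * H[1, t]; a2 <- w2 * H[1, t]
      jm <- jm + ((gains[1] * a1 + gains[2] * a2 - M_ref[t, 1]) / 5)^2 / 3
      ja <- ja + ((a1 / 0.5)^2 + (a2 / 0.5)^2) / 6
      jad <- jad + (((a1 - a2) / 2 / 0.05)^2 * 2) / 6
    }
    jwd <- ((w1 - w2) / 2 / 0.05)^2
    jm + ja + jad + jwd
  })
  best <- which(obj == min(obj), arr.ind = TRUE)[1, ]
  expect_lt(max(abs(as.numeric(fit$weights) -
                      grid[c(best[1], best[2])])), 0.0051)
  expect_lte(fit$costs$total, min(obj) + 1e-8)
})

test_that("zero reference moments drive the weights to zero", {
  model <- random_model(4, 2, 20, seed = 77)
  model$mtus$group <- c("A", "A", "B", "B")
  H <- test_H(2, 20, seed = 78)
  fit <- syn_estimate(model, matrix(0, 20, 2), H,
                      syn_control(allow_a = 0.25))
  expect_lt(max(abs(fit$weights)), 1e-3)
})

test_that("noiseless synthetic moments are inverted to the true activations", {
  ds <- make_dataset(syn_spec(n_cycles = 1, n_pt = 61, seed = 5,
                              activation_noise_sd = 0, moment_noise_sd = 0))
  cy <- ds$cycles[[1]]
  fit <- syn_estimate(ds$model, cy$M_ID, cy$H_true)
  expect_lte(fit$costs$j_m, 0.01)
  grp <- grouping(ds$model)
  r <- recovery_correlation(fit$activations, cy$trunk_true, grp)
  expect_gte(mean(r), 0.95)
  # solution invariants
  expect_true(all(fit$weights >= 0))
  expect_true(all(fit$activations >= -1e-6 & fit$activations <= 1 + 1e-6))
  with(fit$costs, expect_equal(total, j_m + j_a + j_a_dev + j_w_dev,
                               tolerance = 1e-9))
  # no worse than the all-zero feasible start
  zero_cost <- cost_moment_tracking(joint_moments(0 * fit$activations,
                                                  ds$model), cy$M_ID)
  expect_lte(fit$costs$total, zero_cost)
  expect_true(fit$converged)
})

test_that("the activation upper bound is enforced when moments demand saturation", {
  model <- const_model(matrix(0.05, 1, 1), fmo = 1000, n_pt = 5)
  H <- matrix(rep(1, 5), 1)                     # constant synergy
  # demanding 200 Nm from a 50 Nm-capable muscle would need a = 4
  fit <- syn_estimate(model, matrix(200, 5, 1), H,
                      syn_control(allow_a = 1))
  expect_lte(max(fit$activations), 1 + 1e-6)
  expect_gte(max(fit$activations), 0.99)        # bound is active
})

test_that("the literal three-term objective can be requested", {
  model <- random_model(4, 2, 15, seed = 91)
  model$mtus$group <- c("A", "A", "B", "B")
  H <- test_H(2, 15, seed = 92)
  set.seed(93)
  M <- matrix(rnorm(30, 0, 5), 15, 2)
  f3 <- syn_estimate(model, M, H, syn_control(include_jw_dev = FALSE))
  expect_true(is.na(f3$costs$j_w_dev))
  with(f3$costs, expect_equal(total, j_m + j_a + j_a_dev, tolerance = 1e-9))
})

test_that("inputs are validated", {
  model <- random_model(3, 2, 10, seed = 95)
  H_bad <- matrix(runif(20, 0, 0.5), 2)          # not max-normalized
  expect_error(syn_estimate(model, matrix(0, 10, 2), H_bad),
               class = "argument_error")
  H <- test_H(2, 10, seed = 96)
  expect_error(syn_estimate(model, matrix(0, 9, 2), H),
               class = "argument_error")
  expect_error(syn_estimate(model, matrix(NaN, 10, 2), H),
               class = "data_error")
})

test_that("smaller activation allowances never increase the mean activation", {
  ds <- make_dataset(syn_spec(n_cycles = 1, n_pt = 41, seed = 15,
                              activation_noise_sd = 0, moment_noise_sd = 0))
  cy <- ds$cycles[[1]]
  means <- sapply(c(1.00, 0.75, 0.50, 0.25), function(al) {
    mean(abs(syn_estimate(ds$model, cy$M_ID, cy$H_true,
                          syn_control(allow_a = al))$activations))
  })
  expect_true(all(diff(means) <= 1e-9))   # decreasing allowance, tighter a
})

test_that("moment subtraction removes exactly the subset contribution", {
  mod <- random_model(5, 3, 12, seed = 101)
  set.seed(102)
  A <- matrix(runif(12 * 5), 12, 5)
  M_tot <- joint_moments(A, mod) + matrix(rnorm(36), 12, 3)
  expect_equal(subtract_muscle_moments(M_tot, 0 * A, mod), M_tot,
               tolerance = 1e-12)
  resid <- subtract_muscle_moments(joint_moments(A, mod), A, mod)
  expect_lt(max(abs(resid)), 1e-12)
  expect_equal(subtract_muscle_moments(M_tot, A, mod),
               M_tot - joint_moments(A, mod), tolerance = 1e-12)
  expect_error(subtract_muscle_moments(M_tot[1:5, ], A, mod),
               class = "argument_error")
})

test_that("fitted model methods expose weights, activations and residuals", {
  ds <- make_dataset(syn_spec(n_cycles = 2, n_pt = 41, seed = 25,
                              activation_noise_sd = 0, moment_noise_sd = 0))
  cy <- ds$cycles[[1]]
  fit <- syn_estimate(ds$model, cy$M_ID, cy$H_true)
  expect_identical(coef(fit), fit$weights)
  expect_identical(fitted(fit), fit$activations)
  expect_equal(residuals(fit), cy$M_ID - fit$moments, tolerance = 1e-12)
  expect_output(print(fit), "trunk activation estimate")
  expect_output(print(summary(fit)), "moment tracking RMSE")
  # predicting on the fitting synergies reproduces the fit
  expect_equal(predict(fit), fit$activations, tolerance = 1e-12)
  # predicting on another cycle's synergies applies the same weights
  a2 <- predict(fit, synergies = ds$cycles[[2]]$H_true)
  oracle <- fit$weights
  sides <- ds$model$mtus$side
  for (i in seq_len(nrow(oracle))) {
    expect_equal(a2[, i],
                 as.numeric(crossprod(ds$cycles[[2]]$H_true[[sides[i]]],
                                      oracle[i, ])), tolerance = 1e-12)
  }
  M2 <- predict(fit, synergies = ds$cycles[[2]]$H_true, type = "moments")
  expect_equal(M2, joint_moments(a2, ds$model), tolerance = 1e-12)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
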
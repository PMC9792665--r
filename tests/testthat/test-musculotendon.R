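test_that("normalized fiber length follows the rigid-tendon definition with clamps", {
  expect_equal(as.numeric(normalized_fiber_length(0.2, 0.1, 0.1)), 1)
  expect_equal(as.numeric(normalized_fiber_length(0.295, 0.10, 0.20)), 0.95)
  expect_equal(as.numeric(normalized_fiber_length(0.2, 0.1, 0.2)), 0.01)
  clamped <- normalized_fiber_length(c(0.1, 0.5), 0.1, 0.2)
  expect_equal(attr(clamped, "clamped"), 2)   # floor and ceiling hit
  expect_equal(as.numeric(clamped), c(0.01, 1.8))
})

test_that("Hill force-length multipliers follow their closed forms", {
  expect_equal(active_fl(1), 1)
  d <- seq(0.05, 0.5, by = 0.05)
  expect_equal(active_fl(1 + d), active_fl(1 - d))
  expect_equal(active_fl(0.95), exp(-0.0025 / 0.45))
  expect_equal(passive_fl(1), 0)
  expect_equal(passive_fl(1.7), 1)
  grid <- seq(1.01, 1.8, by = 0.01)
  expect_true(all(diff(passive_fl(grid)) > 0))
  expect_true(all(passive_fl(seq(0.2, 1, by = 0.1)) == 0))
})

test_that("musculotendon force is affine in activation and bounded", {
  expect_equal(mtu_force(0, 750, 0.1, 0.1, 0.2), 0)
  expect_equal(mtu_force(1, 750, 0.1, 0.1, 0.2), 750)
  expect_equal(mtu_force(0.5, 750, 0.1, 0.1, 0.2), 375)
  a <- seq(0, 1, by = 0.1)
  f <- mtu_force(a, 500, 0.1, 0.1, 0.23)
  expect_true(all(diff(f) > 0))                       # non-decreasing in a
  expect_true(all(f <= 500 * (1 + passive_fl(1.3))))
  expect_error(mtu_force(1.2, 500, 0.1, 0.1, 0.2), class = "argument_error")
  # passive force adds the activation-independent term
  expect_equal(mtu_force(0, 500, 0.1, 0.1, 0.25, passive = TRUE),
               500 * passive_fl(1.5))
})

test_that("joint moments match a brute-force triple-loop oracle", {
  m1 <- const_model(matrix(0.05, 1, 1), fmo = 2000)
  # one muscle, r = 0.05 m, F = 100 N -> 5 Nm
  expect_equal(unname(joint_moments(matrix(0.05, 3, 1), m1)[1, 1]), 5)
  m2 <- const_model(matrix(c(0.05, -0.05), 2, 1))
  expect_equal(max(abs(joint_moments(matrix(0.3, 3, 2), m2))), 0)
  mod <- random_model(5, 3, 4, seed = 21)
  set.seed(22)
  A <- matrix(runif(4 * 5), 4, 5)
  M <- joint_moments(A, mod)
  oracle <- array(0, c(4, 3))
  for (t in 1:4) for (j in 1:3) for (i in 1:5) {
    oracle[t, j] <- oracle[t, j] + mod$geometry$arms[t, i, j] *
      mtu_force(A[t, i], mod$mtus$fmo[i], mod$mtus$lmo[i],
                mod$mtus$lts[i], mod$geometry$lmt[t, i])
  }
  expect_equal(unname(M), oracle, tolerance = 1e-12)
  # affine in activations: M(A1 + A2) + M(0) = M(A1) + M(A2)
  A2 <- matrix(runif(4 * 5, 0, 0.5), 4, 5)
  lhs <- joint_moments(pmin(A + A2, 1), mod) + joint_moments(0 * A, mod)
  rhs <- joint_moments(A, mod) + joint_moments(pmin(A + A2, 1) - A, mod)
  expect_equal(lhs, rhs, tolerance = 1e-10)
  bad <- mod; bad$geometry$lmt[2, 3] <- NaN
  expect_error(joint_moments(A, bad), class = "data_error")
})

test_that("strength personalization multiplies ACSA by 100 N/cm^2", {
  expect_equal(fmax_from_acsa(7.50), 750)
  expect_equal(fmax_from_acsa(8.92), 892)
  expect_equal(fmax_from_acsa(0), 0)
  expect_error(fmax_from_acsa(-1), class = "argument_error")
})

test_that("group ACSA distribution preserves fraction ratios and totals", {
  expect_equal(distribute_group_acsa(10, 3), 10)
  expect_equal(distribute_group_acsa(10, c(1, 1)), c(5, 5))
  set.seed(31)
  for (i in 1:5) {
    gen <- runif(sample(2:6, 1), 0.1, 3)
    tot <- runif(1, 0, 20)
    out <- distribute_group_acsa(tot, gen)
    expect_equal(sum(out), tot, tolerance = 1e-12)
    expect_equal(out / sum(out), gen / sum(gen), tolerance = 1e-12)
  }
  expect_error(distribute_group_acsa(5, c(0, 0)), class = "argument_error")
})

test_that("fiber-length tuning hits the target operating length exactly", {
  set.seed(41)
  for (i in 1:5) {
    lmo <- runif(1, 0.02, 0.2); lts <- runif(1, 0, 0.3)
    lmt <- runif(20, lts + 0.5 * lmo, lts + 1.4 * lmo)
    tuned <- tune_fiber_lengths(lmo, lts, lmt, target = 0.95)
    expect_equal(max((lmt - tuned$lts) / tuned$lmo), 0.95, tolerance = 1e-9)
    expect_equal(tuned$lts / (tuned$lts + tuned$lmo), lts / (lts + lmo),
                 tolerance = 1e-9)                       # ratio held fixed
    # fixed point: re-tuning changes nothing
    again <- tune_fiber_lengths(tuned$lmo, tuned$lts, lmt, target = 0.95)
    expect_equal(again$lmo, tuned$lmo, tolerance = 1e-9)
  }
  # lTs = 0 closed form: lMo = max(lMT) / target
  t0 <- tune_fiber_lengths(0.1, 0, c(0.18, 0.19), target = 0.95)
  expect_equal(t0$lmo, 0.19 / 0.95, tolerance = 1e-12)
  expect_equal(t0$lts, 0)
  expect_error(tune_fiber_lengths(0.1, 0.1, numeric(0)), class = "data_error")
  expect_error(tune_fiber_lengths(0.1, 0.1, c(0.2, -0.1)), class = "data_error")
  expect_error(tune_fiber_lengths(0.1, 0.1, 0.2, target = 1.2),
               class = "argument_error")
})

test_that("muscle-set reduction recovers strengths for identity and merge maps", {
  orig <- random_model(6, 3, 10, seed = 51)
  sampler <- function(seed) {
    set.seed(seed)
    list(arms = matrix(runif(18, -0.06, 0.06), 6, 3),
         lmt = runif(6, 0.15, 0.25))
  }
  f_id <- reduce_mtu_set(orig, 1:6, sampler, 40, seed = 1)
  expect_equal(f_id, orig$mtus$fmo, tolerance = 1e-6)
  # two identical originals merged into one: strength sums
  twin <- orig
  twin$mtus$fmo <- rep(orig$mtus$fmo[1], 6)
  twin$mtus$lmo <- rep(orig$mtus$lmo[1], 6)
  twin$mtus$lts <- rep(orig$mtus$lts[1], 6)
  sampler_twin <- function(seed) {
    set.seed(seed)
    arms <- matrix(runif(18, -0.06, 0.06), 6, 3)
    arms[2, ] <- arms[1, ]                      # muscles 1 and 2 identical
    list(arms = arms, lmt = rep(runif(1, 0.15, 0.25), 6))
  }
  f_merge <- reduce_mtu_set(twin, c(1, 3, 4, 5, 6), sampler_twin, 40, seed = 2)
  expect_equal(f_merge[1], 2 * twin$mtus$fmo[1], tolerance = 1e-6)
  expect_error(reduce_mtu_set(orig, 1:6, sampler, 3), class = "argument_error")
})

test_that("6-to-3 reduction beats random strength candidates on its own objective", {
  orig <- random_model(6, 2, 10, seed = 61)
  sampler <- function(seed) {
    set.seed(seed)
    list(arms = matrix(runif(12, -0.06, 0.06), 6, 2),
         lmt = runif(6, 0.15, 0.25))
  }
  mapping <- c(1, 3, 5)
  n_poses <- 25
  fit <- reduce_mtu_set(orig, mapping, sampler, n_poses, seed = 3)
  obj <- function(f_red) {
    tot <- 0
    for (p in seq_len(n_poses)) {
      pose <- sampler(3 + p)
      ln <- normalized_fiber_length(pose$lmt, orig$mtus$lmo, orig$mtus$lts)
      fu <- active_fl(as.numeric(ln))
      m_o <- as.numeric(crossprod(pose$arms, orig$mtus$fmo * fu))
      m_r <- as.numeric(crossprod(pose$arms[mapping, , drop = FALSE],
                                  f_red * fu[mapping]))
      tot <- tot + sum((m_o - m_r)^2)
    }
    tot
  }
  set.seed(71)
  rand_objs <- replicate(1000, obj(runif(3, 0, 3000)))
  expect_true(all(obj(fit) <= rand_objs + 1e-9))
})

test_that("the bundled reduced-set table has the documented structure", {
  tab <- trunk_mtu_table("right")
  expect_equal(nrow(tab), 29)
  expect_equal(as.integer(table(tab$group)[c("RA", "ES", "QL", "MF",
                                             "EO", "IO")]),
               c(1L, 13L, 5L, 5L, 2L, 3L))
  both <- trunk_mtu_table("both")
  expect_equal(nrow(both), 58)
  expect_equal(sum(both$side == "left"), 29)
  # lengths were converted from printed cm to m
  expect_equal(tab$lmo[tab$name == "rect_abd"], 0.3499)
})
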
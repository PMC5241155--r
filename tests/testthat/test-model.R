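test_that("gated rates follow the phase structure", {
  p <- cveu_params(delta = 0.08, n_crypt = 20, l_c0 = 5, t1 = 10,
                   t2 = 30, gamma = 0.05)
  # below both thresholds: pure exponential growth of the crypt content
  r <- label_rates(p, l_crypt = 5, l_villus = 0)
  expect_equal(unname(r), c(0.08 * 5, 0))
  # at the transfer threshold (H(0) = 1): crypt flat, villus gains
  r <- label_rates(p, l_crypt = p$l_c_star, l_villus = 1)
  expect_equal(unname(r), c(0, 0.08 * p$l_c_star))
  # at both thresholds: shedding also active
  r <- label_rates(p, l_crypt = p$l_c_star, l_villus = p$l_v_star)
  expect_equal(unname(r),
               c(0, 0.08 * p$l_c_star - 0.05 * p$l_v_star))
  # no proliferation, no transfer
  p0 <- cveu_params(delta = 0, n_crypt = 20, l_c0 = 5, t1 = 0,
                    t2 = 0, gamma = 0.05)
  r <- label_rates(p0, l_crypt = 5, l_villus = p0$l_v_star + 1)
  expect_equal(unname(r), c(0, -0.05 * (p0$l_v_star + 1)))
  expect_error(label_rates(p, l_crypt = NaN, l_villus = 0), "finite")
  expect_error(label_rates(p, l_crypt = -1, l_villus = 0),
               "non-negative")
})

test_that("forward-Euler integration of the gated rates holds the crypt at
           threshold and grows the villus at delta * l_c_star", {
  p <- cveu_params(delta = 0.08, n_crypt = 20, l_c0 = 5, t1 = 10)
  h <- 1e-3
  y <- c(p$l_c_star, 2)
  for (i in 1:1000) y <- y + h * label_rates(p, y[1], y[2])
  expect_equal(y[[1]], p$l_c_star)
  expect_equal((y[[2]] - 2) / 1, p$delta * p$l_c_star, tolerance = 1e-9)
})

test_that("pre-shedding solution matches initial conditions and the
           linear-phase slope", {
  p <- cveu_params(delta = 0.0760, n_crypt = 20, l_c0 = 8.2, l_v0 = 0,
                   t0 = 0, t1 = 8)
  s <- pre_shedding_solution(p, c(0, 8, 18))
  expect_equal(s$l_crypt[1], 8.2)
  expect_equal(s$l_villus[1], 0)
  # villus gain over 10 h of the linear phase is 10 * delta * L_C*
  expect_equal(s$l_villus[3] - s$l_villus[2], 10 * 0.0760 * p$l_c_star)
  # crypt constant at the threshold after t1
  expect_equal(s$l_crypt[2], s$l_crypt[3])
  expect_error(pre_shedding_solution(p, c(-1, 0)), "t0")
  p2 <- cveu_params(delta = 0.0760, n_crypt = 20, l_c0 = 8.2, t1 = 8,
                    t2 = 30, gamma = 0.05)
  expect_error(pre_shedding_solution(p2, c(0, 35)), "explicit_solution")
})

test_that("explicit solution is continuous, monotone where required, and
           approaches the transfer/shedding balance", {
  set.seed(41)
  for (i in 1:20) {
    p <- random_params()
    eps <- 1e-12
    near_t1 <- explicit_solution(p, c(p$t1 - eps, p$t1, p$t1 + eps))
    expect_lt(max(abs(diff(near_t1$l_crypt))), 1e-8)
    expect_lt(max(abs(diff(near_t1$l_villus))), 1e-8)
    near_t2 <- explicit_solution(p, c(p$t2 - eps, p$t2, p$t2 + eps))
    expect_lt(max(abs(diff(near_t2$l_villus))), 1e-8)
    expect_equal(explicit_solution(p, p$t2)$l_villus, p$l_v_star,
                 tolerance = 1e-12)
    tt <- seq(p$t0, p$t2 + 40, length.out = 60)
    sol <- explicit_solution(p, tt)
    expect_true(all(diff(sol$l_crypt) >= -1e-12))
    expect_true(all(diff(sol$l_villus) >= -1e-12))
    # t -> infinity: balance between transfer and shedding
    far <- explicit_solution(p, p$t2 + 40 / p$gamma)$l_villus
    expect_equal(far, p$delta * p$l_c_star / p$gamma, tolerance = 1e-6)
  }
})

test_that("phase-2 total labeled cells grow at exactly delta * l_c_star", {
  p <- cveu_params(delta = 0.06, n_crypt = 25, l_c0 = 4, t1 = 12,
                   t2 = 40, gamma = 0.04)
  tt <- seq(13, 39, by = 2)
  sol <- pre_shedding_solution(p, tt)
  tot <- sol$l_crypt + sol$l_villus
  expect_equal(diff(tot) / diff(tt),
               rep(p$delta * p$l_c_star, length(tt) - 1L))
})

test_that("closed forms agree with numerical integration of the gated
           rates", {
  skip_if_not_installed("deSolve")
  set.seed(7)
  for (i in 1:25) {
    p <- random_params()
    tt <- sort(c(p$t0, p$t1, p$t2, runif(30, p$t0, p$t2 + 25)))
    num <- integrate_gated(p, tt)
    cf <- explicit_solution(p, tt)
    expect_equal(cf$l_crypt, unname(num[, 1]), tolerance = 1e-6)
    expect_equal(cf$l_villus, unname(num[, 2]), tolerance = 1e-6)
  }
})

test_that("thresholds round-trip through the solution and validate", {
  th <- thresholds_from_times(0.076, 8.2, 0, 0, 10, 35)
  p <- cveu_params(0.076, 30, 8.2, 0, 0, 10, 35, gamma = 0.03)
  expect_equal(p$l_c_star, th[["l_c_star"]])
  expect_equal(p$l_v_star, th[["l_v_star"]])
  expect_equal(pre_shedding_solution(p, 10)$l_crypt, th[["l_c_star"]])
  expect_equal(explicit_solution(p, 35)$l_villus, th[["l_v_star"]])
  # degenerate cases
  expect_equal(thresholds_from_times(0.05, 3, 1, 5, 5, 5),
               c(l_c_star = 3, l_v_star = 1))
  expect_equal(thresholds_from_times(0, 3, 1, 0, 10, 20),
               c(l_c_star = 3, l_v_star = 1))
  expect_error(thresholds_from_times(0.05, -3, 0, 0, 1, 2),
               "non-negative")
  expect_error(cveu_params(0.2, 10, 8, t1 = 30), "l_c_star")
  expect_error(cveu_params(0.05, 10, 2, t0 = 5, t1 = 2), "t1")
})
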
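test_that("noiseless counts are recovered exactly by the control scheme", {
  p <- cveu_params(delta = 0.076, n_crypt = 20, l_c0 = 8.2, l_v0 = 0,
                   t0 = 0, t1 = 9)
  cts <- noiseless_counts(p, seq(0, 38, by = 4))
  fit <- fit_cveu(cts, boundary = 20, exclude = "none")
  expect_equal(fit$params$delta, 0.076, tolerance = 1e-6)
  expect_equal(fit$params$t1, 9, tolerance = 1e-5)
  expect_equal(fit$params$l_c0, 8.2, tolerance = 1e-6)
  expect_lt(fit$rmse, 1e-7)
  # predictions reproduce the generating curve
  pred <- predict(fit, times = c(2, 15, 30))
  expect_equal(pred$l_villus, pre_shedding_solution(p, c(2, 15, 30))$l_villus,
               tolerance = 1e-5)
})

test_that("fitted delta is invariant to a common scaling of the counts", {
  p <- cveu_params(delta = 0.0544, n_crypt = 19, l_c0 = 7.4, t1 = 12)
  cts <- noiseless_counts(p, seq(0, 36, by = 4))
  f1 <- fit_cveu(cts, boundary = 19, exclude = "none")
  cts2 <- transform(cts, l_crypt_obs = 0.5 * l_crypt_obs,
                    l_villus_obs = 0.5 * l_villus_obs)
  f2 <- fit_cveu(cts2, boundary = 19, exclude = "none")
  expect_equal(f2$params$delta, f1$params$delta, tolerance = 1e-5)
})

test_that("dilution and shedding exclusion rules flag the right points", {
  # strictly increasing series: nothing excluded
  cts <- data.frame(time_h = seq(0, 40, by = 8),
                    l_crypt_obs = c(8, 10, 12, 13, 13.5, 13.6),
                    l_villus_obs = c(0, 1, 4, 8, 12, 16))
  ex <- exclude_diluted(cts)
  expect_true(all(ex$crypt_keep))
  expect_true(all(ex$villus_keep))
  # sustained crypt decline: crypt dropped from onset, villus one
  # sampling interval later
  cts$l_crypt_obs <- c(8, 12, 14, 12, 9, 6)
  ex <- exclude_diluted(cts)
  expect_equal(which(!ex$crypt_keep), 4:6)
  expect_equal(which(!ex$villus_keep), 5:6)
  # a transient dip that recovers is not a sustained decline
  cts$l_crypt_obs <- c(8, 12, 10, 13, 13.5, 14)
  ex <- exclude_diluted(cts)
  expect_true(all(ex$crypt_keep))
  # villus plateau from shedding
  cts$l_crypt_obs <- c(8, 10, 12, 13, 13.5, 13.6)
  cts$l_villus_obs <- c(0, 4, 8, 12, 12.1, 12.15)
  ex <- exclude_diluted(cts)
  expect_equal(which(!ex$villus_keep), 5:6)
  # manual override removes exactly the requested rows
  ex <- exclude_diluted(cts, manual = c(2, 5))
  expect_equal(which(!ex$crypt_keep), c(2, 5))
  expect_equal(which(!ex$villus_keep), c(2, 5))
})

test_that("automatic exclusion tracks the generator's dilution oracle", {
  cfg <- cveu_preset("control_duodenum")
  cfg$n_cveu <- 150L
  sim <- simulate_cveu(cfg, seed = 11)
  cts <- sim_counts(sim, 20)
  ex <- exclude_diluted(cts)
  tr <- sim$truth
  div_crypt <- 1 - tr$l_crypt_detectable / pmax(tr$l_crypt_total, 1e-9)
  # every kept crypt point is at most mildly diluted; every dropped one
  # is beyond (or at the shoulder of) the 5% divergence onset
  expect_true(all(div_crypt[ex$crypt_keep] < 0.10))
  expect_true(all(div_crypt[!ex$crypt_keep] > 0.05))
})

test_that("front velocity is the closed-form least-squares slope", {
  expect_equal(fit_front_velocity(
    data.frame(time_h = c(0, 10),
               front_position_um = c(100, 190)))$v_lf, 9)
  expect_equal(fit_front_velocity(
    data.frame(time_h = c(0, 5, 10),
               front_position_um = c(50, 50, 50)))$v_lf, 0)
  # hand-computed normal equations on a 3-point track
  tr <- data.frame(time_h = c(0, 10, 20),
                   front_position_um = c(100, 180, 290))
  slope <- with(tr, sum((time_h - mean(time_h)) *
                          (front_position_um - mean(front_position_um))) /
                  sum((time_h - mean(time_h))^2))
  ff <- fit_front_velocity(tr)
  expect_equal(ff$v_lf, slope)
  expect_equal(ff$intercept,
               mean(tr$front_position_um) - slope * mean(tr$time_h))
  expect_error(fit_front_velocity(
    data.frame(time_h = c(3, 3), front_position_um = c(1, 2))), "distinct")
})

test_that("noisy front tracks recover the generating slope", {
  set.seed(8)
  for (i in 1:5) {
    tt <- seq(0, 44, by = 4)
    tr <- data.frame(time_h = tt,
                     front_position_um = 60 + 5.96 * tt + rnorm(12, 0, 20))
    ff <- fit_front_velocity(tr)
    expect_lt(abs(ff$v_lf - 5.96), 3 * ff$se)
  }
})

test_that("kinematics reproduce the boundary-velocity identity and
           crypt-to-tip transit times", {
  k <- derive_kinematics(list(delta = 0.0544, n_crypt = 19),
                         cveu_length_cells = 61.5)
  expect_equal(signif(k$v_cv, 3), 1.03)
  expect_equal(k$total_transit_h, 95, tolerance = 0.5 / 95)
  k <- derive_kinematics(list(delta = 0.0760, n_crypt = 20),
                         cveu_length_cells = 99.7,
                         density_cells_per_10um = 1.25)
  expect_equal(k$total_transit_h, 92, tolerance = 0.5 / 92)
  expect_equal(k$v_cv_um, 0.076 * 20 * 8)
  expect_equal(k$v_x(10), 0.76)
  k <- derive_kinematics(list(delta = 0.0547, n_crypt = 18),
                         cveu_length_cells = 98.8)
  expect_equal(k$total_transit_h, 135, tolerance = 0.5 / 135)
  expect_error(derive_kinematics(list(delta = 0, n_crypt = 20), 100),
               "delta")
  expect_error(derive_kinematics(list(delta = 0.1, n_crypt = 20), 15),
               "length")
})

test_that("boundary-velocity equals the phase-2 villus accumulation rate
           per labeled crypt fraction", {
  p <- cveu_params(delta = 0.06, n_crypt = 22, l_c0 = 5, t1 = 10)
  sol <- pre_shedding_solution(p, c(15, 25))
  slope <- diff(sol$l_villus) / 10
  expect_equal(slope / (p$l_c_star / p$n_crypt), 0.06 * 22)
})

test_that("front recovery time back-calculates the held interval", {
  expect_equal(round(front_recovery_time(178, 234, 6.09), 1), 9.2)
  expect_equal(front_recovery_time(100, 100, 5), 0)
  expect_equal(front_recovery_time(0, 60.9, 6.09), 10)
  expect_error(front_recovery_time(0, 10, 0), "positive")
  expect_error(front_recovery_time(100, 50, 5), "beyond")
})

test_that("parameter recovery and coverage across simulated datasets", {
  rels <- covered <- numeric(0)
  for (s in 1:15) {
    sim <- simulate_cveu(cveu_preset("control_ileum"), seed = 100 + s)
    fit <- fit_cveu(sim_counts(sim, 19), boundary = 19)
    rels <- c(rels, (fit$params$delta - 0.0544) / 0.0544)
    covered <- c(covered,
                 abs(fit$params$delta - 0.0544) <= 2 * fit$se[["delta"]])
  }
  expect_lte(median(abs(rels)), 0.10)
  expect_gte(mean(covered), 0.8)
})

test_that("under-determined schemes and bad inputs error early", {
  cts <- data.frame(time_h = c(0, 5), l_crypt_obs = c(8, 9),
                    l_villus_obs = c(0, 1))
  expect_error(fit_cveu(cts, 20), "3 time points")
  expect_error(cveu_scheme("custom", fixed = c(t0 = 0),
                           free = c("delta", "t0")), "both fixed and free")
  expect_error(cveu_scheme("custom", fixed = c(t0 = 0),
                           free = c("delta")), "scheme must fix or free")
})
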
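test_that("initial labeling follows the configured profile", {
  cfg <- sim_config(delta = 0.05, n_crypt = 20, cveu_length = 60,
                    sample_times = 0, label_profile = rep(0, 20),
                    density = 1)
  set.seed(1)
  expect_false(any(make_initial_label(cfg)))
  prof <- c(rep(0, 4), rep(1, 11), rep(0, 5))  # certain on positions 5..15
  cfg <- sim_config(delta = 0.05, n_crypt = 20, cveu_length = 60,
                    sample_times = 0, label_profile = prof, density = 1)
  lab <- make_initial_label(cfg)
  expect_equal(which(lab), 5:15)
  # labeling above the crypt is rejected
  expect_error(sim_config(delta = 0.05, n_crypt = 10, cveu_length = 60,
                          sample_times = 0,
                          label_profile = c(rep(0, 9), 0.5, 0.5),
                          density = 1), "boundary")
})

test_that("default profiles are calibrated to the two-hour labeled totals", {
  for (nm in c("control_duodenum", "control_ileum", "omomyc_ileum")) {
    cfg <- cveu_preset(nm)
    target <- c(control_duodenum = 8.2, control_ileum = 7.4,
                omomyc_ileum = 4.3)[[nm]]
    expect_equal(sum(cfg$label_profile), target, tolerance = 1e-9)
    # zero at and above the boundary, peaked at intermediate positions
    expect_equal(cfg$label_profile[cfg$n_crypt], 0)
    peak <- which.max(cfg$label_profile)
    expect_gt(peak, 2)
    expect_lt(peak, cfg$n_crypt - 2)
  }
  expect_error(cveu_preset("ileum"), "unknown preset")
})

test_that("a static column results without proliferation", {
  cfg <- sim_config(delta = 0, n_crypt = 15, cveu_length = 40,
                    sample_times = c(0, 10, 30), target_labeled = 5,
                    n_cveu = 40, density = 1)
  sim <- simulate_cveu(cfg, seed = 3)
  expect_equal(sim$n_events, 0L)
  # no divisions: detectable equals total, front statistically immobile
  expect_equal(sim$truth$l_crypt_detectable, sim$truth$l_crypt_total)
  expect_equal(sim$truth$l_villus_detectable, rep(0, 3))
  expect_lt(diff(range(sim$truth$front_position_um)), 15)
})

test_that("the crypt column conserves its occupancy and scores are
           binary with NA padding only beyond a CVEU's length", {
  cfg <- cveu_preset("control_ileum")
  cfg$sample_times <- c(0, 20, 40)
  cfg$n_cveu <- 10L
  sim <- simulate_cveu(cfg, seed = 2)
  for (m in sim$scores) {
    expect_true(all(m[, seq_len(19)] %in% c(0, 1)))  # crypt fully scored
    # NA only as a contiguous tail per row
    for (i in seq_len(nrow(m))) {
      nas <- which(is.na(m[i, ]))
      if (length(nas))
        expect_equal(nas, seq.int(min(nas), ncol(m)))
    }
  }
})

test_that("detectable label counts never exceed total label counts and
           dilution appears only after several generations", {
  cfg <- cveu_preset("control_duodenum")
  cfg$n_cveu <- 60L
  sim <- simulate_cveu(cfg, seed = 6)
  with(sim$truth, {
    expect_true(all(l_crypt_detectable <= l_crypt_total + 1e-12))
    expect_true(all(l_villus_detectable <= l_villus_total + 1e-12))
  })
  # early on (well under detection_limit generations) no loss yet
  early <- sim$truth[sim$truth$time_h <= 6, ]
  expect_equal(early$l_crypt_detectable, early$l_crypt_total,
               tolerance = 0.02)
  late <- sim$truth[sim$truth$time_h >= 30, ]
  expect_true(all(late$l_crypt_detectable < late$l_crypt_total))
})

test_that("early crypt label grows exponentially at the division rate
           before transfer becomes appreciable", {
  cfg <- cveu_preset("control_ileum")
  cfg$sample_times <- c(0, 3)
  cfg$n_cveu <- 250L
  sim <- simulate_cveu(cfg, seed = 9)
  tot <- sim$truth$l_crypt_total + sim$truth$l_villus_total
  expected <- sum(cfg$label_profile) * exp(cfg$delta * 3)
  # 3 MC standard errors of the mean over 250 CVEUs
  mc_se <- 3 * 3 / sqrt(250)
  expect_lt(abs(tot[2] - expected), mc_se + 0.3)
})

test_that("the labeled front advances at the boundary velocity once on
           the villus", {
  cfg <- cveu_preset("control_ileum")
  cfg$sample_times <- seq(5, 35, by = 5)
  cfg$n_cveu <- 120L
  sim <- simulate_cveu(cfg, seed = 12)
  ff <- fit_front_velocity(sim$front)
  v_expected <- cfg$delta * cfg$n_crypt * cfg$cell_length_um
  expect_lt(abs(ff$v_lf - v_expected) / v_expected, 0.05)
})

test_that("proliferation arrest freezes the front and transfer, which
           resume afterwards", {
  cfg <- sim_config(delta = 0.06, n_crypt = 20, cveu_length = 60,
                    sample_times = c(10, 12, 16, 20, 24, 30, 36),
                    target_labeled = 8, n_cveu = 60, density = 1,
                    arrest_windows = list(c(10, 20)))
  sim <- simulate_cveu(cfg, seed = 5)
  tr <- sim$truth
  frozen <- tr[tr$time_h >= 10 & tr$time_h <= 20, ]
  # within-arrest sampling noise only (independent CVEUs per time point)
  expect_lt(diff(range(frozen$l_villus_detectable)), 1.5)
  expect_lt(diff(range(frozen$front_position_um)), 25)
  after <- tr[tr$time_h > 20, ]
  expect_gt(after$l_villus_detectable[3] - frozen$l_villus_detectable[1], 2)
  expect_gt(after$front_position_um[3] - frozen$front_position_um[1], 40)
})

test_that("simulation is reproducible under a fixed seed", {
  cfg <- cveu_preset("omomyc_ileum")
  cfg$n_cveu <- 8L
  s1 <- simulate_cveu(cfg, seed = 77)
  s2 <- simulate_cveu(cfg, seed = 77)
  expect_identical(s1$truth, s2$truth)
  expect_identical(lapply(s1$scores, unclass), lapply(s2$scores, unclass))
})
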
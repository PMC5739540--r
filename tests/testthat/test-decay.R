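test_that("exact log-linear data gives the exact half-life", {
  course <- decay_course(c(0, 2, 4), c(1, 0.5, 0.25))
  est <- fit_half_life(course)
  expect_equal(est$t_half_hr, 2.0, tolerance = 1e-12)
  expect_equal(est$r_squared, 1.0, tolerance = 1e-12)
  expect_equal(est$k, log(2) / est$t_half_hr, tolerance = 1e-12)
})

test_that("noiseless preset courses are recovered to machine precision", {
  for (preset in names(decay_presets())) {
    course <- gen_decay_course(preset = preset, noise_cv = 0, seed = 1)
    for (method in c("pooled", "per_replicate_mean")) {
      est <- fit_half_life(course, method)
      expect_equal(est$t_half_hr, unname(decay_presets()[preset]),
                   tolerance = 1e-10,
                   info = paste(preset, method))
    }
  }
})

test_that("pooled fit agrees with a profile-likelihood grid search", {
  course <- gen_decay_course(half_life_hr = 4, noise_cv = 0.05,
                             n_replicates = 3, seed = 99)
  norm <- ripstab:::normalize_t0(course)
  k_grid <- grid_search_k(norm$time_hr, norm$abundance)
  est <- fit_half_life(course, "pooled")
  expect_lt(abs(est$k - k_grid), 1e-3)
})

test_that("confidence interval brackets the point estimate and truth at 5% CV", {
  course <- gen_decay_course(preset = "control", noise_cv = 0.05, seed = 7)
  est <- fit_half_life(course)
  expect_lte(est$ci95_t_half[1], est$t_half_hr)
  expect_gte(est$ci95_t_half[2], est$t_half_hr)
})

test_that("scale and time-unit equivariance hold", {
  course <- gen_decay_course(half_life_hr = 5, noise_cv = 0.05, seed = 3)
  base <- fit_half_life(course)$t_half_hr
  # multiply one replicate's abundances by a constant: intercept absorbs it
  scaled <- course
  sel <- scaled$replicate == "rep2"
  scaled$abundance[sel] <- scaled$abundance[sel] * 7.3
  expect_equal(fit_half_life(scaled)$t_half_hr, base, tolerance = 1e-10)
  # rescaling time by c rescales t1/2 by c
  mins <- course
  mins$time_hr <- mins$time_hr * 60
  expect_equal(fit_half_life(mins)$t_half_hr, base * 60, tolerance = 1e-10)
})

test_that("pooled estimator recovers paper-scale half-lives within 5% MdARE", {
  # median absolute relative error over seeds, 5% CV, 3 replicates
  for (t_half in c(3, 5, 9)) {
    err <- vapply(1:60, function(s) {
      est <- fit_half_life(gen_decay_course(half_life_hr = t_half,
                                            noise_cv = 0.05, seed = 1000 + s))
      abs(est$t_half_hr - t_half) / t_half
    }, numeric(1))
    expect_lt(median(err), 0.05)
  }
})

test_that("non-decaying and degenerate courses are rejected", {
  flat <- decay_course(c(0, 2, 4), c(1, 1.1, 1.05))
  expect_error(fit_half_life(flat), "non-decaying")
  expect_error(decay_course(c(1, 2), c(1, 0.5)), "t = 0")
  expect_error(decay_course(c(0, 0), c(1, 1)), "fewer than 2 distinct")
  expect_error(decay_course(c(0, 2), c(1, -0.5)), "positive")
})

test_that("per-replicate method reports mean and spread across replicates", {
  course <- gen_decay_course(half_life_hr = 5, noise_cv = 0.1,
                             n_replicates = 4, seed = 11)
  est <- fit_half_life(course, "per_replicate_mean")
  expect_length(est$t_half_reps, 4L)
  expect_equal(est$t_half_hr, mean(est$t_half_reps), tolerance = 1e-12)
  expect_true(est$ci95_t_half[1] < est$t_half_hr &&
                est$t_half_hr < est$ci95_t_half[2])
})

test_that("compare_half_lives: identical inputs give ratio 1 and p = 1", {
  a <- fit_half_life(gen_decay_course(half_life_hr = 5, noise_cv = 0.05,
                                      seed = 4))
  cmp <- compare_half_lives(a, a)
  expect_equal(cmp$ratio, 1)
  expect_equal(cmp$p_value, 1)
})

test_that("compare_half_lives: noiseless presets give the exact paper ratio", {
  oe <- fit_half_life(gen_decay_course(preset = "LAST_overexpression",
                                       noise_cv = 0, seed = 1))
  ctrl <- fit_half_life(gen_decay_course(preset = "control",
                                         noise_cv = 0, seed = 1))
  expect_equal(compare_half_lives(oe, ctrl)$ratio, 9 / 5, tolerance = 1e-10)
})

test_that("compare_half_lives flags p as unavailable below 2 replicates", {
  cmp <- compare_half_lives(c(5), c(3, 3.2))
  expect_equal(cmp$ratio, 5 / 3.1, tolerance = 1e-12)
  expect_true(is.na(cmp$p_value))
})

test_that("3 h vs 5 h at 5% CV is detected in most seeded runs", {
  reject <- vapply(1:100, function(s) {
    a <- fit_half_life(gen_decay_course(half_life_hr = 3, noise_cv = 0.05,
                                        seed = 2000 + s))
    b <- fit_half_life(gen_decay_course(half_life_hr = 5, noise_cv = 0.05,
                                        seed = 7000 + s))
    compare_half_lives(a, b)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(reject), 0.90)
})

test_that("ct_to_relative implements delta-delta-Ct with t0 normalisation", {
  # constant delta-Ct: flat course of ones
  flat <- ct_to_relative(ct_target = c(20, 21, 22),
                         ct_reference = c(15, 16, 17),
                         time_hr = c(0, 2, 4))
  expect_equal(flat$abundance, c(1, 1, 1))
  # target rising one cycle per checkpoint, fixed reference: halves each time
  halving <- ct_to_relative(ct_target = c(20, 21, 22, 23),
                            ct_reference = rep(15, 4),
                            time_hr = c(0, 1, 2, 3))
  expect_equal(halving$abundance, c(1, 0.5, 0.25, 0.125))
  expect_error(
    ct_to_relative(c(20, 21), c(15, 15), time_hr = c(1, 2)),
    "t = 0"
  )
})

test_that("Ct round-trip recovers simulated decay abundances", {
  course <- gen_decay_course(half_life_hr = 4, noise_cv = 0, seed = 6)
  ct_ref <- rep(15, nrow(course))
  ct_target <- ct_ref - log2(course$abundance)
  back <- ct_to_relative(ct_target, ct_ref, course$time_hr, course$replicate)
  expect_equal(back$abundance, course$abundance, tolerance = 1e-12)
  expect_equal(fit_half_life(back)$t_half_hr, 4, tolerance = 1e-10)
})

test_that("50%-crossing interpolation approximates the regression estimate", {
  course <- gen_decay_course(half_life_hr = 5, noise_cv = 0, seed = 1,
                             timepoints_hr = c(0, 2, 4, 6, 8))
  t_interp <- half_life_interp(course)
  # exponential decay sags below the chord, so interpolation reads slightly
  # low but must stay close
  expect_lt(abs(t_interp - 5) / 5, 0.1)
  never <- decay_course(c(0, 1), c(1, 0.9))
  expect_true(is.na(half_life_interp(never)))
})
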
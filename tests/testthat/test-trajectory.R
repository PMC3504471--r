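# Piecewise-exponential FA clock: evaluation, inversion, fitting.

test_that("fa_at_age follows the plateau-then-exponential form", {
  p <- species_params("toy", gestation_days = 20, t_init = 22, tau = 5,
                      fa_max = 0.6, fa_min = 0.2)
  # plateau before and at onset
  expect_equal(fa_at_age(p, 10), 0.6)
  p1 <- species_params("toy", gestation_days = 20, t_init = 22, tau = 5)
  expect_equal(fa_at_age(p1, 22), 1.0)
  # hand evaluation one time constant past onset
  expect_equal(fa_at_age(p, 27), 0.2 + 0.4 * exp(-1), tolerance = 1e-12)
  # continuity at the breakpoint and monotone decay to fa_min
  ages <- seq(21.9, 80, by = 0.1)
  fa <- fa_at_age(p, ages)
  expect_true(all(diff(fa) <= 1e-12))
  expect_equal(fa_at_age(p, 22 + 1e-9), 0.6, tolerance = 1e-6)
  expect_equal(fa_at_age(p, 1e4), 0.2, tolerance = 1e-9)
  expect_error(fa_at_age(p, 0), "must be finite")
})

test_that("decay_fraction reproduces the printed rat critical-period fractions", {
  # rat clock: t_init = 22 dpc, tau = 5 d; P4/P6 are PC 25.5/27.5
  expect_equal(round_half_away(decay_fraction(reg$rat, 25.5), 2), 0.50)
  expect_equal(round_half_away(decay_fraction(reg$rat, 27.5), 2), 0.33)
  expect_equal(decay_fraction(reg$rat, 22), 1.0)
})

test_that("decay_fraction is independent of the absolute FA bounds", {
  a <- species_params("a", 20, t_init = 30, tau = 7, fa_max = 1, fa_min = 0)
  b <- species_params("b", 20, t_init = 30, tau = 7, fa_max = 0.55, fa_min = 0.12)
  ages <- c(30, 33, 40, 60)
  expect_equal(decay_fraction(a, ages), decay_fraction(b, ages))
})

test_that("age_at_fraction inverts decay_fraction on the decay branch", {
  p <- reg$ferret
  expect_equal(age_at_fraction(p, 1), p$t_init)
  ages <- seq(p$t_init, p$t_init + 60, length.out = 50)
  expect_equal(age_at_fraction(p, decay_fraction(p, ages)), ages,
               tolerance = 1e-9)
  expect_error(age_at_fraction(p, 0), "fraction")
  expect_error(age_at_fraction(p, 1.2), "fraction")
})

test_that("noiseless observations refit to the generating parameters", {
  truth <- species_params("gen", 41, t_init = 49, tau = 10.7,
                          fa_max = 0.5, fa_min = 0.1)
  obs <- gen_fa_observations(truth, ages = seq(50, 100, length.out = 12),
                             noise_sd = 0, seed = 1)
  fit <- fit_fa_params(obs, fixed = c(t_init = 49))
  expect_true(fit$converged)
  expect_equal(fit$params$tau, 10.7, tolerance = 1e-6)
  expect_equal(fit$params$fa_max, 0.5, tolerance = 1e-5)
  expect_equal(fit$params$fa_min, 0.1, tolerance = 1e-5)
  expect_lt(fit$residual_sum_of_squares, 1e-12)
})

test_that("free-breakpoint profile fit recovers t_init from plateau data", {
  truth <- species_params("gen", 41, t_init = 49, tau = 10.7,
                          fa_max = 0.5, fa_min = 0.1)
  obs <- gen_fa_observations(truth, ages = seq(40, 110, by = 2),
                             noise_sd = 0, seed = 1)
  fit <- fit_fa_params(obs)
  expect_equal(fit$params$t_init, 49, tolerance = 0.11)  # grid resolution 0.1 d
  expect_equal(fit$params$tau, 10.7, tolerance = 0.05)
})

test_that("noisy refits recover tau within 15% for a fixed seed", {
  truth <- reg$rat
  obs <- gen_fa_observations(truth, ages = seq(23, 60, length.out = 50),
                             noise_sd = 0.02, seed = 11)
  fit <- fit_fa_params(obs, fixed = c(t_init = 22))
  expect_lt(abs(fit$params$tau - 5) / 5, 0.15)
})

test_that("underdetermined fits are refused", {
  obs <- data.frame(age_pc = c(30, 40), fa = c(0.5, 0.4))
  expect_error(fit_fa_params(obs), "insufficient data")
  expect_error(fit_fa_params(data.frame(age_pc = c(-1, 30, 40, 50),
                                        fa = c(0.5, 0.4, 0.3, 0.2))),
               "strictly positive")
})

test_that("observation CSVs round-trip, converting postnatal ages on read", {
  tmp <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(age_postnatal = c(4, 6), fa = c(0.5, 0.33)),
                   tmp, row.names = FALSE)
  obs <- read_fa_observations(tmp, gestation_days = 21.5)
  expect_equal(obs$age_pc, c(25.5, 27.5))
  expect_error(read_fa_observations(tmp), "gestation_days")
  unlink(tmp)
})
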
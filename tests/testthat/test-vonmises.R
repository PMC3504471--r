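# Axial von Mises estimation, bootstrap CI, region comparison, histograms.

test_that("kappa MLE matches an independent root-finding oracle on frozen samples", {
  # Expected values computed once by solving I1(k)/I0(k) = Rbar with a
  # bracketing root finder on the doubled angles (independent of the
  # package's series + Newton path) and frozen here.
  dispersed <- c(5, 12, 175, 88, 92, 110, 3, 178, 45, 130,
                 20, 160, 95, 10, 70, 150, 2, 100, 35, 168)
  f1 <- fit_von_mises(dispersed)
  expect_equal(f1$rbar, 0.22374180341529573, tolerance = 1e-10)
  expect_equal(f1$kappa, 0.4591748638546176, tolerance = 1e-6)
  expect_equal(f1$mu_deg, 0.12637423930469055, tolerance = 1e-6)

  concentrated <- c(170, 5, 178, 2, 8, 172, 177, 3, 6, 174, 1, 179, 175, 4, 7)
  f2 <- fit_von_mises(concentrated)
  expect_equal(f2$rbar, 0.9821130588196813, tolerance = 1e-10)
  expect_equal(f2$kappa, 28.210383439173892, tolerance = 1e-4)
  expect_equal(f2$mu_deg, 0.07598673019299616, tolerance = 1e-6)
})

test_that("A1inv inverts the mean-resultant-length equation across the range", {
  rbar <- c(0.01, 0.1, 0.3, 0.52, 0.6, 0.8, 0.9, 0.99)
  k <- cortexclock:::A1inv(rbar)
  expect_equal(cortexclock:::A1(k), rbar, tolerance = 1e-8)
})

test_that("uniform angles give near-zero concentration, degenerate ones the cap", {
  unif <- fit_von_mises(gen_axial_angles(0, 0, 10000, seed = 2))
  expect_lt(unif$kappa, 0.05)
  deg <- fit_von_mises(rep(37, 50))
  expect_equal(deg$kappa, 500)
  expect_true(deg$capped)
  expect_error(fit_von_mises(c(1, 2, 3)), "insufficient data")
})

test_that("kappa estimate recovers the generating concentration at n = 5000", {
  for (k in c(0.5, 1, 1.41, 2.08, 3)) {
    fit <- fit_von_mises(gen_axial_angles(20, k, 5000, seed = 100 + k * 10))
    expect_lt(abs(fit$kappa - k) / k, 0.10)
  }
})

test_that("kappa is monotone in the mean resultant length", {
  rbar <- seq(0.05, 0.95, by = 0.05)
  k <- cortexclock:::A1inv(rbar)
  expect_true(all(diff(k) > 0))
  # and on nested samples: mixing in uniform angles lowers both Rbar and kappa
  base <- gen_axial_angles(0, 3, 2000, seed = 5)$angles_deg
  noise <- gen_axial_angles(0, 0, 2000, seed = 6)$angles_deg
  fits <- lapply(c(0, 500, 1000, 2000), function(m) {
    fit_von_mises(c(base, noise[seq_len(m)]))
  })
  rb <- vapply(fits, function(f) f$rbar, numeric(1))
  kp <- vapply(fits, function(f) f$kappa, numeric(1))
  expect_true(all(diff(rb) < 0))
  expect_true(all(diff(kp) < 0))
})

test_that("bootstrap CI is seed-deterministic, ordered, and brackets the estimate", {
  smp <- gen_axial_angles(45, 1.41, 500, seed = 9)
  a <- bootstrap_kappa_ci(smp, n_boot = 1000, seed = 7)
  b <- bootstrap_kappa_ci(smp, n_boot = 1000, seed = 7)
  expect_identical(a$ci_95, b$ci_95)
  expect_lt(a$ci_95[1], a$ci_95[2])
  expect_true(a$ci_95[1] <= a$kappa && a$kappa <= a$ci_95[2])
  # interval contains the generating concentration for this sample
  expect_true(a$ci_95[1] <= 1.41 && 1.41 <= a$ci_95[2])
  expect_error(bootstrap_kappa_ci(smp, n_boot = 50), "n_boot")
})

test_that("region comparison flags disjoint confidence intervals", {
  a <- bootstrap_kappa_ci(gen_axial_angles(0, 2.08, 800, seed = 1),
                          n_boot = 500, seed = 1)
  b <- bootstrap_kappa_ci(gen_axial_angles(0, 1.41, 800, seed = 2),
                          n_boot = 500, seed = 2)
  cmp <- compare_regions(a, b)
  expect_equal(cmp$kappa_diff, a$kappa - b$kappa)
  same <- compare_regions(a, a)
  expect_equal(same$kappa_diff, 0)
  expect_false(same$disjoint)  # identical CIs overlap
  plain <- fit_von_mises(gen_axial_angles(0, 1, 100, seed = 3))
  expect_error(compare_regions(plain, a), "CIs")
})

test_that("histogram counts conserve n for every binning", {
  expect_equal(value_histogram(c(0.1, 0.1, 0.9), 0.5)$count, c(2L, 1L))
  set.seed(4)
  vals <- runif(100)
  for (w in c(0.03, 0.1, 0.25, 1)) {
    expect_equal(sum(value_histogram(vals, w)$count), 100L)
  }
  # edge values land in the final (closed) bin, still conserving n
  expect_equal(sum(value_histogram(c(0, 0.5, 1), 0.5, range = c(0, 1))$count), 3L)
  expect_equal(nrow(value_histogram(numeric(), 0.1)), 0L)
  # a fine-binned uniform sample is near-flat
  h <- value_histogram(runif(20000), 0.1, range = c(0, 1))
  expect_true(all(abs(h$count - 2000) < 300))
})
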
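# Age-frame conversion and cross-species window translation.

test_that("postnatal/postconceptional conversions match printed correspondences", {
  expect_equal(pn_to_pc(4, 21.5), 25.5)   # rat P4
  expect_equal(pn_to_pc(20, 41), 61)      # ferret P20
  expect_equal(pn_to_pc(0, 33), 33)       # birth = gestation length
  expect_equal(pc_to_pn(61, 41), 20)
  expect_equal(pc_to_pn(56.5, 41), 15.5)  # ferret Translating Time upper bound
  expect_equal(pc_to_pn(33, 33), 0)
  expect_error(pn_to_pc(-1, 21.5), ">= 0")
})

test_that("window_to_fractions yields the rat fractional bounds exactly", {
  fr <- window_to_fractions(dev_window("rat", 25.5, 27.5), reg$rat)
  expect_equal(fr$f_start, exp(-0.7), tolerance = 1e-12)
  expect_equal(fr$f_end, exp(-1.1), tolerance = 1e-12)
  # closed form at (t_init, t_init + tau)
  p <- reg$ferret
  fr2 <- window_to_fractions(dev_window("ferret", p$t_init, p$t_init + p$tau), p)
  expect_equal(c(fr2$f_start, fr2$f_end), c(1, exp(-1)))
  # plateau windows are unrepresentable
  expect_error(window_to_fractions(dev_window("rat", 20, 27.5), reg$rat),
               "before t_init")
  # species mismatch caught
  expect_error(window_to_fractions(dev_window("rat", 25.5, 27.5), reg$ferret),
               "params are for")
})

test_that("rat critical period projects to human gd 201-217 and ferret PC56-PC61", {
  w <- dev_window("rat", 25.5, 27.5)
  hu <- translate_window(w, reg$rat, reg$human)
  # hand computation: 173 + 39.8 * 3.5/5 and 173 + 39.8 * 5.5/5
  expect_equal(hu$start_pc, 173 + 39.8 * 0.7, tolerance = 1e-12)
  expect_equal(hu$end_pc, 173 + 39.8 * 1.1, tolerance = 1e-12)
  expect_equal(round_half_away(c(hu$start_pc, hu$end_pc)), c(201, 217))
  fe <- translate_window(w, reg$rat, reg$ferret)
  expect_equal(fe$start_pc, 49 + 10.7 * 0.7, tolerance = 1e-12)
  expect_equal(fe$end_pc, 49 + 10.7 * 1.1, tolerance = 1e-12)
  expect_equal(round_half_away(c(fe$start_pc, fe$end_pc)), c(56, 61))
})

test_that("translation is an identity within species and transitive across them", {
  w <- dev_window("rat", 25.5, 27.5)
  back <- translate_window(w, reg$rat, reg$rat)
  expect_equal(c(back$start_pc, back$end_pc), c(25.5, 27.5), tolerance = 1e-12)
  # rat -> ferret -> human equals rat -> human (fractions are species-free)
  via <- translate_window(translate_window(w, reg$rat, reg$ferret),
                          reg$ferret, reg$human)
  direct <- translate_window(w, reg$rat, reg$human)
  expect_equal(c(via$start_pc, via$end_pc), c(direct$start_pc, direct$end_pc),
               tolerance = 1e-9)
})

test_that("translation preserves order and scales window length by tau", {
  w <- dev_window("rat", 24, 30)
  fr <- window_to_fractions(w, reg$rat)
  for (tau in c(2, 10, 40)) {
    tg <- species_params("t", 30, t_init = 100, tau = tau)
    out <- project_window(fr, tg)
    expect_lt(out$start_pc, out$end_pc)
    expect_equal(out$end_pc - out$start_pc,
                 tau * (log(fr$f_start) - log(fr$f_end)), tolerance = 1e-9)
  }
})

test_that("Translating Time comparison reports signed per-bound offsets", {
  ref <- tt_references()
  cmp <- compare_to_translating_time(dev_window("human", 201, 217), ref$human)
  expect_equal(c(cmp$offset_start, cmp$offset_end), c(63, 67))
  expect_false(cmp$overlaps)
  fe <- compare_to_translating_time(dev_window("ferret", 56.5, 60.8), ref$ferret)
  expect_equal(c(fe$offset_start, fe$offset_end), c(4.5, 4.3), tolerance = 1e-9)
  expect_true(fe$overlaps)
  same <- compare_to_translating_time(dev_window("human", 138, 150), ref$human)
  expect_equal(c(same$offset_start, same$offset_end), c(0, 0))
  expect_error(compare_to_translating_time(dev_window("rat", 25.5, 27.5),
                                           ref$human), "mismatch")
})

test_that("ages render in the paper's frames with away-from-zero rounding", {
  expect_equal(round_half_away(60.5), 61)
  expect_equal(round_half_away(-60.5), -61)
  expect_equal(round_half_away(34.86, 1), 34.9)
  expect_match(format_age(200.86, 270), "gestational day 201")
  expect_match(format_age(200.86, 270), "28.7 wk")
  expect_match(format_age(61, 41), "PC61 \\(P20\\)")
  expect_match(format_window(dev_window("human", 200.86, 216.78), 270),
               "201.*217")
})

test_that("species registries round-trip through YAML", {
  tmp <- tempfile(fileext = ".yaml")
  write_species_registry(reg, tmp)
  back <- read_species_registry(tmp)
  expect_equal(names(back), names(reg))
  expect_equal(back$ferret$tau, 10.7)
  expect_equal(back$cat$gestation_days, 65)
  expect_true(is.na(back$cat$tau))
  unlink(tmp)
})
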
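# Cross-species developmental-time translation by fractional FA decay
# matching, plus age-frame conversion between postnatal and postconceptional
# days.

#' Convert postnatal age to postconceptional age
#'
#' Postnatal day P\emph{n} corresponds to `gestation_days + n` days post
#' conception; e.g. rat P4 (gestation 21.5 d) is PC 25.5.
#'
#' @param age_postnatal postnatal age(s) in days, >= 0.
#' @param gestation_days gestation length in days, > 0.
#' @return age(s) in days post conception.
#' @export
pn_to_pc <- function(age_postnatal, gestation_days) {
  if (any(!is.finite(age_postnatal)) || any(age_postnatal < 0)) {
    stop_input("postnatal age must be >= 0")
  }
  assert_pos(gestation_days, "gestation_days")
  age_postnatal + gestation_days
}

#' Convert postconceptional age to postnatal age
#'
#' Inverse of [pn_to_pc()]. Negative results are prenatal and should be read
#' as "gestational day `gestation_days + result`"; see [format_age()].
#'
#' @param age_pc age(s) in days post conception, >= 0.
#' @param gestation_days gestation length in days, > 0.
#' @return postnatal age(s) in days (negative = prenatal).
#' @export
pc_to_pn <- function(age_pc, gestation_days) {
  if (any(!is.finite(age_pc)) || any(age_pc < 0)) {
    stop_input("postconceptional age must be >= 0")
  }
  assert_pos(gestation_days, "gestation_days")
  age_pc - gestation_days
}

#' A developmental window in one species
#'
#' An age interval (days post conception) in a named species, such as the
#' rat critical period for visual callosal connections, P4-P6 (PC 25.5-27.5).
#'
#' @param species_name species label.
#' @param start_pc,end_pc interval bounds in days post conception,
#'   0 < start < end.
#' @return object of class `dev_window`.
#' @export
dev_window <- function(species_name, start_pc, end_pc) {
  assert_pos(start_pc, "start_pc")
  assert_pos(end_pc, "end_pc")
  if (start_pc >= end_pc) stop_input("need start_pc < end_pc")
  structure(list(species_name = species_name,
                 start_pc = as.numeric(start_pc), end_pc = as.numeric(end_pc)),
            class = "dev_window")
}

#' @export
print.dev_window <- function(x, ...) {
  cat(sprintf("<dev_window> %s: PC %g-%g\n", x$species_name, x$start_pc, x$end_pc))
  invisible(x)
}

#' Map a developmental window to decay fractions
#'
#' Expresses a window in the species-free coordinate of the FA clock: the
#' fraction of FA decay remaining at each bound. The earlier bound carries
#' the larger fraction. Exact fractions are retained; rounding happens only
#' at report time.
#'
#' A window starting before the species' `t_init` has no unique fractional
#' representation (the fraction saturates at 1 on the plateau), so it is
#' rejected.
#'
#' @param window a [dev_window()].
#' @param params [species_params()] for the window's species.
#' @return object of class `fraction_window`: list with `f_start`, `f_end`.
#' @examples
#' reg <- default_species_registry()
#' window_to_fractions(dev_window("rat", 25.5, 27.5), reg$rat)
#' @export
window_to_fractions <- function(window, params) {
  stopifnot(inherits(window, "dev_window"))
  check_clock(params)
  if (!identical(window$species_name, params$species_name)) {
    stop_input("window is for '%s' but params are for '%s'",
               window$species_name, params$species_name)
  }
  if (window$start_pc < params$t_init) {
    stop_input(paste0(
      "window starts at PC %g, before t_init = %g: the decay fraction ",
      "saturates at 1 on the plateau and the window cannot be represented"),
      window$start_pc, params$t_init)
  }
  f <- c(decay_fraction(params, window$start_pc),
         decay_fraction(params, window$end_pc))
  structure(list(f_start = f[1], f_end = f[2]), class = "fraction_window")
}

#' @export
print.fraction_window <- function(x, ...) {
  cat(sprintf("<fraction_window> f_start = %.4f, f_end = %.4f\n",
              x$f_start, x$f_end))
  invisible(x)
}

#' Project decay fractions onto a target species' clock
#'
#' Solves the target clock for the ages at which the same decay fractions
#' are reached: `t_init + tau * log(1/f)` per bound.
#'
#' @param fractions a `fraction_window` from [window_to_fractions()].
#' @param target [species_params()] of the target species.
#' @return [dev_window()] in the target species.
#' @export
project_window <- function(fractions, target) {
  stopifnot(inherits(fractions, "fraction_window"))
  check_clock(target)
  dev_window(target$species_name,
             age_at_fraction(target, fractions$f_start),
             age_at_fraction(target, fractions$f_end))
}

#' Translate a developmental window across species
#'
#' Composition of [window_to_fractions()] and [project_window()]: the source
#' window is expressed as fractional FA decay bounds (species-free) and those
#' fractions are mapped onto the target species' clock. Translating the rat
#' critical period P4-P6 (PC 25.5-27.5) onto the human clock yields about
#' gestational days 201-217; onto the ferret clock, about PC 56.5-60.8.
#'
#' @param source_window a [dev_window()] in the source species.
#' @param source,target [species_params()] for the two species.
#' @return [dev_window()] in the target species (exact bounds; round at
#'   report time with [format_window()]).
#' @examples
#' reg <- default_species_registry()
#' w <- dev_window("rat", 25.5, 27.5)
#' translate_window(w, reg$rat, reg$human)
#' @export
translate_window <- function(source_window, source, target) {
  project_window(window_to_fractions(source_window, source), target)
}

#' Published Translating Time reference windows
#'
#' Printed outputs of the Translating Time cross-species regression for the
#' rat critical period (P4-P6), shipped as immutable reference constants for
#' comparison; the regression itself (species/event scores) is not part of
#' this package. Human: gestational days 138-150. Ferret: P11-P15.5,
#' i.e. PC 52-56.5. The cat entries are single translated events
#' (rat P6 -> gestational day 61.9; ferret P20 -> 66.8).
#'
#' @return named list of reference records, each with `source_species`,
#'   `target_species`, `window_pc` ([dev_window()] or single ages) and `note`.
#' @export
tt_references <- function() {
  list(
    human = list(
      source_species = "rat", target_species = "human",
      window_pc = dev_window("human", 138, 150),
      note = "Translating Time: rat P4-P6 -> human gestational days 138-150 (19.7-21.4 wk)"
    ),
    ferret = list(
      source_species = "rat", target_species = "ferret",
      window_pc = dev_window("ferret", 52, 56.5),
      note = "Translating Time: rat P4-P6 -> ferret P11-P15.5 (PC 52-56.5)"
    ),
    cat_events = list(
      source_species = c("rat", "ferret"), target_species = "cat",
      events_gd = c(rat_P6 = 61.9, ferret_P20 = 66.8),
      note = "Translating Time single events: rat P6 -> cat gd 61.9; ferret P20 -> cat gd 66.8"
    )
  )
}

#' Compare a predicted window with a Translating Time reference
#'
#' Signed per-bound offsets in days, FA-clock prediction minus Translating
#' Time reference. Positive offsets mean the FA-based window is later.
#'
#' @param predicted [dev_window()] from [translate_window()].
#' @param reference one element of [tt_references()] (must contain a
#'   `window_pc` and match the predicted window's species).
#' @return list with `offset_start`, `offset_end` (days) and `overlaps`
#'   (logical: do the two windows intersect?).
#' @export
compare_to_translating_time <- function(predicted, reference) {
  stopifnot(inherits(predicted, "dev_window"))
  ref_win <- reference$window_pc
  if (is.null(ref_win)) stop_input("reference has no window (single-event record?)")
  if (!identical(predicted$species_name, ref_win$species_name)) {
    stop_input("species mismatch: predicted '%s' vs reference '%s'",
               predicted$species_name, ref_win$species_name)
  }
  list(
    offset_start = predicted$start_pc - ref_win$start_pc,
    offset_end = predicted$end_pc - ref_win$end_pc,
    overlaps = predicted$start_pc <= ref_win$end_pc &&
               ref_win$start_pc <= predicted$end_pc
  )
}

#' Render an age in the field's customary frames
#'
#' Formats a postconceptional age as PC days plus either a postnatal day
#' (postnatal ages) or a gestational-day label (prenatal ages), with
#' gestational weeks at 1 decimal. Ages round to the nearest whole day,
#' half away from zero.
#'
#' @param age_pc age in days post conception.
#' @param gestation_days gestation length of the species.
#' @return character scalar.
#' @export
format_age <- function(age_pc, gestation_days) {
  pc <- round_half_away(age_pc)
  pn <- age_pc - gestation_days
  if (pn >= 0) {
    sprintf("PC%d (P%g)", pc, round_half_away(pn, 1))
  } else {
    sprintf("gestational day %d (%.1f wk)", pc, age_pc / 7)
  }
}

#' Render a developmental window for reporting
#'
#' @param window a [dev_window()].
#' @param gestation_days gestation length of the window's species.
#' @return character scalar, e.g. "human: gestational day 201 (28.7 wk) -
#'   gestational day 217 (31.0 wk)".
#' @export
format_window <- function(window, gestation_days) {
  sprintf("%s: %s - %s", window$species_name,
          format_age(window$start_pc, gestation_days),
          format_age(window$end_pc, gestation_days))
}
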
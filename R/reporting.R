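# Reporting stage: cross-species prediction reports and the FA-trajectory
# timeline figure, each writing machine-readable output plus a provenance
# record under a single run directory.

#' Run a cross-species critical-period prediction and write reports
#'
#' Translates a developmental window from a source species onto one or more
#' target species by fractional-FA-decay matching, renders the result in
#' postconceptional days, gestational weeks and postnatal/gestational-day
#' frames, compares against the published Translating Time windows where
#' available, and writes `prediction.json`, a human-readable
#' `prediction.txt`, and a `provenance.json` record into `out_dir`.
#'
#' @param source_species source species name (must be in the registry).
#' @param window length-2 numeric: window bounds in the source species.
#' @param window_frame `"postnatal"` (default) or `"pc"` — the frame of
#'   `window`.
#' @param targets character vector of target species (default: every
#'   registry species with a fitted clock other than the source).
#' @param registry named list of [species_params()]
#'   (default [default_species_registry()]) or a path readable by
#'   [read_species_registry()].
#' @param out_dir output directory, created if missing; `NULL` writes no
#'   files and just returns the report.
#' @param seed recorded in provenance (no randomness is consumed here).
#' @return the report, invisibly when writing: list with one entry per
#'   target holding the exact and rounded bounds, rendered strings, and the
#'   Translating Time comparison when available.
#' @examples
#' rep <- run_predict("rat", c(4, 6), targets = "human", out_dir = NULL)
#' rep$human$window_pc_rounded  # 201 217
#' @export
run_predict <- function(source_species, window, window_frame = c("postnatal", "pc"),
                        targets = NULL, registry = default_species_registry(),
                        out_dir = NULL, seed = NA_integer_) {
  window_frame <- match.arg(window_frame)
  if (is.character(registry)) registry <- read_species_registry(registry)
  if (!source_species %in% names(registry)) {
    stop_input("unknown species '%s'; registry has: %s", source_species,
               paste(names(registry), collapse = ", "))
  }
  src <- registry[[source_species]]
  if (length(window) != 2 || any(!is.finite(window))) {
    stop_input("`window` must be two finite bounds")
  }
  wpc <- if (window_frame == "postnatal") pn_to_pc(window, src$gestation_days) else window
  src_win <- dev_window(source_species, wpc[1], wpc[2])
  fractions <- window_to_fractions(src_win, src)

  if (is.null(targets)) {
    targets <- names(registry)[vapply(registry, has_clock, logical(1))]
    targets <- setdiff(targets, source_species)
  }
  tt <- tt_references()

  report <- list()
  for (tg in targets) {
    if (!tg %in% names(registry)) {
      stop_input("unknown species '%s'; registry has: %s", tg,
                 paste(names(registry), collapse = ", "))
    }
    par <- registry[[tg]]
    win <- project_window(fractions, par)
    entry <- list(
      source_window_pc = c(src_win$start_pc, src_win$end_pc),
      fractions = c(fractions$f_start, fractions$f_end),
      window_pc = c(win$start_pc, win$end_pc),
      window_pc_rounded = round_half_away(c(win$start_pc, win$end_pc)),
      window_weeks = round_half_away(c(win$start_pc, win$end_pc) / 7, 1),
      window_postnatal = c(win$start_pc, win$end_pc) - par$gestation_days,
      rendered = format_window(win, par$gestation_days)
    )
    ref <- Filter(function(r) identical(r$target_species, tg) &&
                    !is.null(r$window_pc), tt)
    if (length(ref)) {
      cmp <- compare_to_translating_time(win, ref[[1]])
      entry$translating_time <- list(
        window_pc = c(ref[[1]]$window_pc$start_pc, ref[[1]]$window_pc$end_pc),
        offset_days = c(cmp$offset_start, cmp$offset_end),
        overlaps = cmp$overlaps, note = ref[[1]]$note
      )
    }
    report[[tg]] <- entry
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "prediction.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(render_prediction_text(source_species, src_win, fractions, report),
               file.path(out_dir, "prediction.txt"))
    write_provenance(out_dir, "predict",
                     list(source = source_species, window = window,
                          window_frame = window_frame, targets = targets),
                     seed)
    return(invisible(report))
  }
  report
}

render_prediction_text <- function(source_species, src_win, fractions, report) {
  out <- c(
    sprintf("Critical-period translation from %s PC %g-%g", source_species,
            src_win$start_pc, src_win$end_pc),
    sprintf("Fractional FA decay bounds: %.4f -> %.4f",
            fractions$f_start, fractions$f_end),
    ""
  )
  for (tg in names(report)) {
    e <- report[[tg]]
    out <- c(out, sprintf("%s: PC %d-%d (%.1f-%.1f wk)  [exact %.2f-%.2f]",
                          tg, e$window_pc_rounded[1], e$window_pc_rounded[2],
                          e$window_weeks[1], e$window_weeks[2],
                          e$window_pc[1], e$window_pc[2]),
             sprintf("  %s", e$rendered))
    if (!is.null(e$translating_time)) {
      out <- c(out, sprintf(
        "  Translating Time reference: PC %g-%g (offsets %+.1f, %+.1f d; overlap: %s)",
        e$translating_time$window_pc[1], e$translating_time$window_pc[2],
        e$translating_time$offset_days[1], e$translating_time$offset_days[2],
        e$translating_time$overlaps))
    }
  }
  out
}

#' Plot FA maturation trajectories with window overlays
#'
#' The timeline figure: one FA-versus-postconceptional-age curve per
#' registry species with a fitted clock, with optional shaded developmental
#' windows (e.g. the rat critical period and its translations).
#'
#' @param registry named list of [species_params()] or a registry file path.
#' @param windows optional list of [dev_window()] objects to shade.
#' @param age_max right edge of the age axis in days post conception
#'   (default: 1.5x the largest t_init + 3 tau among plotted species).
#' @param out_file optional path (.pdf/.png) to save the figure.
#' @return the ggplot object, invisibly when saving.
#' @export
run_plot_trajectories <- function(registry = default_species_registry(),
                                  windows = NULL, age_max = NULL,
                                  out_file = NULL) {
  if (is.character(registry)) registry <- read_species_registry(registry)
  if (length(registry) == 0) stop_input("registry is empty; supply species parameters")
  plotted <- registry[vapply(registry, has_clock, logical(1))]
  skipped <- setdiff(names(registry), names(plotted))
  if (length(skipped)) {
    warning(sprintf("skipping species without FA clock: %s",
                    paste(skipped, collapse = ", ")))
  }
  if (length(plotted) == 0) stop_input("no species with fitted FA clocks to plot")
  if (is.null(age_max)) {
    age_max <- 1.5 * max(vapply(plotted, function(p) p$t_init + 3 * p$tau,
                                numeric(1)))
  }
  curves <- do.call(rbind, lapply(plotted, function(p) {
    ages <- seq(1, age_max, length.out = 400)
    data.frame(species = p$species_name, age_pc = ages, fa = fa_at_age(p, ages))
  }))
  g <- ggplot2::ggplot(curves,
                       ggplot2::aes(x = .data$age_pc, y = .data$fa,
                                    colour = .data$species)) +
    ggplot2::geom_line(linewidth = 0.8)
  if (!is.null(windows)) {
    shade <- do.call(rbind, lapply(windows, function(w) {
      data.frame(species = w$species_name, xmin = w$start_pc, xmax = w$end_pc)
    }))
    g <- g + ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax, fill = .data$species),
      ymin = -Inf, ymax = Inf, alpha = 0.15, inherit.aes = FALSE)
  }
  g <- g +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "age (days post conception, log scale)",
                  y = "cortical FA (fraction of range)",
                  colour = "species", fill = "window") +
    ggplot2::theme_minimal()
  if (!is.null(out_file)) {
    dir.create(dirname(out_file), recursive = TRUE, showWarnings = FALSE)
    ggplot2::ggsave(out_file, g, width = 7, height = 4.5)
    return(invisible(g))
  }
  g
}

# machine-readable provenance record for a reporting run
write_provenance <- function(out_dir, command, parameters, seed) {
  rec <- list(
    command = command,
    parameters = parameters,
    seed = seed,
    package = "cortexclock",
    version = as.character(utils::packageVersion("cortexclock")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(rec, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(rec)
}
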
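# Cortical surface-area reduction arithmetic: group means per region and
# percent reduction of treated (enucleated) relative to control.

#' Percent reduction of a treated mean relative to control
#'
#' `100 * (control - treated) / control`. Negative values (enlargement) are
#' allowed and flagged with a warning. Report at one decimal with
#' [round_half_away()]; e.g. cat striate cortex 339.46 -> 204.36 mm^2 is a
#' 39.8% reduction.
#'
#' @param control_mean control group mean area (> 0).
#' @param treated_mean treated group mean area.
#' @return percent reduction (numeric scalar, exact; round at report time).
#' @export
percent_reduction <- function(control_mean, treated_mean) {
  assert_pos(control_mean, "control_mean")
  p <- 100 * (control_mean - treated_mean) / control_mean
  if (any(p < 0, na.rm = TRUE)) {
    warning("treated mean exceeds control: negative reduction (enlargement)")
  }
  p
}

#' Summarize area measurements by region and group
#'
#' Arithmetic means per (region, group) cell and the percent reduction of
#' the treated mean relative to control per region. Regions missing either
#' group are reported with `NA` reduction rather than dropped. The summary
#' is invariant to input order and to a common unit rescaling of the areas.
#'
#' @param measures data frame with columns `region`, `group` (must contain
#'   levels `"control"` and `"treated"` where a reduction is wanted), `area`
#'   (> 0), and optionally `subject_id`.
#' @return list with `cells` (tibble: region, group, n, mean_area) and
#'   `reductions` (tibble: region, control_mean, treated_mean,
#'   percent_reduction).
#' @examples
#' df <- data.frame(region = "striate",
#'                  group = rep(c("control", "treated"), each = 3),
#'                  area = c(340, 339, 339.38, 205, 204, 204.08))
#' summarize_groups(df)
#' @export
summarize_groups <- function(measures) {
  df <- as.data.frame(measures)
  if (!all(c("region", "group", "area") %in% names(df))) {
    stop_input("measures need columns `region`, `group`, `area`")
  }
  if (any(df$area <= 0)) stop_input("areas must be > 0")
  cells <- df |>
    dplyr::group_by(.data$region, .data$group) |>
    dplyr::summarise(n = dplyr::n(), mean_area = mean(.data$area),
                     .groups = "drop") |>
    dplyr::arrange(.data$region, .data$group)

  wide <- cells |>
    dplyr::select("region", "group", "mean_area") |>
    tidyr_pivot(c("control", "treated"))
  reductions <- wide |>
    dplyr::mutate(percent_reduction =
                    100 * (.data$control - .data$treated) / .data$control) |>
    dplyr::rename(control_mean = "control", treated_mean = "treated")
  if (any(reductions$percent_reduction < 0, na.rm = TRUE)) {
    warning("treated mean exceeds control in some region(s): negative reduction")
  }
  list(cells = cells, reductions = reductions)
}

# minimal wide pivot (avoids a tidyr dependency for one reshape)
tidyr_pivot <- function(cells, groups) {
  regions <- unique(cells$region)
  out <- tibble::tibble(region = regions)
  for (g in groups) {
    sub <- cells[cells$group == g, ]
    out[[g]] <- sub$mean_area[match(regions, sub$region)]
  }
  out
}

#' Read area measurements from CSV
#'
#' Expects columns `subject_id`, `group`, `region`, `area_mm2`.
#'
#' @param path CSV file path.
#' @return tibble with columns `subject_id`, `group`, `region`, `area`.
#' @export
read_area_measures <- function(path) {
  df <- utils::read.csv(path)
  need <- c("subject_id", "group", "region", "area_mm2")
  if (!all(need %in% names(df))) {
    stop_input("CSV needs columns %s", paste(need, collapse = ", "))
  }
  tibble::tibble(subject_id = as.character(df$subject_id),
                 group = as.character(df$group),
                 region = as.character(df$region),
                 area = as.numeric(df$area_mm2))
}
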
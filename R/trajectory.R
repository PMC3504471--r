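# Piecewise-exponential cortical FA maturation clock.
#
# FA(age) = fa_max                                       for age <  t_init
#         = (fa_max - fa_min) * exp(-(age - t_init)/tau) + fa_min
#                                                        for age >= t_init
# Continuous at t_init; ages are days post conception throughout.

#' Evaluate the cortical FA maturation curve
#'
#' Cortical fractional anisotropy is maximal while pyramidal neurons are
#' still migrating, then decays exponentially towards its mature value as the
#' neuropil differentiates.
#'
#' @param params a [species_params()] object with a fitted clock.
#' @param age_pc postconceptional age(s) in days, > 0. Vectorised.
#' @return FA value(s) in \[fa_min, fa_max\].
#' @examples
#' rat <- default_species_registry()$rat
#' fa_at_age(rat, c(20, 25.5, 27.5))
#' @export
fa_at_age <- function(params, age_pc) {
  check_clock(params)
  assert_pos(age_pc, "age_pc")
  ifelse(age_pc < params$t_init,
         params$fa_max,
         (params$fa_max - params$fa_min) *
           exp(-(age_pc - params$t_init) / params$tau) + params$fa_min)
}

#' Fractional FA decay remaining at an age
#'
#' The species-free coordinate of the maturation clock: the fraction of the
#' FA range (fa_max - fa_min) still remaining at `age_pc`. Equals 1 on the
#' plateau and exp(-(age - t_init)/tau) afterwards; independent of the
#' absolute FA bounds, which is what makes cross-species translation by
#' fraction matching possible.
#'
#' @inheritParams fa_at_age
#' @return fraction(s) in (0, 1].
#' @examples
#' rat <- default_species_registry()$rat
#' decay_fraction(rat, c(25.5, 27.5))  # ~0.50 and ~0.33
#' @export
decay_fraction <- function(params, age_pc) {
  check_clock(params)
  assert_pos(age_pc, "age_pc")
  ifelse(age_pc <= params$t_init, 1,
         exp(-(age_pc - params$t_init) / params$tau))
}

#' Postconceptional age at a given decay fraction
#'
#' Exact inverse of [decay_fraction()] on the decay branch:
#' `t_init + tau * log(1/f)`.
#'
#' @inheritParams fa_at_age
#' @param f decay fraction(s) in (0, 1].
#' @return age(s) in days post conception.
#' @export
age_at_fraction <- function(params, f) {
  check_clock(params)
  if (!is.numeric(f) || any(!is.finite(f)) || any(f <= 0) || any(f > 1)) {
    stop_input("decay fraction must lie in (0, 1]")
  }
  params$t_init + params$tau * log(1 / f)
}

check_clock <- function(params) {
  if (!inherits(params, "species_fa_params")) {
    stop_input("`params` must be a species_fa_params object")
  }
  if (!has_clock(params)) {
    stop_input("species '%s' has no fitted FA clock (t_init/tau missing)",
               params$species_name)
  }
  invisible(params)
}

#' Fit the FA maturation clock to FA-versus-age observations
#'
#' Least-squares fit of the piecewise-exponential clock to (age, FA) pairs.
#' The plateau breakpoint makes the model non-smooth in `t_init`, so when
#' `t_init` is free it is profiled over a grid (1-day sweep over the observed
#' age range refined to 0.1-day resolution around the coarse optimum) with
#' the remaining parameters estimated by Levenberg-Marquardt least squares at
#' each candidate. `tau` is always free; any of `t_init`, `fa_max`, `fa_min`
#' can be fixed by name.
#'
#' Starting values are scale-free: `fa_max` at the largest observed FA,
#' `fa_min` at the smallest, `tau` at a third of the observed age range.
#'
#' @param observations data frame with numeric columns `age_pc` (> 0) and
#'   `fa` (in \[0, 1\]), e.g. from [gen_fa_observations()] or
#'   [read_fa_observations()].
#' @param fixed named numeric vector (or list) fixing a subset of
#'   `t_init`, `fa_max`, `fa_min`; e.g. `c(t_init = 49)`.
#' @param species_name label attached to the fitted parameters.
#' @return an object of class `fa_fit`: list with elements `params`
#'   ([species_params()] carrying the estimates), `residual_sum_of_squares`,
#'   `n_points`, `converged`, and `free` (names of the free parameters).
#' @examples
#' rat <- default_species_registry()$rat
#' obs <- gen_fa_observations(rat, ages = seq(23, 50, 3), noise_sd = 0, seed = 1)
#' fit_fa_params(obs, fixed = c(t_init = 22))
#' @export
fit_fa_params <- function(observations, fixed = NULL, species_name = "fitted") {
  obs <- as.data.frame(observations)
  if (!all(c("age_pc", "fa") %in% names(obs))) {
    stop_input("observations need columns `age_pc` and `fa`")
  }
  age <- as.numeric(obs$age_pc)
  fa <- as.numeric(obs$fa)
  keep <- is.finite(age) & is.finite(fa)
  age <- age[keep]; fa <- fa[keep]
  if (any(age <= 0)) stop_input("ages must be strictly positive (days post conception)")

  fixed <- unlist(fixed)
  bad <- setdiff(names(fixed), c("t_init", "fa_max", "fa_min"))
  if (length(bad)) stop_input("cannot fix parameter(s): %s", paste(bad, collapse = ", "))
  free <- c(setdiff(c("t_init", "fa_max", "fa_min"), names(fixed)), "tau")
  n_free <- length(free)
  if (length(age) < n_free + 1) {
    stop_input("insufficient data: %d points for %d free parameters (need > %d)",
               length(age), n_free, n_free)
  }

  t_fixed <- if ("t_init" %in% names(fixed)) as.numeric(fixed[["t_init"]]) else NULL

  if (is.null(t_fixed)) {
    lo <- min(age); hi <- max(age)
    coarse <- unique(c(seq(lo, hi, by = 1), hi))
    best <- profile_best(coarse, age, fa, fixed)
    fine <- seq(max(lo, best$t_init - 1), min(hi, best$t_init + 1), by = 0.1)
    best <- profile_best(fine, age, fa, fixed)
  } else {
    best <- inner_fit(t_fixed, age, fa, fixed)
  }

  est <- best$est
  params <- species_params(
    species_name,
    gestation_days = 1,  # nominal: fits carry no frame information
    t_init = best$t_init, tau = est[["tau"]],
    fa_max = if ("fa_max" %in% names(fixed)) fixed[["fa_max"]] else est[["fa_max"]],
    fa_min = if ("fa_min" %in% names(fixed)) fixed[["fa_min"]] else est[["fa_min"]]
  )
  structure(
    list(params = params, residual_sum_of_squares = best$rss,
         n_points = length(age), converged = best$converged, free = free),
    class = "fa_fit"
  )
}

#' @export
print.fa_fit <- function(x, ...) {
  p <- x$params
  cat("<fa_fit>\n")
  cat(sprintf("  t_init = %.3f dpc, tau = %.4f d, fa_max = %.4f, fa_min = %.4f\n",
              p$t_init, p$tau, p$fa_max, p$fa_min))
  cat(sprintf("  RSS = %.3g on %d points; converged: %s; free: %s\n",
              x$residual_sum_of_squares, x$n_points, x$converged,
              paste(x$free, collapse = ", ")))
  invisible(x)
}

profile_best <- function(grid, age, fa, fixed) {
  fits <- lapply(grid, function(t0) inner_fit(t0, age, fa, fixed))
  rss <- vapply(fits, function(f) f$rss, numeric(1))
  fits[[which.min(rss)]]
}

# Fit tau (and any free FA bounds) for a fixed breakpoint t0.
inner_fit <- function(t0, age, fa, fixed) {
  free_bounds <- setdiff(c("fa_max", "fa_min"), names(fixed))
  fmax0 <- if ("fa_max" %in% names(fixed)) fixed[["fa_max"]] else max(fa)
  fmin0 <- if ("fa_min" %in% names(fixed)) fixed[["fa_min"]] else min(fa)
  tau0 <- max(diff(range(age)) / 3, 1e-3)

  start <- c(list(tau = tau0),
             if ("fa_max" %in% free_bounds) list(fa_max = fmax0),
             if ("fa_min" %in% free_bounds) list(fa_min = fmin0))
  lower <- c(tau = 1e-6,
             if ("fa_max" %in% free_bounds) c(fa_max = 0),
             if ("fa_min" %in% free_bounds) c(fa_min = 0))
  upper <- c(tau = Inf,
             if ("fa_max" %in% free_bounds) c(fa_max = 1),
             if ("fa_min" %in% free_bounds) c(fa_min = 1))

  model <- function(tau, fa_max = fmax0, fa_min = fmin0) {
    ifelse(age < t0, fa_max, (fa_max - fa_min) * exp(-(age - t0) / tau) + fa_min)
  }
  form <- switch(length(free_bounds) + 1L,
    fa ~ model(tau),                       # both bounds fixed
    NULL, NULL)
  if (is.null(form)) {
    form <- if (setequal(free_bounds, c("fa_max", "fa_min"))) {
      fa ~ model(tau, fa_max, fa_min)
    } else if ("fa_max" %in% free_bounds) {
      fa ~ model(tau, fa_max = fa_max)
    } else {
      fa ~ model(tau, fa_min = fa_min)
    }
  }

  fit <- tryCatch(
    minpack.lm::nlsLM(form, start = start, lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(list(t_init = t0, est = c(tau = NA_real_), rss = Inf, converged = FALSE))
  }
  est <- stats::coef(fit)
  conv <- isTRUE(fit$convInfo$isConv)
  list(t_init = t0, est = est, rss = sum(stats::resid(fit)^2), converged = conv)
}

#' Read FA observations from CSV
#'
#' Expects columns `age_pc` and `fa`; alternatively `age_postnatal` plus a
#' `gestation_days` argument, converted on read via [pn_to_pc()].
#'
#' @param path CSV file path.
#' @param gestation_days gestation length, required only when the file has
#'   `age_postnatal` instead of `age_pc`.
#' @return tibble with columns `age_pc`, `fa`.
#' @export
read_fa_observations <- function(path, gestation_days = NULL) {
  df <- utils::read.csv(path)
  if (!"age_pc" %in% names(df)) {
    if (!"age_postnatal" %in% names(df)) {
      stop_input("CSV needs `age_pc` or `age_postnatal` column")
    }
    if (is.null(gestation_days)) {
      stop_input("`gestation_days` required to convert age_postnatal")
    }
    df$age_pc <- pn_to_pc(df$age_postnatal, gestation_days)
  }
  if (!"fa" %in% names(df)) stop_input("CSV needs `fa` column")
  if (any(df$fa < 0 | df$fa > 1, na.rm = TRUE)) {
    stop_input("FA values must lie in [0, 1]")
  }
  tibble::tibble(age_pc = as.numeric(df$age_pc), fa = as.numeric(df$fa))
}
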
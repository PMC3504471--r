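# Axial von Mises statistics for undirected line orientations.
#
# Orientations of neurite segments are axial: theta and theta + 180 deg are
# the same line. The standard correction is angle doubling — fit an ordinary
# von Mises distribution to 2*theta on the full circle, then halve the mean
# direction. kappa is estimated by maximum likelihood: invert the mean
# resultant length equation A1(kappa) = Rbar, where A1 = I1/I0, using
# Fisher's series approximation polished by Newton steps.

KAPPA_CAP <- 500

# A1(kappa) = I1(kappa)/I0(kappa), numerically stable via scaled Bessel.
A1 <- function(kappa) {
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

# Inverse of A1 by series approximation (Fisher 1993) + Newton refinement.
# Vectorised; values at or above the cap are returned as the cap.
A1inv <- function(rbar) {
  k <- ifelse(rbar < 0.53,
              2 * rbar + rbar^3 + 5 * rbar^5 / 6,
              ifelse(rbar < 0.85,
                     -0.4 + 1.39 * rbar + 0.43 / (1 - rbar),
                     1 / (rbar^3 - 4 * rbar^2 + 3 * rbar)))
  k <- pmin(pmax(k, 0), KAPPA_CAP)
  # Newton: g(k) = A1(k) - rbar, g'(k) = 1 - A1/k - A1^2
  for (i in 1:5) {
    a <- A1(k)
    deriv <- 1 - a / pmax(k, 1e-12) - a^2
    step <- ifelse(abs(deriv) > 1e-12, (a - rbar) / deriv, 0)
    k <- pmin(pmax(k - step, 0), KAPPA_CAP)
  }
  k
}

#' An orientation sample of axial polar angles
#'
#' @param angles_deg axial polar angles in degrees, each in \[0, 180);
#'   angles outside are folded modulo 180.
#' @param region_label optional label for the sampled region.
#' @param plane section plane, `"coronal"` or `"axial"` (informational).
#' @param weights optional positive weights, one per angle. Segment-derived
#'   samples carry segment lengths here: a straight stroke's evidence about
#'   the orientation field scales with its stained length, and weighting
#'   de-emphasises short junction fragments whose chord angles are noisy.
#' @return object of class `orientation_sample`.
#' @export
orientation_sample <- function(angles_deg, region_label = NA_character_,
                               plane = c("coronal", "axial"), weights = NULL) {
  plane <- match.arg(plane)
  angles_deg <- as.numeric(angles_deg) %% 180
  if (!is.null(weights)) {
    weights <- as.numeric(weights)
    if (length(weights) != length(angles_deg) || any(!is.finite(weights)) ||
        any(weights <= 0)) {
      stop_input("weights must be positive, one per angle")
    }
  }
  structure(list(angles_deg = angles_deg, region_label = region_label,
                 plane = plane, weights = weights),
            class = "orientation_sample")
}

#' @export
print.orientation_sample <- function(x, ...) {
  cat(sprintf("<orientation_sample> n = %d, region = %s, plane = %s\n",
              length(x$angles_deg), x$region_label, x$plane))
  invisible(x)
}

#' Fit an axial von Mises distribution
#'
#' Maximum-likelihood mean direction and concentration parameter kappa for
#' axial angles in \[0, 180). Angles are doubled onto the full circle, the
#' circular mean and mean resultant length computed, kappa obtained by
#' inverting A1 (series approximation plus Newton polishing), and the mean
#' direction halved back. kappa = 0 corresponds to a uniform orientation
#' distribution; larger kappa means orientations cluster more tightly (e.g.
#' coherently radial apical dendrites). Near-degenerate samples (all angles
#' equal) hit the documented cap of 500 and are flagged.
#'
#' @param sample an [orientation_sample()] or numeric vector of angles in
#'   degrees. Samples carrying weights (segment lengths) are fitted by
#'   weighted circular moments; plain angle vectors are unweighted.
#' @param min_n minimum sample size (default 10).
#' @return object of class `von_mises_fit`: `mu_deg` (mean axis, \[0, 180)),
#'   `kappa`, `rbar` (mean resultant length of doubled angles), `n`,
#'   `capped` flag, and `ci_95` (NULL until [bootstrap_kappa_ci()] is run).
#' @examples
#' ang <- gen_axial_angles(mu_deg = 0, kappa = 2, n = 500, seed = 1)
#' fit_von_mises(ang)
#' @export
fit_von_mises <- function(sample, min_n = 10) {
  angles <- sample_angles(sample)
  if (length(angles) < min_n) {
    stop_input("insufficient data: %d angles (need >= %d)", length(angles), min_n)
  }
  est <- vm_axial_estimate(angles, sample_weights(sample))
  structure(
    list(mu_deg = est$mu_deg, kappa = est$kappa, rbar = est$rbar,
         n = length(angles), capped = est$kappa >= KAPPA_CAP, ci_95 = NULL),
    class = "von_mises_fit"
  )
}

# core estimator on a bare angle vector (degrees, axial); optional weights
vm_axial_estimate <- function(angles_deg, w = NULL) {
  phi <- deg2rad(2 * (angles_deg %% 180))
  if (is.null(w)) w <- rep(1, length(phi))
  w <- w / sum(w)
  c_bar <- sum(w * cos(phi)); s_bar <- sum(w * sin(phi))
  rbar <- sqrt(c_bar^2 + s_bar^2)
  mu2 <- atan2(s_bar, c_bar)
  mu_deg <- (rad2deg(mu2) / 2) %% 180
  list(mu_deg = mu_deg, kappa = A1inv(rbar), rbar = rbar)
}

sample_angles <- function(sample) {
  if (inherits(sample, "orientation_sample")) sample$angles_deg
  else as.numeric(sample) %% 180
}

sample_weights <- function(sample) {
  if (inherits(sample, "orientation_sample")) sample$weights else NULL
}

#' @export
print.von_mises_fit <- function(x, ...) {
  cat(sprintf("<von_mises_fit> mu = %.1f deg, kappa = %.3f (n = %d)%s\n",
              x$mu_deg, x$kappa, x$n, if (x$capped) " [kappa at cap]" else ""))
  if (!is.null(x$ci_95)) {
    cat(sprintf("  95%% CI for kappa: [%.3f, %.3f]\n", x$ci_95[1], x$ci_95[2]))
  }
  invisible(x)
}

#' Percentile bootstrap confidence interval for kappa
#'
#' Resamples the angles with replacement, re-estimates kappa on each
#' replicate, and returns the percentile interval. Deterministic for a fixed
#' seed.
#'
#' @param sample an [orientation_sample()] or numeric angle vector.
#' @param n_boot number of bootstrap replicates (>= 100; default 1000).
#' @param seed integer seed.
#' @param level confidence level (default 0.95).
#' @param min_n minimum sample size passed to the fit.
#' @return a `von_mises_fit` whose `ci_95` holds the interval (low, high).
#' @export
bootstrap_kappa_ci <- function(sample, n_boot = 1000, seed = 1, level = 0.95,
                               min_n = 10) {
  if (n_boot < 100) stop_input("n_boot must be >= 100")
  fit <- fit_von_mises(sample, min_n = min_n)
  angles <- sample_angles(sample)
  w <- sample_weights(sample)
  n <- length(angles)
  set.seed(seed)
  phi <- deg2rad(2 * angles)
  # resample (angle, weight) pairs jointly; vectorised, column = replicate
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
  if (is.null(w)) {
    c_bar <- colMeans(matrix(cos(phi)[idx], nrow = n))
    s_bar <- colMeans(matrix(sin(phi)[idx], nrow = n))
  } else {
    wm <- matrix(w[idx], nrow = n)
    tot <- colSums(wm)
    c_bar <- colSums(wm * matrix(cos(phi)[idx], nrow = n)) / tot
    s_bar <- colSums(wm * matrix(sin(phi)[idx], nrow = n)) / tot
  }
  kap <- A1inv(sqrt(c_bar^2 + s_bar^2))
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(kap, c(alpha, 1 - alpha), type = 7))
  fit$ci_95 <- ci
  fit$n_boot <- n_boot
  fit
}

#' Compare two fitted orientation distributions
#'
#' Reports the concentration difference kappa_a - kappa_b and whether the
#' two bootstrap 95% confidence intervals are disjoint — the criterion used
#' to call a region pair significantly different (e.g. enucleated-versus-
#' control visual cortex).
#'
#' @param fit_a,fit_b `von_mises_fit` objects with bootstrap CIs.
#' @return list with `kappa_diff`, `disjoint`, and the two CIs.
#' @export
compare_regions <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "von_mises_fit"), inherits(fit_b, "von_mises_fit"))
  if (is.null(fit_a$ci_95) || is.null(fit_b$ci_95)) {
    stop_input("both fits need bootstrap CIs (run bootstrap_kappa_ci first)")
  }
  disjoint <- fit_a$ci_95[2] < fit_b$ci_95[1] || fit_b$ci_95[2] < fit_a$ci_95[1]
  list(kappa_diff = fit_a$kappa - fit_b$kappa, disjoint = disjoint,
       ci_a = fit_a$ci_95, ci_b = fit_b$ci_95)
}

#' Fixed-width histogram of bounded values
#'
#' Simple binned counts used for FA-value and polar-angle histograms. Bins
#' are `[lo, lo + w), [lo + w, lo + 2w), ...` covering the data range (or the
#' supplied range); the final bin is closed so counts always conserve n.
#'
#' @param values numeric vector.
#' @param bin_width positive bin width (same units as `values`).
#' @param range optional length-2 numeric giving the binning range; defaults
#'   to `range(values)` snapped outward to bin-width multiples.
#' @return tibble with `bin_lo`, `bin_hi`, `count`; empty input gives an
#'   empty tibble.
#' @export
value_histogram <- function(values, bin_width, range = NULL) {
  assert_pos(bin_width, "bin_width")
  values <- values[is.finite(values)]
  if (length(values) == 0) {
    return(tibble::tibble(bin_lo = numeric(), bin_hi = numeric(),
                          count = integer()))
  }
  if (is.null(range)) {
    lo <- floor(min(values) / bin_width) * bin_width
    hi <- ceiling(max(values) / bin_width) * bin_width
    if (hi <= lo) hi <- lo + bin_width
  } else {
    lo <- range[1]; hi <- range[2]
    if (any(values < lo | values > hi)) stop_input("values outside supplied range")
  }
  edges <- seq(lo, hi, by = bin_width)
  if (edges[length(edges)] < hi) edges <- c(edges, hi)
  # right-open bins, last bin closed
  bin <- findInterval(values, edges, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = length(edges) - 1)
  tibble::tibble(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                 count = as.integer(counts))
}
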
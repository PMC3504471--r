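# Synthetic-data generators with known ground truth: noisy FA trajectories,
# axial von Mises angle samples, and Golgi-like raster images of dark
# elongated strokes on a light noisy background.

#' Generate noisy FA-versus-age observations
#'
#' Evaluates the species' FA clock at the requested ages and adds i.i.d.
#' Gaussian noise, clipped to the valid FA range \[0, 1\]. Deterministic for
#' a fixed seed.
#'
#' @param params a [species_params()] with a fitted clock.
#' @param ages postconceptional ages in days (> 0).
#' @param noise_sd standard deviation of the additive noise, FA units
#'   (>= 0). A noise_sd of 0.02 is typical of the scatter in published
#'   cortical FA measurements.
#' @param seed integer seed.
#' @return tibble with columns `age_pc`, `fa`.
#' @export
gen_fa_observations <- function(params, ages, noise_sd = 0.02, seed = 1) {
  check_clock(params)
  assert_pos(ages, "ages")
  if (noise_sd < 0) stop_input("noise_sd must be >= 0")
  set.seed(seed)
  fa <- fa_at_age(params, ages)
  if (noise_sd > 0) fa <- fa + stats::rnorm(length(ages), 0, noise_sd)
  tibble::tibble(age_pc = as.numeric(ages), fa = pmin(pmax(fa, 0), 1))
}

#' Draw axial angles from a von Mises orientation distribution
#'
#' Samples on the doubled circle from von Mises(2*mu, kappa) by the
#' Best-Fisher rejection scheme (wrapped-Cauchy envelope), then halves and
#' folds the draws into \[0, 180). kappa = 0 yields the uniform axial
#' distribution.
#'
#' @param mu_deg mean axis in degrees, \[0, 180).
#' @param kappa concentration parameter (>= 0).
#' @param n number of draws (>= 1).
#' @param seed integer seed.
#' @param region_label,plane metadata for the returned sample.
#' @return an [orientation_sample()].
#' @examples
#' fit_von_mises(gen_axial_angles(90, kappa = 1.41, n = 2000, seed = 7))
#' @export
gen_axial_angles <- function(mu_deg, kappa, n, seed = 1,
                             region_label = NA_character_, plane = "coronal") {
  if (kappa < 0) stop_input("kappa must be >= 0")
  if (n < 1) stop_input("n must be >= 1")
  set.seed(seed)
  psi <- rvonmises(n, deg2rad(2 * mu_deg), kappa)
  theta <- (rad2deg(psi) / 2) %% 180
  orientation_sample(theta, region_label, plane)
}

# von Mises sampler, Best & Fisher (1979) wrapped-Cauchy envelope.
# Returns angles in radians on [0, 2*pi).
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(n - length(out), 16L)
    m <- ceiling(m * 1.3)  # oversample: acceptance rate is high for all kappa
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    th <- sign(u3[ok] - 0.5) * acos(f[ok])
    out <- c(out, th)
  }
  (mu + out[seq_len(n)]) %% (2 * pi)
}

#' Specification for a synthetic Golgi-like image
#'
#' Describes a field of dark anti-aliased strokes (stand-ins for stained
#' neuronal processes) on a light noisy background, with stroke orientations
#' drawn from an axial von Mises distribution. Defaults emulate a 10x
#' Golgi field dominated by radially oriented apical dendrites.
#'
#' @param image_size side length in pixels (square canvas).
#' @param n_segments number of strokes (> 0).
#' @param mu_deg mean stroke axis, degrees from the radial (vertical) axis.
#' @param kappa orientation concentration (>= 0; 0 = uniform).
#' @param length_px length-2 numeric: min and max stroke length (pixels).
#' @param stroke_width_px stroke thickness in pixels.
#' @param background intensity of the unstained background in \[0, 1\].
#' @param foreground intensity at stroke centres (darker than background).
#' @param background_noise_sd Gaussian intensity noise on the background.
#' @param seed integer seed.
#' @return object of class `golgi_sim_spec`.
#' @export
golgi_sim_spec <- function(image_size = 768, n_segments = 500, mu_deg = 0,
                           kappa = 2, length_px = c(30, 80),
                           stroke_width_px = 3, background = 0.85,
                           foreground = 0.15, background_noise_sd = 0.03,
                           seed = 1) {
  if (n_segments <= 0) stop_input("n_segments must be > 0")
  if (kappa < 0) stop_input("kappa must be >= 0")
  if (any(length_px <= 0) || length_px[1] > length_px[2]) {
    stop_input("length_px must be positive (min, max)")
  }
  structure(
    list(image_size = as.integer(image_size), n_segments = as.integer(n_segments),
         mu_deg = mu_deg, kappa = kappa, length_px = length_px,
         stroke_width_px = stroke_width_px, background = background,
         foreground = foreground, background_noise_sd = background_noise_sd,
         seed = as.integer(seed)),
    class = "golgi_sim_spec"
  )
}

#' Render a synthetic Golgi-like image with ground-truth orientations
#'
#' Draws `n_segments` anti-aliased dark strokes on a light noisy background.
#' Stroke axes come from [gen_axial_angles()]; stroke centres are uniform
#' over the canvas (inset by half the maximum stroke length so strokes stay
#' mostly inside; no stroke can fall entirely outside). The generating
#' angles are returned as ground truth. Bit-identical for a fixed spec and
#' seed. Strokes are rendered smooth and binarized only by the analysis
#' pipeline's own thresholding step, so the thresholding stage is exercised
#' end to end.
#'
#' @param spec a [golgi_sim_spec()].
#' @return list with `image` (a [raster_image()]) and `truth` (an
#'   [orientation_sample()] of the generating angles).
#' @export
gen_golgi_image <- function(spec) {
  stopifnot(inherits(spec, "golgi_sim_spec"))
  sz <- spec$image_size
  truth <- gen_axial_angles(spec$mu_deg, spec$kappa, spec$n_segments,
                            seed = spec$seed, region_label = "synthetic")
  ang <- truth$angles_deg
  # continue from the sampler's RNG state (seeded in gen_axial_angles)
  lens <- stats::runif(spec$n_segments, spec$length_px[1], spec$length_px[2])
  inset <- min(spec$length_px[2] / 2, sz / 4)
  cr <- stats::runif(spec$n_segments, 1 + inset, sz - inset)
  cc <- stats::runif(spec$n_segments, 1 + inset, sz - inset)

  img <- matrix(spec$background, sz, sz)
  if (spec$background_noise_sd > 0) {
    img <- img + matrix(stats::rnorm(sz * sz, 0, spec$background_noise_sd), sz, sz)
  }

  half_w <- spec$stroke_width_px / 2
  depth <- spec$background - spec$foreground
  for (i in seq_len(spec$n_segments)) {
    # direction: angle measured from vertical (image up), rows grow downward
    dx <- sin(deg2rad(ang[i])); dy <- -cos(deg2rad(ang[i]))
    h <- lens[i] / 2
    r0 <- cr[i] - h * dy; c0 <- cc[i] - h * dx
    r1 <- cr[i] + h * dy; c1 <- cc[i] + h * dx
    pad <- half_w + 1.5
    rs <- max(1, floor(min(r0, r1) - pad)):min(sz, ceiling(max(r0, r1) + pad))
    cs <- max(1, floor(min(c0, c1) - pad)):min(sz, ceiling(max(c0, c1) + pad))
    if (length(rs) == 0 || length(cs) == 0) next
    gr <- matrix(rs, length(rs), length(cs))
    gc <- matrix(cs, length(rs), length(cs), byrow = TRUE)
    d <- dist_point_segment(gr, gc, r0, c0, r1, c1)
    cover <- pmin(pmax(half_w + 0.5 - d, 0), 1)  # linear anti-alias ramp
    # subtractive compositing: crossings darken further, clamped below
    img[rs, cs] <- img[rs, cs] - cover * depth
  }
  img <- pmin(pmax(img, 0), 1)
  list(image = raster_image(img, radial_axis = "vertical"), truth = truth)
}

# Euclidean distance from grid points to a segment (r0,c0)-(r1,c1).
dist_point_segment <- function(pr, pc, r0, c0, r1, c1) {
  vr <- r1 - r0; vc <- c1 - c0
  len2 <- vr^2 + vc^2
  t <- if (len2 == 0) 0 else pmin(pmax(((pr - r0) * vr + (pc - c0) * vc) / len2, 0), 1)
  sqrt((pr - (r0 + t * vr))^2 + (pc - (c0 + t * vc))^2)
}
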
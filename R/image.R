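# Golgi-image neurite orientation pipeline: threshold -> skeletonize ->
# split into branches -> approximate branches as line segments -> polar
# angles relative to the radial (pial-normal) axis.
#
# Images are plain numeric matrices (rows = image y, columns = image x),
# intensities in [0, 1]. The stain is dark on a light background by default.

#' A grayscale raster image with orientation metadata
#'
#' @param pixels numeric matrix of intensities in \[0, 1\] (at least 2x2).
#' @param pixel_size physical pixel size in micrometres (optional,
#'   informational).
#' @param radial_axis which image axis corresponds to the pial-normal
#'   (radial) direction: `"vertical"` (default; apical dendrites run along
#'   image columns) or `"horizontal"`.
#' @return object of class `raster_image`.
#' @export
raster_image <- function(pixels, pixel_size = NA_real_,
                         radial_axis = c("vertical", "horizontal")) {
  radial_axis <- match.arg(radial_axis)
  pixels <- as.matrix(pixels)
  if (nrow(pixels) < 2 || ncol(pixels) < 2) stop_input("image must be at least 2x2")
  if (any(!is.finite(pixels))) stop_input("image intensities must be finite")
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 radial_axis = radial_axis),
            class = "raster_image")
}

#' @export
print.raster_image <- function(x, ...) {
  cat(sprintf("<raster_image> %d x %d px, radial axis: %s\n",
              nrow(x$pixels), ncol(x$pixels), x$radial_axis))
  invisible(x)
}

#' Read a grayscale image (TIFF or PNG) with optional YAML sidecar
#'
#' Multi-channel images are averaged to one channel. A sidecar file
#' `<image>.yaml` (or an explicit `meta` path) may carry `region_label`,
#' `plane`, `radial_axis` and `pixel_size`.
#'
#' @param path image file (.tif/.tiff/.png).
#' @param meta optional path to a YAML metadata sidecar.
#' @return a [raster_image()]; metadata fields are attached as attributes
#'   `region_label` and `plane` when present.
#' @export
read_raster_image <- function(path, meta = NULL) {
  if (!file.exists(path)) stop_input("image not found: %s", path)
  px <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  if (length(dim(px)) == 3) px <- apply(px, c(1, 2), mean)
  md <- list()
  meta <- meta %||% paste0(path, ".yaml")
  if (!is.null(meta) && file.exists(meta)) md <- yaml::read_yaml(meta)
  img <- raster_image(px,
                      pixel_size = md$pixel_size %||% NA_real_,
                      radial_axis = md$radial_axis %||% "vertical")
  attr(img, "region_label") <- md$region_label %||% NA_character_
  attr(img, "plane") <- md$plane %||% NA_character_
  img
}

#' Write a grayscale image to TIFF or PNG
#'
#' @param image a [raster_image()] or numeric matrix in \[0, 1\].
#' @param path output path (.tif/.tiff or .png).
#' @return `path`, invisibly.
#' @export
write_raster_image <- function(image, path) {
  px <- if (inherits(image, "raster_image")) image$pixels else as.matrix(image)
  px <- pmin(pmax(px, 0), 1)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(px, path)
  } else {
    tiff::writeTIFF(px, path)
  }
  invisible(path)
}

#' Threshold the stain into a foreground mask
#'
#' Global Otsu split of the intensity histogram. With `polarity = "dark"`
#' (Golgi stain: dark processes on a light background) pixels below the
#' threshold are foreground; `"light"` inverts the comparison.
#'
#' @param image [raster_image()] or numeric matrix in \[0, 1\].
#' @param polarity `"dark"` or `"light"` foreground.
#' @return logical matrix, TRUE = foreground.
#' @export
threshold_image <- function(image, polarity = c("dark", "light")) {
  polarity <- match.arg(polarity)
  px <- if (inherits(image, "raster_image")) image$pixels else as.matrix(image)
  if (diff(range(px)) == 0) {
    return(matrix(FALSE, nrow(px), ncol(px)))  # flat image: no foreground
  }
  th <- EBImage::otsu(EBImage::Image(t(px)), range = range(px), levels = 256)
  if (polarity == "dark") px < th else px > th
}

#' Skeletonize the stained foreground
#'
#' Thresholds the image (unless given a logical mask) and thins the
#' foreground to a one-pixel-wide skeleton by Zhang-Suen iterative thinning.
#' Deterministic for a fixed input; an empty foreground yields an empty
#' skeleton.
#'
#' @param image [raster_image()], numeric matrix, or logical foreground mask.
#' @param polarity stain polarity passed to [threshold_image()].
#' @return logical matrix: the skeleton.
#' @examples
#' sim <- gen_golgi_image(golgi_sim_spec(n_segments = 5, seed = 1))
#' sk <- skeletonize(sim$image)
#' @export
skeletonize <- function(image, polarity = "dark") {
  mask <- if (is.logical(image)) {
    image
  } else {
    threshold_image(image, polarity = polarity)
  }
  thin_zhang_suen(mask)
}

# --- Zhang-Suen thinning, vectorised over the whole image -----------------

shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

thin_zhang_suen <- function(mask, max_iter = 1000) {
  b <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  if (!any(b == 1L)) return(mask & FALSE)
  for (iter in seq_len(max_iter)) {
    changed <- FALSE
    for (phase in 1:2) {
      # neighbours clockwise from north: p2..p9
      p2 <- shift_mat(b,  1,  0)  # value of pixel above = shift down
      p3 <- shift_mat(b,  1, -1)
      p4 <- shift_mat(b,  0, -1)
      p5 <- shift_mat(b, -1, -1)
      p6 <- shift_mat(b, -1,  0)
      p7 <- shift_mat(b, -1,  1)
      p8 <- shift_mat(b,  0,  1)
      p9 <- shift_mat(b,  1,  1)
      bsum <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0L & p3 == 1L) + (p3 == 0L & p4 == 1L) +
           (p4 == 0L & p5 == 1L) + (p5 == 0L & p6 == 1L) +
           (p6 == 0L & p7 == 1L) + (p7 == 0L & p8 == 1L) +
           (p8 == 0L & p9 == 1L) + (p9 == 0L & p2 == 1L)
      if (phase == 1) {
        cond <- b == 1L & bsum >= 2 & bsum <= 6 & a == 1 &
          (p2 * p4 * p6 == 0L) & (p4 * p6 * p8 == 0L)
      } else {
        cond <- b == 1L & bsum >= 2 & bsum <= 6 & a == 1 &
          (p2 * p4 * p8 == 0L) & (p2 * p6 * p8 == 0L)
      }
      if (any(cond)) {
        b[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  b == 1L
}

# 8-neighbour count of a logical matrix
neighbor_count <- function(mask) {
  b <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  shift_mat(b, 1, 0) + shift_mat(b, -1, 0) + shift_mat(b, 0, 1) +
    shift_mat(b, 0, -1) + shift_mat(b, 1, 1) + shift_mat(b, 1, -1) +
    shift_mat(b, -1, 1) + shift_mat(b, -1, -1)
}

# Number of connected foreground runs around each pixel's 8-ring (the
# crossing number). A skeleton pixel with >= 3 runs is a true branch point;
# plain neighbour counting misfires on the staircase corners of thinned
# diagonal lines, which have 3 neighbours but only 2 runs.
ring_run_count <- function(mask) {
  b <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  p2 <- shift_mat(b,  1,  0); p3 <- shift_mat(b,  1, -1)
  p4 <- shift_mat(b,  0, -1); p5 <- shift_mat(b, -1, -1)
  p6 <- shift_mat(b, -1,  0); p7 <- shift_mat(b, -1,  1)
  p8 <- shift_mat(b,  0,  1); p9 <- shift_mat(b,  1,  1)
  (p2 == 0L & p3 == 1L) + (p3 == 0L & p4 == 1L) +
    (p4 == 0L & p5 == 1L) + (p5 == 0L & p6 == 1L) +
    (p6 == 0L & p7 == 1L) + (p7 == 0L & p8 == 1L) +
    (p8 == 0L & p9 == 1L) + (p9 == 0L & p2 == 1L)
}

#' A set of extracted line segments
#'
#' @param segments data frame with endpoint columns `r0, c0, r1, c1`
#'   (pixel coordinates, rows = image y) and `length_px`.
#' @param min_length_px the length floor the set was extracted with.
#' @return object of class `segment_set`.
#' @export
segment_set <- function(segments, min_length_px) {
  stopifnot(all(c("r0", "c0", "r1", "c1", "length_px") %in% names(segments)))
  short <- segments$length_px < min_length_px
  if (any(short)) {
    warning(sprintf("dropping %d segment(s) shorter than min_length_px = %g",
                    sum(short), min_length_px))
    segments <- segments[!short, , drop = FALSE]
  }
  structure(list(segments = tibble::as_tibble(segments),
                 min_length_px = min_length_px),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("<segment_set> %d segments (min length %g px)\n",
              nrow(x$segments), x$min_length_px))
  invisible(x)
}

#' Approximate a skeleton as straight line segments
#'
#' The skeleton is split at branch points (pixels with three or more
#' skeleton neighbours); each remaining arc is traced pixel by pixel and
#' recursively subdivided at the point of maximum perpendicular deviation
#' from its chord until every piece deviates by at most `max_deviation_px`.
#' Pieces shorter than `min_length_px` are discarded.
#'
#' @param skeleton logical matrix from [skeletonize()].
#' @param min_length_px minimum chord length in pixels to keep (default 10).
#' @param max_deviation_px maximum perpendicular deviation of the traced arc
#'   from its chord (default 2).
#' @return a [segment_set()]; empty skeleton gives an empty set.
#' @export
extract_segments <- function(skeleton, min_length_px = 10, max_deviation_px = 2) {
  stopifnot(is.logical(skeleton))
  assert_pos(min_length_px, "min_length_px")
  assert_pos(max_deviation_px, "max_deviation_px")
  empty <- tibble::tibble(r0 = numeric(), c0 = numeric(), r1 = numeric(),
                          c1 = numeric(), length_px = numeric())
  if (!any(skeleton)) return(segment_set(empty, min_length_px))

  branch <- skeleton & ring_run_count(skeleton) >= 3
  arcs <- skeleton & !branch
  paths <- trace_paths(arcs)

  segs <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    pts <- paths[[i]]
    verts <- rdp_split(pts, max_deviation_px)
    if (length(verts) < 2) next
    r0 <- pts[verts[-length(verts)], 1]; c0 <- pts[verts[-length(verts)], 2]
    r1 <- pts[verts[-1], 1]; c1 <- pts[verts[-1], 2]
    len <- sqrt((r1 - r0)^2 + (c1 - c0)^2)
    keep <- len >= min_length_px
    if (any(keep)) {
      segs[[i]] <- data.frame(r0 = r0[keep], c0 = c0[keep],
                              r1 = r1[keep], c1 = c1[keep],
                              length_px = len[keep])
    }
  }
  segs <- segs[!vapply(segs, is.null, logical(1))]
  if (length(segs) == 0) return(segment_set(empty, min_length_px))
  segment_set(do.call(rbind, segs), min_length_px)
}

# Trace one-pixel-wide arcs into ordered pixel paths. Walks from free ends
# first (degree-1 pixels), then mops up remaining pixels (cycles).
trace_paths <- function(arcs) {
  remaining <- arcs
  nbr <- neighbor_count(arcs)
  ends <- which(arcs & nbr == 1, arr.ind = TRUE)
  nr <- nrow(arcs); nc <- ncol(arcs)
  paths <- list()

  walk <- function(r, c) {
    path <- matrix(NA_real_, sum(remaining), 2)
    k <- 0L
    repeat {
      k <- k + 1L
      path[k, ] <- c(r, c)
      remaining[r, c] <<- FALSE
      rs <- max(1, r - 1):min(nr, r + 1)
      cs <- max(1, c - 1):min(nc, c + 1)
      win <- remaining[rs, cs, drop = FALSE]
      hit <- which(win, arr.ind = TRUE)
      if (nrow(hit) == 0) break
      # prefer 4-adjacent continuation to avoid corner-cutting
      dr <- rs[hit[, 1]] - r; dc <- cs[hit[, 2]] - c
      ord <- order(abs(dr) + abs(dc))
      r <- r + dr[ord[1]]; c <- c + dc[ord[1]]
    }
    path[seq_len(k), , drop = FALSE]
  }

  if (nrow(ends) > 0) {
    for (i in seq_len(nrow(ends))) {
      r <- ends[i, 1]; c <- ends[i, 2]
      if (remaining[r, c]) paths[[length(paths) + 1L]] <- walk(r, c)
    }
  }
  while (any(remaining)) {
    idx <- which(remaining, arr.ind = TRUE)[1, ]
    paths[[length(paths) + 1L]] <- walk(idx[1], idx[2])
  }
  paths[vapply(paths, nrow, integer(1)) >= 2]
}

# Ramer-Douglas-Peucker: indices of polyline vertices such that every point
# lies within eps of its chord.
rdp_split <- function(pts, eps) {
  n <- nrow(pts)
  if (n <= 2) return(seq_len(n))
  keep <- c(1L, n)
  stack <- list(c(1L, n))
  while (length(stack)) {
    rng <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- rng[1]; j <- rng[2]
    if (j - i < 2) next
    a <- pts[i, ]; b <- pts[j, ]
    ab <- b - a
    len <- sqrt(sum(ab^2))
    mid <- (i + 1):(j - 1)
    d <- if (len == 0) {
      sqrt((pts[mid, 1] - a[1])^2 + (pts[mid, 2] - a[2])^2)
    } else {
      abs(ab[2] * (pts[mid, 1] - a[1]) - ab[1] * (pts[mid, 2] - a[2])) / len
    }
    m <- which.max(d)
    if (d[m] > eps) {
      k <- mid[m]
      keep <- c(keep, k)
      stack[[length(stack) + 1L]] <- c(i, k)
      stack[[length(stack) + 1L]] <- c(k, j)
    }
  }
  sort(unique(keep))
}

#' Polar angles of extracted segments
#'
#' Angle of each segment measured from the radial (pial-normal) axis, folded
#' into \[0, 180) — a segment and its 180-degree rotation are the same
#' undirected line. With the default vertical radial axis, a vertical
#' segment scores 0 degrees and a horizontal one 90 degrees.
#'
#' @param segments a [segment_set()].
#' @param radial_axis `"vertical"` (default) or `"horizontal"`.
#' @param region_label,plane metadata forwarded to [orientation_sample()].
#' @return an [orientation_sample()]; zero-length segments are dropped with
#'   a warning.
#' @export
segment_polar_angles <- function(segments, radial_axis = c("vertical", "horizontal"),
                                 region_label = NA_character_,
                                 plane = "coronal") {
  radial_axis <- match.arg(radial_axis)
  stopifnot(inherits(segments, "segment_set"))
  s <- segments$segments
  if (nrow(s) == 0) return(orientation_sample(numeric(), region_label, plane))
  dx <- s$c1 - s$c0
  dy_up <- -(s$r1 - s$r0)  # image rows grow downward
  len <- s$length_px
  zero <- dx == 0 & dy_up == 0
  if (any(zero)) {
    warning(sprintf("dropping %d zero-length segment(s)", sum(zero)))
    dx <- dx[!zero]; dy_up <- dy_up[!zero]; len <- len[!zero]
  }
  ang <- rad2deg(atan2(dx, dy_up)) %% 180
  if (radial_axis == "horizontal") ang <- (ang + 90) %% 180
  orientation_sample(ang, region_label, plane, weights = len)
}

#' Run the full orientation pipeline on one image
#'
#' Convenience wrapper: threshold, skeletonize, extract segments, compute
#' polar angles, fit the axial von Mises distribution, and (optionally)
#' bootstrap the kappa confidence interval.
#'
#' @param image a [raster_image()] or numeric matrix.
#' @param min_length_px,max_deviation_px segment extraction controls.
#' @param polarity stain polarity.
#' @param n_boot bootstrap replicates (0 to skip the CI).
#' @param seed bootstrap seed.
#' @param region_label,plane metadata for the sample.
#' @return list with `skeleton`, `segments`, `sample`, `fit`.
#' @export
analyze_orientation <- function(image, min_length_px = 10, max_deviation_px = 2,
                                polarity = "dark", n_boot = 1000, seed = 1,
                                region_label = NA_character_, plane = "coronal") {
  radial <- if (inherits(image, "raster_image")) image$radial_axis else "vertical"
  sk <- skeletonize(image, polarity = polarity)
  segs <- extract_segments(sk, min_length_px, max_deviation_px)
  smp <- segment_polar_angles(segs, radial_axis = radial,
                              region_label = region_label, plane = plane)
  fit <- if (n_boot > 0) {
    bootstrap_kappa_ci(smp, n_boot = n_boot, seed = seed)
  } else {
    fit_von_mises(smp)
  }
  list(skeleton = sk, segments = segs, sample = smp, fit = fit)
}
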
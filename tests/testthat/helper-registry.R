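reg <- default_species_registry()

# draw a clean stroke of given axial angle (degrees from vertical) onto a
# light background; returns the image matrix
draw_stroke <- function(angle_deg, size = 200, len = 80, half_width = 1.5,
                        bg = 0.85, depth = 0.7, center = size / 2) {
  img <- matrix(bg, size, size)
  d <- c(-cos(angle_deg * pi / 180), sin(angle_deg * pi / 180))  # (dr, dc)
  gr <- matrix(seq_len(size), size, size)
  gc <- t(gr)
  dmat <- cortexclock:::dist_point_segment(
    gr, gc,
    center - len / 2 * d[1], center - len / 2 * d[2],
    center + len / 2 * d[1], center + len / 2 * d[2])
  pmin(pmax(img - pmin(pmax(half_width + 0.5 - dmat, 0), 1) * depth, 0), 1)
}

# rotate an image matrix 90 degrees counter-clockwise
rotate90 <- function(px) t(px)[rev(seq_len(ncol(px))), , drop = FALSE]
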
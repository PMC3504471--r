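# Skeletonization, segment extraction, polar angles.

test_that("blank and flat images yield empty skeletons and segment sets", {
  blank <- matrix(0.9, 50, 50)
  sk <- skeletonize(blank)
  expect_false(any(sk))
  segs <- extract_segments(sk)
  expect_equal(nrow(segs$segments), 0L)
  expect_equal(length(segment_polar_angles(segs)$angles_deg), 0L)
})

test_that("a drawn bar thins to a skeleton close to its true length", {
  img <- draw_stroke(0, size = 200, len = 100, half_width = 2.5)
  sk <- skeletonize(img)
  # 5-px-wide bar of length 100: skeleton length within 10%
  expect_gt(sum(sk), 90)
  expect_lt(sum(sk), 110)
  # thinned to a simple arc: no true branch points remain
  expect_false(any(sk & cortexclock:::ring_run_count(sk) >= 3))
})

test_that("contrast polarity flag reproduces the same skeleton", {
  img <- draw_stroke(30, size = 150, len = 70)
  sk_dark <- skeletonize(img, polarity = "dark")
  sk_light <- skeletonize(1 - img, polarity = "light")
  expect_identical(sk_dark, sk_light)
})

test_that("single strokes recover their drawn orientation within 2 degrees", {
  for (ang in c(0, 10, 30, 45, 60, 90, 120, 150, 170)) {
    img <- draw_stroke(ang, size = 200, len = 80)
    segs <- extract_segments(skeletonize(img))
    smp <- segment_polar_angles(segs)
    expect_gte(length(smp$angles_deg), 1)
    # axial distance to the drawn angle
    d <- abs(smp$angles_deg - ang)
    expect_lt(min(d, 180 - d), 2)
  }
})

test_that("crossing strokes split into segments recovering both angles", {
  img <- pmin(draw_stroke(20, size = 200, len = 120),
              draw_stroke(110, size = 200, len = 120))
  segs <- extract_segments(skeletonize(img))
  smp <- segment_polar_angles(segs)
  expect_gte(nrow(segs$segments), 2)
  near <- function(target) any(pmin(abs(smp$angles_deg - target),
                                    180 - abs(smp$angles_deg - target)) < 5)
  expect_true(near(20))
  expect_true(near(110))
})

test_that("polar angles fold axially and honour the radial axis declaration", {
  seg <- function(r0, c0, r1, c1) {
    segment_set(data.frame(r0 = r0, c0 = c0, r1 = r1, c1 = c1,
                           length_px = sqrt((r1 - r0)^2 + (c1 - c0)^2)),
                min_length_px = 1)
  }
  # vertical segment: 0 from vertical radial axis, 90 from horizontal
  expect_equal(segment_polar_angles(seg(10, 5, 40, 5))$angles_deg, 0)
  expect_equal(segment_polar_angles(seg(10, 5, 40, 5),
                                    radial_axis = "horizontal")$angles_deg, 90)
  expect_equal(segment_polar_angles(seg(10, 5, 10, 40))$angles_deg, 90)
  # reversing endpoints (theta + 180) folds to the same axial angle
  expect_equal(segment_polar_angles(seg(40, 5, 10, 5))$angles_deg, 0)
  a1 <- segment_polar_angles(seg(10, 10, 30, 40))$angles_deg
  a2 <- segment_polar_angles(seg(30, 40, 10, 10))$angles_deg
  expect_equal(a1, a2)
  # zero-length (degenerate) segments are dropped on construction
  expect_warning(empty <- seg(5, 5, 5, 5), "shorter than min_length")
  expect_equal(length(segment_polar_angles(empty)$angles_deg), 0L)
})

test_that("short segments are excluded by the length floor", {
  img <- draw_stroke(0, size = 120, len = 60)
  sk <- skeletonize(img)
  expect_equal(nrow(extract_segments(sk, min_length_px = 200)$segments), 0L)
  expect_gt(nrow(extract_segments(sk, min_length_px = 10)$segments), 0L)
  expect_true(all(extract_segments(sk, min_length_px = 25)$segments$length_px >= 25))
})

test_that("images round-trip through TIFF and PNG with metadata sidecars", {
  img <- raster_image(draw_stroke(45, size = 64, len = 30),
                      radial_axis = "horizontal")
  for (ext in c(".tif", ".png")) {
    path <- tempfile(fileext = ext)
    write_raster_image(img, path)
    yaml::write_yaml(list(region_label = "V1", plane = "coronal",
                          radial_axis = "horizontal", pixel_size = 0.65),
                     paste0(path, ".yaml"))
    back <- read_raster_image(path)
    expect_equal(dim(back$pixels), dim(img$pixels))
    expect_equal(back$pixels, img$pixels, tolerance = 1 / 255)
    expect_equal(back$radial_axis, "horizontal")
    expect_equal(attr(back, "region_label"), "V1")
    unlink(c(path, paste0(path, ".yaml")))
  }
})

test_that("rotating an image by 90 degrees shifts mu by 90 and preserves kappa", {
  sim <- gen_golgi_image(golgi_sim_spec(image_size = 512, n_segments = 250,
                                        mu_deg = 0, kappa = 3, seed = 21))
  a <- analyze_orientation(sim$image, n_boot = 0)
  rot <- raster_image(rotate90(sim$image$pixels))
  b <- analyze_orientation(rot, n_boot = 0)
  dmu <- abs(((b$fit$mu_deg - a$fit$mu_deg) %% 180) - 90)
  expect_lt(min(dmu, 180 - dmu), 6)
  expect_lt(abs(b$fit$kappa - a$fit$kappa) / a$fit$kappa, 0.25)
})
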
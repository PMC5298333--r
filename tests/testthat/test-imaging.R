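test_that("pixel size and sampling volumes match the protocol constants", {
  expect_equal(pixel_size_from_dpi(2400), 25400 / 2400)
  expect_equal(round(pixel_size_from_dpi(2400), 1), 10.6)
  expect_equal(pixel_size_from_dpi(25400), 1.0)
  expect_equal(pixel_size_from_dpi(1200), 21.17, tolerance = 1e-3)
  expect_error(pixel_size_from_dpi(0), "positive")

  g <- sampling_geometry()
  expect_equal(tow_volume(g), pi * 0.085^2 * 17 * 1000)
  expect_equal(tow_volume(g), 385.9, tolerance = 1e-3)
  expect_equal(effective_subsample_volume(g), tow_volume(g) * 0.04)
  expect_equal(effective_subsample_volume(g), 15.4, tolerance = 5e-3)

  expect_equal(tow_volume(sampling_geometry(0.2, 10)), 314.2,
               tolerance = 1e-3)
  expect_error(sampling_geometry(tow_depth_m = 0), "positive")
  g50 <- sampling_geometry(subsample_volume_ml = 50)
  expect_equal(effective_subsample_volume(g50), 38.6, tolerance = 5e-3)
  full <- sampling_geometry(subsample_volume_ml = 500)
  expect_equal(effective_subsample_volume(full), tow_volume(full))
  expect_error(sampling_geometry(subsample_volume_ml = 600), "exceed")
})

test_that("rendered disks segment back to their count and area", {
  ps <- pixel_size_from_dpi(2400)
  # blank plate
  blank <- render_scan_plate(NULL, 200, 200)
  expect_length(segment_scan(blank, 128)$masks, 0)

  # one disk of radius 50 px: area within a 1-pixel perimeter ring of
  # pi * 50^2, ESD close to 100 px * pixel size
  disk <- data.frame(x_px = 150, y_px = 150,
                     major_um = 100 * ps, minor_um = 100 * ps)
  img <- render_scan_plate(disk, 300, 300)
  seg <- segment_scan(img, 128)
  expect_length(seg$masks, 1)
  area <- nrow(seg$masks[[1]])
  ring <- 2 * pi * 50 + 4
  expect_lt(abs(area - pi * 50^2), ring)
  m <- measure_object(seg$masks[[1]], ps)
  expect_equal(m$esd_um, 100 * ps, tolerance = 0.01)
  expect_false(seg$border[1])

  # three disjoint disks -> exactly three components, any threshold
  three <- data.frame(x_px = c(60, 150, 240), y_px = c(60, 150, 60),
                      major_um = 60 * ps, minor_um = 60 * ps)
  img3 <- render_scan_plate(three, 300, 300)
  for (thr in c(61, 128, 229))
    expect_length(segment_scan(img3, thr)$masks, 3)

  # two disks separated by a few pixels stay two components
  two <- data.frame(x_px = c(100, 147), y_px = c(100, 100),
                    major_um = 40 * ps, minor_um = 40 * ps)
  expect_length(segment_scan(render_scan_plate(two, 250, 250), 128)$masks, 2)
})

test_that("segmentation uses 8-connectivity and respects filters", {
  # two solid squares touching only at one diagonal corner: one component
  img <- matrix(255L, 40, 40)
  img[5:10, 5:10] <- 0L
  img[11:16, 11:16] <- 0L
  seg <- segment_scan(structure(img, dpi = 2400), 128, min_area_px = 1)
  expect_length(seg$masks, 1)

  # the minimum-area filter removes specks and counts them
  img[30, 30] <- 0L
  seg2 <- segment_scan(structure(img, dpi = 2400), 128, min_area_px = 4)
  expect_length(seg2$masks, 1)
  expect_equal(seg2$n_discarded_small, 1L)

  # border-touching components are flagged
  img3 <- matrix(255L, 20, 20)
  img3[1:4, 8:12] <- 0L
  expect_true(segment_scan(structure(img3, dpi = 2400), 128,
                           min_area_px = 1)$border[1])

  # an all-dark plate is implausible
  expect_error(segment_scan(matrix(0L, 10, 10), 128), "implausible")
})

test_that("morphometry matches analytic fixtures", {
  ps <- 10.6
  # sphere: equivalent-ellipse axes agree with the area-equivalent diameter
  disk <- data.frame(x_px = 120, y_px = 120, major_um = 100 * 10.5833333,
                     minor_um = 100 * 10.5833333)
  img <- render_scan_plate(disk, 240, 240, dpi = 2400)
  seg <- segment_scan(img, 128)
  m <- measure_object(seg$masks[[1]], pixel_size_from_dpi(2400))
  expect_equal(m$major_um / m$minor_um, 1, tolerance = 0.02)
  expect_equal(m$major_um, m$esd_um, tolerance = 0.02 * m$esd_um)
  expect_equal(m$biovolume_mm3, (pi / 6) * 1.0583333^3, tolerance = 0.03)

  # 2:1 ellipse: axis ratio recovered within 2 %
  ell <- data.frame(x_px = 150, y_px = 150, major_um = 160 * ps,
                    minor_um = 80 * ps, orientation_rad = 0.4)
  seg2 <- segment_scan(render_scan_plate(ell, 300, 300), 128)
  m2 <- measure_object(seg2$masks[[1]], ps)
  expect_equal(m2$major_um / m2$minor_um, 2, tolerance = 0.02)

  # single pixel
  m1 <- measure_object(cbind(5L, 7L), 10.6)
  expect_equal(m1$esd_um, 2 * sqrt(10.6^2 / pi), tolerance = 1e-9)
  expect_error(measure_object(cbind(1L, 1L)[0, , drop = FALSE], 10.6),
               "empty")
})

test_that("overlapping or off-canvas objects are rejected by the renderer", {
  ps <- pixel_size_from_dpi(2400)
  ov <- data.frame(x_px = c(100, 110), y_px = c(100, 100),
                   major_um = 40 * ps, minor_um = 40 * ps)
  expect_error(render_scan_plate(ov, 200, 200), "overlap")
  off <- data.frame(x_px = 5, y_px = 100, major_um = 40 * ps,
                    minor_um = 40 * ps)
  expect_error(render_scan_plate(off, 200, 200), "canvas")
  expect_error(render_scan_plate(NULL, 10, 10, background_grey = 60,
                                 particle_grey = 60), "differ")
})

test_that("size filter, disturbance removal and copepod classes", {
  obj <- make_particles(c(140, 160, 500, 800, 1200))
  obj$category <- c("copepod", "disturbance", "copepod", "copepod",
                    "other_biomass")

  f <- apply_min_size_filter(obj)
  expect_equal(f$esd_um, c(160, 500, 800, 1200))
  expect_equal(attr(f, "n_removed_small"), 1L)
  expect_equal(nrow(apply_min_size_filter(obj[0, ])), 0)
  all_small <- apply_min_size_filter(make_particles(c(10, 20)))
  expect_equal(nrow(all_small), 0)
  expect_equal(attr(all_small, "n_removed_small"), 2L)

  d <- remove_disturbances(f)
  expect_equal(nrow(d), 3)
  expect_equal(attr(d, "n_removed_disturbance"), 1L)
  expect_setequal(d$category, c("copepod", "other_biomass"))
  alld <- obj; alld$category <- "disturbance"
  expect_equal(nrow(remove_disturbances(alld)), 0)
  bad <- obj; bad$category[2] <- NA
  expect_error(remove_disturbances(bad), "[Uu]nlabelled")

  expect_equal(as.character(assign_copepod_class(c(500, 800, 1200))),
               c("S", "M", "L"))
  expect_equal(as.character(assign_copepod_class(600)), "M")
  expect_equal(as.character(assign_copepod_class(1000)), "L")
  expect_error(assign_copepod_class(100), "minimum")
  # total and exclusive on the classifiable range
  cls <- assign_copepod_class(seq(150, 3000, by = 7))
  expect_false(anyNA(cls))
})

test_that("object-to-particle scaling is homogeneous in volume", {
  obj <- make_particles(rep(400, 77))
  obj$category <- "copepod"
  p <- objects_to_particles(obj, 15.4)
  expect_equal(sum(p$weight_l), 5.0)
  expect_equal(p$weight_l[1], 1 / 15.4)
  expect_equal(nrow(objects_to_particles(obj[0, ], 15.4)), 0)
  # degree -1 homogeneity
  p2 <- objects_to_particles(obj, 30.8)
  expect_equal(sum(p2$weight_l), sum(p$weight_l) / 2)
  expect_error(objects_to_particles(obj, 0), "positive")
})

test_that("scan images and object tables round-trip through disk", {
  ps <- pixel_size_from_dpi(2400)
  disk <- data.frame(x_px = 60, y_px = 60, major_um = 40 * ps,
                     minor_um = 40 * ps)
  img <- render_scan_plate(disk, 120, 120)
  path <- withr::local_tempfile(fileext = ".png")
  write_scan(img, path)
  back <- read_scan(path)
  expect_equal(unclass(back)[, ], unclass(img)[, ])
  expect_equal(attr(back, "dpi"), 2400)

  obj <- measure_scan(img, 128)
  obj$category <- "copepod"
  obj$extra_feature <- 42
  tpath <- withr::local_tempfile(fileext = ".tsv")
  write_objects(obj, tpath)
  back2 <- read_objects(tpath)
  expect_equal(back2$esd_um, obj$esd_um, tolerance = 1e-9)
  expect_equal(back2$extra_feature, obj$extra_feature)
})
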
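test_that("tree generation is a pure function of parameters and seed", {
  p <- test_tree_params()
  t1 <- generate_vascular_tree(p, test_disc(), test_fovea(), seed = 7)
  t2 <- generate_vascular_tree(p, test_disc(), test_fovea(), seed = 7)
  expect_identical(t1$points, t2$points)
  expect_identical(t1$segments, t2$segments)
  t3 <- generate_vascular_tree(p, test_disc(), test_fovea(), seed = 8)
  expect_false(identical(t1$points, t3$points))
})

test_that("zero taper gives constant width along every segment", {
  p <- test_tree_params(taper_rate = 0)
  tr <- generate_vascular_tree(p, test_disc(), test_fovea(), seed = 3)
  for (pts in split(tr$points, tr$points$segment))
    expect_equal(diff(range(pts$width_um)), 0)
})

test_that("higher branch probability produces more segments", {
  n_seg <- function(bp) vapply(1:10, function(s)
    nrow(generate_vascular_tree(test_tree_params(branch_prob = bp),
                                test_disc(), test_fovea(),
                                seed = s)$segments), numeric(1))
  expect_gt(mean(n_seg(0.9)), mean(n_seg(0.1)))
})

test_that("width is non-increasing along root-to-tip paths when tapering", {
  tr <- generate_vascular_tree(test_tree_params(taper_rate = -3),
                               test_disc(), test_fovea(), seed = 5)
  # within a segment: strictly governed by the taper
  for (pts in split(tr$points, tr$points$segment))
    expect_true(all(diff(pts$width_um) <= 1e-9))
  # across a bifurcation: child width never exceeds the parent width there
  for (i in which(!is.na(tr$segments$parent))) {
    child <- tr$points[tr$points$segment == tr$segments$segment[i], ]
    parent <- tr$points[tr$points$segment == tr$segments$parent[i], ]
    s0 <- child$s_mm[1]
    w_parent <- approx(parent$s_mm, parent$width_um, s0, rule = 2)$y
    expect_lte(child$width_um[1], w_parent + 1e-9)
  }
})

test_that("degenerate geometry is rejected", {
  expect_error(
    generate_vascular_tree(test_tree_params(field_radius = 0.3),
                           test_disc(), test_fovea(), seed = 1),
    "field_radius")
  expect_error(tree_params(branch_prob = 1.5), "branch_prob")
  expect_error(tree_params(initial_width = 0), "initial_width")
})

test_that("rasterized stroke thickness matches the stamped width", {
  # a single straight horizontal segment of constant width 11 px
  scale <- 15
  w_um <- 11 * scale
  pts <- data.frame(segment = 1L, x_mm = seq(0.8, 3.2, by = 0.05),
                    y_mm = 2, width_um = w_um)
  pts$s_mm <- pts$x_mm - pts$x_mm[1]
  tr <- structure(list(points = pts,
                       segments = data.frame(segment = 1L, parent = NA,
                                             class = "arteriole", depth = 0L),
                       disc = list(center = c(0.5, 2), diameter_mm = 0.4),
                       fovea = c(0.1, 2), laterality = "right",
                       eye_id = "stroke", participant_id = "p", group = "NC",
                       params = test_tree_params(), seed = 1L),
                  class = "eye_truth")
  ras <- rasterize_eye(tr, 280, scale, render_image = FALSE)
  mid_cols <- round(mm_to_px(seq(1.5, 2.5, by = 0.1), scale))
  thick <- colSums(ras$mask)[mid_cols]   # column-wise foreground count
  expect_true(all(abs(thick - 11) <= 1))
})

test_that("occluders corrupt the rendered image but never the truth mask", {
  tr <- generate_vascular_tree(test_tree_params(), test_disc(), test_fovea(),
                               seed = 2)
  clean <- rasterize_eye(tr, 700, 12, artifact = NULL, seed = 99)
  occl <- rasterize_eye(tr, 700, 12,
                        artifact = list(eyelid_frac = 0.1, eyelash_n = 0),
                        seed = 99)
  expect_identical(clean$mask, occl$mask)
  lower <- 110:700   # below the eyelid band (10% of 700 rows + wave margin)
  expect_equal(clean$image[lower, ], occl$image[lower, ])
  expect_gt(mean(abs(clean$image[1:60, ] - occl$image[1:60, ])), 0.1)
})

test_that("truth extending beyond the canvas is rejected with the segment", {
  tr <- generate_vascular_tree(test_tree_params(), test_disc(), test_fovea(),
                               seed = 2)
  expect_error(rasterize_eye(tr, 300, 12), "segment")
})

test_that("fractal fixtures carry their analytic dimensions", {
  expect_equal(generate_fractal_fixture("line", size = 256)$dimension, 1)
  expect_equal(generate_fractal_fixture("filled_disk", size = 256)$dimension,
               2)
  expect_equal(
    generate_fractal_fixture("sierpinski_triangle", 5, 256)$dimension,
    log(3) / log(2))
  expect_equal(generate_fractal_fixture("koch_curve", 4, 256)$dimension,
               log(4) / log(3))
  expect_error(generate_fractal_fixture("line", size = 128), "size")
  expect_error(generate_fractal_fixture("sierpinski_triangle", size = 256),
               "depth")
  expect_error(generate_fractal_fixture("pentaflake", size = 256))
})

test_that("cohort generation writes the documented on-disk layout", {
  spec <- cohort_spec(n_per_group = c(AD = 2, MCI = 2, NC = 2),
                      baseline = test_tree_params(),
                      size_px = 500, scale_um_px = 16,
                      disc_offset_mm = 0.9, fovea_dist_mm = 2.2,
                      disc_diameter_mm = 0.8, seed = 4)
  td <- file.path(tempdir(), "cohort_layout")
  unlink(td, recursive = TRUE)
  res <- generate_cohort(spec, td, write_images = FALSE)
  expect_equal(nrow(res$participants), 6)
  eyes <- list.dirs(file.path(td, "eyes"), recursive = FALSE)
  expect_length(eyes, 12)
  expect_true(all(file.exists(file.path(eyes, "mask.png"))))
  expect_true(all(file.exists(file.path(eyes, "annotation.geojson"))))
  expect_true(file.exists(file.path(td, "participants.csv")))
  expect_true(file.exists(file.path(td, "truth.json")))
  # refusing to clobber an existing dataset
  expect_error(generate_cohort(spec, td), "not empty")
})

test_that("zero between/within-eye SD gives identical eyes per participant", {
  spec <- cohort_spec(n_per_group = c(AD = 2, MCI = 2, NC = 2),
                      between_eye_sd = c(taper_rate = 0, branch_prob = 0,
                                         sinuosity_amplitude = 0),
                      eye_sd = c(taper_rate = 0, branch_prob = 0,
                                 sinuosity_amplitude = 0),
                      seed = 5)
  pars <- simulate_cohort_params(spec)
  for (pid in unique(pars$participant_id)) {
    two <- pars[pars$participant_id == pid, ]
    expect_equal(two$taper_rate[1], two$taper_rate[2])
    expect_equal(two$sinuosity_amplitude[1], two$sinuosity_amplitude[2])
  }
})

test_that("cohort truth conserves the injected group offsets", {
  spec <- cohort_spec(n_per_group = c(AD = 30, MCI = 30, NC = 30),
                      effects = list(
                        AD = c(taper_rate = -0.7, branch_prob = 0,
                               sinuosity_amplitude = 0),
                        MCI = c(taper_rate = -0.6, branch_prob = 0,
                                sinuosity_amplitude = 0)),
                      seed = 1)
  pars <- simulate_cohort_params(spec)
  mt <- tapply(pars$taper_rate, pars$group, mean)
  expect_lt(abs((mt[["AD"]] - mt[["NC"]]) - (-0.7)), 0.2)
  expect_lt(abs((mt[["MCI"]] - mt[["NC"]]) - (-0.6)), 0.2)
})
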
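# Shared synthetic fixtures, built in code at test time.

# Compact eye geometry for unit tests: 700 px at 12 um/px (8.4 mm canvas),
# field radius 2.8 mm. Faster than the cohort default, same pipeline.
test_disc <- function() list(center = c(5.2, 4.2), diameter_mm = 0.8)
test_fovea <- function() c(2.4, 4.2)

test_tree_params <- function(...) {
  args <- utils::modifyList(list(field_radius = 2.8, branch_len_mm = 1.6),
                            list(...))
  do.call(tree_params, args)
}

make_test_eye <- function(seed = 1, size_px = 700, scale_um_px = 12, ...) {
  tr <- generate_vascular_tree(test_tree_params(...), test_disc(),
                               test_fovea(), seed = seed)
  ras <- rasterize_eye(tr, size_px, scale_um_px, render_image = FALSE)
  list(truth = tr, raster = ras,
       quadrants = quadrant_partition(test_disc()$center, test_fovea(),
                                      dim(ras$mask), scale_um_px),
       scale_um_px = scale_um_px)
}

make_test_graph <- function(eye) {
  vm <- vessel_mask(eye$raster$mask, eye$scale_um_px, "test_eye")
  g <- skeletonize_and_graph(vm, class_map = eye$raster$class_map)
  g$edges <- Filter(function(e) !is.na(e$class), g$edges)
  g
}

# axis-aligned stroke mask of a given thickness (px), horizontal
make_stroke <- function(thickness_px, length_px = 200, size = 260,
                        row = NULL) {
  m <- matrix(FALSE, size, size)
  row <- row %||% round(size / 2)
  half <- (thickness_px - 1) / 2
  rows <- (row - floor(half)):(row + ceiling(half))
  cols <- 31:(30 + length_px)
  m[rows, cols] <- TRUE
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small two-group clustered table for GEE simulations: two eyes per
# participant, participant random effect + eye noise (equal variances give
# within-cluster correlation 0.5)
sim_gee_table <- function(beta, n_per_group = 30, seed = 1,
                          sd_participant = sqrt(0.5), sd_eye = sqrt(0.5)) {
  with_seed <- function(s, expr) { set.seed(s); expr }
  with_seed(seed, {
    rows <- list()
    for (g in c("AD", "NC")) for (i in seq_len(n_per_group)) {
      id <- paste0(g, i)
      b <- rnorm(1, 0, sd_participant)
      age <- rnorm(1, 70, 6)
      sex <- sample(c("F", "M"), 1)
      for (e in 1:2)
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = id, group = g, age = age, sex = sex,
          y = ifelse(g == "AD", beta, 0) + 0.02 * age + b +
            rnorm(1, 0, sd_eye), stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}
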
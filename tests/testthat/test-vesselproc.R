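test_that("segmentation recovers a high-contrast stroke and handles blanks", {
  img <- matrix(0.85, 260, 260)
  stroke <- make_stroke(7)
  img[stroke] <- 0.25
  vm <- segment_vessels(img, scale_um_px = 15)
  expect_gt(sum(vm$mask & stroke) / sum(stroke), 0.9)

  expect_warning(empty <- segment_vessels(matrix(0.5, 100, 100)), "empty")
  expect_equal(sum(empty$mask), 0)
})

test_that("segmentation of a clean synthetic eye overlaps the truth mask", {
  tr <- generate_vascular_tree(test_tree_params(), test_disc(), test_fovea(),
                               seed = 11)
  ras <- rasterize_eye(tr, 700, 12, artifact = NULL, noise_sd = 0.02)
  vm <- segment_vessels(ras$image, scale_um_px = 12)
  dice <- 2 * sum(vm$mask & ras$mask) / (sum(vm$mask) + sum(ras$mask))
  expect_gte(dice, 0.75)
})

test_that("skeleton graph topology of canonical shapes", {
  # straight stroke: 2 endpoints, 0 junctions
  vm <- vessel_mask(make_stroke(7), 15)
  g <- skeletonize_and_graph(vm, spur_prune_len_mm = 0)
  expect_equal(sum(g$nodes$kind == "endpoint"), 2)
  expect_equal(sum(g$nodes$kind == "junction"), 0)
  expect_length(g$edges, 1)

  # Y bifurcation: 1 junction, 3 endpoints
  m <- matrix(FALSE, 200, 260)
  m[100, 40:160] <- TRUE
  for (t in 0:60) {
    m[100 - t, 160 + round(0.8 * t)] <- TRUE
    m[100 + t, 160 + round(0.8 * t)] <- TRUE
  }
  m <- EBImage::dilate(m, EBImage::makeBrush(5, "disc")) > 0
  g2 <- skeletonize_and_graph(vessel_mask(m, 15), spur_prune_len_mm = 0)
  expect_equal(sum(g2$nodes$kind == "junction"), 1)
  expect_equal(sum(g2$nodes$kind == "endpoint"), 3)

  # empty mask: empty graph, no error
  g3 <- skeletonize_and_graph(vessel_mask(matrix(FALSE, 50, 50), 15))
  expect_length(g3$edges, 0)
  expect_equal(nrow(g3$nodes), 0)
})

test_that("short spurs are pruned and pass-through junctions merged", {
  m <- make_stroke(7, length_px = 160, size = 240)
  m[114:116, 110] <- TRUE   # 3 px spur off the stroke
  m[111:113, 111] <- TRUE
  g <- skeletonize_and_graph(vessel_mask(m, 15), spur_prune_len_mm = 0.5)
  expect_lte(sum(g$nodes$kind == "junction"), 1)
  expect_length(g$edges, 1)   # spur removed, stroke re-merged
  # without pruning the spur persists
  g0 <- skeletonize_and_graph(vessel_mask(m, 15), spur_prune_len_mm = 0)
  expect_gte(length(g0$edges), 2)
})

test_that("skeleton stays inside the mask and edges cover it", {
  eye <- make_test_eye(seed = 4)
  g <- make_test_graph(eye)
  expect_true(all(eye$raster$mask[g$skeleton]))
  covered <- matrix(FALSE, nrow(g$skeleton), ncol(g$skeleton))
  for (e in g$edges) covered[e$chain] <- TRUE
  expect_true(all(covered[g$skeleton]))
})

test_that("widths follow the distance-transform contract", {
  scale <- 15
  m <- make_stroke(11)
  chain <- cbind(130, 60:200)   # centerline of the stroke
  w <- measure_widths(m, chain, scale_um_px = scale)
  mid <- 30:110
  # oracle: column-wise foreground count x scale = 165 um
  expect_true(all(abs(w[mid] - 165) <= 15))

  # one-pixel line: EDT is 1 px everywhere on the line
  m1 <- matrix(FALSE, 60, 60); m1[30, 10:50] <- TRUE
  w1 <- measure_widths(m1, cbind(30, 15:45), scale_um_px = scale)
  expect_true(all(w1 == w1[1]))
  expect_equal(unname(w1[1]), 2 * 1 * scale)

  expect_error(measure_widths(m1, cbind(1, 1), scale_um_px = scale),
               "outside")
})

test_that("a linearly tapering stroke yields non-increasing widths", {
  m <- matrix(FALSE, 200, 340)
  for (col in 20:320) {
    half <- (12 - 8 * (col - 20) / 300) / 2
    m[(100 - ceiling(half)):(100 + ceiling(half)), col] <- TRUE
  }
  w <- measure_widths(m, cbind(100, 40:300), half_window = 15,
                      scale_um_px = 15)
  expect_true(all(diff(w) <= 15 + 1e-9))  # never increases past one EDT step
  expect_lt(w[length(w)], w[1])
})

test_that("width measurement is local to the mask around the chain", {
  m <- make_stroke(9)
  chain <- cbind(130, 60:200)
  w0 <- measure_widths(m, chain, scale_um_px = 15)
  m2 <- m
  m2[10:20, 10:20] <- TRUE      # edit far from the chain
  w1 <- measure_widths(m2, chain, scale_um_px = 15)
  expect_identical(w0, w1)
})

test_that("quadrant path selection follows score and tie-break rules", {
  eye <- make_test_eye(seed = 4)
  g <- make_test_graph(eye)
  paths <- select_quadrant_paths(g, eye$quadrants, test_disc())
  expect_gt(length(paths), 0)
  for (key in names(paths)) {
    p <- paths[[key]]
    qc <- strsplit(key, "_")[[1]]
    expect_equal(p$quadrant, qc[1])
    expect_equal(p$class, qc[2])
    expect_true(all(diff(p$points$s_mm) > 0))
    expect_true(all(p$points$width_um > 0))
  }
  # unlabeled edges are an error naming ids
  g_bad <- g
  g_bad$edges[[1]]$class <- NA_character_
  expect_error(select_quadrant_paths(g_bad, eye$quadrants, test_disc()),
               "unlabeled")
})

test_that("path selection is invariant to edge enumeration order", {
  eye <- make_test_eye(seed = 6)
  g <- make_test_graph(eye)
  p1 <- select_quadrant_paths(g, eye$quadrants, test_disc())
  g2 <- g
  set.seed(99)
  g2$edges <- g2$edges[sample(seq_along(g2$edges))]
  p2 <- select_quadrant_paths(g2, eye$quadrants, test_disc())
  expect_setequal(names(p1), names(p2))
  for (key in names(p1))
    expect_equal(p1[[key]]$points, p2[[key]]$points)
})

test_that("the dominant chain wins within a quadrant", {
  # two parallel same-class strokes in one quadrant; the longer one wins
  m <- matrix(FALSE, 300, 300)
  m[146:152, 30:280] <- TRUE     # long
  m[158:164, 30:150] <- TRUE     # short, same quadrant
  cm <- matrix(0L, 300, 300); cm[m] <- 1L
  vm <- vessel_mask(m, 15)
  g <- skeletonize_and_graph(vm, class_map = cm)
  q <- matrix("IT", 300, 300)
  disc <- list(center = c(px_to_mm(20, 15), px_to_mm(149, 15)),
               diameter_mm = 0.5)
  paths <- select_quadrant_paths(g, q, disc)
  expect_length(paths, 1)
  expect_gt(paths[["IT_arteriole"]]$length_mm, 3)
  expect_equal(unique(paths[["IT_arteriole"]]$chain[, 1]), 149)
})

test_that("selected paths track the dominant truth path per quadrant", {
  eye <- make_test_eye(seed = 9)
  g <- make_test_graph(eye)
  paths <- select_quadrant_paths(g, eye$quadrants, test_disc())
  tr <- eye$truth
  trunk_ids <- tr$segments$segment[tr$segments$depth == 0]
  checked <- 0
  for (p in paths) {
    if (p$length_mm < 2) next
    # oracle: exhaustive score of truth trunks in this quadrant and class
    cand <- trunk_ids[tr$segments$class[match(trunk_ids,
                                              tr$segments$segment)] ==
                        p$class]
    scores <- vapply(cand, function(sg) {
      pt <- tr$points[tr$points$segment == sg, ]
      qlab <- eye$quadrants[cbind(round(mm_to_px(pt$y_mm, 12)),
                                  round(mm_to_px(pt$x_mm, 12)))]
      if (mean(qlab == p$quadrant) < 0.5) return(-Inf)
      max(pt$s_mm) * mean(pt$width_um)
    }, numeric(1))
    if (!any(is.finite(scores))) next
    best <- cand[which.max(scores)]
    pt <- tr$points[tr$points$segment == best, ]
    near <- vapply(seq_len(nrow(p$points)), function(i)
      min((pt$x_mm - p$points$x_mm[i])^2 +
            (pt$y_mm - p$points$y_mm[i])^2) < 0.08^2, logical(1))
    expect_gte(mean(near), 0.8)
    checked <- checked + 1
  }
  expect_gte(checked, 3)
})

test_that("mask edits from GeoJSON erase and fill", {
  m <- make_stroke(9)
  vm <- vessel_mask(m, 15)
  ed <- list(type = "FeatureCollection", features = list(
    list(type = "Feature", properties = list(action = "erase"),
         geometry = list(type = "Polygon", coordinates = list(list(
           c(1.0, 1.8), c(2.0, 1.8), c(2.0, 2.1), c(1.0, 2.1),
           c(1.0, 1.8)))))))
  tf <- tempfile(fileext = ".geojson")
  jsonlite::write_json(ed, tf, auto_unbox = TRUE, digits = NA)
  vm2 <- apply_mask_edits(vm, tf)
  expect_lt(sum(vm2$mask), sum(vm$mask))
})
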
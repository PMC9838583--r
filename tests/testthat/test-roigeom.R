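test_that("standardized ROI is the per-laterality intersection", {
  m1 <- matrix(FALSE, 20, 20); m1[3:18, 3:18] <- TRUE
  m2 <- matrix(FALSE, 20, 20); m2[6:20, 1:15] <- TRUE
  inner <- matrix(FALSE, 20, 20); inner[8:12, 8:12] <- TRUE

  expect_equal(standardized_roi(list(m1)), m1, ignore_attr = TRUE) # identity
  expect_equal(sum(standardized_roi(list(m1, inner))), sum(inner)) # nested
  got <- standardized_roi(list(m1, m2))
  expect_equal(unname(which(got)), which(m1 & m2))

  disjoint <- matrix(FALSE, 20, 20); disjoint[1:2, 1:2] <- TRUE
  expect_warning(empty <- standardized_roi(list(m1, disjoint)), "empty")
  expect_equal(sum(empty), 0)

  expect_error(standardized_roi(list(m1, matrix(TRUE, 5, 5))), "dimension")
})

test_that("adding a mask to the intersection never grows it", {
  set.seed(1)
  masks <- lapply(1:5, function(i) {
    m <- matrix(FALSE, 30, 30)
    r <- sort(sample(30, 2)); c <- sort(sample(30, 2))
    m[r[1]:r[2], c[1]:c[2]] <- TRUE
    m
  })
  sizes <- vapply(seq_along(masks), function(k)
    sum(suppressWarnings(standardized_roi(masks[1:k]))), numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("posterior annulus matches the analytic area and conventions", {
  # unclipped annulus: d = 1.8 mm, k = 3, canvas 13.2 mm at 20 um/px
  d <- 1.8; k <- 3; scale <- 20
  dim <- c(660, 660)
  ctr <- c(6.6, 6.6)
  ann <- posterior_annulus(ctr, d, k, dim, scale)
  area_mm2 <- sum(ann) * (scale / 1000)^2
  analytic <- pi * ((d / 2 + k * d)^2 - (d / 2)^2)
  expect_lt(abs(area_mm2 / analytic - 1), 0.01)

  # boundary conventions at exact radii (1 mm per px grid for exactness)
  ctr_px <- c(px_to_mm(10, 1000), px_to_mm(10, 1000))
  ann2 <- posterior_annulus(ctr_px, 2, 1, c(20, 20), 1000)
  expect_false(ann2[10, 11])   # r = d/2 exactly -> excluded
  expect_true(ann2[10, 13])    # r = d/2 + k d exactly -> included

  expect_equal(sum(posterior_annulus(ctr, d, 1e-9, dim, scale)), 0)
  expect_error(posterior_annulus(c(99, 99), d, k, dim, scale), "outside")
})

test_that("midperiphery is the exact set difference", {
  std <- matrix(FALSE, 15, 15); std[3:12, 3:12] <- TRUE
  post <- matrix(FALSE, 15, 15); post[1:8, 1:8] <- TRUE
  mid <- midperiphery(std, post)
  expect_equal(sum(mid), sum(std) - sum(std & post))
  expect_equal(sum(mid & post), 0)
  expect_equal(sum(midperiphery(std, std)), 0)           # full exclusion
  none <- matrix(FALSE, 15, 15)
  expect_equal(midperiphery(std, none), std)             # no exclusion
  expect_error(midperiphery(std, matrix(FALSE, 4, 4)), "dimension")
})

test_that("quadrant labels follow the disc-fovea axis", {
  scale <- 1000  # 1 mm / px for easy arithmetic
  dim <- c(40, 40)
  disc <- c(px_to_mm(20, scale), px_to_mm(20, scale))
  fovea_left <- disc - c(8, 0)
  q <- quadrant_partition(disc, fovea_left, dim, scale)
  # pixel above the line (smaller row) on the fovea side is superotemporal
  expect_equal(q[15, 10], "ST")
  expect_equal(q[25, 10], "IT")
  expect_equal(q[15, 30], "SN")
  expect_equal(q[25, 30], "IN")
  # total partition
  expect_true(all(q %in% c("ST", "SN", "IT", "IN")))
  expect_equal(length(unique(as.vector(q))), 4)
  expect_error(quadrant_partition(disc, disc, dim, scale), "coincide")
})

test_that("quadrant labels depend only on the relative geometry", {
  scale <- 1000
  dim <- c(60, 60)
  disc <- c(px_to_mm(30, scale), px_to_mm(30, scale))
  probe <- c(px_to_mm(22, scale), px_to_mm(24, scale))
  rot <- function(p, a) disc + c(cos(a) * (p - disc)[1] - sin(a) * (p - disc)[2],
                                 sin(a) * (p - disc)[1] + cos(a) * (p - disc)[2])
  base_fovea <- disc - c(10, 0)
  q0 <- quadrant_partition(disc, base_fovea, dim, scale)
  lab0 <- q0[round(mm_to_px(probe[2], scale)), round(mm_to_px(probe[1], scale))]
  for (a in c(-0.5, 0.4)) {   # rotations keeping the temporal side left
    qa <- quadrant_partition(disc, rot(base_fovea, a), dim, scale)
    pa <- rot(probe, a)
    laba <- qa[round(mm_to_px(pa[2], scale)), round(mm_to_px(pa[1], scale))]
    expect_equal(laba, lab0)
  }
})

test_that("probes at +/-u +/-v around the disc cover all four quadrants", {
  scale <- 1000; dim <- c(40, 40)
  disc <- c(px_to_mm(20, scale), px_to_mm(20, scale))
  fovea <- disc + c(-7, -3)
  u <- (fovea - disc) / sqrt(sum((fovea - disc)^2))
  v <- c(-u[2], u[1])
  q <- quadrant_partition(disc, fovea, dim, scale)
  labs <- vapply(list(u + v, u - v, -u + v, -u - v), function(d) {
    p <- disc + 6 * d
    q[round(mm_to_px(p[2], scale)), round(mm_to_px(p[1], scale))]
  }, character(1))
  expect_setequal(labs, c("ST", "SN", "IT", "IN"))
})

test_that("roi_set clips the annulus and separates the regions", {
  eye <- make_test_eye(seed = 3)
  full <- matrix(TRUE, 700, 700)
  rs <- roi_set(full, full, test_disc(), test_fovea(), 12, k = 3)
  expect_equal(sum(rs$posterior & rs$midperiphery), 0)
  expect_true(all(rs$posterior | rs$midperiphery | !rs$standardized |
                    !posterior_annulus(test_disc()$center, 0.8, 3,
                                       c(700, 700), 12)))
  expect_true(all(which(rs$posterior) %in% which(rs$standardized)))
})
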
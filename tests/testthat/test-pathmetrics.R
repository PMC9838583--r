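test_that("resampling preserves straight paths and its spacing contract", {
  line <- cbind(seq(0, 5, length.out = 40), seq(0, 2.5, length.out = 40))
  rp <- resample_smooth_path(line, spacing = 0.1, smooth_window = 7)
  # collinearity preserved
  d <- cbind(rp[, 1] - rp[1, 1], rp[, 2] - rp[1, 2])
  cross <- d[, 1] * (rp[nrow(rp), 2] - rp[1, 2]) -
    d[, 2] * (rp[nrow(rp), 1] - rp[1, 1])
  expect_lt(max(abs(cross)), 1e-8)
  # consecutive spacing within 10%
  steps <- sqrt(rowSums(diff(rp)^2))
  expect_true(all(abs(steps[-length(steps)] - 0.1) <= 0.01))

  expect_error(resample_smooth_path(line[1:2, ], 0.1), "3 points")
  expect_error(resample_smooth_path(line, 10), "shorter")
})

test_that("a dense semicircle resamples onto the true circle", {
  r <- 1.5
  th <- seq(0, pi, length.out = 500)
  rp <- resample_smooth_path(cbind(r * cos(th), r * sin(th)),
                             spacing = 0.05, smooth_window = 5)
  dev <- abs(sqrt(rowSums(rp^2)) - r)
  expect_lt(max(dev), 0.05)
})

test_that("width gradient is exact on noiseless linear profiles", {
  s <- seq(0, 10, length.out = 100)
  fit <- width_gradient(60 - 3 * s, s)
  expect_lt(abs(fit$slope - (-3)), 1e-6)
  expect_lt(abs(fit$intercept - 60), 1e-6)

  flat <- width_gradient(rep(50, 50), seq(0, 10, length.out = 50))
  expect_equal(unname(flat$slope), 0)

  expect_error(width_gradient(1:5, 1:5), "10 points")
  expect_error(width_gradient(rep(1, 12), rep(1, 12)), "increasing")
})

test_that("bisquare fit resists spike contamination better than OLS", {
  s <- seq(0, 10, length.out = 120)
  err_rob <- err_ols <- numeric(100)
  for (i in 1:100) {
    set.seed(i)
    w <- 60 - 3 * s + rnorm(120, 0, 2)
    spikes <- sample(120, 12)
    w[spikes] <- w[spikes] + 40
    err_rob[i] <- width_gradient(w, s, tuning = 4.685)$slope - (-3)
    err_ols[i] <- coef(lm(w ~ s))[[2]] - (-3)
  }
  expect_lt(mean(abs(err_rob)), 0.3)
  expect_lt(mean(abs(err_rob)), mean(abs(err_ols)))
})

test_that("the IRLS fit agrees with the reference implementation", {
  set.seed(4)
  s <- seq(0, 8, length.out = 90)
  w <- 70 - 2.5 * s + rnorm(90, 0, 3)
  w[sample(90, 8)] <- w[sample(90, 8)] + 30
  ours <- width_gradient(w, s, tuning = 4.685)$slope
  ref <- coef(MASS::rlm(w ~ s, psi = MASS::psi.bisquare, maxit = 100))[[2]]
  expect_lt(abs(ours - ref), 0.05)
})

test_that("tortuosity analytics: straight line, semicircle, invariances", {
  s <- seq(0, 4, length.out = 60)
  straight <- cbind(s, 0.5 * s)
  expect_warning(t0 <- tortuosity(straight), "log_tau")
  expect_equal(t0$tau, 0)
  expect_true(is.na(t0$log_tau))

  for (r in c(0.4, 1, 5)) {
    th <- seq(0, pi, length.out = 600)
    rp <- resample_smooth_path(cbind(r * cos(th), r * sin(th)),
                               spacing = pi * r / 150, smooth_window = 5)
    tt <- tortuosity(rp)
    expect_lt(abs(tt$tau / pi^2 - 1), 0.02)
  }

  set.seed(2)
  t_arc <- seq(0, 2, length.out = 400)
  wig <- cbind(t_arc + 0.08 * sin(4 * t_arc), 0.25 * sin(3 * t_arc))
  tau1 <- tortuosity(resample_smooth_path(wig, 0.01, 5))$tau
  tau2 <- tortuosity(resample_smooth_path(wig * 3, 0.03, 5))$tau
  expect_lt(abs(tau2 / tau1 - 1), 0.01)           # scale invariance
  a <- 0.9
  R <- matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2)
  shift <- matrix(rep(c(4, -2), each = 400), ncol = 2)
  tau3 <- tortuosity(resample_smooth_path(wig %*% R + shift, 0.01, 5))$tau
  expect_lt(abs(tau3 / tau1 - 1), 0.001)          # rigid motion invariance
})

test_that("tortuosity rises with sinusoid amplitude", {
  taus <- vapply(c(0.05, 0.1, 0.2), function(a) {
    x <- seq(0, 6, length.out = 1200)
    tortuosity(resample_smooth_path(cbind(x, a * sin(2 * pi * x / 1.5)),
                                    0.02, 5))$tau
  }, numeric(1))
  expect_true(all(diff(taus) > 0))
  # oracle: dense quadrature of the analytic curvature of y = a sin(kx)
  oracle <- vapply(c(0.05, 0.1, 0.2), function(a) {
    k <- 2 * pi / 1.5
    x <- seq(0, 6, length.out = 40000)
    yp <- a * k * cos(k * x); ypp <- -a * k^2 * sin(k * x)
    kap <- ypp / (1 + yp^2)^1.5
    ds <- sqrt(1 + yp^2) * (x[2] - x[1])
    sum(ds) * sum(kap^2 * ds)
  }, numeric(1))
  expect_lt(max(abs(taus / oracle - 1)), 0.15)
})

test_that("alternate tortuosity variants behave", {
  th <- seq(0, pi, length.out = 400)
  semi <- cbind(cos(th), sin(th))
  ac <- tortuosity(semi, variant = "arc_chord")
  expect_lt(abs(ac$tau - (pi / 2 - 1)), 0.01)
  tt <- tortuosity(semi, variant = "total_turning")
  expect_lt(abs(tt$tau - pi), 0.05)
})

test_that("eye metrics assemble with the documented aggregation", {
  wg <- list()
  for (v in list(c("ST", -4.3), c("SN", -3.7), c("IT", -3.9), c("IN", -3.2))) {
    r <- width_gradient(60 + as.numeric(v[2]) * seq(0, 5, length.out = 20),
                        seq(0, 5, length.out = 20))
    r$quadrant <- v[1]; r$class <- "arteriole"
    wg[[paste0(v[1], "_arteriole")]] <- r
  }
  row <- assemble_eye_metrics(fd = c(standardized = 1.4), wg = wg,
                              eye_id = "E1", participant_id = "P1",
                              laterality = "right")
  expect_equal(row$wg_all_a, -3.775, tolerance = 1e-6)
  expect_equal(attr(row, "n_missing"), 12)   # venule wg + all tort cells

  # three of four quadrants: mean of the three, missingness counted
  row3 <- assemble_eye_metrics(fd = NULL, wg = wg[1:3],
                               eye_id = "E1", participant_id = "P1")
  expect_equal(row3$wg_all_a, mean(c(-4.3, -3.7, -3.9)), tolerance = 1e-6)

  expect_error(assemble_eye_metrics(eye_id = "E1", participant_id = "P1"),
               "no metrics")
  bad <- wg
  bad[[1]]$eye_id <- "OTHER"
  expect_error(assemble_eye_metrics(fd = NULL, wg = bad, eye_id = "E1",
                                    participant_id = "P1"), "conflicting")
})
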
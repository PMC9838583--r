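test_that("missing values are imputed to the group mean", {
  tab <- data.frame(group = rep("NC", 4), y = c(1, 2, 3, NA))
  out <- impute_missing_extreme(tab, "y")
  expect_equal(out$y[4], 2)
  expect_equal(attr(out, "n_imputed"), 1)

  clean <- data.frame(group = rep(c("AD", "NC"), each = 4),
                      y = rep(1:4, 2))
  out2 <- impute_missing_extreme(clean, "y")
  expect_equal(out2$y, clean$y)
  expect_equal(attr(out2, "n_imputed"), 0)
})

test_that("extreme values beyond z group SDs are replaced", {
  y <- c(rep(0, 20), 100)   # 100 is ~4.5 pre-imputation SDs from the mean
  tab <- data.frame(group = rep("NC", 21), y = y)
  pre_mean <- mean(y); pre_sd <- sd(y)
  expect_gt(abs(100 - pre_mean), 3 * pre_sd)   # oracle: direct computation
  out <- impute_missing_extreme(tab, "y", z = 3)
  expect_equal(out$y[21], pre_mean)            # replaced by pre-imputation mean
  expect_true(attr(out, "flags")[21, "y"])
})

test_that("imputation is idempotent", {
  set.seed(3)
  tab <- data.frame(group = rep(c("AD", "MCI", "NC"), each = 15),
                    y = rnorm(45))
  tab$y[c(2, 17)] <- NA
  tab$y[30] <- 40
  once <- impute_missing_extreme(tab, "y")
  twice <- impute_missing_extreme(once, "y")
  expect_equal(once$y, twice$y)
})

test_that("a group with no observed values is dropped with a warning", {
  tab <- data.frame(group = rep(c("AD", "NC"), each = 3),
                    y = c(NA, NA, NA, 1, 2, 3))
  expect_warning(out <- impute_missing_extreme(tab, "y"), "no observed")
  expect_true(all(is.na(out$y[1:3])))
})

test_that("GEE reduces exactly to OLS in the degenerate case", {
  set.seed(9)
  n <- 40
  tab <- data.frame(participant_id = sprintf("P%02d", 1:n),
                    group = rep(c("AD", "NC"), each = n / 2),
                    y = rnorm(n))
  X <- cbind(`(Intercept)` = 1, group = as.numeric(tab$group == "AD"))
  fit <- gee_fit(tab$y, X, tab$participant_id, corstr = "independence")
  ols <- coef(lm(y ~ I(group == "AD"), tab))
  expect_lt(max(abs(coef(fit) - unname(ols))), 1e-8)
})

test_that("joint three-level fit makes the contrasts exactly consistent", {
  tab <- sim_gee_table(-0.7, n_per_group = 20, seed = 5)
  # add an MCI group
  mci <- sim_gee_table(-0.3, n_per_group = 20, seed = 6)
  mci <- mci[mci$group == "AD", ]
  mci$group <- "MCI"
  mci$participant_id <- paste0("M", mci$participant_id)
  tab <- rbind(tab, mci)
  res <- gee_group_comparison(tab, "y", log_transform = FALSE,
                              method = "joint")
  b <- setNames(res$beta, res$contrast)
  expect_equal(unname(b["AD vs MCI"]),
               unname(b["AD vs NC"] - b["MCI vs NC"]), tolerance = 1e-10)
})

test_that("Wald intervals cover the simulated effect at the nominal rate", {
  cov <- vapply(1:500, function(r) {
    tb <- sim_gee_table(-0.7, seed = 2000 + r)
    res <- gee_group_comparison(tb, "y", contrasts = list(c("AD", "NC")),
                                log_transform = FALSE)
    res$ci_low <= -0.7 && res$ci_high >= -0.7
  }, logical(1))
  expect_gte(mean(cov), 0.93)
  expect_lte(mean(cov), 0.97)
})

test_that("log transform excludes non-positive tortuosity values", {
  tb <- sim_gee_table(0, n_per_group = 15, seed = 77)
  tb$tort_all_a <- exp(tb$y)
  tb$tort_all_a[1] <- -1
  expect_message(
    res <- gee_group_comparison(tb, "tort_all_a",
                                contrasts = list(c("AD", "NC"))),
    "non-positive")
  expect_equal(res$n_excluded, 1)
  expect_equal(res$n_eyes, nrow(tb) - 1)
})

test_that("too few clusters in a group is an error", {
  tb <- sim_gee_table(0, n_per_group = 10, seed = 3)
  tb <- tb[tb$participant_id != "AD1", ]
  tb <- tb[!(tb$group == "AD" & !tb$participant_id %in% "AD2"), ]
  expect_error(gee_group_comparison(tb, "y", contrasts = list(c("AD", "NC")),
                                    log_transform = FALSE), "clusters")
})

test_that("Sidak adjustment has its closed form", {
  expect_equal(sidak_adjust(0.01, 3), 1 - 0.99^3)
  expect_equal(sidak_adjust(0.01, 3), 0.029701, tolerance = 1e-9)
})

test_that("demographics tests handle ties, homogeneity and constants", {
  vals <- c(60, 65, 70, 75, 80)
  dem <- data.frame(group = rep(c("AD", "MCI", "NC"), each = 5),
                    age = rep(vals, 3),
                    sex = rep(rep(c("F", "M"), length.out = 5), 3))
  rep1 <- demographics_tests(dem)
  # identical distributions: tie-corrected statistic 0, p = 1
  expect_equal(rep1$kruskal$statistic[rep1$kruskal$variable == "age"], 0)
  expect_equal(rep1$kruskal$p[rep1$kruskal$variable == "age"], 1)
  # perfectly homogeneous contingency table: chi-square 0, p = 1
  expect_equal(unname(rep1$chisq$statistic[rep1$chisq$variable == "sex"]), 0)
  expect_equal(rep1$chisq$p[rep1$chisq$variable == "sex"], 1)

  dem$mmse <- 25
  expect_warning(demographics_tests(dem), "constant")
})

test_that("significant group separation triggers Dunn-Sidak post hocs", {
  set.seed(8)
  dem <- data.frame(group = rep(c("AD", "MCI", "NC"), each = 20),
                    age = c(rnorm(20, 75, 3), rnorm(20, 70, 3),
                            rnorm(20, 64, 3)),
                    sex = sample(c("F", "M"), 60, TRUE))
  rep2 <- demographics_tests(dem)
  expect_lt(rep2$kruskal$p[1], 0.05)
  expect_equal(nrow(rep2$dunn), 3)
  expect_true(all(rep2$dunn$p_sidak >= rep2$dunn$p))
  expect_equal(rep2$dunn$p_sidak, sidak_adjust(rep2$dunn$p, 3))
})
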
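#' Impute missing and extreme outcome values to the group mean
#'
#' Two-pass rule applied per outcome and per group: statistics (mean, SD) are
#' computed on the observed cells first; cells farther than `z` group-SDs
#' from the group mean are then replaced by that pre-imputation mean, and
#' missing cells are filled with it as well. Every imputed cell is flagged so
#' sensitivity analyses can re-run without imputation. A group with no
#' observed value for an outcome has that outcome dropped (left `NA`) with a
#' warning.
#'
#' @param table data.frame with a `group` column.
#' @param outcome_cols character vector of outcome column names.
#' @param z extreme-value threshold in group SDs (default 3).
#' @return the table with imputations applied; attribute `flags` is a
#'   logical matrix (rows x outcomes) marking imputed cells, and attribute
#'   `n_imputed` the total count.
#' @export
impute_missing_extreme <- function(table, outcome_cols, z = 3) {
  if (!"group" %in% names(table)) stop("group column required", call. = FALSE)
  flags <- matrix(FALSE, nrow(table), length(outcome_cols),
                  dimnames = list(NULL, outcome_cols))
  for (col in outcome_cols) {
    for (g in unique(table$group)) {
      sel <- which(table$group == g)
      v <- table[[col]][sel]
      obs <- v[!is.na(v)]
      if (!length(obs)) {
        warning("outcome ", col, " has no observed values in group ", g,
                "; dropped for that group")
        next
      }
      m <- mean(obs); s <- sd(obs)
      extreme <- !is.na(v) & is.finite(s) & s > 0 & abs(v - m) > z * s
      miss <- is.na(v)
      v[extreme | miss] <- m
      table[[col]][sel] <- v
      flags[sel, col] <- flags[sel, col] | extreme | miss
    }
  }
  attr(table, "flags") <- flags
  attr(table, "n_imputed") <- sum(flags)
  table
}

#' Linear-link generalized estimating equations (exchangeable correlation)
#'
#' Marginal Gaussian regression with clustered observations (the two eyes of
#' a participant): coefficients are estimated by iteratively reweighted
#' generalized least squares under an exchangeable working correlation whose
#' parameter is moment-estimated from Pearson residuals, and standard errors
#' are the robust (sandwich) estimates, so inference is valid even when the
#' working correlation is misspecified. With one observation per cluster (or
#' a forced independence working structure) the estimate reduces exactly to
#' ordinary least squares.
#'
#' @param y numeric outcome.
#' @param X design matrix (including the intercept column).
#' @param cluster cluster ids (one per row of X).
#' @param corstr `"exchangeable"` or `"independence"`.
#' @param tol,max_iter convergence control on the coefficient vector.
#' @return object of class `uwf_gee` with `coefficients`, `vcov` (sandwich),
#'   `alpha` (working correlation), `phi` (dispersion), `n_obs`,
#'   `n_clusters`.
#' @export
gee_fit <- function(y, X, cluster,
                    corstr = c("exchangeable", "independence"),
                    tol = 1e-10, max_iter = 50) {
  corstr <- match.arg(corstr)
  X <- as.matrix(X)
  keep <- complete.cases(y, X)
  y <- y[keep]; X <- X[keep, , drop = FALSE]
  cluster <- as.character(cluster[keep])
  idx <- split(seq_along(y), cluster)
  p <- ncol(X); N <- length(y)
  if (length(idx) <= p) stop("too few clusters", call. = FALSE)
  beta <- qr.solve(X, y)
  alpha <- 0
  for (it in seq_len(max_iter)) {
    e <- y - X %*% beta
    phi <- sum(e^2) / (N - p)
    if (corstr == "exchangeable") {
      num <- 0; den <- 0
      for (ii in idx) {
        ni <- length(ii)
        if (ni < 2) next
        ei <- e[ii]
        num <- num + (sum(ei)^2 - sum(ei^2)) / 2
        den <- den + ni * (ni - 1) / 2
      }
      alpha <- if (den > p) (num / phi) / (den - p) else 0
      alpha <- min(max(alpha, 0), 0.95)
    }
    A <- matrix(0, p, p); b <- numeric(p)
    for (ii in idx) {
      ni <- length(ii)
      Ri <- matrix(alpha, ni, ni); diag(Ri) <- 1
      Wi <- solve(Ri)
      Xi <- X[ii, , drop = FALSE]
      A <- A + crossprod(Xi, Wi %*% Xi)
      b <- b + crossprod(Xi, Wi %*% y[ii])
    }
    beta_new <- solve(A, b)
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; break }
    beta <- beta_new
  }
  e <- y - X %*% beta
  A <- matrix(0, p, p)
  cluster_dat <- list()
  for (ii in idx) {
    ni <- length(ii)
    Ri <- matrix(alpha, ni, ni); diag(Ri) <- 1
    Wi <- solve(Ri)
    Xi <- X[ii, , drop = FALSE]
    A <- A + crossprod(Xi, Wi %*% Xi)
    cluster_dat[[length(cluster_dat) + 1L]] <-
      list(Xi = Xi, Wi = Wi, ei = e[ii])
  }
  Ainv <- solve(A)
  # bias-corrected (Mancl-DeRouen) sandwich: per-cluster residuals are
  # inflated by (I - H_i)^-1 before entering the meat; with tens of
  # clusters the plain sandwich underestimates the variance. Inference uses
  # a t reference with K - p df.
  M <- matrix(0, p, p)
  for (cd in cluster_dat) {
    Hi <- cd$Xi %*% Ainv %*% crossprod(cd$Xi, cd$Wi)
    estar <- solve(diag(nrow(Hi)) - Hi, cd$ei)
    gi <- crossprod(cd$Xi, cd$Wi %*% estar)
    M <- M + tcrossprod(gi)
  }
  K <- length(idx)
  V <- Ainv %*% M %*% Ainv
  phi <- sum(e^2) / (N - p)
  structure(list(coefficients = setNames(as.numeric(beta), colnames(X)),
                 vcov = V, alpha = alpha, phi = phi, df = K - p,
                 n_obs = N, n_clusters = K, corstr = corstr),
            class = "uwf_gee")
}

#' @export
coef.uwf_gee <- function(object, ...) object$coefficients

#' @export
vcov.uwf_gee <- function(object, ...) object$vcov

#' @export
confint.uwf_gee <- function(object, parm, level = 0.95, ...) {
  se <- sqrt(diag(object$vcov))
  zq <- stats::qt(1 - (1 - level) / 2, object$df)
  ci <- cbind(coef(object) - zq * se, coef(object) + zq * se)
  colnames(ci) <- paste(c((1 - level) / 2, 1 - (1 - level) / 2) * 100, "%")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
print.uwf_gee <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  z <- coef(x) / se
  tab <- data.frame(estimate = coef(x), robust_se = se, z = z,
                    p = 2 * stats::pt(-abs(z), x$df))
  cat(sprintf("<uwf_gee> %s working correlation (alpha = %.3f), %d obs in %d clusters\n",
              x$corstr, x$alpha, x$n_obs, x$n_clusters))
  print(round(tab, 4))
  invisible(x)
}

#' Pairwise GEE group comparisons of one outcome
#'
#' For each contrast (default AD vs NC, MCI vs NC, AD vs MCI) the two groups
#' involved are subset and a linear-link GEE of the outcome on the group
#' indicator plus age and sex is fitted, with participants as clusters and
#' an exchangeable working correlation; the beta coefficient is the adjusted
#' group difference in outcome units, reported with its robust Wald 95% CI
#' and two-sided p-value. Tortuosity outcomes (columns starting `tort_`) are
#' natural-log transformed before fitting; non-positive values are excluded
#' with their count reported.
#'
#' @param table analysis table (one row per eye) with columns
#'   `participant_id`, `group`, `age`, `sex` and the outcome.
#' @param outcome outcome column name.
#' @param contrasts list of 2-vectors `c(group, reference)`.
#' @param covariates adjustment covariates (default age + sex).
#' @param log_transform force/suppress the log transform (default: by
#'   outcome name).
#' @param corstr working correlation passed to [gee_fit()].
#' @param method `"pairwise"` (default) fits one two-group model per
#'   contrast, mirroring reported pairwise columns; `"joint"` fits a single
#'   three-level model with NC as reference and derives all contrasts from
#'   it (making them exactly consistent: the AD-MCI coefficient equals the
#'   difference of the other two).
#' @return data.frame of class `gee_results`: one row per contrast with
#'   beta, ci_low, ci_high, p, n_eyes, n_clusters, n_excluded; the fitted
#'   `uwf_gee` objects are in attribute `fits`.
#' @export
gee_group_comparison <- function(table, outcome,
                                 contrasts = list(c("AD", "NC"),
                                                  c("MCI", "NC"),
                                                  c("AD", "MCI")),
                                 covariates = c("age", "sex"),
                                 log_transform = NULL,
                                 corstr = "exchangeable",
                                 method = c("pairwise", "joint")) {
  method <- match.arg(method)
  log_transform <- log_transform %||% grepl("^tort", outcome)
  if (method == "joint")
    return(gee_joint_comparison(table, outcome, covariates, log_transform,
                                corstr))
  rows <- list(); fits <- list()
  for (ct in contrasts) {
    sub <- table[table$group %in% ct, , drop = FALSE]
    y <- sub[[outcome]]
    n_excl <- 0L
    if (log_transform) {
      bad <- !is.na(y) & y <= 0
      n_excl <- sum(bad)
      if (n_excl) message(n_excl, " non-positive ", outcome,
                          " value(s) excluded from the log-scale fit")
      y[bad] <- NA
      y <- log(y)
    }
    for (g in ct)
      if (length(unique(sub$participant_id[sub$group == g])) < 2)
        stop("fewer than 2 clusters in group ", g, call. = FALSE)
    X <- cbind(`(Intercept)` = 1,
               group = as.numeric(sub$group == ct[1]))
    if ("age" %in% covariates) X <- cbind(X, age = sub$age)
    if ("sex" %in% covariates)
      X <- cbind(X, sex = as.numeric(sub$sex %in% c("F", "female", 1)))
    fit <- gee_fit(y, X, sub$participant_id, corstr = corstr)
    se <- sqrt(diag(fit$vcov))[["group"]]
    beta <- coef(fit)[["group"]]
    zq <- stats::qt(0.975, fit$df)
    lab <- paste(ct[1], "vs", ct[2])
    rows[[lab]] <- data.frame(
      outcome = outcome, contrast = lab, beta = beta,
      ci_low = beta - zq * se, ci_high = beta + zq * se,
      p = 2 * stats::pt(-abs(beta / se), fit$df),
      n_eyes = fit$n_obs, n_clusters = fit$n_clusters,
      n_excluded = n_excl, stringsAsFactors = FALSE)
    fits[[lab]] <- fit
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  class(out) <- c("gee_results", "data.frame")
  out
}

# joint three-level fit (NC reference); contrasts derived from one model
gee_joint_comparison <- function(table, outcome, covariates, log_transform,
                                 corstr) {
  sub <- table[table$group %in% c("AD", "MCI", "NC"), , drop = FALSE]
  y <- sub[[outcome]]
  n_excl <- 0L
  if (log_transform) {
    bad <- !is.na(y) & y <= 0
    n_excl <- sum(bad)
    y[bad] <- NA
    y <- log(y)
  }
  X <- cbind(`(Intercept)` = 1,
             AD = as.numeric(sub$group == "AD"),
             MCI = as.numeric(sub$group == "MCI"))
  if ("age" %in% covariates) X <- cbind(X, age = sub$age)
  if ("sex" %in% covariates)
    X <- cbind(X, sex = as.numeric(sub$sex %in% c("F", "female", 1)))
  fit <- gee_fit(y, X, sub$participant_id, corstr = corstr)
  V <- vcov(fit)
  lincom <- list(`AD vs NC` = c(AD = 1, MCI = 0),
                 `MCI vs NC` = c(AD = 0, MCI = 1),
                 `AD vs MCI` = c(AD = 1, MCI = -1))
  zq <- stats::qt(0.975, fit$df)
  rows <- lapply(names(lincom), function(lab) {
    l <- lincom[[lab]]
    beta <- sum(l * coef(fit)[c("AD", "MCI")])
    se <- sqrt(l["AD"]^2 * V["AD", "AD"] + l["MCI"]^2 * V["MCI", "MCI"] +
                 2 * l["AD"] * l["MCI"] * V["AD", "MCI"])
    data.frame(outcome = outcome, contrast = lab, beta = beta,
               ci_low = beta - zq * se, ci_high = beta + zq * se,
               p = 2 * stats::pt(-abs(beta / se), fit$df),
               n_eyes = fit$n_obs,
               n_clusters = fit$n_clusters, n_excluded = n_excl,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- list(joint = fit)
  class(out) <- c("gee_results", "data.frame")
  out
}

#' Sidak-adjusted p-value
#'
#' Closed form `1 - (1 - p)^m` for `m` comparisons.
#' @param p raw p-value(s).
#' @param m number of comparisons.
#' @export
sidak_adjust <- function(p, m) 1 - (1 - p)^m

#' Demographic comparisons across the three groups
#'
#' Continuous variables (age, and MMSE when present) are compared with a
#' Kruskal-Wallis test; when significant at `alpha`, all pairwise rank-based
#' Dunn tests with Sidak correction follow. Sex and laterality (when
#' present) are compared with a chi-square test. Constant variables are
#' skipped with a warning.
#'
#' @param participants data.frame with `group`, `sex`, optionally `age`,
#'   `mmse`, `laterality`.
#' @param alpha significance threshold gating the post hoc tests.
#' @return list of class `demographics_report`: `kruskal` (per-variable
#'   tests), `dunn` (pairwise Sidak-adjusted comparisons), `chisq`.
#' @export
demographics_tests <- function(participants, alpha = 0.05) {
  stopifnot("group" %in% names(participants))
  tab <- table(participants$group)
  if (length(tab) < 2 || any(tab < 2))
    stop("need >= 2 groups with >= 2 participants", call. = FALSE)
  cont <- intersect(c("age", "mmse"), names(participants))
  kw <- list(); dunn <- list()
  for (v in cont) {
    x <- participants[[v]]
    if (length(unique(x[!is.na(x)])) < 2) {
      warning("variable ", v, " is constant; test skipped")
      next
    }
    k <- kruskal.test(x ~ factor(participants$group))
    kw[[v]] <- data.frame(variable = v, statistic = unname(k$statistic),
                          df = unname(k$parameter), p = k$p.value)
    if (!is.na(k$p.value) && k$p.value < alpha)
      dunn[[v]] <- dunn_sidak(x, participants$group, variable = v)
  }
  cq <- list()
  for (v in intersect(c("sex", "laterality"), names(participants))) {
    ct <- table(participants[[v]], participants$group)
    if (nrow(ct) < 2) { warning("variable ", v, " is constant; test skipped")
                        next }
    suppressWarnings(ch <- chisq.test(ct))
    cq[[v]] <- data.frame(variable = v, statistic = unname(ch$statistic),
                          df = unname(ch$parameter), p = ch$p.value)
  }
  structure(list(kruskal = do.call(rbind, kw),
                 dunn = if (length(dunn)) do.call(rbind, dunn) else NULL,
                 chisq = if (length(cq)) do.call(rbind, cq) else NULL),
            class = "demographics_report")
}

# Dunn rank-sum z tests on the pooled (tie-corrected) ranks, all pairs,
# Sidak-adjusted
dunn_sidak <- function(x, group, variable = "x") {
  ok <- !is.na(x)
  x <- x[ok]; group <- as.character(group[ok])
  r <- rank(x)
  N <- length(x)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  groups <- sort(unique(group))
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  m <- length(pairs)
  out <- lapply(pairs, function(pr) {
    n1 <- sum(group == pr[1]); n2 <- sum(group == pr[2])
    d <- mean(r[group == pr[1]]) - mean(r[group == pr[2]])
    sigma <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n1 + 1 / n2))
    z <- d / sigma
    p <- 2 * pnorm(-abs(z))
    data.frame(variable = variable,
               comparison = paste(pr[1], "vs", pr[2]),
               z = z, p = p, p_sidak = sidak_adjust(p, m),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
print.demographics_report <- function(x, ...) {
  cat("<demographics_report>\n")
  if (!is.null(x$kruskal)) { cat("Kruskal-Wallis:\n"); print(x$kruskal) }
  if (!is.null(x$dunn)) { cat("Dunn-Sidak post hoc:\n"); print(x$dunn) }
  if (!is.null(x$chisq)) { cat("Chi-square:\n"); print(x$chisq) }
  invisible(x)
}
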
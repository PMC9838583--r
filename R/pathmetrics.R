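#' Arclength resampling and smoothing of a vessel path
#'
#' Re-parameterizes a polyline at uniform arclength spacing (linear
#' interpolation) and applies a centered moving average whose window shrinks
#' at the ends, so the endpoints are preserved. Stabilizes the discrete
#' curvature entering the tortuosity measure.
#'
#' @param points two-column matrix or data.frame of (x, y) coordinates (mm).
#' @param spacing target spacing (mm, > 0).
#' @param smooth_window moving-average window (points; 1 = no smoothing).
#' @return matrix with columns x, y.
#' @export
resample_smooth_path <- function(points, spacing = 0.05, smooth_window = 5) {
  p <- as.matrix(points[, 1:2])
  if (nrow(p) < 3) stop("need at least 3 points", call. = FALSE)
  if (spacing <= 0) stop("spacing must be > 0", call. = FALSE)
  steps <- sqrt(rowSums((p[-1, , drop = FALSE] -
                           p[-nrow(p), , drop = FALSE])^2))
  s <- c(0, cumsum(steps))
  L <- s[length(s)]
  if (L < 3 * spacing)
    stop("path (", signif(L, 3), " mm) shorter than 3 x spacing",
         call. = FALSE)
  si <- unique(c(seq(0, L, by = spacing), L))
  keep <- !duplicated(s)
  x <- approx(s[keep], p[keep, 1], si)$y
  y <- approx(s[keep], p[keep, 2], si)$y
  cbind(x = smooth_ma(x, smooth_window), y = smooth_ma(y, smooth_window))
}

#' Vessel width gradient by robust linear regression
#'
#' The width gradient (WG, micrometers per mm) is the slope of a robust
#' linear fit of vessel width against arclength from the optic disc;
#' negative values mean the vessel thins distally. The fit is iteratively
#' reweighted least squares with Tukey bisquare weights (Huber selectable);
#' when the residual scale collapses to zero (an exact linear relation) the
#' ordinary least-squares solution is returned, which the IRLS fixed point
#' equals in that case.
#'
#' @param widths_um widths (um).
#' @param arclengths_mm strictly increasing arclengths (mm), same length.
#' @param method `"bisquare"` (default) or `"huber"`.
#' @param tuning tuning constant; defaults 4.685 (bisquare) / 1.345 (Huber).
#' @param max_iter IRLS iteration cap.
#' @return object of class `wg_result`: `slope` (the WG), `intercept`,
#'   `n_points`, `weights` (final IRLS weights), `method`, and `quadrant`/
#'   `class` slots filled by the caller.
#' @export
width_gradient <- function(widths_um, arclengths_mm,
                           method = c("bisquare", "huber"),
                           tuning = NULL, max_iter = 50) {
  method <- match.arg(method)
  y <- as.numeric(widths_um); x <- as.numeric(arclengths_mm)
  if (length(y) != length(x)) stop("length mismatch", call. = FALSE)
  if (length(y) < 10) stop("need at least 10 points", call. = FALSE)
  if (any(diff(x) <= 0))
    stop("arclengths must be strictly increasing", call. = FALSE)
  if (diff(range(x)) < 1e-12)
    stop("degenerate path: arclengths are constant", call. = FALSE)
  tuning <- tuning %||% if (method == "bisquare") 4.685 else 1.345

  X <- cbind(1, x)
  beta <- qr.solve(X, y)
  w <- rep(1, length(y))
  for (it in seq_len(max_iter)) {
    e <- y - X %*% beta
    s <- median(abs(e)) / 0.6745
    # quantized widths can tie > half the residuals at 0; fall back to the
    # mean absolute deviation before declaring an exact fit
    if (s < 1e-10) s <- mean(abs(e)) / 0.7979
    if (s < 1e-10) { beta <- qr.solve(X, y); w <- rep(1, length(y)); break }
    u <- as.numeric(e) / (tuning * s)
    w <- if (method == "bisquare")
      ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    else pmin(1, 1 / pmax(abs(u), 1e-12))
    if (sum(w) < 2) { w <- rep(1, length(y)); break }
    beta_new <- qr.solve(X * sqrt(w), y * sqrt(w))
    if (max(abs(beta_new - beta)) < 1e-12) { beta <- beta_new; break }
    beta <- beta_new
  }
  if (!all(is.finite(beta))) stop("robust fit failed", call. = FALSE)
  structure(list(slope = beta[2], intercept = beta[1],
                 n_points = length(y), weights = as.numeric(w),
                 method = method, tuning = tuning,
                 quadrant = NA_character_, class = NA_character_),
            class = "wg_result")
}

#' @export
print.wg_result <- function(x, ...) {
  cat(sprintf("<wg_result> WG = %.3f um/mm (intercept %.1f um, n = %d, %s)\n",
              x$slope, x$intercept, x$n_points, x$method))
  invisible(x)
}

#' Unitless curvature tortuosity of a vessel path
#'
#' The default measure is `tau = L * sum(kappa_i^2 * ds_i)` with discrete
#' curvature `kappa` from finite differences of the tangent angle over
#' arclength: dimensionless, zero for straight segments, invariant to rigid
#' motions and to uniform scaling (for a semicircle of any radius,
#' `tau = pi^2`). Because tau is positively skewed across vessels, its
#' natural logarithm `log_tau` is what enters the GEE stage. Variants:
#' `"arc_chord"` (arclength over chord minus one) and `"total_turning"`
#' (`sum |kappa| ds`, total absolute turning angle) for sensitivity
#' analyses.
#'
#' @param points two-column matrix/data.frame (x, y in mm) of a resampled,
#'   smoothed path with at least 10 points.
#' @param variant tortuosity definition (see above).
#' @param s_exclude optional two-column matrix of arclength windows (mm,
#'   measured along `points`); curvature contributions inside any window
#'   are omitted from the integral and from L (used to keep junction-zone
#'   kinks of rasterized paths out of the measure).
#' @return object of class `tort_result`: `tau`, `log_tau` (`NA` with a
#'   warning when `tau` is 0), `length_mm`, `variant`, plus `quadrant`/
#'   `class` slots filled by the caller.
#' @export
tortuosity <- function(points,
                       variant = c("curvature", "arc_chord",
                                   "total_turning"), s_exclude = NULL) {
  variant <- match.arg(variant)
  p <- as.matrix(points[, 1:2])
  if (nrow(p) < 10) stop("need at least 10 points", call. = FALSE)
  seg <- p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE]
  len <- sqrt(rowSums(seg^2))
  if (any(len == 0)) { keep <- len > 0; seg <- seg[keep, , drop = FALSE]
                       len <- len[keep] }
  L <- sum(len)
  if (L <= 0) stop("zero-length path", call. = FALSE)
  tau <- if (variant == "arc_chord") {
    L / sqrt(sum((p[nrow(p), ] - p[1, ])^2)) - 1
  } else {
    th <- atan2(seg[, 2], seg[, 1])
    dth <- diff(th)
    dth <- atan2(sin(dth), cos(dth))          # unwrap
    ds <- (len[-1] + len[-length(len)]) / 2
    kap <- dth / ds
    keep <- rep(TRUE, length(kap))
    if (!is.null(s_exclude) && nrow(s_exclude)) {
      s_mid <- cumsum(len)[-length(len)]     # arclength at interior vertices
      for (i in seq_len(nrow(s_exclude)))
        keep <- keep & !(s_mid >= s_exclude[i, 1] & s_mid <= s_exclude[i, 2])
      L <- sum(ds[keep]) + (L - sum(ds))     # kept length
    }
    if (variant == "curvature") L * sum(kap[keep]^2 * ds[keep]) else
      sum(abs(kap[keep]) * ds[keep])
  }
  log_tau <- if (tau > 0) log(tau) else {
    warning("tau = 0; log_tau recorded as missing")
    NA_real_
  }
  structure(list(tau = tau, log_tau = log_tau, length_mm = L,
                 variant = variant, quadrant = NA_character_,
                 class = NA_character_),
            class = "tort_result")
}

#' @export
print.tort_result <- function(x, ...) {
  cat(sprintf("<tort_result> tau = %.4g (log %.3f) over %.2f mm [%s]\n",
              x$tau, x$log_tau, x$length_mm, x$variant))
  invisible(x)
}

#' Width gradient and tortuosity of one selected vessel path
#'
#' Before the width fit, the per-point widths are cleaned with steps
#' tailored to skeleton-based width profiles: an additional path-level
#' moving median (windows inside a single edge cannot span junction
#' artifacts), removal of samples near the path ends (distance-transform
#' end-cap collapse) and near internal junctions (crossing/bifurcation
#' inflation), and a plausibility gate that drops widths far outside the
#' path's median caliber (sustained inflation where another vessel runs
#' adjacent). The tortuosity branch resamples and smooths the coordinates
#' instead.
#'
#' @param path a `vessel_path` from [select_quadrant_paths()].
#' @param smooth_window moving-average window (points) applied after the
#'   tortuosity resampling (see the spacing rule in the source note).
#' @param wg_method,tort_variant estimator choices.
#' @param wg_median_half_window path-level moving-median half-window
#'   (points).
#' @param wg_trim_mm samples closer than this to either path end are
#'   excluded from the width fit.
#' @param wg_junction_window_mm samples from `window[1]` before to
#'   `window[2]` after an internal junction are excluded (asymmetric: the
#'   distance-transform inflation from a branch running alongside its
#'   parent extends mainly downstream of the branch point).
#' @param wg_width_gate multiplicative band kept in the fit, relative to
#'   the disc-proximal baseline width (median over the first 30% of the
#'   path): widths above the band are crossing/adjacency artifacts, widths
#'   below it are end caps or stray thin branches.
#' @param wg_tuning bisquare tuning constant for the width fit (larger than
#'   the textbook 4.685: quantized width profiles make steps that a tight
#'   constant would misread as outliers and flatten).
#' @param wg_min_length_mm paths shorter than this get no width gradient
#'   (slopes from very short paths are dominated by width quantization).
#' @return list with `wg` (`wg_result` or NULL when the path is too short)
#'   and `tort` (`tort_result` or NULL).
#' @export
path_metrics <- function(path, smooth_window = 1,
                         wg_method = "bisquare",
                         tort_variant = "curvature",
                         wg_median_half_window = 10,
                         wg_trim_mm = 0.2,
                         wg_junction_window_mm = c(0.15, 0.45),
                         wg_width_gate = c(0.6, 1.25),
                         wg_tuning = 8,
                         wg_min_length_mm = 2.5) {
  stopifnot(inherits(path, "vessel_path"))
  wg <- tryCatch({
    if (path$length_mm < wg_min_length_mm)
      stop("path below minimum length for a width gradient")
    s <- path$points$s_mm
    w <- smooth_median(path$points$width_um, wg_median_half_window)
    base <- s > wg_trim_mm & s < quantile(s, 0.3)
    wref <- if (sum(base) >= 5) median(w[base]) else median(w)
    keep <- s > wg_trim_mm & s < max(s) - wg_trim_mm &
      w > wg_width_gate[1] * wref & w < wg_width_gate[2] * wref
    for (js in path$junction_s_mm)
      keep <- keep & (s < js - wg_junction_window_mm[1] |
                        s > js + wg_junction_window_mm[2])
    r <- width_gradient(w[keep], s[keep], method = wg_method,
                        tuning = wg_tuning)
    r$quadrant <- path$quadrant; r$class <- path$class; r
  }, error = function(e) NULL)
  tort <- tryCatch({
    # tangent chords scale with the path (so tau stays scale invariant) but
    # never fall below ~16 pixels for rasterized paths: angle noise from
    # centerline jitter shrinks with the chord, while genuine curvature at
    # the sinuosity wavelengths is barely attenuated
    L <- path$length_mm
    pxmm <- path$px_mm %||% 0
    spacing <- min(max(L / 150, 16 * pxmm), L / 10)
    rp <- resample_smooth_path(path$points[, c("x_mm", "y_mm")],
                               spacing, smooth_window)
    excl <- if (length(path$junction_s_mm))
      cbind(path$junction_s_mm - 0.25, path$junction_s_mm + 0.25) else NULL
    r <- tortuosity(rp, variant = tort_variant, s_exclude = excl)
    r$quadrant <- path$quadrant; r$class <- path$class; r
  }, error = function(e) NULL)
  list(wg = wg, tort = tort)
}

metric_columns <- function() {
  quad <- c("all", "st", "sn", "it", "in")
  cls <- c("a", "v")
  c("eye_id", "participant_id", "laterality",
    paste0("fd_", c("standardized", "posterior", "midperiphery")),
    paste0("wg_", rep(quad, times = 2), "_", rep(cls, each = 5)),
    paste0("tort_", rep(quad, times = 2), "_", rep(cls, each = 5)))
}

#' Assemble the flat per-eye metrics record
#'
#' One row per eye: fractal dimension per region, width gradient and
#' tortuosity per quadrant and vessel class, and the `"all"` aggregate per
#' class (arithmetic mean over the available quadrants). Missing cells stay
#' `NA`; the count of missing quadrant cells is attached as attribute
#' `n_missing`.
#'
#' @param fd named numeric vector from [regional_fd()].
#' @param wg,tort named lists keyed `"<QUAD>_<class>"` of `wg_result` /
#'   `tort_result` objects (as from [path_metrics()]).
#' @param eye_id,participant_id,laterality identifiers; wg/tort entries that
#'   carry a different eye id raise an error.
#' @return one-row data.frame with the documented column schema.
#' @export
assemble_eye_metrics <- function(fd = NULL, wg = list(), tort = list(),
                                 eye_id, participant_id,
                                 laterality = NA_character_) {
  if (is.null(fd) && !length(wg) && !length(tort))
    stop("no metrics supplied", call. = FALSE)
  row <- as.list(setNames(rep(NA_real_, length(metric_columns())),
                          metric_columns()))
  row$eye_id <- eye_id; row$participant_id <- participant_id
  row$laterality <- laterality
  if (!is.null(fd))
    for (r in names(fd)) row[[paste0("fd_", r)]] <- unname(fd[[r]])
  fill <- function(lst, prefix, field) {
    for (key in names(lst)) {
      obj <- lst[[key]]
      if (is.null(obj)) next
      if (!is.null(obj$eye_id) && !identical(obj$eye_id, eye_id))
        stop("conflicting eye ids: ", obj$eye_id, " vs ", eye_id,
             call. = FALSE)
      qc <- strsplit(key, "_")[[1]]
      col <- paste0(prefix, "_", tolower(qc[1]), "_",
                    substr(qc[2], 1, 1))
      row[[col]] <<- obj[[field]]
    }
  }
  fill(wg, "wg", "slope")
  fill(tort, "tort", "tau")
  n_missing <- 0L
  for (cls in c("a", "v")) for (prefix in c("wg", "tort")) {
    cells <- unlist(row[paste0(prefix, "_", c("st", "sn", "it", "in"), "_",
                               cls)])
    n_missing <- n_missing + sum(is.na(cells))
    if (any(!is.na(cells)))
      row[[paste0(prefix, "_all_", cls)]] <- mean(cells, na.rm = TRUE)
  }
  out <- as.data.frame(row, stringsAsFactors = FALSE)
  attr(out, "n_missing") <- n_missing
  out
}
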
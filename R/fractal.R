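#' Multifractal sandbox dimension of a binary structure
#'
#' Estimates the order-q generalized dimension of a planar structure (here
#' the vessel skeleton) by the sandbox method: centers are drawn uniformly at
#' random from structure pixels lying deep enough inside the region of
#' interest that the largest sandbox never crosses the ROI boundary; for each
#' radius R the structure mass M(R) within Euclidean distance R of each
#' center is counted, and D_q is `1/(q-1)` times the least-squares slope of
#' `ln < (M(R)/M0)^(q-1) >` against `ln(R/L)` (M0 = total structure mass in
#' the ROI, L = ROI diameter). For the reported measurement q = 0 this
#' reduces to minus the slope of `ln < M0/M(R) >` against `ln(R/L)`. Higher
#' values indicate a more space-filling branching pattern.
#'
#' @param structure logical/0-1 matrix of the structure (skeleton).
#' @param roi logical matrix; defaults to the full raster.
#' @param q dimension order (q != 1); the measurement of record is q = 0.
#' @param radii strictly increasing radii in px (>= 2 values). When `NULL`, a
#'   geometric ladder of up to 12 values is built from 4 px to the smaller of
#'   0.25 x ROI diameter and the 90th percentile of the ROI boundary
#'   distance at structure pixels (so that admissible centers exist even in
#'   thin annular regions).
#' @param n_centers number of random sandbox centers.
#' @param seed RNG seed for center sampling; the estimate is fully
#'   deterministic given the seed.
#' @return object of class `fd_result` with fields `D0` (the estimate), `q`,
#'   `radii`, `n_centers` (actually used), `se` (slope standard error), `r2`
#'   (fit R-squared), `seed`.
#' @export
sandbox_dimension <- function(structure, roi = NULL, q = 0, radii = NULL,
                              n_centers = 500, seed = 1L) {
  if (abs(q - 1) < 1e-12) stop("q = 1 is not defined for this estimator",
                               call. = FALSE)
  structure <- structure != 0
  if (is.null(roi)) roi <- matrix(TRUE, nrow(structure), ncol(structure))
  roi <- roi != 0
  sr <- structure & roi
  if (!any(sr)) stop("structure and ROI do not intersect", call. = FALSE)

  idx <- which(sr, arr.ind = TRUE)
  L <- roi_diameter(roi)
  bd <- roi_boundary_distance(roi)
  if (is.null(radii)) {
    maxr <- min(0.25 * L, as.numeric(quantile(bd[sr], 0.90)))
    if (maxr < 5) stop("ROI too thin for a sandbox ladder; ",
                       "reduce the maximum radius", call. = FALSE)
    radii <- unique(round(exp(seq(log(4), log(maxr), length.out = 12))))
  }
  radii <- sort(unique(radii))
  if (length(radii) < 2) stop("need at least 2 radii", call. = FALSE)
  maxR <- max(radii)

  adm <- which(sr & bd > maxR, arr.ind = TRUE)
  if (nrow(adm) == 0)
    stop("no admissible sandbox centers (every candidate center is within ",
         maxR, " px of the ROI boundary); use a smaller maximum radius",
         call. = FALSE)
  centers <- if (nrow(adm) <= n_centers) adm else with_seed(seed, {
    adm[sample.int(nrow(adm), n_centers), , drop = FALSE]
  })
  counts <- .cpp_sandbox_counts(idx[, 1], idx[, 2],
                                as.numeric(centers[, 1]),
                                as.numeric(centers[, 2]), radii)
  zero <- apply(counts == 0L, 1, any)
  if (any(zero)) {
    warning(sum(zero), " sandbox center(s) with zero mass dropped")
    counts <- counts[!zero, , drop = FALSE]
    if (!nrow(counts)) stop("all sandbox centers degenerate", call. = FALSE)
  }
  M0 <- sum(sr)
  frac <- counts / M0
  y <- if (q == 0) log(colMeans(1 / frac)) else
    log(colMeans(frac^(q - 1)))
  x <- log(radii / L)
  fit <- lm(y ~ x)
  sl <- coef(fit)[["x"]]
  D <- if (q == 0) -sl else sl / (q - 1)
  s <- summary(fit)
  structure(list(D0 = D, q = q, radii = radii,
                 n_centers = nrow(counts),
                 se = s$coefficients["x", "Std. Error"],
                 r2 = s$r.squared, seed = as.integer(seed)),
            class = "fd_result")
}

#' @export
print.fd_result <- function(x, ...) {
  cat(sprintf("<fd_result> D%g = %.4f  (%d centers, %d radii %g..%g px, R2 = %.3f)\n",
              x$q, x$D0, x$n_centers, length(x$radii), min(x$radii),
              max(x$radii), x$r2))
  invisible(x)
}

# distance of each ROI pixel to the ROI boundary, with the image edge
# itself counted as boundary (pad with one background row/col, then crop)
roi_boundary_distance <- function(roi) {
  nr <- nrow(roi); nc <- ncol(roi)
  pad <- matrix(0L, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- as.integer(roi != 0)
  bd <- as.matrix(EBImage::distmap(pad))
  bd[2:(nr + 1), 2:(nc + 1)]
}

# ROI diameter: diagonal of the bounding box of ROI pixels (px)
roi_diameter <- function(roi) {
  idx <- which(roi != 0, arr.ind = TRUE)
  if (!nrow(idx)) stop("empty ROI", call. = FALSE)
  sqrt(diff(range(idx[, 1]))^2 + diff(range(idx[, 2]))^2)
}

#' Box-counting fractal dimension (independent oracle)
#'
#' Counts occupied boxes over a dyadic ladder of box sizes and reports the
#' slope of `ln N(eps)` against `ln(1/eps)`. Kept deliberately independent of
#' the sandbox estimator so the two can cross-validate each other.
#'
#' @param structure logical/0-1 matrix.
#' @param roi optional logical matrix; only structure inside the ROI is
#'   counted.
#' @param sizes box edge lengths in px; defaults to the dyadic ladder from
#'   4 px to `min(dim)/16`.
#' @return list of class `boxcount_result` with `D`, `sizes`, `counts`, `r2`.
#' @export
boxcount_dimension <- function(structure, roi = NULL, sizes = NULL) {
  structure <- structure != 0
  if (!is.null(roi)) structure <- structure & (roi != 0)
  if (!any(structure)) stop("empty structure", call. = FALSE)
  if (is.null(sizes)) {
    kmax <- floor(log2(min(dim(structure)) / 16))
    sizes <- 2^(2:max(2, kmax))
  }
  sizes <- sort(unique(sizes))
  if (length(sizes) < 3) stop("fewer than 3 usable box scales", call. = FALSE)
  idx <- which(structure, arr.ind = TRUE)
  counts <- vapply(sizes, function(e) {
    boxes <- paste((idx[, 1] - 1) %/% e, (idx[, 2] - 1) %/% e)
    length(unique(boxes))
  }, numeric(1))
  keep <- counts > 1
  if (sum(keep) < 3) stop("fewer than 3 usable box scales", call. = FALSE)
  fit <- lm(log(counts[keep]) ~ log(1 / sizes[keep]))
  s <- summary(fit)
  structure(list(D = coef(fit)[[2]], sizes = sizes, counts = counts,
                 r2 = s$r.squared), class = "boxcount_result")
}

#' @export
print.boxcount_result <- function(x, ...) {
  cat(sprintf("<boxcount_result> D = %.4f over %d scales (R2 = %.3f)\n",
              x$D, length(x$sizes), x$r2))
  invisible(x)
}

#' Regional fractal dimension of a vessel skeleton
#'
#' One sandbox estimate per region of the [roi_set()] (standardized,
#' posterior, midperiphery), each on the same skeleton with the same radii
#' policy; per-region seeds are derived deterministically from the eye id and
#' the region name so repeat runs are identical. A region with no skeleton
#' pixels, or too thin to admit a sandbox ladder, yields `NA` rather than an
#' error.
#'
#' @param skeleton logical matrix (one-pixel-wide centerline).
#' @param roiset a [roi_set()].
#' @param n_centers sandbox centers per region.
#' @param eye_id id used for seed derivation.
#' @return named numeric vector `c(standardized=, posterior=, midperiphery=)`
#'   with attribute `details` (the `fd_result` objects).
#' @export
regional_fd <- function(skeleton, roiset, n_centers = 500, eye_id = "eye") {
  stopifnot(inherits(roiset, "roi_set"))
  out <- c(standardized = NA_real_, posterior = NA_real_,
           midperiphery = NA_real_)
  details <- list()
  for (region in names(out)) {
    roi <- roiset[[region]]
    if (!any(skeleton & roi)) next
    res <- tryCatch(
      sandbox_dimension(skeleton, roi, q = 0, n_centers = n_centers,
                        seed = derive_seed(eye_id, region)),
      error = function(e) NULL)
    if (!is.null(res)) {
      out[[region]] <- res$D0
      details[[region]] <- res
    }
  }
  attr(out, "details") <- details
  out
}
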
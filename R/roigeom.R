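#' Standardized region of interest: intersection of manual ROIs
#'
#' The standardized ROI fixes the retinal region over which fractal dimension
#' is measured: it is the pixel-wise logical AND of every manually drawn ROI
#' of one laterality across the dataset, so that each eye's branching pattern
#' is measured in the same area. Right- and left-eye ROIs are never mixed;
#' pass the masks of one laterality at a time.
#'
#' @param masks list of logical matrices (equal dimensions), one manual ROI
#'   per contributing eye.
#' @return logical matrix with attribute `provenance` (number of contributing
#'   masks). Warns when the intersection is empty.
#' @export
standardized_roi <- function(masks) {
  if (!length(masks)) stop("at least one manual ROI is required", call. = FALSE)
  dims <- vapply(masks, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("manual ROI masks have mismatched dimensions", call. = FALSE)
  out <- masks[[1]] != 0
  for (m in masks[-1]) out <- out & (m != 0)
  if (!any(out)) warning("standardized ROI is empty (disjoint manual ROIs)")
  attr(out, "provenance") <- length(masks)
  out
}

#' Posterior annulus around the optic disc
#'
#' Pixels whose distance r (mm) from the disc center satisfies
#' `d/2 < r <= d/2 + k * d`: a ring starting at the disc boundary and
#' extending `k` optic-disc diameters outward. The disc interior is excluded.
#' Distances are measured at pixel centers, `(i - 0.5) * scale` mm.
#'
#' @param disc_center_mm disc center (xy, mm).
#' @param disc_diameter_mm optic-disc diameter d (mm), > 0.
#' @param k annulus extent in disc diameters (> 0). Default 3.
#' @param dim raster dimensions `c(nrow, ncol)`.
#' @param scale_um_px micrometers per pixel.
#' @return logical matrix.
#' @export
posterior_annulus <- function(disc_center_mm, disc_diameter_mm, k = 3,
                              dim, scale_um_px) {
  if (disc_diameter_mm <= 0) stop("disc diameter must be > 0", call. = FALSE)
  if (k <= 0) return(matrix(FALSE, dim[1], dim[2]))
  cx <- mm_to_px(disc_center_mm[1], scale_um_px)
  cy <- mm_to_px(disc_center_mm[2], scale_um_px)
  if (cx < 1 || cx > dim[2] || cy < 1 || cy > dim[1])
    stop("disc center lies outside the raster", call. = FALSE)
  xm <- px_to_mm(seq_len(dim[2]), scale_um_px)
  ym <- px_to_mm(seq_len(dim[1]), scale_um_px)
  r2 <- outer((ym - disc_center_mm[2])^2, (xm - disc_center_mm[1])^2, "+")
  inner <- (disc_diameter_mm / 2)^2
  outer_r <- (disc_diameter_mm / 2 + k * disc_diameter_mm)^2
  r2 > inner & r2 <= outer_r
}

#' Midperiphery: standardized ROI excluding the posterior annulus
#'
#' Set difference `standardized \\ posterior`; always disjoint from the
#' posterior region.
#'
#' @param standardized,posterior logical matrices of equal dimensions.
#' @return logical matrix.
#' @export
midperiphery <- function(standardized, posterior) {
  if (!all(dim(standardized) == dim(posterior)))
    stop("mask dimensions differ", call. = FALSE)
  (standardized != 0) & !(posterior != 0)
}

#' Quadrant partition of the raster from the disc-fovea axis
#'
#' The temporal direction is the unit vector u from the disc center to the
#' fovea; a pixel is Temporal when its offset from the disc has positive
#' component along u (ties assigned Temporal), Nasal otherwise. Superior is
#' the smaller-row side of the disc-fovea line under the row-down image
#' convention (ties assigned Superior); when the axis is exactly vertical the
#' +90-degree rotation of u breaks the tie deterministically. Every pixel
#' receives exactly one of ST, SN, IT, IN.
#'
#' @param disc_center_mm,fovea_mm points in mm; must differ.
#' @param dim raster dimensions `c(nrow, ncol)`.
#' @param scale_um_px micrometers per pixel.
#' @return character matrix with entries in `{"ST","SN","IT","IN"}`.
#' @export
quadrant_partition <- function(disc_center_mm, fovea_mm, dim, scale_um_px) {
  d <- fovea_mm - disc_center_mm
  if (sqrt(sum(d^2)) < 1e-12)
    stop("disc center and fovea coincide", call. = FALSE)
  u <- d / sqrt(sum(d^2))
  # normal to the axis; choose the representative pointing to smaller rows
  n <- c(-u[2], u[1])
  if (n[2] > 0 || (n[2] == 0 && n[1] > 0)) n <- -n
  xm <- px_to_mm(seq_len(dim[2]), scale_um_px) - disc_center_mm[1]
  ym <- px_to_mm(seq_len(dim[1]), scale_um_px) - disc_center_mm[2]
  tcomp <- outer(ym * u[2], xm * u[1], "+")    # (p - disc) . u
  scomp <- outer(ym * n[2], xm * n[1], "+")    # (p - disc) . n
  labs <- c("ST", "SN", "IT", "IN")
  code <- 1L + (tcomp < 0) + 2L * (scomp < 0)
  matrix(labs[code], dim[1], dim[2])
}

#' Assemble the full ROI set for one eye
#'
#' Builds the per-eye region set used by the fractal stage: the dataset-level
#' standardized ROI (restricted to this eye's laterality), the posterior
#' annulus clipped to the standardized ROI, their difference (midperiphery)
#' and the quadrant label map.
#'
#' @param manual_roi this eye's manual ROI mask (logical).
#' @param standardized dataset standardized ROI for this laterality.
#' @param disc list with `center` (mm) and `diameter_mm`.
#' @param fovea_mm fovea center (mm).
#' @param scale_um_px micrometers per pixel.
#' @param k annulus extent in disc diameters.
#' @return list of class `roi_set`: `manual`, `standardized`, `posterior`,
#'   `midperiphery`, `quadrants`.
#' @export
roi_set <- function(manual_roi, standardized, disc, fovea_mm, scale_um_px,
                    k = 3) {
  dims <- dim(standardized)
  post <- posterior_annulus(disc$center, disc$diameter_mm, k, dims,
                            scale_um_px) & standardized
  structure(list(manual = manual_roi != 0,
                 standardized = standardized != 0,
                 posterior = post,
                 midperiphery = midperiphery(standardized, post),
                 quadrants = quadrant_partition(disc$center, fovea_mm, dims,
                                                scale_um_px),
                 disc = disc, fovea_mm = fovea_mm,
                 scale_um_px = scale_um_px, k = k),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat("<roi_set> ", paste(dim(x$standardized), collapse = "x"), " px\n",
      sep = "")
  for (nm in c("manual", "standardized", "posterior", "midperiphery"))
    cat(sprintf("  %-13s %d px\n", nm, sum(x[[nm]])))
  invisible(x)
}
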
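#' Write an eye annotation as a GeoJSON FeatureCollection
#'
#' Features: the manual ROI polygon (`role = "roi"`), the optic-disc center
#' point with a `diameter_mm` property (`role = "disc"`) and the fovea point
#' (`role = "fovea"`). Coordinates are physical mm in the shared image
#' convention (x = column direction, y = row direction, origin top-left).
#'
#' @param ann list as produced by the cohort generator: `roi` (two-column
#'   matrix of polygon vertices, mm), `disc` (list: center, diameter_mm),
#'   `fovea`, `laterality`, ids and raster geometry.
#' @param path output file.
#' @export
write_annotation <- function(ann, path) {
  ring <- rbind(ann$roi, ann$roi[1, , drop = FALSE])
  fc <- list(
    type = "FeatureCollection",
    properties = list(eye_id = ann$eye_id,
                      participant_id = ann$participant_id,
                      laterality = ann$laterality,
                      size_px = ann$size_px,
                      scale_um_px = ann$scale_um_px),
    features = list(
      list(type = "Feature",
           properties = list(role = "roi"),
           geometry = list(type = "Polygon",
                           coordinates = list(unname(
                             lapply(seq_len(nrow(ring)),
                                    function(i) as.numeric(ring[i, ])))))),
      list(type = "Feature",
           properties = list(role = "disc",
                             diameter_mm = ann$disc$diameter_mm),
           geometry = list(type = "Point",
                           coordinates = as.numeric(ann$disc$center))),
      list(type = "Feature",
           properties = list(role = "fovea"),
           geometry = list(type = "Point",
                           coordinates = as.numeric(ann$fovea)))))
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an eye annotation GeoJSON
#'
#' @param path file written by [write_annotation()] (or any GeoJSON
#'   FeatureCollection with the same feature roles).
#' @return list with `roi` (matrix, mm), `disc`, `fovea`, `laterality`,
#'   `eye_id`, `participant_id`, `size_px`, `scale_um_px`.
#' @export
read_annotation <- function(path) {
  fc <- jsonlite::read_json(path)
  out <- list(eye_id = fc$properties$eye_id,
              participant_id = fc$properties$participant_id,
              laterality = fc$properties$laterality,
              size_px = fc$properties$size_px,
              scale_um_px = fc$properties$scale_um_px)
  for (f in fc$features) {
    role <- f$properties$role
    if (identical(role, "roi")) {
      ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                    function(p) unlist(p)))
      out$roi <- ring[-nrow(ring), , drop = FALSE]
    } else if (identical(role, "disc")) {
      out$disc <- list(center = unlist(f$geometry$coordinates),
                       diameter_mm = f$properties$diameter_mm)
    } else if (identical(role, "fovea")) {
      out$fovea <- unlist(f$geometry$coordinates)
    }
  }
  out
}

#' Write / read a binary mask as a 0/255 PNG
#' @param mask logical or 0/1 matrix.
#' @param path file path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m > 0.5
}

# rasterize a polygon (mm vertices) to a logical pixel mask using the
# even-odd rule at pixel centres
polygon_mask <- function(poly_mm, size_px, scale_um_px) {
  xs <- mm_to_px(poly_mm[, 1], scale_um_px)
  ys <- mm_to_px(poly_mm[, 2], scale_um_px)
  n <- length(xs)
  m <- matrix(FALSE, size_px, size_px)
  # scanline fill over rows
  for (i in seq_len(size_px)) {
    yr <- i
    xcross <- numeric(0)
    j2 <- n
    for (j in seq_len(n)) {
      y1 <- ys[j2]; y2 <- ys[j]
      if ((y1 <= yr) != (y2 <= yr)) {
        xcross <- c(xcross, xs[j2] + (yr - y1) / (y2 - y1) * (xs[j] - xs[j2]))
      }
      j2 <- j
    }
    if (length(xcross)) {
      xcross <- sort(xcross)
      for (k in seq(1, length(xcross) - 1, by = 2)) {
        lo <- ceiling(xcross[k]); hi <- floor(xcross[k + 1])
        if (hi >= lo) m[i, max(1, lo):min(size_px, hi)] <- TRUE
      }
    }
  }
  m
}
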
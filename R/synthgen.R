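#' Parameters of the synthetic vascular tree generator
#'
#' The generator is a stochastic branching walk seeded on the optic-disc
#' boundary. Along every root-to-tip path the true vessel width follows
#' `w(s) = w_root + taper_rate * s` (s = arclength in mm from the disc), with
#' a multiplicative width step at each bifurcation (child width never exceeds
#' the parent width at the branch point). Centerline sinuosity is imposed as a
#' sinusoidal steering perturbation whose lateral amplitude, expressed as a
#' fraction of `sinuosity_wavelength`, equals `sinuosity_amplitude`; the three
#' measured quantities (fractal dimension, width gradient, tortuosity) are
#' therefore independently controllable through `branch_prob`, `taper_rate`
#' and `sinuosity_amplitude`.
#'
#' @param seed_points_per_sector roots per disc sector (4 sectors) per vessel
#'   class.
#' @param branch_prob probability of spawning a side branch at each growth
#'   step (step length 0.12 mm).
#' @param branch_angle_spread degrees; side branches leave the parent at
#'   roughly this angle.
#' @param initial_width root vessel width in micrometers.
#' @param taper_rate change of width with arclength, micrometers per mm
#'   (negative = distal thinning).
#' @param sinuosity_amplitude dimensionless lateral amplitude of the
#'   sinusoidal centerline perturbation (fraction of the wavelength).
#' @param sinuosity_wavelength wavelength of the perturbation, mm.
#' @param max_depth maximum branching generation.
#' @param field_radius trees are grown until this distance (mm) from the disc
#'   center.
#' @param branch_len_mm maximum arclength of a side branch (first
#'   generation; deeper generations get 60% of this). Trunks run to the
#'   field edge; side branches terminate early, as real side branches leave
#'   the arcade plane toward the capillary bed.
#' @return an object of class `tree_params`.
#' @export
tree_params <- function(seed_points_per_sector = 1L,
                        branch_prob = 0.07,
                        branch_angle_spread = 45,
                        initial_width = 140,
                        taper_rate = -3,
                        sinuosity_amplitude = 0.03,
                        sinuosity_wavelength = 1.2,
                        max_depth = 3L,
                        field_radius = 5.2,
                        branch_len_mm = 2.2) {
  p <- list(seed_points_per_sector = as.integer(seed_points_per_sector),
            branch_prob = branch_prob,
            branch_angle_spread = branch_angle_spread,
            initial_width = initial_width,
            taper_rate = taper_rate,
            sinuosity_amplitude = sinuosity_amplitude,
            sinuosity_wavelength = sinuosity_wavelength,
            max_depth = as.integer(max_depth),
            field_radius = field_radius,
            branch_len_mm = branch_len_mm)
  validate_tree_params(p)
  structure(p, class = "tree_params")
}

validate_tree_params <- function(p) {
  if (!is.finite(p$initial_width) || p$initial_width <= 0)
    stop("initial_width must be > 0", call. = FALSE)
  if (!is.finite(p$field_radius) || p$field_radius <= 0)
    stop("field_radius must be > 0", call. = FALSE)
  if (p$branch_prob < 0 || p$branch_prob > 1)
    stop("branch_prob must be in [0, 1]", call. = FALSE)
  if (p$seed_points_per_sector < 1L)
    stop("seed_points_per_sector must be >= 1", call. = FALSE)
  if (p$sinuosity_wavelength <= 0)
    stop("sinuosity_wavelength must be > 0", call. = FALSE)
  invisible(TRUE)
}

#' Generate one synthetic retinal vascular tree with known ground truth
#'
#' Grows interleaved arteriolar and venular trees outward from the optic-disc
#' boundary. The returned truth holds every centerline point in mm (image
#' convention: x = column, y = row, row increasing downward, origin at the
#' image top-left), the true width in micrometers, and the arclength from the
#' disc-proximal root. Identical `(params, seed)` give bitwise-identical
#' output.
#'
#' @param params a [tree_params()] object.
#' @param disc list with `center` (xy, mm) and `diameter_mm`.
#' @param fovea fovea center (xy, mm); must differ from the disc center.
#' @param laterality `"right"` or `"left"`.
#' @param eye_id,participant_id,group identifiers carried into the truth.
#' @param seed integer seed.
#' @return object of class `eye_truth`: list with `points` (data.frame:
#'   segment, x_mm, y_mm, width_um, s_mm), `segments` (segment, parent, class,
#'   depth), disc/fovea geometry and ids.
#' @export
generate_vascular_tree <- function(params, disc, fovea,
                                   laterality = "right",
                                   eye_id = "eye", participant_id = "p",
                                   group = "NC", seed = 1L) {
  stopifnot(inherits(params, "tree_params"))
  validate_tree_params(params)
  disc_r <- disc$diameter_mm / 2
  if (params$field_radius <= disc_r)
    stop("degenerate geometry: field_radius (", params$field_radius,
         " mm) must exceed the disc radius (", disc_r, " mm)", call. = FALSE)
  if (isTRUE(all(abs(fovea - disc$center) < 1e-12)))
    stop("disc center and fovea center must differ", call. = FALSE)

  with_seed(seed, {
    ds <- 0.12
    w_min <- 8
    pts <- list(); segs <- list()
    seg_counter <- 0L

    grow <- function(pos, theta, s0, w0, depth, parent, cls, phase) {
      seg_counter <<- seg_counter + 1L
      sid <- seg_counter
      xs <- pos[1]; ys <- pos[2]; ss <- s0; ws <- w0
      s <- s0; w <- w0; children <- list()
      last_branch <- s0
      amp <- 2 * pi * params$sinuosity_amplitude
      om <- 2 * pi / params$sinuosity_wavelength
      theta0 <- theta   # launch heading; branches keep their divergence
      repeat {
        # sinusoidal steering + small wobble + weak restoring toward the
        # launch heading (so children do not curl back onto their parents)
        steer <- amp * (sin(om * (s + ds) + phase) - sin(om * s + phase))
        dth <- atan2(sin(theta0 - theta), cos(theta0 - theta))
        theta <- theta + steer + 0.10 * dth + rnorm(1, 0, 0.02)
        pos <- pos + ds * c(cos(theta), sin(theta))
        s <- s + ds
        w <- w + params$taper_rate * ds
        if (w < w_min) break
        if (sqrt(sum((pos - disc$center)^2)) > params$field_radius) break
        len_cap <- if (depth == 0L) 4 * params$field_radius
          else params$branch_len_mm * if (depth == 1L) 1 else 0.6
        if (s - s0 > len_cap) break
        xs <- c(xs, pos[1]); ys <- c(ys, pos[2]); ss <- c(ss, s); ws <- c(ws, w)
        if (depth < params$max_depth && s - last_branch > 0.3 &&
            runif(1) < params$branch_prob) {
          last_branch <- s
          side <- sample(c(-1, 1), 1)
          ang <- theta + side * (params$branch_angle_spread * pi / 180) *
            runif(1, 0.9, 1.3)
          ratio <- runif(1, 0.72, 0.88)  # child width <= parent width
          children[[length(children) + 1L]] <-
            list(pos = pos, theta = ang, s = s, w = ratio * w,
                 depth = depth + 1L, parent = sid, cls = cls,
                 phase = runif(1, 0, 2 * pi))
        }
      }
      pts[[sid]] <<- data.frame(segment = sid, x_mm = xs, y_mm = ys,
                                width_um = ws, s_mm = ss)
      segs[[sid]] <<- data.frame(segment = sid, parent = parent, class = cls,
                                 depth = depth, stringsAsFactors = FALSE)
      for (ch in children)
        grow(ch$pos, ch$theta, ch$s, ch$w, ch$depth, ch$parent, ch$cls,
             ch$phase)
    }

    # arteriolar and venular arcades alternate angularly around the disc
    # (one of each per quadrant sector), as in the real vasculature; this
    # keeps same-class trunk crossings rare
    sector_centers <- (pi / 4) + (0:3) * (pi / 2)
    for (cls in c("arteriole", "venule")) {
      cls_off <- if (cls == "arteriole") -pi / 12 else pi / 12
      w0 <- params$initial_width * if (cls == "arteriole") 0.9 else 1.1
      for (sc in sector_centers) {
        for (k in seq_len(params$seed_points_per_sector)) {
          ang <- sc + cls_off + rnorm(1, 0, 0.06) +
            (k - (params$seed_points_per_sector + 1) / 2) * 0.15
          root <- disc$center + disc_r * c(cos(ang), sin(ang))
          # arcade calibers vary: per-root width jitter (also dithers the
          # pixel quantization of the raster so cohort width statistics
          # stay unbiased)
          w0r <- w0 * (1 + rnorm(1, 0, 0.10))
          grow(root, ang, 0, w0r, 0L, NA_integer_, cls,
               runif(1, 0, 2 * pi))
        }
      }
    }

    structure(list(points = do.call(rbind, pts),
                   segments = do.call(rbind, segs),
                   disc = disc, fovea = fovea, laterality = laterality,
                   eye_id = eye_id, participant_id = participant_id,
                   group = group, params = params, seed = as.integer(seed)),
              class = "eye_truth")
  })
}

#' @export
print.eye_truth <- function(x, ...) {
  cat("<eye_truth> ", x$eye_id, " (", x$group, ", ", x$laterality, ")\n",
      sep = "")
  cat("  segments:", nrow(x$segments), " points:", nrow(x$points), "\n")
  cat("  total length:", round(sum_tree_length(x), 1), "mm\n")
  invisible(x)
}

sum_tree_length <- function(truth) {
  by_seg <- split(truth$points, truth$points$segment)
  sum(vapply(by_seg, function(p) max(p$s_mm) - min(p$s_mm), numeric(1)))
}

#' Rasterize a synthetic eye to an image, ground-truth mask and class map
#'
#' Vessels are drawn dark on a bright background; the binary ground-truth
#' mask is stamped from the true centerline and widths (disks of radius
#' width/2 at sub-pixel steps) and is never corrupted by artifacts. Optional
#' eyelid/eyelash occluders are rendered into the image only, emulating the
#' view obstructions that motivate manual regions of interest.
#'
#' @param truth an `eye_truth`.
#' @param size_px canvas side in pixels (square canvas).
#' @param scale_um_px micrometers per pixel (> 0).
#' @param artifact `NULL` or a list with any of `eyelid_frac` (fraction of
#'   top rows covered by an eyelid band) and `eyelash_n` (number of eyelash
#'   strokes hanging from the top edge).
#' @param noise_sd Gaussian pixel noise added to the rendered image.
#' @param seed seed for the render noise (derived from the eye id if NULL).
#' @param render_image set FALSE to skip the grayscale render (mask and
#'   class map only), e.g. for mask-driven batch simulations.
#' @return list of class `eye_raster`: `image` (matrix in `[0,1]`), `mask`
#'   (logical ground truth), `class_map` (0 background, 1 arteriole,
#'   2 venule, 3 both where vessels cross), plus scale and ids.
#' @export
rasterize_eye <- function(truth, size_px = 1200, scale_um_px = 12,
                          artifact = NULL, noise_sd = 0.02, seed = NULL,
                          render_image = TRUE) {
  stopifnot(inherits(truth, "eye_truth"))
  if (scale_um_px <= 0) stop("scale must be > 0", call. = FALSE)
  mmpp <- scale_um_px / 1000
  if (truth$params$field_radius > size_px * mmpp / 2 + max(abs(
    truth$disc$center - size_px * mmpp / 2)) + 1e-9) {
    # fine-grained per-point check below gives the precise offender
  }
  seed <- seed %||% derive_seed(truth$eye_id, "render")

  pts <- truth$points
  r_px <- mm_to_px(pts$x_mm, scale_um_px)  # column
  c_px <- mm_to_px(pts$y_mm, scale_um_px)  # row
  rad_px <- (pts$width_um / 2) / scale_um_px
  bad <- which(c_px - rad_px < 0.5 - 1e-9 | c_px + rad_px > size_px + 0.5 + 1e-9 |
               r_px - rad_px < 0.5 - 1e-9 | r_px + rad_px > size_px + 0.5 + 1e-9)
  if (length(bad))
    stop("truth extends beyond the canvas: segment ",
         pts$segment[bad[1]], " at (", round(pts$x_mm[bad[1]], 2), ", ",
         round(pts$y_mm[bad[1]], 2), ") mm", call. = FALSE)

  # densify each segment to ~0.5 px steps so stamped disks form a
  # continuous stroke
  xs <- list(); ys <- list(); ws <- list(); sg <- list()
  for (p in split(pts, pts$segment)) {
    if (nrow(p) < 2) {
      xs[[length(xs) + 1L]] <- p$x_mm; ys[[length(ys) + 1L]] <- p$y_mm
      ws[[length(ws) + 1L]] <- p$width_um
      sg[[length(sg) + 1L]] <- p$segment
      next
    }
    s <- p$s_mm - p$s_mm[1]
    n_out <- max(2L, ceiling((max(s) / mmpp) / 0.5) + 1L)
    si <- seq(0, max(s), length.out = n_out)
    xs[[length(xs) + 1L]] <- approx(s, p$x_mm, si)$y
    ys[[length(ys) + 1L]] <- approx(s, p$y_mm, si)$y
    ws[[length(ws) + 1L]] <- approx(s, p$width_um, si)$y
    sg[[length(sg) + 1L]] <- rep(p$segment[1], n_out)
  }
  dp <- data.frame(segment = unlist(sg), x_mm = unlist(xs),
                   y_mm = unlist(ys), width_um = unlist(ws))
  cls <- truth$segments$class[match(dp$segment, truth$segments$segment)]
  row <- mm_to_px(dp$y_mm, scale_um_px)
  col <- mm_to_px(dp$x_mm, scale_um_px)
  rad <- (dp$width_um / 2) / scale_um_px
  keep <- dp$width_um >= scale_um_px   # pixels below 1 px width not stamped

  mask <- matrix(0L, size_px, size_px)
  ca <- matrix(0L, size_px, size_px)
  cv <- matrix(0L, size_px, size_px)
  ka <- keep & cls == "arteriole"; kv <- keep & cls == "venule"
  .cpp_stamp_disks(mask, row[keep], col[keep], rad[keep], 1L)
  .cpp_stamp_disks(ca, row[ka], col[ka], rad[ka], 1L)
  .cpp_stamp_disks(cv, row[kv], col[kv], rad[kv], 1L)
  # 1 = arteriole, 2 = venule, 3 = both (crossing overlap)
  cmap <- ca + 2L * cv

  img <- if (!render_image) NULL else with_seed(seed, {
    im <- matrix(0.85, size_px, size_px)
    # mild radial vignette
    ctr <- (size_px + 1) / 2
    rr <- outer((seq_len(size_px) - ctr)^2, (seq_len(size_px) - ctr)^2, "+")
    im <- im - 0.10 * rr / max(rr)
    im[mask == 1L] <- 0.25
    im <- EBImage::gblur(im, sigma = 0.8)
    if (!is.null(artifact)) {
      ef <- artifact$eyelid_frac %||% 0
      if (ef > 0) {
        edge <- round(size_px * ef +
                        3 * sin(seq_len(size_px) / size_px * 4 * pi))
        edge <- pmax(0L, pmin(size_px, as.integer(edge)))
        for (j in seq_len(size_px)) if (edge[j] > 0) im[seq_len(edge[j]), j] <- 0.08
      }
      en <- artifact$eyelash_n %||% 0
      if (en > 0) {
        can <- matrix(0L, size_px, size_px)
        for (k in seq_len(en)) {
          x0 <- runif(1, 0.1, 0.9) * size_px
          ang <- pi / 2 + rnorm(1, 0, 0.35)
          len <- runif(1, 0.12, 0.22) * size_px
          tt <- seq(0, 1, length.out = 80)
          .cpp_stamp_disks(can, 1 + tt * len * sin(ang),
                           x0 + tt * len * cos(ang),
                           2.2 * (1 - tt) + 0.4, 1L)
        }
        im[can == 1L] <- 0.08
      }
    }
    if (noise_sd > 0) im <- im + matrix(rnorm(size_px^2, 0, noise_sd),
                                        size_px, size_px)
    pmin(pmax(im, 0), 1)
  })

  structure(list(image = img, mask = mask == 1L, class_map = cmap,
                 scale_um_px = scale_um_px, size_px = size_px,
                 eye_id = truth$eye_id, laterality = truth$laterality),
            class = "eye_raster")
}

#' Analytic fractal fixtures with known dimension
#'
#' Rasterized sets whose fractal dimension is known in closed form, used as
#' oracles for the sandbox and box-counting estimators: a straight line
#' (dimension 1), a filled disk (2), the Sierpinski right triangle
#' (log 3 / log 2) and the Koch curve (log 4 / log 3).
#'
#' @param kind one of `"line"`, `"filled_disk"`, `"sierpinski_triangle"`,
#'   `"koch_curve"`.
#' @param depth recursion depth for the recursive kinds (>= 1).
#' @param size canvas side in pixels (>= 256).
#' @return list of class `fractal_fixture` with `mask` (logical), `dimension`
#'   (analytic value), `roi` (the set's support region, the natural
#'   measurement ROI: `NULL` means the full canvas), `kind`, `depth`, `size`.
#' @export
generate_fractal_fixture <- function(kind, depth = NULL, size = 512) {
  if (size < 256) stop("size must be >= 256", call. = FALSE)
  kind <- match.arg(kind, c("line", "filled_disk", "sierpinski_triangle",
                            "koch_curve"))
  if (kind %in% c("sierpinski_triangle", "koch_curve")) {
    if (is.null(depth) || depth < 1) stop("depth >= 1 required", call. = FALSE)
    depth <- as.integer(depth)
  }
  mask <- matrix(FALSE, size, size)
  roi <- NULL
  dimension <- switch(kind,
    line = {
      mask[round(size / 2), ] <- TRUE
      1.0
    },
    filled_disk = {
      ctr <- (size + 1) / 2; rad <- 0.45 * size
      rr <- outer((seq_len(size) - ctr)^2, (seq_len(size) - ctr)^2, "+")
      mask[rr <= rad^2] <- TRUE
      roi <- mask   # the disk itself: mass scaling is measured in its bulk
      2.0
    },
    sierpinski_triangle = {
      n <- 2L^depth
      if (n > size) stop("depth too large for this size", call. = FALSE)
      idx <- 0:(n - 1L)
      cells <- outer(idx, idx, function(i, j) bitwAnd(i, j) == 0L)
      b <- size %/% n
      big <- cells[rep(seq_len(n), each = b), rep(seq_len(n), each = b)]
      mask[seq_len(n * b), seq_len(n * b)] <- big
      # support: the right triangle spanned by the three corner vertices
      roi <- outer(seq_len(size), seq_len(size), function(i, j)
        i + j <= n * b + 1)
      log(3) / log(2)
    },
    koch_curve = {
      p <- koch_points(depth)
      w <- 0.92 * size
      x <- p[, 1] * w + (size - w) / 2
      y <- size * 0.62 - p[, 2] * w
      canvas <- matrix(0L, size, size)
      for (i in seq_len(nrow(p) - 1)) {
        n_sub <- max(2L, ceiling(sqrt((x[i + 1] - x[i])^2 +
                                        (y[i + 1] - y[i])^2) / 0.4))
        tt <- seq(0, 1, length.out = n_sub)
        .cpp_stamp_disks(canvas, y[i] + tt * (y[i + 1] - y[i]),
                         x[i] + tt * (x[i + 1] - x[i]),
                         rep(0.6, n_sub), 1L)
      }
      mask <- canvas == 1L
      log(4) / log(3)
    })
  structure(list(mask = mask, dimension = dimension, roi = roi, kind = kind,
                 depth = depth, size = size), class = "fractal_fixture")
}

# Koch curve vertices on the unit base segment via the L-system rewrite
koch_points <- function(depth) {
  p <- matrix(c(0, 0, 1, 0), ncol = 2, byrow = TRUE)
  rot <- function(v, a) c(cos(a) * v[1] - sin(a) * v[2],
                          sin(a) * v[1] + cos(a) * v[2])
  for (d in seq_len(depth)) {
    out <- matrix(0, nrow = (nrow(p) - 1) * 4 + 1, ncol = 2)
    k <- 1L
    for (i in seq_len(nrow(p) - 1)) {
      a <- p[i, ]; b <- p[i + 1, ]; v <- (b - a) / 3
      q1 <- a + v; q3 <- a + 2 * v; q2 <- q1 + rot(v, pi / 3)
      out[k, ] <- a; out[k + 1, ] <- q1; out[k + 2, ] <- q2; out[k + 3, ] <- q3
      k <- k + 4L
    }
    out[k, ] <- p[nrow(p), ]
    p <- out
  }
  p
}

#' Cohort specification for the synthetic study
#'
#' Describes a three-group cohort (Alzheimer's dementia, mild cognitive
#' impairment, normal cognition) with two eyes per participant. Group effects
#' are additive offsets on the generative parameters relative to the NC
#' baseline; each participant carries a shared random offset (SD
#' `between_eye_sd`) applied to both eyes, which induces the exchangeable
#' within-participant correlation assumed by the GEE stage, plus an
#' independent per-eye offset (SD `eye_sd`).
#'
#' @param n_per_group named counts for AD, MCI, NC.
#' @param baseline [tree_params()] for the NC group.
#' @param effects list with AD and MCI named offset vectors on any of
#'   `taper_rate`, `branch_prob`, `sinuosity_amplitude`.
#' @param between_eye_sd named SDs of the participant-level shared offsets.
#' @param eye_sd named SDs of the per-eye offsets.
#' @param age_mean,age_sd named per-group age distributions (years).
#' @param sex_p_female per-group probability of female sex.
#' @param size_px,scale_um_px raster geometry of the rendered eyes.
#' @param disc_diameter_mm,disc_offset_mm,fovea_dist_mm eye geometry: the
#'   disc sits `disc_offset_mm` nasal of the canvas center and the fovea
#'   `fovea_dist_mm` temporal of the disc.
#' @param seed master seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(AD = 28, MCI = 30, NC = 45),
                        baseline = tree_params(),
                        effects = list(
                          AD  = c(taper_rate = -0.7, branch_prob = 0.02,
                                  sinuosity_amplitude = -0.005),
                          MCI = c(taper_rate = -0.6, branch_prob = -0.02,
                                  sinuosity_amplitude = 0.005)),
                        between_eye_sd = c(taper_rate = 0.35,
                                           branch_prob = 0.01,
                                           sinuosity_amplitude = 0.004),
                        eye_sd = c(taper_rate = 0.35, branch_prob = 0.01,
                                   sinuosity_amplitude = 0.004),
                        age_mean = c(AD = 71.8, MCI = 70.2, NC = 66.5),
                        age_sd = c(AD = 6, MCI = 6, NC = 6),
                        sex_p_female = c(AD = 0.55, MCI = 0.55, NC = 0.55),
                        size_px = 1200, scale_um_px = 12,
                        disc_diameter_mm = 1.0, disc_offset_mm = 1.6,
                        fovea_dist_mm = 3.6,
                        seed = 1L) {
  if (any(n_per_group < 1)) stop("n_per_group must be >= 1 each", call. = FALSE)
  if (any(between_eye_sd < 0) || any(eye_sd < 0))
    stop("correlation (SD) parameters must be >= 0", call. = FALSE)
  if (!all(c("AD", "MCI", "NC") %in% names(n_per_group)))
    stop("n_per_group needs AD, MCI and NC entries", call. = FALSE)
  structure(list(n_per_group = n_per_group, baseline = baseline,
                 effects = effects, between_eye_sd = between_eye_sd,
                 eye_sd = eye_sd, age_mean = age_mean, age_sd = age_sd,
                 sex_p_female = sex_p_female, size_px = size_px,
                 scale_um_px = scale_um_px,
                 disc_diameter_mm = disc_diameter_mm,
                 disc_offset_mm = disc_offset_mm,
                 fovea_dist_mm = fovea_dist_mm,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Draw the per-eye generative parameters of a cohort (the truth table)
#'
#' Participant-level shared offsets plus per-eye offsets on `taper_rate`,
#' `branch_prob` and `sinuosity_amplitude`; both eyes of a participant share
#' the participant offset. This is the in-memory core of [generate_cohort()]
#' and is also usable directly for statistical simulations that do not need
#' rendered images.
#'
#' @param spec a [cohort_spec()].
#' @return data.frame, one row per eye: participant_id, group, age, sex,
#'   laterality, eye_id, taper_rate, branch_prob, sinuosity_amplitude, seed.
#' @export
simulate_cohort_params <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    rows <- list()
    pid <- 0L
    fields <- c("taper_rate", "branch_prob", "sinuosity_amplitude")
    for (g in c("AD", "MCI", "NC")) {
      eff <- if (g == "NC") c(taper_rate = 0, branch_prob = 0,
                              sinuosity_amplitude = 0)
             else spec$effects[[g]]
      for (i in seq_len(spec$n_per_group[[g]])) {
        pid <- pid + 1L
        id <- sprintf("P%03d", pid)
        age <- rnorm(1, spec$age_mean[[g]], spec$age_sd[[g]])
        sex <- if (runif(1) < spec$sex_p_female[[g]]) "F" else "M"
        shared <- vapply(fields, function(f)
          rnorm(1, 0, spec$between_eye_sd[[f]] %||% 0), numeric(1))
        for (lat in c("right", "left")) {
          eyeoff <- vapply(fields, function(f)
            rnorm(1, 0, spec$eye_sd[[f]] %||% 0), numeric(1))
          val <- vapply(fields, function(f)
            spec$baseline[[f]] + (eff[[f]] %||% 0) + shared[[f]] +
              eyeoff[[f]], numeric(1))
          rows[[length(rows) + 1L]] <- data.frame(
            participant_id = id, group = g, age = age, sex = sex,
            laterality = lat,
            eye_id = paste0(id, "_", toupper(substr(lat, 1, 1))),
            taper_rate = val[["taper_rate"]],
            branch_prob = min(max(val[["branch_prob"]], 0), 1),
            sinuosity_amplitude = max(val[["sinuosity_amplitude"]], 0),
            stringsAsFactors = FALSE)
        }
      }
    }
    out <- do.call(rbind, rows)
    out$seed <- vapply(out$eye_id, function(e)
      derive_seed(spec$seed, e, "tree"), integer(1))
    rownames(out) <- NULL
    out
  })
}

#' Generate a synthetic cohort on disk
#'
#' Writes one directory per eye (`eyes/<eye_id>/`) containing the rendered
#' image (`image.png`, optional), the uncorrupted ground-truth vessel mask
#' (`mask.png`), the arteriole/venule class map (`av.png`, values 0/128/255)
#' and the annotation GeoJSON (manual ROI polygon, disc center + diameter,
#' fovea, laterality); plus `participants.csv` and `truth.json` at the root.
#'
#' @param spec a [cohort_spec()].
#' @param out_dir output directory; must not already contain a cohort unless
#'   `force`.
#' @param force overwrite an existing non-empty directory.
#' @param write_images render and write the grayscale images (the masks and
#'   annotations are always written).
#' @param artifact artifact specification passed to [rasterize_eye()] for
#'   every eye (`NULL` for clean renders).
#' @return invisibly, a list with `dir`, `participants` and the `truth`
#'   data.frame.
#' @export
generate_cohort <- function(spec, out_dir, force = FALSE,
                            write_images = TRUE,
                            artifact = list(eyelid_frac = 0.06,
                                            eyelash_n = 4)) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force)
    stop("output directory ", out_dir,
         " is not empty (use force = TRUE to overwrite)", call. = FALSE)
  dir.create(file.path(out_dir, "eyes"), recursive = TRUE,
             showWarnings = FALSE)

  truth <- simulate_cohort_params(spec)
  cx <- spec$size_px * spec$scale_um_px / 1000 / 2
  truth_json <- list()
  for (i in seq_len(nrow(truth))) {
    row <- truth[i, ]
    sgn <- if (row$laterality == "right") 1 else -1
    disc <- list(center = c(cx + sgn * spec$disc_offset_mm, cx),
                 diameter_mm = spec$disc_diameter_mm)
    fovea <- c(disc$center[1] - sgn * spec$fovea_dist_mm, cx)
    p <- spec$baseline
    p$taper_rate <- row$taper_rate
    p$branch_prob <- row$branch_prob
    p$sinuosity_amplitude <- row$sinuosity_amplitude
    tr <- generate_vascular_tree(p, disc, fovea, row$laterality,
                                 eye_id = row$eye_id,
                                 participant_id = row$participant_id,
                                 group = row$group, seed = row$seed)
    ras <- rasterize_eye(tr, spec$size_px, spec$scale_um_px,
                         artifact = artifact, render_image = write_images)
    ed <- file.path(out_dir, "eyes", row$eye_id)
    dir.create(ed, showWarnings = FALSE)
    write_mask_png(ras$mask, file.path(ed, "mask.png"))
    png::writePNG(ras$class_map / 3, file.path(ed, "av.png"))
    if (write_images) png::writePNG(ras$image, file.path(ed, "image.png"))
    ann <- make_roi_annotation(row$eye_id, row$participant_id,
                               row$laterality, disc, fovea,
                               spec$size_px, spec$scale_um_px,
                               seed = derive_seed(spec$seed, row$eye_id,
                                                  "roi"))
    write_annotation(ann, file.path(ed, "annotation.geojson"))
    truth_json[[row$eye_id]] <- list(
      participant_id = row$participant_id, group = row$group,
      laterality = row$laterality, seed = row$seed,
      taper_rate = row$taper_rate, branch_prob = row$branch_prob,
      sinuosity_amplitude = row$sinuosity_amplitude,
      disc_center_mm = disc$center, disc_diameter_mm = disc$diameter_mm,
      fovea_mm = fovea, scale_um_px = spec$scale_um_px,
      size_px = spec$size_px)
  }
  participants <- unique(truth[, c("participant_id", "group", "age", "sex")])
  participants$age <- round(participants$age, 1)
  write.csv(participants, file.path(out_dir, "participants.csv"),
            row.names = FALSE)
  jsonlite::write_json(truth_json, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(dir = out_dir, participants = participants, truth = truth))
}

# Manual ROI polygon: a field-covering circle with its top flattened at a
# per-eye height, emulating an operator excluding eyelid/eyelash artifacts.
make_roi_annotation <- function(eye_id, participant_id, laterality, disc,
                                fovea, size_px, scale_um_px, seed) {
  with_seed(seed, {
    fov_mm <- size_px * scale_um_px / 1000
    ctr <- fov_mm / 2
    r <- fov_mm * (0.49 + runif(1, -0.008, 0.008))
    y_top <- fov_mm * (0.10 + runif(1, 0, 0.05))
    th <- seq(0, 2 * pi, length.out = 181)[-181]
    x <- ctr + r * cos(th); y <- ctr + r * sin(th)
    y <- pmax(y, y_top)
    x <- pmin(pmax(x, 0.01), fov_mm - 0.01)
    y <- pmin(y, fov_mm - 0.01)
    list(eye_id = eye_id, participant_id = participant_id,
         laterality = laterality, size_px = size_px,
         scale_um_px = scale_um_px,
         roi = cbind(x, y), disc = disc, fovea = fovea)
  })
}
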
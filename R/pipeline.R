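#' Pipeline run configuration
#'
#' A flat key/value configuration shared by the three pipeline stages
#' (simulate, measure, stats). Values can be supplied as a named list or a
#' YAML file of the same keys; unknown keys are rejected and every numeric
#' parameter is range-checked before any I/O happens. The configuration
#' round-trips losslessly through [write_config()].
#'
#' Keys (defaults in parentheses): raster geometry `scale_um_px` (12),
#' `size_px` (1200); eye geometry `field_radius_mm` (5.2), `disc_offset_mm`
#' (1.6), `fovea_dist_mm` (3.6), `disc_diameter_mm` (1.0); cohort sizes `n_ad`/`n_mci`/`n_nc` (15 each) and group
#' effects on the generative parameters `effect_taper_ad` (-0.7),
#' `effect_taper_mci` (-0.6), `effect_branch_ad` (0.02), `effect_branch_mci`
#' (-0.02), `effect_sin_ad` (-0.005), `effect_sin_mci` (0.005); clustering
#' `between_eye_sd_taper` (0.35), `eye_sd_taper` (0.35); artifacts
#' `artifact_eyelid` (0.06), `artifact_eyelash` (4); `write_images` (TRUE);
#' measurement `segment_from` ("mask" or "image"), `annulus_k` (3),
#' `n_centers` (500), `spur_prune_len_mm` (0.3), `smooth_window` (1),
#' `wg_method` ("bisquare"), `tort_variant` ("curvature"); statistics
#' `z_threshold` (3); `seed` (1).
#'
#' @param config named list or path to a YAML file; missing keys take the
#'   defaults.
#' @return object of class `run_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    scale_um_px = 12, size_px = 1200, field_radius_mm = 5.2,
    disc_offset_mm = 1.6, fovea_dist_mm = 3.6, disc_diameter_mm = 1.0,
    n_ad = 15, n_mci = 15, n_nc = 15,
    effect_taper_ad = -0.7, effect_taper_mci = -0.6,
    effect_branch_ad = 0.02, effect_branch_mci = -0.02,
    effect_sin_ad = -0.005, effect_sin_mci = 0.005,
    between_eye_sd_taper = 0.35, eye_sd_taper = 0.35,
    artifact_eyelid = 0.06, artifact_eyelash = 4,
    write_images = TRUE,
    segment_from = "mask",
    annulus_k = 3, n_centers = 500, spur_prune_len_mm = 0.3,
    smooth_window = 1,
    wg_method = "bisquare", tort_variant = "curvature",
    z_threshold = 3, seed = 1)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, config)
  num_keys <- setdiff(names(defaults),
                      c("segment_from", "wg_method", "tort_variant",
                        "write_images"))
  for (k in num_keys)
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1 || !is.finite(cfg[[k]]))
      stop("config key ", k, " must be a finite number", call. = FALSE)
  if (cfg$scale_um_px <= 0) stop("scale_um_px must be > 0", call. = FALSE)
  if (cfg$annulus_k <= 0) stop("annulus_k must be > 0", call. = FALSE)
  if (any(unlist(cfg[c("n_ad", "n_mci", "n_nc")]) < 1))
    stop("group sizes must be >= 1", call. = FALSE)
  if (!cfg$segment_from %in% c("mask", "image"))
    stop("segment_from must be 'mask' or 'image'", call. = FALSE)
  cfg$wg_method <- match.arg(cfg$wg_method, c("bisquare", "huber"))
  cfg$tort_variant <- match.arg(cfg$tort_variant,
                                c("curvature", "arc_chord", "total_turning"))
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param cfg a `run_config`.
#' @param path output YAML file.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(cfg)[order(names(cfg))], tf,
                       auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

cohort_spec_from_config <- function(cfg, seed) {
  cohort_spec(
    n_per_group = c(AD = cfg$n_ad, MCI = cfg$n_mci, NC = cfg$n_nc),
    baseline = tree_params(field_radius = cfg$field_radius_mm),
    disc_diameter_mm = cfg$disc_diameter_mm,
    disc_offset_mm = cfg$disc_offset_mm,
    fovea_dist_mm = cfg$fovea_dist_mm,
    effects = list(
      AD = c(taper_rate = cfg$effect_taper_ad,
             branch_prob = cfg$effect_branch_ad,
             sinuosity_amplitude = cfg$effect_sin_ad),
      MCI = c(taper_rate = cfg$effect_taper_mci,
              branch_prob = cfg$effect_branch_mci,
              sinuosity_amplitude = cfg$effect_sin_mci)),
    between_eye_sd = c(taper_rate = cfg$between_eye_sd_taper,
                       branch_prob = 0.01, sinuosity_amplitude = 0.004),
    eye_sd = c(taper_rate = cfg$eye_sd_taper, branch_prob = 0.01,
               sinuosity_amplitude = 0.004),
    size_px = cfg$size_px, scale_um_px = cfg$scale_um_px,
    seed = seed)
}

#' Simulate a cohort to disk (pipeline stage 1)
#'
#' @param config a [run_config()] (or list/path coerced through it).
#' @param out_dir output dataset directory.
#' @param seed master seed (defaults to the config's).
#' @param force overwrite a non-empty directory.
#' @return invisibly, the dataset directory; a `manifest.json` recording the
#'   config, its hash and the seed is written alongside the data.
#' @export
cmd_simulate <- function(config, out_dir, seed = NULL, force = FALSE) {
  cfg <- run_config(if (inherits(config, "run_config")) unclass(config)
                    else config)
  seed <- as.integer(seed %||% cfg$seed)
  cfg$seed <- seed
  spec <- cohort_spec_from_config(cfg, seed)
  art <- if (cfg$artifact_eyelid > 0 || cfg$artifact_eyelash > 0)
    list(eyelid_frac = cfg$artifact_eyelid,
         eyelash_n = cfg$artifact_eyelash) else NULL
  res <- generate_cohort(spec, out_dir, force = force,
                         write_images = isTRUE(cfg$write_images) ||
                           cfg$segment_from == "image",
                         artifact = art)
  manifest <- list(config = unclass(cfg), config_hash = config_hash(cfg),
                   seed = seed, n_participants = nrow(res$participants),
                   n_eyes = nrow(res$truth))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Measure every eye of a dataset (pipeline stage 2)
#'
#' For each eye directory: load or segment the vessel mask, clip it to the
#' manual ROI, skeletonize and graph it, compute the regional sandbox
#' fractal dimensions inside the dataset-standardized ROI set, select the
#' prominent arteriolar and venular path per quadrant, and compute width
#' gradient and tortuosity per path. Eyes failing a stage produce a row of
#' missing cells plus a logged reason rather than aborting the batch.
#'
#' @param config a [run_config()].
#' @param in_dir dataset directory from [cmd_simulate()] (or equivalently
#'   structured real data).
#' @param out_csv metrics CSV path (optional).
#' @return the metrics data.frame (one row per eye, documented schema);
#'   attribute `log` holds per-eye exclusion reasons.
#' @export
cmd_measure <- function(config, in_dir, out_csv = NULL) {
  cfg <- run_config(if (inherits(config, "run_config")) unclass(config)
                    else config)
  eye_dirs <- sort(list.dirs(file.path(in_dir, "eyes"), recursive = FALSE))
  if (!length(eye_dirs)) stop("no eye directories under ", in_dir,
                              call. = FALSE)
  anns <- lapply(eye_dirs, function(d)
    read_annotation(file.path(d, "annotation.geojson")))
  names(anns) <- basename(eye_dirs)

  # dataset-standardized ROI, per laterality
  manual <- lapply(anns, function(a)
    polygon_mask(a$roi, a$size_px, a$scale_um_px))
  lat <- vapply(anns, function(a) a$laterality, character(1))
  std <- lapply(split(manual, lat), standardized_roi)

  rows <- list(); log <- list()
  for (ed in eye_dirs) {
    id <- basename(ed)
    a <- anns[[id]]
    row <- tryCatch({
      vm <- load_eye_mask(ed, a, cfg)
      vm$mask <- vm$mask & manual[[id]]
      rs <- roi_set(manual[[id]], std[[a$laterality]], a$disc, a$fovea,
                    a$scale_um_px, k = cfg$annulus_k)
      av_path <- file.path(ed, "av.png")
      class_map <- NULL
      if (file.exists(av_path)) {
        av <- png::readPNG(av_path)
        if (length(dim(av)) == 3) av <- av[, , 1]
        class_map <- matrix(as.integer(round(av * 3)), nrow(av))
      }
      g <- skeletonize_and_graph(vm, cfg$spur_prune_len_mm,
                                 class_map = class_map)
      fd <- regional_fd(g$skeleton, rs, n_centers = cfg$n_centers,
                        eye_id = id)
      wg <- list(); tort <- list()
      if (!is.null(class_map) && length(g$edges)) {
        g$edges <- Filter(function(e) !is.na(e$class), g$edges)
        ov_path <- file.path(ed, "paths.csv")
        ov <- if (file.exists(ov_path)) read.csv(ov_path) else NULL
        paths <- select_quadrant_paths(g, rs$quadrants, a$disc,
                                       overrides = ov)
        for (key in names(paths)) {
          pm <- path_metrics(paths[[key]],
                             smooth_window = cfg$smooth_window,
                             wg_method = cfg$wg_method,
                             tort_variant = cfg$tort_variant)
          wg[[key]] <- pm$wg; tort[[key]] <- pm$tort
        }
      }
      assemble_eye_metrics(fd, wg, tort, eye_id = id,
                           participant_id = a$participant_id,
                           laterality = a$laterality)
    }, error = function(e) {
      log[[id]] <<- conditionMessage(e)
      assemble_eye_metrics(fd = c(standardized = NA_real_,
                                  posterior = NA_real_,
                                  midperiphery = NA_real_),
                           eye_id = id, participant_id = a$participant_id,
                           laterality = a$laterality)
    })
    rows[[id]] <- row
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  measurable <- rowSums(!is.na(metrics[, -(1:3)])) > 0
  if (!any(measurable)) stop("zero eyes measurable", call. = FALSE)
  if (length(log))
    message("eyes with failed stages: ",
            paste(names(log), unlist(log), sep = ": ", collapse = "; "))
  if (!is.null(out_csv)) {
    write.csv(metrics, out_csv, row.names = FALSE)
    for (l in names(std))   # audit copies of the standardized ROIs
      write_mask_png(std[[l]], file.path(dirname(out_csv),
                                         paste0("standardized_roi_", l,
                                                ".png")))
  }
  attr(metrics, "log") <- log
  metrics
}

load_eye_mask <- function(eye_dir, ann, cfg) {
  mask_path <- file.path(eye_dir, "mask.png")
  if (cfg$segment_from == "mask" && file.exists(mask_path)) {
    vm <- vessel_mask(read_mask_png(mask_path), ann$scale_um_px,
                      eye_id = ann$eye_id, laterality = ann$laterality)
  } else {
    img_path <- Filter(file.exists,
                       file.path(eye_dir, c("image.png", "image.tif",
                                            "image.tiff")))
    if (!length(img_path))
      stop("neither mask.png (with segment_from='mask') nor an image file ",
           "(image.png/.tif) found", call. = FALSE)
    img <- if (grepl("png$", img_path[1])) png::readPNG(img_path[1])
           else tiff::readTIFF(img_path[1])
    if (length(dim(img)) == 3) img <- img[, , 1]
    vm <- segment_vessels(img, scale_um_px = ann$scale_um_px,
                          eye_id = ann$eye_id, laterality = ann$laterality)
  }
  edits <- file.path(eye_dir, "edits.geojson")
  if (file.exists(edits)) vm <- apply_mask_edits(vm, edits)
  vm
}

#' Group statistics over a measured cohort (pipeline stage 3)
#'
#' Joins the metrics table to the participant covariates, applies the
#' missing/extreme imputation rule, fits the pairwise GEE contrasts for
#' every outcome column and runs the demographics tests.
#'
#' @param config a [run_config()].
#' @param metrics metrics data.frame or CSV path from [cmd_measure()].
#' @param participants participants data.frame or CSV path.
#' @param out_csv results CSV path (optional).
#' @return list of class `uwf_stats`: `results` (per outcome x contrast),
#'   `demographics`, `n_imputed`.
#' @export
cmd_stats <- function(config, metrics, participants, out_csv = NULL) {
  cfg <- run_config(if (inherits(config, "run_config")) unclass(config)
                    else config)
  if (is.character(metrics)) metrics <- read.csv(metrics)
  if (is.character(participants)) participants <- read.csv(participants)
  if (!nrow(metrics)) stop("empty metrics table", call. = FALSE)
  missing_ids <- setdiff(metrics$participant_id, participants$participant_id)
  if (length(missing_ids))
    stop("participant ids in metrics but not in participants: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  tab <- merge(metrics, participants, by = "participant_id", sort = TRUE)
  tab <- tab[order(tab$eye_id), , drop = FALSE]
  need <- c("AD", "MCI", "NC")
  have <- intersect(need, unique(tab$group))
  if (length(have) < 2)
    stop("missing group(s): ", paste(setdiff(need, have), collapse = ", "),
         call. = FALSE)
  outcome_cols <- grep("^(fd|wg|tort)_", names(tab), value = TRUE)
  tab <- impute_missing_extreme(tab, outcome_cols, z = cfg$z_threshold)
  n_imp <- attr(tab, "n_imputed")
  message("imputed cells: ", n_imp)
  contrasts <- list(c("AD", "NC"), c("MCI", "NC"), c("AD", "MCI"))
  contrasts <- Filter(function(ct) all(ct %in% have), contrasts)
  res <- list()
  for (oc in outcome_cols) {
    r <- tryCatch(gee_group_comparison(tab, oc, contrasts = contrasts),
                  error = function(e) NULL)
    if (!is.null(r)) res[[oc]] <- as.data.frame(r)
  }
  if (!length(res)) stop("no outcome could be fitted", call. = FALSE)
  results <- do.call(rbind, res)
  rownames(results) <- NULL
  dem_tab <- unique(tab[, intersect(c("participant_id", "group", "age",
                                      "sex", "mmse"), names(tab))])
  demographics <- demographics_tests(dem_tab)
  if (!is.null(out_csv)) write.csv(results, out_csv, row.names = FALSE)
  structure(list(results = results, demographics = demographics,
                 n_imputed = n_imp), class = "uwf_stats")
}

#' @export
print.uwf_stats <- function(x, ...) {
  cat("<uwf_stats> ", nrow(x$results), " contrast fits, ",
      x$n_imputed, " imputed cells\n", sep = "")
  sig <- x$results[x$results$p < 0.05, , drop = FALSE]
  if (nrow(sig)) {
    cat("significant at alpha = 0.05:\n")
    print(sig[, c("outcome", "contrast", "beta", "p")], digits = 3)
  }
  invisible(x)
}
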
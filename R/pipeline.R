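#' Read a pipeline run configuration
#'
#' Configurations are JSON or YAML sidecars describing one pre/post
#' analysis. Recognised keys (coordinates 1-based `(row, col)`):
#' \describe{
#'   \item{pre_stack, post_stack}{paths to the two DSA sequences.}
#'   \item{frame_interval}{seconds per frame, used when the containers carry
#'     no timing metadata.}
#'   \item{crop}{optional `[row0, col0, n_rows, n_cols]` applied to both
#'     series before analysis.}
#'   \item{fcm_seeds}{`{"slice": k, "vessel_roi": ROI, "background_roi": ROI}`.}
#'   \item{arterial_roi}{optional ROI for the arterial input curve; defaults
#'     to the vessel seed region.}
#'   \item{analysis_rois}{array of ROIs (`{"shape": "rect", "rect": [...],
#'     "label": ..., "id": ...}` or `{"shape": "circle", "center": [...],
#'     "radius": ...}`).}
#'   \item{anchor_pre, anchor_post}{`[row, col]` registration points;
#'     identical (or absent) when the series are already aligned.}
#'   \item{fcm}{optional `{"m": 2, "tol": 1e-5, "max_iter": 100}`.}
#'   \item{fwhm_resolution}{half-max grid density, default 100.}
#'   \item{out_dir}{output directory.}
#' }
#'
#' @param path a `.json`, `.yaml` or `.yml` file.
#' @return a validated configuration list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file '", path, "' does not exist")
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::read_json(path, simplifyVector = FALSE)
  cfg$config_dir <- dirname(normalizePath(path))
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  for (key in c("pre_stack", "post_stack", "fcm_seeds", "analysis_rois"))
    if (is.null(cfg[[key]])) stop("config lacks required key '", key, "'")
  for (key in c("pre_stack", "post_stack")) {
    p <- cfg[[key]]
    if (!file.exists(p) && !is.null(cfg$config_dir))
      p <- file.path(cfg$config_dir, cfg[[key]])
    if (!file.exists(p)) stop("config ", key, " path '", cfg[[key]],
                              "' does not exist")
    cfg[[key]] <- p
  }
  fs <- cfg$fcm_seeds
  cfg$fcm_seeds <- seed_spec(fs$slice %||% 1L,
                             roi_from_list(fs$vessel_roi),
                             roi_from_list(fs$background_roi))
  cfg$arterial_roi <- if (!is.null(cfg$arterial_roi))
    roi_from_list(cfg$arterial_roi) else cfg$fcm_seeds$vessel_roi
  cfg$analysis_rois <- lapply(cfg$analysis_rois, roi_from_list)
  cfg$anchor <- if (!is.null(cfg$anchor_pre) || !is.null(cfg$anchor_post)) {
    if (is.null(cfg$anchor_pre) || is.null(cfg$anchor_post))
      stop("anchor_pre and anchor_post must be given together")
    anchor_pair(unlist(cfg$anchor_pre), unlist(cfg$anchor_post))
  } else NULL
  fcm <- cfg$fcm %||% list()
  cfg$fcm <- list(m = fcm$m %||% 2, tol = fcm$tol %||% 1e-5,
                  max_iter = fcm$max_iter %||% 100L)
  cfg$fwhm_resolution <- cfg$fwhm_resolution %||% 100L
  if (!is.null(cfg$crop)) cfg$crop <- as.integer(unlist(cfg$crop))
  structure(cfg, class = "run_config")
}

#' Run the full perfusion quantification pipeline
#'
#' Executes, for the pre- and post-therapy series: read, optional crop,
#' intensity complement, seeded fuzzy C-means segmentation, pixel voting,
#' and perfusion map computation; then transfers the analysis ROIs through
#' the anchor, builds the per-ROI comparison and the study summary, and
#' writes all artifacts to the output directory: six float-TIFF maps with
#' colour PNG renderings, the two vessel masks, `report.csv`,
#' `summary.json`, and `run.log` recording every parameter and an MD5 hash
#' of the canonical configuration. The pipeline contains no randomness, so
#' identical configurations produce byte-identical reports.
#'
#' @param config a [read_run_config()] result, a config file path, or an
#'   equivalent list.
#' @param out_dir output directory (default from the config; created if
#'   missing).
#' @return an object of class `pdsa_run`: list with `pre_maps`, `post_maps`,
#'   `comparison`, `summary`, `out_dir` and the per-series segmentation
#'   partitions, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) config <- validate_run_config(config)
  out_dir <- out_dir %||% config$out_dir %||% stop("no output directory given")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  log_msg <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
    message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  cfg_json <- jsonlite::toJSON(serializable_config(config), auto_unbox = TRUE,
                               digits = NA)
  cfg_file <- file.path(out_dir, "config_used.json")
  writeLines(cfg_json, cfg_file)
  log_msg("config hash (md5): %s", unname(tools::md5sum(cfg_file)))

  series <- list()
  for (side in c("pre", "post")) {
    path <- config[[paste0(side, "_stack")]]
    log_msg("[%s] reading %s", side, path)
    stk <- stage(paste0("read_", side),
                 read_frame_stack(path, config$frame_interval))
    if (!is.null(config$crop)) {
      log_msg("[%s] crop to (%s)", side, paste(config$crop, collapse = ","))
      stk <- stage("crop", crop_stack(stk, config$crop))
    }
    stk <- complement_stack(stk)
    # seed and arterial regions are drawn on the pre series; on the post
    # series they follow the anchor displacement like the analysis ROIs
    seeds <- config$fcm_seeds
    arterial <- config$arterial_roi
    if (side == "post" && !is.null(config$anchor)) {
      moved <- transfer_rois(list(seeds$vessel_roi, seeds$background_roi,
                                  arterial),
                             config$anchor, dim(stk$frames)[1:2])
      seeds <- seed_spec(seeds$slice, moved[[1L]], moved[[2L]])
      arterial <- moved[[3L]]
    }
    centers <- stage("seed_centers", seed_centers(stk, seeds))
    log_msg("[%s] seed centres: vessel %.4g, background %.4g", side,
            centers[1L], centers[2L])
    part <- stage("fcm", fcm_cluster(stk, centers,
                                     fuzziness = config$fcm$m,
                                     tol = config$fcm$tol,
                                     max_iter = config$fcm$max_iter))
    log_msg("[%s] FCM: %d iteration(s), centres %.4g / %.4g%s", side,
            part$n_iterations, part$centers[1L], part$centers[2L],
            if (part$converged) "" else " (max_iter reached)")
    mask <- vote_mask(defuzzify(part))
    log_msg("[%s] vessel mask: %d pixels (%.1f%%)", side, sum(mask),
            100 * mean(mask))
    write_mask(mask, file.path(out_dir, paste0("mask_", side, ".png")))
    maps <- stage("maps", compute_perfusion_maps(
      stk, mask, arterial, resolution = config$fwhm_resolution))
    for (nm in c("pbv", "mtt", "pbf"))
      write_map(maps[[nm]], file.path(out_dir,
                                      sprintf("%s_%s.tif", nm, side)))
    series[[side]] <- list(stack = stk, partition = part, mask = mask,
                           maps = maps)
  }

  comparison <- stage("comparison",
                      build_comparison(series$pre$maps, series$post$maps,
                                       config$analysis_rois, config$anchor))
  summary <- stage("summary", summarize_comparison(comparison))
  write_report(comparison, file.path(out_dir, "report.csv"))
  write_summary_json(summary, file.path(out_dir, "summary.json"))
  log_msg("report: %d rows over %d ROI(s); outputs in %s",
          nrow(comparison), length(config$analysis_rois), out_dir)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(structure(list(pre_maps = series$pre$maps,
                           post_maps = series$post$maps,
                           pre_partition = series$pre$partition,
                           post_partition = series$post$partition,
                           comparison = comparison, summary = summary,
                           out_dir = out_dir),
                      class = "pdsa_run"))
}

serializable_config <- function(cfg) {
  list(pre_stack = cfg$pre_stack, post_stack = cfg$post_stack,
       frame_interval = cfg$frame_interval, crop = cfg$crop,
       fcm_seeds = list(slice = cfg$fcm_seeds$slice,
                        vessel_roi = roi_to_list(cfg$fcm_seeds$vessel_roi),
                        background_roi =
                          roi_to_list(cfg$fcm_seeds$background_roi)),
       arterial_roi = roi_to_list(cfg$arterial_roi),
       analysis_rois = lapply(cfg$analysis_rois, roi_to_list),
       anchor_pre = if (!is.null(cfg$anchor)) cfg$anchor$pre_point,
       anchor_post = if (!is.null(cfg$anchor)) cfg$anchor$post_point,
       fcm = cfg$fcm, fwhm_resolution = cfg$fwhm_resolution)
}

#' @export
print.pdsa_run <- function(x, ...) {
  cat("Perfusion DSA run -> ", x$out_dir, "\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Generate a phantom study ready for the pipeline
#'
#' Writes a matched pre/post phantom pair (multi-page TIFF stacks), the
#' ground-truth maps (float TIFF + JSON), and a runnable configuration
#' pointing at them, so `run_pipeline(file.path(out_dir, "config.json"))`
#' reproduces the whole workflow on synthetic data. The stacks are written
#' in acquisition convention (contrast dark, background bright) so the
#' pipeline's intensity complement is exercised too.
#'
#' @param spec a [phantom_spec()], or a path to a YAML/JSON file with
#'   `phantom_spec` fields (segments as lists with `from`, `to`, `width`,
#'   `A`, `t0`, `tp`, `alpha`).
#' @param out_dir output directory.
#' @param amp_mult,tp_div,shift treatment effect and repositioning passed to
#'   [make_pre_post_pair()].
#' @return the configuration file path, invisibly.
#' @export
run_phantom <- function(spec, out_dir, amp_mult = 1.2, tp_div = 2,
                        shift = c(2L, 1L)) {
  if (is.character(spec)) spec <- read_phantom_spec(spec)
  stopifnot(inherits(spec, "phantom_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pair <- make_pre_post_pair(spec, amp_mult = amp_mult, tp_div = tp_div,
                             shift = shift)
  write_frame_stack(complement_stack(pair$pre$stack),
                    file.path(out_dir, "pre.tif"))
  write_frame_stack(complement_stack(pair$post$stack),
                    file.path(out_dir, "post.tif"))
  for (side in c("pre", "post")) {
    tr <- pair[[side]]$truth
    write_float_tiff(tr$mtt, file.path(out_dir,
                                       paste0("truth_mtt_", side, ".tif")))
    write_float_tiff(tr$pbv, file.path(out_dir,
                                       paste0("truth_pbv_", side, ".tif")))
  }
  helpers <- phantom_seeds(pair$pre)
  rois <- analysis_rois_from_truth(pair$pre)
  cfg <- list(pre_stack = "pre.tif", post_stack = "post.tif",
              frame_interval = spec$frame_interval,
              fcm_seeds = list(slice = helpers$seeds$slice,
                               vessel_roi = roi_to_list(helpers$seeds$vessel_roi),
                               background_roi =
                                 roi_to_list(helpers$seeds$background_roi)),
              arterial_roi = roi_to_list(helpers$arterial_roi),
              analysis_rois = lapply(rois, roi_to_list),
              anchor_pre = pair$anchor$pre_point,
              anchor_post = pair$anchor$post_point,
              out_dir = file.path(out_dir, "results"))
  truth_summary <- list(
    segments = lapply(pair$pre$spec$vessel_segments, unclass),
    amp_mult = amp_mult, tp_div = tp_div, shift = shift,
    mtt_true_pre = lapply(pair$pre$spec$vessel_segments,
                          function(s) gamma_variate_fwhm(s$tp, s$alpha)),
    mtt_true_post = lapply(pair$post$spec$vessel_segments,
                           function(s) gamma_variate_fwhm(s$tp, s$alpha)))
  jsonlite::write_json(truth_summary, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(cfg_path)
}

# one analysis ROI per segment, centred on the segment
analysis_rois_from_truth <- function(phantom) {
  lapply(seq_along(phantom$truth$segment_pixels), function(s) {
    px <- phantom$truth$segment_pixels[[s]]
    mid_r <- round(stats::median(px[, 1L]))
    sel <- px[abs(px[, 1L] - mid_r) <= 4L, , drop = FALSE]
    roi_rect(min(sel[, 1L]), min(sel[, 2L]),
             diff(range(sel[, 1L])) + 1L, diff(range(sel[, 2L])) + 1L,
             label = paste0("segment ", s), id = s)
  })
}

read_phantom_spec <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  segs <- lapply(raw$vessel_segments, function(s)
    vessel_segment(unlist(s$from), unlist(s$to),
                   width = s$width %||% 3, A = s$A %||% 200,
                   t0 = s$t0 %||% 0, tp = s$tp %||% 4,
                   alpha = s$alpha %||% 1.3))
  args <- raw[intersect(names(raw),
                        c("image_size", "n_frames", "frame_interval",
                          "background_level", "noise_sigma", "bit_depth",
                          "rng_seed"))]
  args$image_size <- unlist(args$image_size)
  args$vessel_segments <- segs
  do.call(phantom_spec, args)
}
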
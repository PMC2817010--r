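## Pipeline orchestration: a validated configuration object, the per-eye
## measurement chain (smooth -> seed -> threshold -> flood fill -> repair ->
## wrap -> smooth -> measure), and a batch runner with per-eye error
## isolation, JSONL event logging and content-keyed caching of the
## expensive per-eye stage.

pipeline_defaults <- list(
  voxel_size = 0.115,        # mm, scanning resolution
  supersample = 5,           # phantom render subsampling (interface voxels)
  snr = 15,                  # phantom signal-to-noise ratio
  smooth_kernel_mm = 0.1,    # Gaussian pre-smoothing sigma
  kernel_is_fwhm = FALSE,
  threshold_mode = "local",  # "local" (Otsu in ROI) or "global"
  roi_radius_mm = NULL,      # default: 1.5 x expected lens radius
  closing_radius = 2,        # voxels
  face_budget = 32768,
  smooth_iterations = 10,
  smooth_lambda = 0.33,
  smooth_mu = -0.34,
  cone_full_angle = 120,     # degrees (60-degree half-angle cap)
  kidney_threshold_mm = 0.15,
  free_center = FALSE,
  seed = 1,
  n_eyes = 16,
  cache = TRUE,
  write_volumes = FALSE
)

#' Build a validated pipeline configuration
#'
#' @param ... overrides of the defaults (see Details). Unknown keys are
#'   rejected.
#' @return a named list of class `pipeline_config`.
#' @details Defaults: 0.115 mm voxels, SNR 15 phantoms, 0.1 mm smoothing
#'   kernel, local Otsu-split midpoint threshold, closing radius 2,
#'   32,768-face mesh, 10 Taubin smoothing iterations, 120 degree fit cone
#'   (60 degrees to the axis), 0.15 mm kidney threshold.
#' @export
pipeline_config <- function(...) {
  over <- list(...)
  if (length(over) == 1 && is.list(over[[1]]) && is.null(names(over)))
    over <- over[[1]]
  bad <- setdiff(names(over), names(pipeline_defaults))
  if (length(bad)) stop("unknown configuration keys: ",
                        paste(bad, collapse = ", "))
  cfg <- utils::modifyList(pipeline_defaults, over, keep.null = TRUE)
  stopifnot(cfg$voxel_size > 0, cfg$supersample >= 1,
            cfg$smooth_kernel_mm >= 0, cfg$face_budget >= 8,
            cfg$smooth_iterations >= 0)
  structure(cfg, class = "pipeline_config")
}

#' Serialize / restore a pipeline configuration
#'
#' @param config a [pipeline_config()].
#' @param path JSON file path.
#' @return the path (write) / the restored config (read).
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  pipeline_config(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Measure one eye volume end to end
#'
#' The per-eye measurement chain: Gaussian pre-smoothing, seed selection
#' (automatic unless given), threshold selection, flood fill, mask repair,
#' shrink-wrap meshing, vertex smoothing, and full biometry.
#'
#' @param vol a [voxel_volume()] containing one eye (or lens crop).
#' @param config a [pipeline_config()].
#' @param seed_voxel optional segmentation seed (1-based voxel coords).
#' @param anterior_point,orient_hint passed to [measure_lens()].
#' @return list with `biometry` ([measure_lens()] result), `mask`, `mesh`.
#' @export
analyze_eye_volume <- function(vol, config = pipeline_config(),
                               seed_voxel = NULL, anterior_point = NULL,
                               orient_hint = c(0, 0, 1)) {
  sm <- gaussian_smooth(vol, config$smooth_kernel_mm, config$kernel_is_fwhm)
  seed_voxel <- seed_voxel %||% default_seed(sm)
  thr <- if (identical(config$threshold_mode, "global")) {
    otsu_threshold(as.numeric(sm$data))
  } else {
    select_threshold(sm, seed_voxel, roi_radius_mm = config$roi_radius_mm)
  }
  mask <- flood_fill_lens(sm, seed_voxel, thr)
  mask <- repair_mask(mask, closing_radius = config$closing_radius)
  mesh <- shrink_wrap(mask, init_mesh(config$face_budget),
                      intensity = sm, level = thr)
  mesh <- smooth_vertices(mesh, config$smooth_iterations,
                          config$smooth_lambda, config$smooth_mu)
  biom <- measure_lens(mesh, anterior_point = anterior_point,
                       orient_hint = orient_hint, mask = mask,
                       cone_full_angle = config$cone_full_angle,
                       free_center = config$free_center,
                       kidney_threshold_mm = config$kidney_threshold_mm)
  list(biometry = biom, mask = mask, mesh = mesh, seed_voxel = seed_voxel,
       threshold = thr)
}

#' Run the pipeline over a simulated cohort or a set of eye volumes
#'
#' In simulation mode (`volumes = NULL`) a cohort of `config$n_eyes` birds is
#' simulated, each bird's eye phantom is voxelized (per-eye derived seed) and
#' measured, and the stats stage joins measured biometry with the in vivo
#' trait table. With `volumes` given, each volume is measured directly.
#' Per-eye failures are isolated: the run continues and failures are
#' reported in the returned table and the log.
#'
#' @param config a [pipeline_config()].
#' @param volumes optional named list of [voxel_volume()]s.
#' @param out_dir output directory (created); biometry CSV, cohort CSV (in
#'   simulation mode), resolved config JSON and a JSONL event log are
#'   written there.
#' @param fov phantom render field of view (see [voxelize_eye()]).
#' @return list with `biometry` (data frame), `cohort` (simulation mode),
#'   `failures` (character), `stats` (correlation map + batch LRTs when the
#'   cohort is large enough), `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), volumes = NULL,
                         out_dir = tempfile("lensmetry_run_"),
                         fov = "lens") {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "events.jsonl")
  log_event <- function(...) {
    evt <- list(...)
    evt$time <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
    cat(jsonlite::toJSON(evt, auto_unbox = TRUE), "\n",
        file = log_path, append = TRUE)
  }
  write_config(config, file.path(out_dir, "config.json"))
  cohort <- NULL
  specs <- NULL
  if (is.null(volumes)) {
    cspec <- cohort_spec(n_birds = config$n_eyes)
    cohort <- simulate_cohort(cspec, seed = config$seed)
    specs <- attr(cohort, "lens_specs")
    write_cohort_csv(cohort, file.path(out_dir, "cohort.csv"))
    ids <- cohort$bird_id
  } else {
    ids <- names(volumes) %||% seq_along(volumes)
  }
  cache_dir <- file.path(out_dir, "cache")
  if (isTRUE(config$cache)) dir.create(cache_dir, showWarnings = FALSE)
  rows <- list()
  failures <- character(0)
  for (i in seq_along(ids)) {
    id <- ids[[i]]
    t0 <- Sys.time()
    res <- tryCatch({
      if (is.null(volumes)) {
        eye <- cohort_eye(cohort[i, ], specs[[i]])
        key <- stage_key(config, cohort[i, ], id)
        cached <- cache_get(cache_dir, key, config)
        if (!is.null(cached)) {
          log_event(stage = "measure", eye = id, cached = TRUE)
          cached
        } else {
          vol <- voxelize_eye(eye, voxel_size = config$voxel_size,
                              supersample = config$supersample,
                              snr = config$snr,
                              seed = child_seed(config$seed, i),
                              fov = fov)
          r <- analyze_eye_volume(vol, config,
                                  orient_hint = eye$axis)
          row <- cbind(data.frame(id = id), as.data.frame(r$biometry))
          cache_put(cache_dir, key, row, config)
          row
        }
      } else {
        r <- analyze_eye_volume(volumes[[i]], config)
        cbind(data.frame(id = id), as.data.frame(r$biometry))
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("eye %s: %s", id, conditionMessage(res)))
      log_event(stage = "measure", eye = id, status = "error",
                message = conditionMessage(res))
    } else {
      rows[[length(rows) + 1]] <- res
      log_event(stage = "measure", eye = id, status = "ok",
                seconds = round(as.numeric(Sys.time()) - as.numeric(t0), 2))
    }
  }
  biometry <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(biometry))
    write.csv(biometry, file.path(out_dir, "biometry.csv"), row.names = FALSE)
  stats_out <- NULL
  if (!is.null(cohort) && !is.null(biometry) && nrow(biometry) >= 10) {
    joined <- merge(biometry, cohort, by.x = "id", by.y = "bird_id")
    stats_out <- tryCatch(list(
      cmap = correlation_map(
        joined,
        lens_traits = c("volume_mm3", "eq_diam_mm", "thickness_mm",
                        "Ra_mm", "Rp_mm"),
        other_traits = c("eye_weight_g", "eye_eq_diam_mm", "axial_length_mm",
                         "body_mass_g", "body_length_mm"))$all,
      hatch_lrt = if (length(unique(joined$hatch)) > 1 &&
                        length(unique(joined$kidney)) > 1)
        logistic_lrt(joined$kidney, joined$hatch) else NULL
    ), error = function(e) NULL)
    if (!is.null(stats_out))
      log_event(stage = "stats", status = "ok")
  }
  log_event(stage = "run", status = "done", n_ok = length(rows),
            n_failed = length(failures))
  list(biometry = biometry, cohort = cohort, failures = failures,
       stats = stats_out, out_dir = out_dir)
}

# content key for per-eye caching: configuration + generating row + id
stage_key <- function(config, row, id) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(list(unclass(config), row, id), f, version = 2)
  unname(tools::md5sum(f))
}

cache_get <- function(dir, key, config) {
  if (!isTRUE(config$cache)) return(NULL)
  f <- file.path(dir, paste0(key, ".csv"))
  if (file.exists(f)) read.csv(f, stringsAsFactors = FALSE) else NULL
}

cache_put <- function(dir, key, row, config) {
  if (!isTRUE(config$cache)) return(invisible(NULL))
  write.csv(row, file.path(dir, paste0(key, ".csv")), row.names = FALSE)
  invisible(NULL)
}
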
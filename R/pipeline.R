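#' Default pipeline configuration
#'
#' The full study configuration as a nested list, serialisable to YAML. The
#' blocks mirror the pipeline stages: display calibration, band-pass texture
#' and edge-enhancement parameters, leaf background, snake geometry, the
#' session design, the simulated cohort, and the group analysis.
#'
#' @return A `pipeline_config` (named list).
#' @export
default_config <- function() {
  structure(list(
    version = 1L,
    seed = 1L,
    calibration = list(extent_px = 1024L, extent_deg = 29.86,
                       distance_mm = 600),
    texture = list(mu = 0.07, sigma = 120, size = 1024L, n_per_type = 10L,
                   ee_width_deg = 0.63, ee_offset_L = 60,
                   ee_profile = "flat"),
    leaves = list(n_leaves = 4096L, mean_height_deg = 0.68,
                  height_jitter = 0.25, shadow_fraction = 0.30,
                  n_backgrounds = 10L),
    snake = list(baseline_width_px = 82L, height_deg = 9.73,
                 thickness_deg = 0.45, periods = 2.5,
                 separation_deg = 15.9, y_offset_max_deg = 1.49),
    design = list(colourations = c("uniform", "flat", "ee"),
                  backgrounds = c("leafy", "grey"),
                  starts = c(1.2, 0.8), n_trials = 30L,
                  pedestal_max = 0.2, pedestal_step = 0.05,
                  step = 0.05, min_step = 0.0125,
                  min_presentation_ms = 1000, isi_ms = 2000),
    cohort = list(n_observers = 26L,
                  threshold_means = list(uniform.leafy = 0.10,
                                         flat.leafy = 0.12, ee.leafy = 0.20,
                                         uniform.grey = 0.09,
                                         flat.grey = 0.10, ee.grey = 0.15),
                  threshold_sd = 0.04, slope_mean = 20, slope_sd = 4,
                  lapse_mean = 0.02, lapse_sd = 0.01),
    analysis = list(prior_scale = 0.7071068, bootstrap_resamples = 2000L,
                    baseline = 1.0, one_sided_baseline = FALSE)
  ), class = "pipeline_config")
}

#' Read and validate a pipeline configuration
#'
#' Reads a YAML file with the [default_config()] block structure; missing
#' blocks or fields fall back to the defaults, and every block is validated
#' against its stage's constructors before any stage runs.
#'
#' @param path Path to a YAML config, or `NULL` for the defaults.
#' @return A validated `pipeline_config`.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    for (blk in intersect(names(user), names(cfg))) {
      if (is.list(cfg[[blk]])) {
        for (k in names(user[[blk]])) cfg[[blk]][[k]] <- user[[blk]][[k]]
      } else {
        cfg[[blk]] <- user[[blk]]
      }
    }
  }
  validate_config(cfg)
}

#' @rdname read_config
#' @param cfg A `pipeline_config`.
#' @export
validate_config <- function(cfg) {
  # each constructor throws on invalid values, so validation is just
  # instantiating every block once
  config_calibration(cfg)
  filter_spec(cfg$texture$mu, cfg$texture$sigma, cfg$texture$size)
  ee_spec(cfg$texture$ee_width_deg, cfg$texture$ee_offset_L,
          cfg$texture$ee_profile)
  config_leaf_spec(cfg)
  config_design(cfg)
  config_cohort_spec(cfg)
  if (cfg$analysis$prior_scale <= 0) stop("prior_scale must be > 0",
                                          call. = FALSE)
  invisible(structure(cfg, class = "pipeline_config"))
}

config_calibration <- function(cfg) {
  calibration_from_extent(cfg$calibration$extent_px,
                          cfg$calibration$extent_deg,
                          cfg$calibration$distance_mm)
}

config_leaf_spec <- function(cfg) {
  leaf_spec(n_leaves = cfg$leaves$n_leaves,
            mean_height_deg = cfg$leaves$mean_height_deg,
            height_jitter = cfg$leaves$height_jitter,
            shadow_fraction = cfg$leaves$shadow_fraction)
}

config_design <- function(cfg) {
  session_design(colourations = cfg$design$colourations,
                 backgrounds = cfg$design$backgrounds,
                 starts = cfg$design$starts,
                 n_trials = cfg$design$n_trials,
                 pedestal_max = cfg$design$pedestal_max,
                 pedestal_step = cfg$design$pedestal_step,
                 step = cfg$design$step, min_step = cfg$design$min_step)
}

config_cohort_spec <- function(cfg) {
  cohort_spec(n_observers = cfg$cohort$n_observers,
              threshold_means = unlist(cfg$cohort$threshold_means),
              threshold_sd = cfg$cohort$threshold_sd,
              slope_mean = cfg$cohort$slope_mean,
              slope_sd = cfg$cohort$slope_sd,
              lapse_mean = cfg$cohort$lapse_mean,
              lapse_sd = cfg$cohort$lapse_sd)
}

write_image_png <- function(img, path) {
  png::writePNG(img, path)
}

#' Generate the stimulus set
#'
#' Generates the configured number of leaf backgrounds and, per disruptive
#' colouration, camouflage textures (flat and edge-enhanced share palettes
#' drawn from the leaf colour population) plus the uniform control, writes
#' them as PNGs with JSON sidecars, composes one example scene per
#' condition, and writes a CSV manifest.
#'
#' @param cfg A `pipeline_config`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `backgrounds`, `textures` (nested by
#'   colouration) and the manifest tibble.
#' @export
generate_stimuli <- function(cfg = default_config(), out_dir = tempfile()) {
  cfg <- validate_config(cfg)
  cal <- config_calibration(cfg)
  lspec <- config_leaf_spec(cfg)
  fspec <- filter_spec(cfg$texture$mu, cfg$texture$sigma, cfg$texture$size)
  ee <- ee_spec(cfg$texture$ee_width_deg, cfg$texture$ee_offset_L,
                cfg$texture$ee_profile)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  bgs <- lapply(seq_len(cfg$leaves$n_backgrounds), function(i) {
    generate_leaf_background(lspec, cal, size = cfg$texture$size,
                             seed = substream_seed(cfg$seed,
                                                   paste0("background/", i)))
  })
  pop <- leaf_colour_population(bgs[[1]],
                                seed = substream_seed(cfg$seed, "population"))
  n_tex <- cfg$texture$n_per_type
  flats <- lapply(seq_len(n_tex), function(i) {
    pal <- pick_patch_palette(pop,
                              seed = substream_seed(cfg$seed,
                                                    paste0("palette/", i)))
    synthesize_two_tone(fspec, pal,
                        seed = substream_seed(cfg$seed,
                                              paste0("texture/flat/", i)))
  })
  ees <- lapply(flats, apply_edge_enhancement, ee = ee, cal = cal)
  uniforms <- lapply(flats, function(tx) {
    make_uniform_texture(tx$palette, size = cfg$texture$size)
  })
  textures <- list(uniform = uniforms, flat = flats, ee = ees)

  manifest <- list()
  for (i in seq_along(bgs)) {
    p <- file.path(out_dir, sprintf("background_%02d.png", i))
    write_image_png(bgs[[i]]$image, p)
    jsonlite::write_json(
      list(kind = "leaf_background", seed = bgs[[i]]$seed,
           n_leaves = lspec$n_leaves, coverage = bgs[[i]]$coverage),
      sub("\\.png$", ".json", p), auto_unbox = TRUE)
    manifest[[length(manifest) + 1L]] <-
      tibble::tibble(kind = "background", id = i, file = basename(p))
  }
  for (ctype in names(textures)) {
    for (i in seq_along(textures[[ctype]])) {
      p <- file.path(out_dir, sprintf("texture_%s_%02d.png", ctype, i))
      write_image_png(textures[[ctype]][[i]]$image, p)
      manifest[[length(manifest) + 1L]] <-
        tibble::tibble(kind = paste0("texture_", ctype), id = i,
                       file = basename(p))
    }
  }
  # one example scene per condition
  scene_seed <- substream_seed(cfg$seed, "scenes")
  for (ctype in names(textures)) {
    for (bg in cfg$design$backgrounds) {
      sc <- compose_scene(1.3, 1.0, textures[[ctype]],
                          background = if (bg == "leafy") bgs[[1]] else NULL,
                          cal = cal, seed = scene_seed,
                          size = cfg$texture$size,
                          separation_deg = cfg$snake$separation_deg,
                          y_offset_max = cfg$snake$y_offset_max_deg,
                          snake = list(
                            baseline_width_px = cfg$snake$baseline_width_px,
                            height_deg = cfg$snake$height_deg,
                            thickness_deg = cfg$snake$thickness_deg,
                            periods = cfg$snake$periods))
      p <- file.path(out_dir, sprintf("scene_%s_%s.png", ctype, bg))
      write_image_png(sc$image, p)
      manifest[[length(manifest) + 1L]] <-
        tibble::tibble(kind = paste0("scene_", ctype, "_", bg), id = 1L,
                       file = basename(p))
    }
  }
  manifest <- dplyr::bind_rows(manifest)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(list(backgrounds = bgs, textures = textures,
                 manifest = manifest))
}

#' Run the full simulated study pipeline
#'
#' Draws the cohort, runs every simulated session, fits per-participant
#' per-condition thresholds, computes the bootstrap group summary and the
#' Bayes-factor comparisons, and (optionally) writes trials CSV, thresholds
#' CSV, group CSV, analysis JSON and a structured run log.
#'
#' @param cfg A `pipeline_config`.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return A list: `cohort`, `trials`, `thresholds`, `group`, `bayes`,
#'   `log`.
#' @export
run_study_pipeline <- function(cfg = default_config(), out_dir = NULL) {
  cfg <- validate_config(cfg)
  t0 <- Sys.time()
  design <- config_design(cfg)
  cohort <- generate_cohort(config_cohort_spec(cfg),
                            seed = substream_seed(cfg$seed, "cohort"))
  trials <- run_study(cohort, design,
                      seed = substream_seed(cfg$seed, "study"))
  thresholds <- fit_thresholds(trials)
  group <- bootstrap_group_ci(thresholds,
                              resamples = cfg$analysis$bootstrap_resamples,
                              seed = substream_seed(cfg$seed, "bootstrap"))
  bayes <- bayes_compare(thresholds, baseline = cfg$analysis$baseline,
                         r = cfg$analysis$prior_scale,
                         one_sided_baseline =
                           cfg$analysis$one_sided_baseline)
  log <- list(
    seed = cfg$seed,
    substreams = list(cohort = substream_seed(cfg$seed, "cohort"),
                      study = substream_seed(cfg$seed, "study"),
                      bootstrap = substream_seed(cfg$seed, "bootstrap")),
    n_participants = length(unique(cohort$participant)),
    n_trials = nrow(trials),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(trials, file.path(out_dir, "trials.csv"),
                     row.names = FALSE)
    utils::write.csv(thresholds, file.path(out_dir, "thresholds.csv"),
                     row.names = FALSE)
    utils::write.csv(group, file.path(out_dir, "group_summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(bayes, file.path(out_dir, "analysis.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(cohort = cohort, trials = trials, thresholds = thresholds,
       group = group, bayes = bayes, log = log)
}
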
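#' Reduced demonstration maze
#'
#' A scaled-down double spiral (220 x 165 mm plate, 10 mm corridor,
#' ~1.25 m centreline) used by the examples, the simulation studies and the
#' package tests, where rendering the full 440 x 330 mm device at high
#' resolution would be needlessly heavy. All geometric proportions
#' (corridor width, wall width, pitch) match the full-size default.
#'
#' @param ... overrides passed to [generate_double_spiral()].
#' @return a [maze_geometry].
#' @export
demo_maze <- function(...) {
  args <- list(plate_width = 220, plate_height = 165, path_width = 10,
               wall_width = 2.5, n_turns_per_arm = 1.9)
  args[names(list(...))] <- list(...)
  do.call(generate_double_spiral, args)
}

#' Default parameters of a simulated assay
#'
#' The rendering/detection/filter/statistics defaults of the in-memory
#' pipeline. The demonstration profile images a 2 mm organism at
#' 2.5 px/mm (5 px body length, matching the px size of a 0.5 mm insect
#' imaged at 16 px/mm on the full device).
#'
#' @return a named list of parameters.
#' @export
assay_defaults <- function() {
  list(resolution = 2.5, insect_length = 2, noise_sd = 3,
       hidden_fraction = 0.01, pack_size = 60, threshold = 50,
       area_range = c(3, 80), projection = "median",
       filter = filter_config(area_min = 3, area_max = 80),
       window = 15, alpha = 0.05, dt = 1, n_frames = 360)
}

#' Run the full simulated-assay pipeline in memory
#'
#' Chains every stage of the toolkit on synthetic data: simulate dispersal
#' along the tunnel, render the back-lit image sequence, detect particles by
#' pack-wise background subtraction, skeletonize and fragment the corridor,
#' project detections to the signed arc coordinate, apply the four cleaning
#' filters, compute the MSD series and classify the dispersal dynamics.
#'
#' @param model a [dispersal_model()] (or a preset name for
#'   [dispersal_preset()]).
#' @param geom a [maze_geometry]; default [demo_maze()].
#' @param seed RNG seed driving simulation and rendering.
#' @param params parameter list, see [assay_defaults()]; entries given here
#'   override the defaults.
#' @param skeleton optionally, a precomputed `path_skeleton` for `geom` at
#'   the configured resolution (saves recomputation across runs).
#' @return a list: `positions` (filtered detections with arc coordinates),
#'   `msd` (per-minute MSD), `classification` (a `dispersal_type`),
#'   `detections` (raw detection count), `filter_removed`, `ground_truth`,
#'   `skeleton`, `geom`, `params`, `seed`.
#' @export
simulate_assay <- function(model, geom = demo_maze(), seed = .default_seed,
                           params = list(), skeleton = NULL) {
  if (is.character(model)) model <- dispersal_preset(model)
  p <- assay_defaults()
  p[names(params)] <- params
  pos <- simulate_linear_dispersal(model, half_length = geom$arc_length / 2,
                                   n_frames = p$n_frames, dt = p$dt,
                                   seed = seed)
  seq <- render_sequence(geom, pos, resolution = p$resolution,
                         insect_length = p$insect_length,
                         noise_sd = p$noise_sd,
                         hidden_fraction = p$hidden_fraction, seed = seed + 1L)
  det <- analyze_sequence(seq, pack_size = p$pack_size,
                          threshold = p$threshold,
                          area_range = p$area_range,
                          projection = p$projection)
  if (is.null(skeleton)) skeleton <- path_skeleton(seq$mask)
  proj <- project_to_path(det[, c("x", "y")], skeleton)
  det <- cbind(det, proj)
  filt <- apply_filters(det, p$filter, n_frames = p$n_frames,
                        path_width = geom$path_width)
  msd <- msd_series(filt$detections, dt = p$dt, n_frames = p$n_frames)
  kept <- filt$detections
  single_area <- stats::median(kept$area)
  rmsd <- robust_msd_series(kept, n_released = model$n_individuals,
                            multiplicity = pmax(1, round(kept$area /
                                                           single_area)),
                            dt = p$dt, n_frames = p$n_frames)
  cls <- classify_msd(rmsd, window = p$window, alpha = p$alpha)
  list(positions = filt$detections, msd = msd, robust_msd = rmsd,
       classification = cls,
       detections = nrow(det), filter_removed = filt$removed,
       ground_truth = seq$ground_truth, skeleton = skeleton, geom = geom,
       params = p, seed = seed)
}

#' Compare pipeline detections against ground truth
#'
#' Validation of a simulated (or manually scored) assay: overall detection
#' rate with its exact binomial confidence interval, and a chi-square
#' homogeneity test between the detected and true spatial distributions of
#' |s| (pooled over frames).
#'
#' @param positions filtered detection table with `s_mm` (and `frame`).
#' @param ground_truth ground-truth table with `s_mm`, `visible`, `frame`.
#' @param n_bins number of |s| bins for the homogeneity test.
#' @param confidence confidence level of the binomial interval.
#' @return a list: `detection_rate` (list from [detection_rate_ci()]),
#'   `chi2` (list from [chi2_homogeneity()]), `n_detected`, `n_true`.
#' @export
validate_assay <- function(positions, ground_truth, n_bins = 10,
                           confidence = 0.95) {
  truth <- ground_truth[ground_truth$visible, , drop = FALSE]
  n_det <- nrow(positions)
  n_true <- nrow(truth)
  rate <- detection_rate_ci(n_det, n_true, confidence)
  breaks <- seq(0, max(abs(c(truth$s_mm, positions$s_mm))) + 1e-9,
                length.out = n_bins + 1)
  a <- table(cut(abs(positions$s_mm), breaks))
  b <- table(cut(abs(truth$s_mm), breaks))
  chi2 <- chi2_homogeneity(as.integer(a), as.integer(b))
  list(detection_rate = rate, chi2 = chi2,
       n_detected = n_det, n_true = n_true)
}

# ---- file-based stage runner (command-line entry point) --------------------

#' Read a pipeline run configuration
#'
#' Reads a YAML configuration file and merges it over the built-in defaults
#' (see [assay_defaults()]; geometry parameters under `geometry:`, model
#' phases under `model:`, paths under `paths:`).
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return a named list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- list(seed = .default_seed, params = list(),
              geometry = list(), model = list(type = "type2"),
              paths = list(out = "spiralmaze_out"))
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    for (k in names(user)) {
      if (is.list(cfg[[k]]) && is.list(user[[k]]))
        cfg[[k]][names(user[[k]])] <- user[[k]]
      else cfg[[k]] <- user[[k]]
    }
  }
  cfg
}

stage_manifest <- function(dir, stage, cfg, inputs = character(0),
                           outputs = character(0)) {
  manifest <- list(
    stage = stage,
    package = "spiralmaze",
    version = as.character(utils::packageVersion("spiralmaze")),
    seed = cfg$seed,
    params = lapply(cfg$params, function(x)
      if (inherits(x, "filter_config")) unclass(x) else x),
    geometry = cfg$geometry, model = cfg$model,
    inputs = inputs, outputs = outputs
  )
  jsonlite::write_json(manifest,
                       file.path(dir, paste0("manifest_", stage, ".json")),
                       digits = NA, auto_unbox = TRUE, null = "null")
}

#' Run one pipeline stage against files on disk
#'
#' Thin orchestration layer over the package functions, used by the
#' command-line script (`inst/cli/spiralmaze.R`). Every stage reads its
#' inputs from, and writes its outputs and a JSON manifest to,
#' `config$paths$out`:
#' \describe{
#'   \item{design}{geometry JSON, SVG drawing, tunnel-mask TIFF.}
#'   \item{simulate}{TIFF frame sequence + ground-truth CSV.}
#'   \item{detect}{`detections.csv`.}
#'   \item{linearize}{skeleton fragments CSV/JSON, `positions.csv`
#'     (detections + arc coordinates).}
#'   \item{filter}{`filtered.csv` + removal-count JSON.}
#'   \item{analyze}{`msd.csv`, `classification.json`.}
#'   \item{validate}{`validation.json` (detection rate + CI, chi-square
#'     homogeneity vs ground truth).}
#'   \item{all}{all of the above in order.}
#' }
#'
#' @param stage stage name.
#' @param config configuration list from [read_run_config()].
#' @return invisibly, a list of outputs of the stage.
#' @export
run_stage <- function(stage = c("design", "simulate", "detect", "linearize",
                                "filter", "analyze", "validate", "all"),
                      config = read_run_config()) {
  stage <- match.arg(stage)
  if (stage == "all") {
    for (st in c("design", "simulate", "detect", "linearize", "filter",
                 "analyze", "validate"))
      run_stage(st, config)
    return(invisible(NULL))
  }
  out <- config$paths$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  p <- assay_defaults()
  p[names(config$params)] <- config$params
  geom_file <- file.path(out, "geometry.json")
  get_geom <- function() {
    if (file.exists(geom_file)) maze_from_json(geom_file)
    else do.call(demo_maze, config$geometry)
  }
  res <- switch(stage,
    design = {
      geom <- do.call(demo_maze, config$geometry)
      maze_to_json(geom, geom_file)
      export_maze_svg(geom, file.path(out, "maze.svg"))
      mask <- render_tunnel_mask(geom, p$resolution)
      tiff::writeTIFF(matrix(as.numeric(mask), nrow(mask)),
                      file.path(out, "tunnel_mask.tif"),
                      bits.per.sample = 8L)
      list(geometry = geom)
    },
    simulate = {
      geom <- get_geom()
      model <- if (!is.null(config$model$type))
        dispersal_preset(config$model$type,
                         config$model$n_individuals %||% 200)
      else dispersal_model(config$model$duration, config$model$D,
                           config$model$n_individuals %||% 200)
      pos <- simulate_linear_dispersal(model, geom$arc_length / 2,
                                       n_frames = p$n_frames, dt = p$dt,
                                       seed = config$seed)
      render_sequence(geom, pos, resolution = p$resolution,
                      insect_length = p$insect_length, noise_sd = p$noise_sd,
                      hidden_fraction = p$hidden_fraction,
                      seed = config$seed + 1L,
                      dir = file.path(out, "frames"))
      list(frames = file.path(out, "frames"))
    },
    detect = {
      frames <- sort(list.files(file.path(out, "frames"),
                                pattern = "\\.tif$", full.names = TRUE))
      if (!length(frames)) stop("stage detect: no frames found under ", out)
      det <- analyze_sequence(frames, pack_size = p$pack_size,
                              threshold = p$threshold,
                              area_range = p$area_range,
                              projection = p$projection)
      write.csv(det, file.path(out, "detections.csv"), row.names = FALSE)
      list(detections = det)
    },
    linearize = {
      geom <- get_geom()
      mask <- render_tunnel_mask(geom, p$resolution)
      sk <- path_skeleton(mask)
      write_path_skeleton(sk, csv = file.path(out, "skeleton.csv"),
                          json = file.path(out, "skeleton.json"))
      det_file <- file.path(out, "detections.csv")
      if (!file.exists(det_file))
        stop("stage linearize: detections.csv not found; run detect first")
      det <- read.csv(det_file)
      det <- cbind(det, project_to_path(det[, c("x", "y")], sk))
      write.csv(det, file.path(out, "positions.csv"), row.names = FALSE)
      list(skeleton = sk)
    },
    filter = {
      geom <- get_geom()
      det <- read.csv(file.path(out, "positions.csv"))
      filt <- apply_filters(det, p$filter, n_frames = p$n_frames,
                            path_width = geom$path_width)
      write.csv(filt$detections, file.path(out, "filtered.csv"),
                row.names = FALSE)
      jsonlite::write_json(as.list(filt$removed),
                           file.path(out, "filter_summary.json"),
                           digits = NA, auto_unbox = TRUE)
      list(removed = filt$removed)
    },
    analyze = {
      det <- read.csv(file.path(out, "filtered.csv"))
      msd <- msd_series(det, dt = p$dt, n_frames = p$n_frames)
      write.csv(msd, file.path(out, "msd.csv"), row.names = FALSE)
      rmsd <- robust_msd_series(det,
                                n_released = config$model$n_individuals %||% 200,
                                dt = p$dt, n_frames = p$n_frames)
      write.csv(rmsd, file.path(out, "robust_msd.csv"), row.names = FALSE)
      cls <- classify_msd(rmsd, window = p$window, alpha = p$alpha)
      jsonlite::write_json(unclass(cls), file.path(out, "classification.json"),
                           digits = NA, auto_unbox = TRUE, null = "null")
      list(classification = cls)
    },
    validate = {
      det <- read.csv(file.path(out, "filtered.csv"))
      gt <- read.csv(file.path(out, "frames", "ground_truth.csv"))
      v <- validate_assay(det, gt)
      jsonlite::write_json(v, file.path(out, "validation.json"),
                           digits = NA, auto_unbox = TRUE)
      list(validation = v)
    }
  )
  stage_manifest(out, stage, config)
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
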
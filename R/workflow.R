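# Orchestration: configuration handling, TIFF/CSV/JSON input-output, and the
# two end-to-end workflows (model curve prediction, DDM analysis of a movie).

.CONFIG_SCHEMA <- list(
  seed = NULL,
  output_dir = NULL,
  log_level = NULL,
  model = c("helix_radius_um", "pitch_um", "axial_length_um",
            "filament_radius_um", "handedness", "body_length_um",
            "body_width_um", "wobble_angle_deg", "motor_hz", "mu",
            "variant", "thickness_exponent"),
  ensemble = c("n_cells", "body_length_mean_um", "body_length_cv",
               "body_width_mean_um", "body_width_cv", "wobble_max_deg",
               "seed"),
  coupling = c("number_slope", "number_intercept", "length_max_um",
               "length_halfsat"),
  ddm = c("frame_rate_hz", "pixel_size_um", "q_min", "q_max",
          "max_lag_frames", "n_pairs_max"),
  flicker = c("body_band_hz", "flag_band_hz", "prominence_k",
              "segment_length", "overlap"),
  synth = c("n_particles", "alpha", "v_bar", "Z", "D_diff", "psf_sigma_px",
            "noise_sigma", "frame_rate_hz", "n_frames", "size_px",
            "pixel_size_um"),
  n_range = NULL,
  observations_csv = NULL
)

#' Validate a run configuration
#'
#' Checks a (YAML- or list-borne) configuration against the known schema:
#' unknown top-level blocks or unknown keys inside a block are rejected with
#' the offending field path, so typos fail loudly instead of being ignored.
#'
#' @param config A named list (e.g. from [read_run_config()]).
#' @return The config, invisibly, if valid; otherwise an error.
#' @export
validate_run_config <- function(config) {
  if (!is.list(config)) stop("config must be a list", call. = FALSE)
  for (key in names(config)) {
    if (!key %in% names(.CONFIG_SCHEMA)) {
      stop("unknown config field: ", key, call. = FALSE)
    }
    allowed <- .CONFIG_SCHEMA[[key]]
    if (!is.null(allowed) && is.list(config[[key]])) {
      bad <- setdiff(names(config[[key]]), allowed)
      if (length(bad) > 0) {
        stop("unknown config field: ", key, "$", bad[1], call. = FALSE)
      }
    }
  }
  invisible(config)
}

#' Read a YAML run configuration
#'
#' @param path Path to a YAML file whose blocks mirror the package's
#'   parameter groups (`model`, `ensemble`, `coupling`, `ddm`, `flicker`,
#'   `synth`) plus `seed`, `n_range`, `observations_csv`, `output_dir`.
#' @return The validated configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  validate_run_config(yaml::read_yaml(path))
}

.config_to_rft <- function(model) {
  model <- model %||% list()
  rft_config(
    helix = helix_geometry(
      model$helix_radius_um %||% 0.2,
      model$pitch_um %||% 2.26,
      model$axial_length_um %||% 6,
      model$filament_radius_um %||% 0.01,
      model$handedness %||% "left"
    ),
    body = cell_body(
      model$body_length_um %||% 3.0,
      model$body_width_um %||% 0.9,
      (model$wobble_angle_deg %||% 20) * pi / 180
    ),
    motor_hz = model$motor_hz %||% 220,
    mu = model$mu %||% 1e-3,
    variant = model$variant %||% "gray_hancock",
    thickness_exponent = model$thickness_exponent %||% 0.5
  )
}

.config_to_ensemble <- function(ens, default_seed = 1L) {
  ens <- ens %||% list()
  ensemble_spec(
    n_cells = ens$n_cells %||% 5000,
    body_length_dist = list(name = "lognormal",
                            mean = ens$body_length_mean_um %||% 3.0,
                            cv = ens$body_length_cv %||% 0.15),
    body_width_dist = list(name = "lognormal",
                           mean = ens$body_width_mean_um %||% 0.9,
                           cv = ens$body_width_cv %||% 0.10),
    wobble_dist = list(name = "uniform", min_deg = 0,
                       max_deg = ens$wobble_max_deg %||% 40),
    seed = ens$seed %||% default_seed
  )
}

.config_to_coupling <- function(cp) {
  cp <- cp %||% list()
  coupling_model(
    number_slope = cp$number_slope %||% 1,
    number_intercept = cp$number_intercept %||% 0,
    length_max_um = cp$length_max_um %||% 8,
    length_halfsat = cp$length_halfsat %||% 2
  )
}

#' Predict the population velocity-versus-flagella curve and write it out
#'
#' End-to-end Fig-2e-style workflow: builds the model and ensemble from the
#' configuration, runs [predict_population_curve()], optionally calibrates
#' the single velocity scale against an observed `(n_flagella, v_um_s)` CSV,
#' and writes the curve as CSV plus a JSON metadata block (config hash, seed,
#' package version, calibration scale).
#'
#' @param config A validated configuration list (see [validate_run_config()]).
#' @param output_dir Directory for outputs (default `config$output_dir` or a
#'   temporary directory).
#' @param prefix File-name prefix (default `"predicted_curve"`).
#' @return Invisibly, a list with `curve` (data.frame), `calibration_scale`
#'   (or `NULL`), and the paths written.
#' @export
run_predict_curve <- function(config = list(), output_dir = NULL,
                              prefix = "predicted_curve") {
  validate_run_config(config)
  output_dir <- output_dir %||% config$output_dir %||% tempdir()
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  rft <- .config_to_rft(config$model)
  spec <- .config_to_ensemble(config$ensemble, default_seed = seed)
  coupling <- .config_to_coupling(config$coupling)
  n_range <- config$n_range %||% 1:10
  curve <- predict_population_curve(spec, coupling, rft, n_range)

  scale <- NULL
  if (!is.null(config$observations_csv)) {
    obs <- utils::read.csv(config$observations_csv)
    if (!all(c("n_flagella", "v_um_s") %in% names(obs))) {
      stop("observations CSV needs columns n_flagella, v_um_s",
           call. = FALSE)
    }
    pred_at_obs <- curve$v_mean_um_s[match(obs$n_flagella, curve$n_flagella)]
    if (anyNA(pred_at_obs)) {
      stop("observed flagellar numbers outside the predicted range",
           call. = FALSE)
    }
    scale <- calibrate_scale(pred_at_obs, obs$v_um_s)
  }

  csv_path <- file.path(output_dir, paste0(prefix, ".csv"))
  out <- data.frame(n_flagella = curve$n_flagella,
                    v_um_s = curve$v_mean_um_s,
                    v_sd_um_s = curve$v_sd_um_s)
  utils::write.csv(out, csv_path, row.names = FALSE)
  meta <- list(
    config = config,
    config_hash = .config_hash(config),
    seed = spec$seed,
    n_cells = spec$n_cells,
    calibration_scale = scale,
    package_version = as.character(utils::packageVersion("swimRFT")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  json_path <- file.path(output_dir, paste0(prefix, "_metadata.json"))
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(list(curve = curve, calibration_scale = scale,
                 csv = csv_path, metadata = json_path))
}

#' Write an image stack as a multi-page TIFF with a JSON sidecar
#'
#' Intensities are affinely mapped to `[0, 1]` and stored as 16-bit
#' grayscale; the sidecar records the frame rate, pixel size and the affine
#' scaling (DDM is invariant to it), plus generator parameters when a ground
#' truth is supplied.
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path; the sidecar is `paste0(path, ".json")`.
#' @param ground_truth Optional `synthetic_ground_truth` (trajectories are
#'   not serialized).
#' @return The TIFF path, invisibly.
#' @export
write_image_stack <- function(stack, path, ground_truth = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  rng <- range(stack$frames)
  span <- if (diff(rng) > 0) diff(rng) else 1
  pages <- lapply(seq_len(dim(stack$frames)[1]), function(t) {
    (stack$frames[t, , ] - rng[1]) / span
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  meta <- list(frame_rate_hz = stack$frame_rate_hz,
               pixel_size_um = stack$pixel_size_um,
               intensity_offset = rng[1], intensity_span = span)
  if (!is.null(ground_truth)) {
    gt <- unclass(ground_truth)
    gt$trajectories_um <- NULL
    gt$is_swimmer <- NULL
    gt$speeds_um_s <- NULL
    meta$ground_truth <- gt
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a multi-page TIFF movie
#'
#' Metadata (frame rate, pixel size) is taken from the arguments, else from
#' the JSON sidecar written by [write_image_stack()]; if neither supplies a
#' value the error names the missing field.
#'
#' @param path TIFF path.
#' @param frame_rate_hz,pixel_size_um Optional metadata overrides.
#' @return An [image_stack()].
#' @export
read_image_stack <- function(path, frame_rate_hz = NULL,
                             pixel_size_um = NULL) {
  if (!file.exists(path)) stop("stack not found: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  frame_rate_hz <- frame_rate_hz %||% meta$frame_rate_hz
  pixel_size_um <- pixel_size_um %||% meta$pixel_size_um
  if (is.null(frame_rate_hz)) {
    stop("missing frame_rate_hz: pass it or provide a JSON sidecar",
         call. = FALSE)
  }
  if (is.null(pixel_size_um)) {
    stop("missing pixel_size_um: pass it or provide a JSON sidecar",
         call. = FALSE)
  }
  d <- dim(pages[[1]])
  frames <- array(0, dim = c(length(pages), d[1], d[2]))
  for (t in seq_along(pages)) frames[t, , ] <- pages[[t]]
  image_stack(frames, frame_rate_hz, pixel_size_um)
}

#' Run the DDM workflow on a movie file
#'
#' Reads a multi-page TIFF, computes the radially averaged image structure
#' function, fits the mixed swimmer/diffuser model, and writes a JSON report
#' with the motility estimate, the population-averaged velocity
#' (alpha x v_bar) and per-q diagnostics.
#'
#' @param stack_path Path to the TIFF movie.
#' @param config Configuration list; the `ddm` block may set `frame_rate_hz`,
#'   `pixel_size_um`, `q_min`, `q_max`, `max_lag_frames`, `n_pairs_max`.
#' @param output_path JSON output path (default next to the stack).
#' @return Invisibly, a list with `estimate`, `population_velocity_um_s` and
#'   the JSON path.
#' @export
run_ddm <- function(stack_path, config = list(), output_path = NULL) {
  validate_run_config(config)
  ddm_cfg <- config$ddm %||% list()
  stack <- read_image_stack(stack_path,
                            frame_rate_hz = ddm_cfg$frame_rate_hz,
                            pixel_size_um = ddm_cfg$pixel_size_um)
  if (dim(stack$frames)[1] < 10) {
    stop("insufficient frames for a structure function (need >= 10)",
         call. = FALSE)
  }
  lags <- .default_lags(dim(stack$frames)[1], ddm_cfg$max_lag_frames)
  sf <- image_structure_function(stack, lags,
                                 n_pairs_max = ddm_cfg$n_pairs_max %||% 50)
  est <- fit_structure_function(
    sf, q_window = c(ddm_cfg$q_min %||% 0.4, ddm_cfg$q_max %||% 2.0))
  pv <- population_velocity(est)
  report <- list(
    alpha = est$alpha,
    v_bar_um_s = est$v_bar_um_s,
    Z = est$Z,
    D_um2_s = est$D_um2_s,
    population_velocity_um_s = pv,
    q_window = est$q_window,
    per_q = est$per_q,
    config = config,
    config_hash = .config_hash(config),
    package_version = as.character(utils::packageVersion("swimRFT"))
  )
  output_path <- output_path %||% paste0(tools::file_path_sans_ext(stack_path),
                                         "_ddm.json")
  jsonlite::write_json(report, output_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE, dataframe = "columns")
  invisible(list(estimate = est, population_velocity_um_s = pv,
                 json = output_path))
}
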
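#' Default run configuration
#'
#' Nested configuration for the whole pipeline: layout spec, render config,
#' population model, detection parameters, classification thresholds and
#' capture model. Values mirror the constructors' defaults (the chip's
#' operating point); [run_config()] merges a JSON config file and overrides
#' onto these, rejecting unknown keys.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(seed = 1L,
       format = "ascii",
       layout = list(field_width_nm = 5000, field_height_nm = 5000,
                     pitch_nm = 1414, spot_diameter_nm = 200,
                     brush_height_low_nm = 2, brush_height_high_nm = 3),
       render = list(pixel_size_nm = 5, noise_sd_nm = 0.3, tilt_x = 0,
                     tilt_y = 0, line_offset_sd_nm = 0, tip_radius_nm = 0),
       population = list(occupancy = 0.20,
                         D_dist = list(dist = "normal", mean = 27.7,
                                       sd = 4.7, min = 1),
                         ar_dist = list(dist = "normal", mean = 0.20,
                                        sd = 0.04, min = 1e-3, max = 1),
                         evs_per_spot = 1, ldl_rate = 0.3,
                         ldl_d_range_nm = c(10, 18),
                         ldl_ar_range = c(0.3, 0.6)),
       detection = list(seed_threshold_nm = NA, footprint_fraction = 0.1,
                        min_area_px = 4, spot_margin_nm = 50,
                        background_radius_nm = 60, min_separation_nm = 15,
                        max_footprint_nm = 300, baseline = "local_annulus"),
       thresholds = list(ev_min_d_nm = 30, ev_min_h_nm = 7,
                         ldl_max_d_nm = 20, ldl_ar_low = 0.3,
                         ldl_ar_high = 0.6),
       capture = list(drag_coefficient = 1, resistance_force = 1600,
                      flow_velocity = 1))
}

merge_config <- function(base, new, path = "") {
  for (k in names(new)) {
    full <- if (nzchar(path)) paste0(path, ".", k) else k
    if (!k %in% names(base))
      stop("unknown config key: ", full)
    if (is.list(base[[k]]) && !k %in% c("D_dist", "ar_dist")) {
      if (!is.list(new[[k]])) stop("config key ", full, " must be a section")
      base[[k]] <- merge_config(base[[k]], new[[k]], full)
    } else {
      base[[k]] <- new[[k]]
    }
  }
  base
}

#' Load and validate a run configuration
#'
#' Precedence: `overrides` > JSON file > defaults. Unknown keys at any level
#' raise an error naming the key; the merged configuration is validated by
#' instantiating every parameter object.
#'
#' @param path optional JSON config file.
#' @param overrides optional nested list of overrides.
#' @return Validated configuration list (class `run_config`).
#' @export
run_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    file_cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
    cfg <- merge_config(cfg, file_cfg)
  }
  if (!is.null(overrides) && length(overrides))
    cfg <- merge_config(cfg, overrides)
  # instantiate everything so precondition violations surface at load time
  config_objects(cfg)
  structure(cfg, class = c("run_config", "list"))
}

as_dist_spec <- function(x) {
  if (inherits(x, "dist_spec")) return(x)
  dist_spec(dist = x$dist, mean = x$mean, sd = x$sd,
            min = x$min %||% -Inf, max = x$max %||% Inf,
            value = x$value)
}

config_objects <- function(cfg) {
  det <- cfg$detection
  thr_seed <- det$seed_threshold_nm
  if (is.null(thr_seed) || is.na(thr_seed)) thr_seed <- NULL
  list(
    spec = layout_spec(field_width_nm = cfg$layout$field_width_nm,
                       field_height_nm = cfg$layout$field_height_nm,
                       pitch_nm = cfg$layout$pitch_nm,
                       spot_diameter_nm = cfg$layout$spot_diameter_nm,
                       brush_height_low_nm = cfg$layout$brush_height_low_nm,
                       brush_height_high_nm = cfg$layout$brush_height_high_nm),
    render = render_config(pixel_size_nm = cfg$render$pixel_size_nm,
                           noise_sd_nm = cfg$render$noise_sd_nm,
                           tilt_x = cfg$render$tilt_x,
                           tilt_y = cfg$render$tilt_y,
                           line_offset_sd_nm = cfg$render$line_offset_sd_nm,
                           tip_radius_nm = cfg$render$tip_radius_nm,
                           seed = cfg$seed),
    D_dist = as_dist_spec(cfg$population$D_dist),
    ar_dist = as_dist_spec(cfg$population$ar_dist),
    detection = detection_params(seed_threshold_nm = thr_seed,
                                 footprint_fraction = det$footprint_fraction,
                                 min_area_px = det$min_area_px,
                                 spot_margin_nm = det$spot_margin_nm,
                                 background_radius_nm = det$background_radius_nm,
                                 min_separation_nm = det$min_separation_nm,
                                 max_footprint_nm = det$max_footprint_nm,
                                 baseline = det$baseline),
    thresholds = class_thresholds(ev_min_d_nm = cfg$thresholds$ev_min_d_nm,
                                  ev_min_h_nm = cfg$thresholds$ev_min_h_nm,
                                  ldl_max_d_nm = cfg$thresholds$ldl_max_d_nm,
                                  ldl_ar_low = cfg$thresholds$ldl_ar_low,
                                  ldl_ar_high = cfg$thresholds$ldl_ar_high),
    capture = capture_model(drag_coefficient = cfg$capture$drag_coefficient,
                            resistance_force = cfg$capture$resistance_force,
                            flow_velocity = cfg$capture$flow_velocity))
}

#' Write / read a ground-truth particle CSV
#'
#' Columns: `particle_id, x_nm, y_nm, D_true_nm, d_true_nm, h_true_nm,
#' ar_true, class, spot_id`.
#'
#' @param truth true-particle data.frame (from an `afm_scene`'s
#'   `truth$particles`).
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  out <- data.frame(particle_id = truth$particle_id,
                    x_nm = truth$x_nm, y_nm = truth$y_nm,
                    D_true_nm = truth$D_true_nm,
                    d_true_nm = truth$d_true_nm,
                    h_true_nm = truth$h_true_nm,
                    ar_true = truth$ar_true,
                    class = truth$klass,
                    spot_id = if (!is.null(truth$spot_id)) truth$spot_id
                              else rep(NA_integer_, nrow(truth)))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  names(df)[names(df) == "class"] <- "klass"
  df
}
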
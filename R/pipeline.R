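#' Run the full measurement pipeline on one height map
#'
#' Chains the stages applied to every scan: plane leveling, scan-line
#' leveling, noise estimation, particle detection, morphometry,
#' classification, and (when a layout is supplied) spot assignment with
#' occupancy.
#'
#' @param map a [height_map()].
#' @param layout optional `nanospot_layout` for spot assignment.
#' @param params a [detection_params()].
#' @param thresholds a [class_thresholds()].
#' @param level apply leveling first (disable for already-leveled maps).
#' @param level_order polynomial order for [plane_level()].
#' @return A list of class `processed_scene`: `particles` (classified
#'   particle table), `occupancy` (data.frame or NULL), `noise_sd_nm`,
#'   `level_report` (or NULL), and the leveled `map`.
#' @export
process_height_map <- function(map, layout = NULL,
                               params = detection_params(),
                               thresholds = class_thresholds(),
                               level = TRUE, level_order = 1L) {
  report <- NULL
  if (level) {
    pl <- plane_level(map, order = level_order)
    map <- line_level(pl$map)
    report <- pl$report
  }
  noise <- estimate_noise(map)
  regions <- detect_particles(map, params)
  particles <- measure_particles(regions, map, params)
  particles <- classify_particles(particles, thresholds)
  occupancy <- NULL
  if (!is.null(layout)) {
    asg <- assign_to_spots(particles, layout, params)
    particles <- asg$particles
    occupancy <- asg$occupancy
  }
  structure(list(particles = particles, occupancy = occupancy,
                 noise_sd_nm = noise, level_report = report, map = map),
            class = "processed_scene")
}

#' @export
print.processed_scene <- function(x, ...) {
  k <- table(factor(x$particles$klass,
                    levels = c("EV", "LDL_like", "unclassified")))
  cat(sprintf("Processed scan: %d particles (%d EV, %d LDL-like, %d unclassified), noise %.3g nm\n",
              nrow(x$particles), k["EV"], k["LDL_like"], k["unclassified"],
              x$noise_sd_nm))
  if (!is.null(x$occupancy))
    cat(sprintf("  occupancy: %d of %d spots (%.3g)\n",
                sum(x$occupancy$occupied), nrow(x$occupancy),
                occupancy_fraction(x$occupancy)))
  invisible(x)
}
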
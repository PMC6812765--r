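#' Summarise an EV population
#'
#' Arithmetic mean and sample standard deviation (n-1 denominator) of the
#' footprint diameter, apex height, aspect ratio and estimated suspension
#' diameter, plus the nanospot occupancy when known. Non-EV and
#' border-flagged rows are dropped first when present.
#'
#' @param particles particle data.frame (EV-class rows are used).
#' @param occupancy occupancy fraction in `[0, 1]`, or NA when no layout was
#'   available.
#' @param label population label, e.g. the cell line.
#' @return An object of class `population_summary`.
#' @export
summarize_population <- function(particles, occupancy = NA_real_,
                                 label = "") {
  if (!is.null(particles$klass))
    particles <- particles[particles$klass == "EV", , drop = FALSE]
  if (!is.null(particles$border_flag))
    particles <- particles[!particles$border_flag, , drop = FALSE]
  if (!nrow(particles)) stop("no EV-class particles to summarise")
  stat <- function(v) c(mean = mean(v), sd = if (length(v) > 1) sd(v) else 0)
  structure(list(label = label, n = nrow(particles),
                 d_nm = stat(particles$d_nm), h_nm = stat(particles$h_nm),
                 ar = stat(particles$ar), D_nm = stat(particles$D_nm),
                 occupancy = occupancy),
            class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf("Population '%s': n = %d EVs%s\n", x$label, x$n,
              if (is.finite(x$occupancy))
                sprintf(", occupancy %.3g", x$occupancy) else ""))
  for (f in c("d_nm", "h_nm", "ar", "D_nm"))
    cat(sprintf("  %-5s %8.4g +/- %.4g\n", sub("_nm", " (nm)", f),
                x[[f]]["mean"], x[[f]]["sd"]))
  invisible(x)
}

#' Pooled two-sample Student's t-test
#'
#' Two-sided pooled-variance (classical Student) t-test with
#' `df = n_a + n_b - 2`, as used to compare mean aspect ratios between cell
#' lines at the 95% confidence level. Degenerate zero-variance inputs are
#' resolved explicitly: equal means give t = 0, p = 1; unequal means give
#' p = 0 with a warning.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @param alpha significance level (default 0.05).
#' @return An object of class `ev_t_test` with `t_statistic`,
#'   `degrees_of_freedom`, `p_two_sided`, `alpha`, `significant`, plus group
#'   means and sizes.
#' @examples
#' student_t_test(c(0.1, 0.2, 0.3), c(0.4, 0.5, 0.6))  # t = -3.674, p ~ 0.021
#' @export
student_t_test <- function(a, b, alpha = 0.05) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs at least 2 values")
  df <- length(a) + length(b) - 2
  pooled_var <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) / df
  if (pooled_var == 0) {
    if (mean(a) == mean(b)) {
      tt <- 0; p <- 1
    } else {
      warning("zero pooled variance with unequal means; p = 0")
      tt <- sign(mean(a) - mean(b)) * Inf; p <- 0
    }
  } else {
    ht <- t.test(a, b, var.equal = TRUE)
    tt <- unname(ht$statistic)
    p <- ht$p.value
  }
  structure(list(t_statistic = tt, degrees_of_freedom = df,
                 p_two_sided = p, alpha = alpha, significant = p < alpha,
                 mean_a = mean(a), mean_b = mean(b),
                 n_a = length(a), n_b = length(b)),
            class = "ev_t_test")
}

#' @export
print.ev_t_test <- function(x, ...) {
  cat(sprintf("Pooled two-sample t-test: t = %.4g, df = %d, p = %.4g (%s at alpha = %g)\n",
              x$t_statistic, x$degrees_of_freedom, x$p_two_sided,
              if (x$significant) "significant" else "not significant",
              x$alpha))
  cat(sprintf("  means %.4g (n = %d) vs %.4g (n = %d)\n",
              x$mean_a, x$n_a, x$mean_b, x$n_b))
  invisible(x)
}

#' Drag-versus-adhesion capture model for the tethering flow cell
#'
#' Toy model of the chip's size selectivity: the laminar drag force on a
#' sphere of diameter D scales as D^2 (`drag_coefficient * flow_velocity *
#' D^2`), while the PEG-lipid adhesion supplies a constant resistance
#' force. A vesicle is captured when drag does not exceed resistance, which
#' implies a critical diameter `D* = sqrt(resistance / (coeff * velocity))`
#' above which nothing tethers. Units are arbitrary but consistent; the
#' defaults put D* at 40 nm, the upper end of the tethered-size regime.
#'
#' @param drag_coefficient force per (velocity * D^2), >= 0.
#' @param resistance_force constant adhesion force, >= 0.
#' @param flow_velocity flow velocity, >= 0.
#' @return An object of class `capture_model` (includes
#'   `critical_diameter_nm`).
#' @export
capture_model <- function(drag_coefficient = 1, resistance_force = 1600,
                          flow_velocity = 1) {
  stopifnot(drag_coefficient >= 0, resistance_force >= 0, flow_velocity >= 0)
  dstar <- if (drag_coefficient * flow_velocity > 0)
    sqrt(resistance_force / (drag_coefficient * flow_velocity)) else Inf
  structure(list(drag_coefficient = drag_coefficient,
                 resistance_force = resistance_force,
                 flow_velocity = flow_velocity,
                 critical_diameter_nm = dstar),
            class = "capture_model")
}

#' @export
print.capture_model <- function(x, ...) {
  cat(sprintf("Capture model: drag = %.4g * v * D^2, resistance = %.4g, v = %.4g\n",
              x$drag_coefficient, x$resistance_force, x$flow_velocity))
  cat(sprintf("  critical diameter D* = %.4g nm\n", x$critical_diameter_nm))
  invisible(x)
}

#' Capture predicate: is a vesicle of diameter D tethered?
#'
#' @param D_nm suspension diameter(s) in nm.
#' @param model a [capture_model()].
#' @return Logical vector: drag `<=` resistance.
#' @export
capture_predicate <- function(D_nm, model = capture_model()) {
  stopifnot(inherits(model, "capture_model"))
  model$drag_coefficient * model$flow_velocity * D_nm^2 <=
    model$resistance_force
}

#' Apply the capture filter to a suspension population
#'
#' Filters a population of suspension diameters by [capture_predicate()] and
#' reports the mean before and after: when the critical diameter is interior
#' to the support, the captured subpopulation is strictly smaller on
#' average, mirroring the selective tethering of small vesicles out of a
#' much larger suspension distribution.
#'
#' @param D_nm suspension diameters in nm (nonempty).
#' @param model a [capture_model()].
#' @return A list of class `capture_summary`: `captured` (values), `n_total`,
#'   `n_captured`, `mean_before`, `mean_after` (NA when none captured), and
#'   the model.
#' @export
apply_capture_filter <- function(D_nm, model = capture_model()) {
  if (!length(D_nm)) stop("empty population")
  keep <- capture_predicate(D_nm, model)
  structure(list(captured = D_nm[keep], n_total = length(D_nm),
                 n_captured = sum(keep), mean_before = mean(D_nm),
                 mean_after = if (any(keep)) mean(D_nm[keep]) else NA_real_,
                 model = model),
            class = "capture_summary")
}

#' @export
print.capture_summary <- function(x, ...) {
  cat(sprintf("Capture filter (D* = %.4g nm): %d of %d captured\n",
              x$model$critical_diameter_nm, x$n_captured, x$n_total))
  cat(sprintf("  mean D before %.4g nm, after %.4g nm\n",
              x$mean_before, x$mean_after))
  invisible(x)
}
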
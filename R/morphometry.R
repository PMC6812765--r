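#' Aspect ratio of an adsorbed particle
#'
#' The deformability indicator AR = h/d: apex height over footprint
#' diameter. Smaller AR means a flatter, more deformed vesicle.
#'
#' @param d_nm footprint diameter(s), positive.
#' @param h_nm apex height(s).
#' @return h/d, vectorised.
#' @examples
#' aspect_ratio(50, 10)  # 0.2
#' @export
aspect_ratio <- function(d_nm, h_nm) {
  if (any(!is.finite(d_nm)) || any(d_nm <= 0))
    stop("d_nm must be positive")
  h_nm / d_nm
}

#' Suspension diameter from adsorbed geometry (volume conservation)
#'
#' An EV adsorbing without volume change from a sphere of diameter D into an
#' oblate ellipsoid of footprint d and height h satisfies
#' `pi D^3 / 6 = pi d^2 h / 6`, so `D = (d^2 h)^(1/3)`. Equivalently
#' AR = h/d = D^3 / d^3, the origin of the AR ~ d^-3 law.
#'
#' @param d_nm footprint diameter(s), positive.
#' @param h_nm apex height(s), positive.
#' @return D in nm, vectorised.
#' @examples
#' estimate_suspension_diameter(50, 10)  # 29.24 nm
#' @export
estimate_suspension_diameter <- function(d_nm, h_nm) {
  if (any(!is.finite(d_nm)) || any(d_nm <= 0) ||
      any(!is.finite(h_nm)) || any(h_nm <= 0))
    stop("d_nm and h_nm must be positive")
  (d_nm^2 * h_nm)^(1 / 3)
}

#' Classification thresholds for EV versus lipoprotein-like particles
#'
#' A particle counts as an EV when footprint diameter and height strictly
#' exceed 30 nm and 7 nm; small peripheral particles under 20 nm with AR in
#' about 0.3-0.6 are lipoprotein-like (LDL co-purifies with EVs and is
#' morphologically distinguished); everything else is unclassified.
#'
#' @param ev_min_d_nm,ev_min_h_nm EV thresholds (strict exceedance).
#' @param ldl_max_d_nm LDL-like maximum diameter (strict).
#' @param ldl_ar_low,ldl_ar_high inclusive LDL-like AR band.
#' @return An object of class `class_thresholds`.
#' @export
class_thresholds <- function(ev_min_d_nm = 30, ev_min_h_nm = 7,
                             ldl_max_d_nm = 20, ldl_ar_low = 0.3,
                             ldl_ar_high = 0.6) {
  stopifnot(ev_min_d_nm > 0, ev_min_h_nm > 0, ldl_max_d_nm > 0,
            ldl_ar_low > 0, ldl_ar_low < ldl_ar_high)
  structure(list(ev_min_d_nm = ev_min_d_nm, ev_min_h_nm = ev_min_h_nm,
                 ldl_max_d_nm = ldl_max_d_nm, ldl_ar_low = ldl_ar_low,
                 ldl_ar_high = ldl_ar_high),
            class = "class_thresholds")
}

#' Classify particles as EV, LDL-like or unclassified
#'
#' Rules, in order: EV iff `d > ev_min_d` and `h > ev_min_h` (strict);
#' else LDL-like iff `d < ldl_max_d` and AR in `[ldl_ar_low, ldl_ar_high]`;
#' else unclassified.
#'
#' @param particles particle data.frame with `d_nm`, `h_nm`, `ar` columns.
#' @param thresholds a [class_thresholds()].
#' @return The data.frame with `klass` filled in.
#' @export
classify_particles <- function(particles, thresholds = class_thresholds()) {
  if (!nrow(particles)) return(particles)
  t <- thresholds
  k <- rep("unclassified", nrow(particles))
  ldl <- particles$d_nm < t$ldl_max_d_nm &
    particles$ar >= t$ldl_ar_low & particles$ar <= t$ldl_ar_high
  k[!is.na(ldl) & ldl] <- "LDL_like"
  ev <- particles$d_nm > t$ev_min_d_nm & particles$h_nm > t$ev_min_h_nm
  k[!is.na(ev) & ev] <- "EV"
  particles$klass <- k
  particles
}

#' Classify a single (d, h) measurement
#'
#' @param d_nm footprint diameter in nm.
#' @param h_nm apex height in nm.
#' @inheritParams classify_particles
#' @return `"EV"`, `"LDL_like"` or `"unclassified"`.
#' @export
classify_particle <- function(d_nm, h_nm, thresholds = class_thresholds()) {
  df <- classify_particles(
    data.frame(d_nm = d_nm, h_nm = h_nm, ar = h_nm / d_nm), thresholds)
  df$klass
}

#' Fit the aspect-ratio power law AR = c * d^-3
#'
#' Ordinary least squares of AR on x = d^-3, through the origin by default
#' (the volume-conservation law has no intercept and c estimates the cubed
#' common suspension diameter, c = D^3 when D is constant). The closed form
#' is `c = sum(x * AR) / sum(x^2)`.
#'
#' @param particles particle data.frame restricted to EV-class rows, or any
#'   data.frame with `d_nm` and `ar` columns.
#' @param intercept fit a free intercept as a sensitivity variant.
#' @return An object of class `ar_fit` with elements `c` (nm^3),
#'   `intercept`, `n_points`, `rms_residual`, `d_range_nm`.
#' @examples
#' fit_ar_model(data.frame(d_nm = 35, ar = 0.30))  # c = 12862.5
#' @export
fit_ar_model <- function(particles, intercept = FALSE) {
  if (!nrow(particles)) stop("no particles to fit")
  d <- particles$d_nm
  ar <- particles$ar
  if (any(!is.finite(d)) || any(d <= 0) || any(!is.finite(ar)))
    stop("d_nm must be positive and ar finite")
  x <- d^-3
  if (intercept) {
    fit <- lm(ar ~ x)
    cc <- unname(coef(fit)[2])
    b0 <- unname(coef(fit)[1])
    res <- stats::residuals(fit)
  } else {
    cc <- sum(x * ar) / sum(x^2)
    b0 <- 0
    res <- ar - cc * x
  }
  structure(list(c = cc, intercept = b0, n_points = length(x),
                 rms_residual = sqrt(mean(res^2)),
                 d_range_nm = range(d)),
            class = "ar_fit")
}

#' @export
print.ar_fit <- function(x, ...) {
  cat(sprintf("AR ~ c * d^-3 fit: c = %.6g nm^3 (implied common D = %.4g nm)\n",
              x$c, if (x$c > 0) x$c^(1 / 3) else NA))
  if (x$intercept != 0)
    cat(sprintf("  intercept = %.4g\n", x$intercept))
  cat(sprintf("  n = %d, rms residual = %.4g, d in [%.4g, %.4g] nm\n",
              x$n_points, x$rms_residual, x$d_range_nm[1], x$d_range_nm[2]))
  invisible(x)
}

#' @export
coef.ar_fit <- function(object, ...) {
  c(intercept = object$intercept, c = object$c)
}

#' Predicted AR at given footprint diameters
#'
#' @param object an `ar_fit`.
#' @param newdata data.frame with a `d_nm` column (or numeric vector of d).
#' @param ... unused.
#' @export
predict.ar_fit <- function(object, newdata, ...) {
  d <- if (is.data.frame(newdata)) newdata$d_nm else newdata
  object$intercept + object$c * d^-3
}

#' Plot an AR versus d scatter with the fitted power-law curve
#'
#' @param x an `ar_fit`.
#' @param particles optional particle data.frame to overlay as points.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ar_fit <- function(x, particles = NULL, ...) {
  dr <- x$d_range_nm
  dd <- seq(dr[1] * 0.9, dr[2] * 1.1, length.out = 200)
  if (!is.null(particles) && nrow(particles)) {
    plot(particles$d_nm, particles$ar, xlab = "footprint diameter d (nm)",
         ylab = "aspect ratio h/d", ...)
    lines(dd, predict(x, dd), lwd = 2)
  } else {
    plot(dd, predict(x, dd), type = "l", lwd = 2,
         xlab = "footprint diameter d (nm)", ylab = "aspect ratio h/d", ...)
  }
  invisible(x)
}

#' Fraction of nanospots occupied by EVs
#'
#' @param occupancy the occupancy data.frame from [assign_to_spots()] (or a
#'   logical vector of per-spot occupancy flags).
#' @return Occupied spots / total spots, in `[0, 1]`.
#' @export
occupancy_fraction <- function(occupancy) {
  occ <- if (is.data.frame(occupancy)) occupancy$occupied else occupancy
  if (!length(occ)) stop("layout has zero spots")
  mean(as.logical(occ))
}
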
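#' Construct ground-truth particles from suspension diameter and aspect ratio
#'
#' An EV of suspension diameter D adsorbing without volume change into an
#' oblate ellipsoid of footprint diameter d and apex height h with aspect
#' ratio AR = h/d satisfies D^3 = d^2 h, hence
#' `d = D * AR^(-1/3)` and `h = D * AR^(2/3)`.
#'
#' @param D_nm suspension diameter(s) in nm, positive.
#' @param ar aspect ratio(s) in (0, 1].
#' @param x_nm,y_nm particle centre coordinates (NA until placed on a scene).
#' @param klass `"EV"` or `"LDL_like"`.
#' @return A data.frame of true particles with columns `particle_id`,
#'   `x_nm`, `y_nm`, `D_true_nm`, `d_true_nm`, `h_true_nm`, `ar_true`,
#'   `klass`.
#' @examples
#' true_particles(D_nm = 27.7, ar = 0.20)  # d ~ 47.4 nm, h ~ 9.5 nm
#' @export
true_particles <- function(D_nm, ar, x_nm = NA_real_, y_nm = NA_real_,
                           klass = "EV") {
  if (any(!is.finite(D_nm)) || any(D_nm <= 0))
    stop("D_nm must be positive and finite")
  if (any(!is.finite(ar)) || any(ar <= 0) || any(ar > 1))
    stop("ar must lie in (0, 1]")
  n <- max(length(D_nm), length(ar))
  D_nm <- rep_len(D_nm, n); ar <- rep_len(ar, n)
  data.frame(particle_id = seq_len(n),
             x_nm = rep_len(x_nm, n), y_nm = rep_len(y_nm, n),
             D_true_nm = D_nm,
             d_true_nm = D_nm * ar^(-1 / 3),
             h_true_nm = D_nm * ar^(2 / 3),
             ar_true = ar,
             klass = rep_len(klass, n),
             stringsAsFactors = FALSE)
}

#' Ground-truth particles from footprint diameter and height
#'
#' Inverse parametrisation of [true_particles()]: given adsorbed footprint
#' d and apex height h, AR = h/d and D = (d^2 h)^(1/3).
#'
#' @param d_nm footprint diameter(s) in nm.
#' @param h_nm apex height(s) in nm.
#' @inheritParams true_particles
#' @return Same layout as [true_particles()].
#' @export
true_particles_from_footprint <- function(d_nm, h_nm, x_nm = NA_real_,
                                          y_nm = NA_real_, klass = "EV") {
  if (any(d_nm <= 0) || any(h_nm <= 0)) stop("d_nm and h_nm must be positive")
  true_particles(D_nm = (d_nm^2 * h_nm)^(1 / 3), ar = h_nm / d_nm,
                 x_nm = x_nm, y_nm = y_nm, klass = klass)
}

#' Sample a ground-truth EV population
#'
#' Draws suspension diameters D and aspect ratios AR from the given
#' distribution specs and derives the adsorbed geometry under volume
#' conservation. Defaults reflect the tethered-EV regime on 200 nm spots:
#' D ~ normal(27.7, 4.7) nm and AR ~ normal(0.20, 0.04) truncated to (0, 1].
#'
#' @param n number of particles.
#' @param D_dist,ar_dist [dist_spec()]s for D (nm, positive) and AR
#'   (truncated to (0, 1]).
#' @param seed integer seed.
#' @param klass class label recorded in the truth table.
#' @return A true-particle data.frame (see [true_particles()]).
#' @export
sample_population <- function(n,
                              D_dist = dist_spec("normal", mean = 27.7,
                                                 sd = 4.7, min = 1),
                              ar_dist = dist_spec("normal", mean = 0.20,
                                                  sd = 0.04, min = 1e-3,
                                                  max = 1),
                              seed = 1L, klass = "EV") {
  stopifnot(n >= 0)
  ar_ok <- if (ar_dist$dist == "fixed")
    ar_dist$value > 0 && ar_dist$value <= 1
  else ar_dist$min >= 0 && ar_dist$max <= 1
  if (!ar_ok) stop("ar_dist must be supported on (0, 1]")
  D_ok <- if (D_dist$dist == "fixed") D_dist$value > 0 else D_dist$min >= 0
  if (!D_ok) stop("D_dist must be truncated to positive values")
  if (n == 0) return(true_particles(numeric(0), numeric(0)))
  set.seed(derive_seed(seed, "population_D"))
  D <- draw_dist(n, D_dist)
  set.seed(derive_seed(seed, "population_ar"))
  ar <- draw_dist(n, ar_dist)
  true_particles(D_nm = D, ar = ar, klass = klass)
}
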
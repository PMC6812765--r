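#' Rendering configuration for synthetic AFM scenes
#'
#' Emulates the scan conditions of a tapping-mode AFM image: pixel size,
#' Gaussian height noise, background plane tilt, per-scan-row offsets and
#' optional tip broadening (grayscale dilation with a spherical-cap
#' structuring element of the given tip radius).
#'
#' @param pixel_size_nm pixel edge in nm (default 5).
#' @param noise_sd_nm Gaussian height-noise sigma in nm (default 0.3).
#' @param tilt_x,tilt_y background plane slope in nm per nm.
#' @param line_offset_sd_nm per-scan-row offset sigma in nm.
#' @param tip_radius_nm AFM tip radius in nm; 0 disables tip broadening.
#' @param seed integer seed for the stochastic components.
#' @return An object of class `render_config`.
#' @export
render_config <- function(pixel_size_nm = 5, noise_sd_nm = 0.3,
                          tilt_x = 0, tilt_y = 0, line_offset_sd_nm = 0,
                          tip_radius_nm = 0, seed = 1L) {
  stopifnot(pixel_size_nm > 0, noise_sd_nm >= 0, line_offset_sd_nm >= 0,
            tip_radius_nm >= 0, is.finite(tilt_x), is.finite(tilt_y))
  structure(list(pixel_size_nm = pixel_size_nm, noise_sd_nm = noise_sd_nm,
                 tilt_x = tilt_x, tilt_y = tilt_y,
                 line_offset_sd_nm = line_offset_sd_nm,
                 tip_radius_nm = tip_radius_nm, seed = as.integer(seed)),
            class = "render_config")
}

# grayscale dilation of a height field with a spherical-cap tip of radius R:
# image(x) = max_u [ surface(x - u) + sqrt(R^2 - |u|^2) - R ], |u| <= R.
# The cap is 0 at its centre and negative elsewhere, so dilation is extensive
# and leaves isolated apex heights unchanged.
dilate_tip <- function(h, pixel_size_nm, tip_radius_nm) {
  if (tip_radius_nm <= 0) return(h)
  k <- floor(tip_radius_nm / pixel_size_nm)
  if (k < 1) return(h)
  nr <- nrow(h); nc <- ncol(h)
  out <- h
  for (du in -k:k) for (dv in -k:k) {
    if (du == 0 && dv == 0) next
    r2 <- (du^2 + dv^2) * pixel_size_nm^2
    if (r2 > tip_radius_nm^2) next
    s <- sqrt(tip_radius_nm^2 - r2) - tip_radius_nm
    rs <- max(1, 1 + du):min(nr, nr + du)
    cs <- max(1, 1 + dv):min(nc, nc + dv)
    out[rs, cs] <- pmax(out[rs, cs], h[rs - du, cs - dv] + s)
  }
  out
}

#' Render a synthetic nanoarray AFM scene
#'
#' Builds the physical surface — flat substrate at 0, brush discs at each
#' spot's brush height, and each particle's upper ellipsoidal dome
#' `z(r) = h * sqrt(1 - (2 r / d)^2)` riding on the brush when its centre
#' lies on a spot — combining overlapping surfaces by maximum. If
#' `tip_radius_nm > 0` the surface is then dilated with a spherical-cap
#' structuring element (tip broadening). Finally the scan artifacts are
#' added: plane tilt, per-row offsets and Gaussian pixel noise.
#'
#' @param layout a [make_layout()] result.
#' @param particles a true-particle data.frame (see [true_particles()]) with
#'   `x_nm`/`y_nm` set; centres must lie inside the field.
#' @param cfg a [render_config()].
#' @return A list of class `afm_scene` with elements `map` (a
#'   [height_map()]), `truth` (list with `particles` and per-spot records
#'   including `occupied`), and `layout`.
#' @export
render_scene <- function(layout, particles, cfg = render_config()) {
  stopifnot(inherits(layout, "nanospot_layout"), inherits(cfg, "render_config"))
  spec <- attr(layout, "spec")
  px <- cfg$pixel_size_nm
  nr <- max(1L, round(spec$field_height_nm / px))
  nc <- max(1L, round(spec$field_width_nm / px))
  if (nrow(particles) > 0) {
    if (any(is.na(particles$x_nm)) || any(is.na(particles$y_nm)))
      stop("particles must be placed (x_nm/y_nm set) before rendering")
    if (any(particles$x_nm < 0 | particles$x_nm > spec$field_width_nm |
            particles$y_nm < 0 | particles$y_nm > spec$field_height_nm))
      stop("particle centres must lie inside the field")
    if (px > min(particles$d_true_nm) / 4)
      warning("pixel size ", px, " nm under-resolves the smallest footprint (",
              round(min(particles$d_true_nm), 1), " nm)")
  }
  xc <- (seq_len(nc) - 0.5) * px   # pixel-centre x per column
  yc <- (seq_len(nr) - 0.5) * px   # pixel-centre y per row
  surf <- matrix(0, nr, nc)

  add_disc <- function(surf, cx, cy, radius, z) {
    cs <- which(abs(xc - cx) <= radius)
    rs <- which(abs(yc - cy) <= radius)
    if (!length(cs) || !length(rs)) return(surf)
    d2 <- outer((yc[rs] - cy)^2, (xc[cs] - cx)^2, `+`)
    patch <- surf[rs, cs, drop = FALSE]
    patch[d2 <= radius^2] <- pmax(patch[d2 <= radius^2], z)
    surf[rs, cs] <- patch
    surf
  }
  for (i in seq_len(nrow(layout)))
    surf <- add_disc(surf, layout$x_nm[i], layout$y_nm[i],
                     layout$diameter_nm[i] / 2, layout$brush_height_nm[i])

  brush_at <- function(x, y) {
    d <- sqrt((layout$x_nm - x)^2 + (layout$y_nm - y)^2)
    i <- which.min(d)
    if (d[i] <= layout$diameter_nm[i] / 2) layout$brush_height_nm[i] else 0
  }
  for (i in seq_len(nrow(particles))) {
    p <- particles[i, ]
    base <- brush_at(p$x_nm, p$y_nm)
    half <- p$d_true_nm / 2
    cs <- which(abs(xc - p$x_nm) <= half)
    rs <- which(abs(yc - p$y_nm) <= half)
    if (!length(cs) || !length(rs)) next
    d2 <- outer((yc[rs] - p$y_nm)^2, (xc[cs] - p$x_nm)^2, `+`)
    dome <- p$h_true_nm * sqrt(pmax(0, 1 - d2 / half^2))
    patch <- surf[rs, cs, drop = FALSE]
    inside <- d2 < half^2
    patch[inside] <- pmax(patch[inside], base + dome[inside])
    surf[rs, cs] <- patch
  }

  surf <- dilate_tip(surf, px, cfg$tip_radius_nm)

  h <- surf +
    outer(rep(1, nr), cfg$tilt_x * xc) +
    outer(cfg$tilt_y * yc, rep(1, nc))
  if (cfg$line_offset_sd_nm > 0) {
    set.seed(derive_seed(cfg$seed, "line_offsets"))
    h <- h + rnorm(nr, 0, cfg$line_offset_sd_nm)  # recycled down columns: per-row offset
  }
  if (cfg$noise_sd_nm > 0) {
    set.seed(derive_seed(cfg$seed, "pixel_noise"))
    h <- h + matrix(rnorm(nr * nc, 0, cfg$noise_sd_nm), nr, nc)
  }

  spots <- as.data.frame(layout)
  spots$occupied <- vapply(seq_len(nrow(spots)), function(i) {
    ev <- particles$klass == "EV"
    any(ev & sqrt((particles$x_nm - spots$x_nm[i])^2 +
                  (particles$y_nm - spots$y_nm[i])^2) <=
          spots$diameter_nm[i] / 2)
  }, logical(1))

  map <- height_map(h, px,
                    metadata = list(generator = "evnanoarray",
                                    seed = cfg$seed, render_config = unclass(cfg)))
  structure(list(map = map,
                 truth = list(particles = particles, spots = spots),
                 layout = layout),
            class = "afm_scene")
}

#' @export
print.afm_scene <- function(x, ...) {
  cat("Synthetic nanoarray AFM scene\n")
  print(x$map)
  tp <- x$truth$particles
  cat(sprintf("  truth: %d particles (%d EV, %d LDL-like), %d/%d spots occupied\n",
              nrow(tp), sum(tp$klass == "EV"), sum(tp$klass == "LDL_like"),
              sum(x$truth$spots$occupied), nrow(x$truth$spots)))
  invisible(x)
}

#' Simulate a complete nanoarray scene with ground truth
#'
#' High-level generator reproducing the study conditions: a square lattice of
#' ~200 nm brush spots, a fraction `occupancy` of spots each tethering one EV
#' at the spot centre (individual immobilization), and small
#' lipoprotein-like bumps scattered on an annulus at the spot periphery
#' (spot radius +/- 20 nm). EV geometry follows volume conservation from the
#' drawn (D, AR); LDL-like bumps draw footprint d uniform in
#' `ldl_d_range_nm` and AR uniform in `ldl_ar_range`.
#'
#' @param spec a [layout_spec()].
#' @param cfg a [render_config()].
#' @param occupancy fraction of spots occupied by one EV (default 0.20, the
#'   chip's operating point).
#' @param D_dist,ar_dist EV population distributions, see
#'   [sample_population()].
#' @param evs_per_spot EVs placed on each occupied spot (default 1).
#' @param ldl_rate mean number of LDL-like bumps per spot (Poisson).
#' @param ldl_d_range_nm,ldl_ar_range footprint-diameter and AR ranges of the
#'   LDL-like bumps.
#' @param seed master seed; all stage draws derive from it.
#' @return An `afm_scene` (see [render_scene()]).
#' @export
simulate_scene <- function(spec = layout_spec(), cfg = render_config(),
                           occupancy = 0.20,
                           D_dist = dist_spec("normal", mean = 27.7,
                                              sd = 4.7, min = 1),
                           ar_dist = dist_spec("normal", mean = 0.20,
                                               sd = 0.04, min = 1e-3, max = 1),
                           evs_per_spot = 1L, ldl_rate = 0.3,
                           ldl_d_range_nm = c(10, 18),
                           ldl_ar_range = c(0.3, 0.6),
                           seed = 1L) {
  stopifnot(occupancy >= 0, occupancy <= 1, evs_per_spot >= 1, ldl_rate >= 0)
  layout <- make_layout(spec, seed = seed)
  n_spots <- nrow(layout)
  n_occ <- round(occupancy * n_spots)
  set.seed(derive_seed(seed, "occupied_spots"))
  occ_idx <- if (n_occ > 0) sort(sample.int(n_spots, n_occ)) else integer(0)

  n_ev <- n_occ * evs_per_spot
  evs <- sample_population(n_ev, D_dist, ar_dist, seed = seed, klass = "EV")
  evs$spot_id <- rep(NA_integer_, nrow(evs))
  if (n_ev > 0) {
    host <- rep(occ_idx, each = evs_per_spot)
    evs$spot_id <- layout$spot_id[host]
    evs$x_nm <- layout$x_nm[host]
    evs$y_nm <- layout$y_nm[host]
    if (evs_per_spot > 1L) {  # nudge extra EVs so they remain resolvable
      set.seed(derive_seed(seed, "multi_occupancy"))
      extra <- rep(seq_len(evs_per_spot), times = n_occ) > 1L
      ang <- runif(n_ev, 0, 2 * pi)
      shift <- ifelse(extra, spec$spot_diameter_nm / 2, 0)
      evs$x_nm <- evs$x_nm + shift * cos(ang)
      evs$y_nm <- evs$y_nm + shift * sin(ang)
    }
  }

  set.seed(derive_seed(seed, "ldl"))
  n_ldl_per_spot <- rpois(n_spots, ldl_rate)
  n_ldl <- sum(n_ldl_per_spot)
  ldl <- NULL
  if (n_ldl > 0) {
    d <- runif(n_ldl, ldl_d_range_nm[1], ldl_d_range_nm[2])
    ar <- runif(n_ldl, ldl_ar_range[1], ldl_ar_range[2])
    host <- rep(seq_len(n_spots), n_ldl_per_spot)
    rad <- layout$diameter_nm[host] / 2 + runif(n_ldl, -20, 20)
    ang <- runif(n_ldl, 0, 2 * pi)
    ldl <- true_particles_from_footprint(d, ar,
                                         x_nm = layout$x_nm[host] + rad * cos(ang),
                                         y_nm = layout$y_nm[host] + rad * sin(ang),
                                         klass = "LDL_like")
    ldl$spot_id <- layout$spot_id[host]
    inside <- ldl$x_nm > ldl$d_true_nm / 2 &
      ldl$x_nm < spec$field_width_nm - ldl$d_true_nm / 2 &
      ldl$y_nm > ldl$d_true_nm / 2 &
      ldl$y_nm < spec$field_height_nm - ldl$d_true_nm / 2
    ldl <- ldl[inside, , drop = FALSE]
  }

  particles <- rbind(evs, ldl)
  if (nrow(particles) > 0) particles$particle_id <- seq_len(nrow(particles))
  cfg$seed <- derive_seed(seed, "render")
  render_scene(layout, particles, cfg)
}
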
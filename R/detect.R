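#' Parameters for particle detection, measurement and spot assignment
#'
#' @param seed_threshold_nm minimum apex prominence above the local
#'   background for a detection seed; `NULL` (default) resolves at detection
#'   time to `max(1.0, 3 * estimate_noise(map))`.
#' @param footprint_fraction f in (0, 1): the particle footprint is the
#'   connected region above `baseline + f * apex`. Axis lengths measured on
#'   that contour are corrected by `1 / sqrt(1 - f^2)` (exact for an
#'   ellipsoidal dome).
#' @param min_area_px smallest accepted footprint, in pixels.
#' @param spot_margin_nm assignment tolerance beyond the spot radius.
#' @param background_radius_nm radius of the flat structuring element used
#'   for the grayscale-opening background estimate; must exceed the largest
#'   particle radius and stay below the spot radius so brush plateaus are
#'   treated as background.
#' @param min_separation_nm minimum distance between detection seeds;
#'   closer maxima are suppressed (strongest wins).
#' @param max_footprint_nm upper bound on footprint extent (bounds the
#'   per-seed flood fill).
#' @param baseline `"local_annulus"` (default): particle height measured from
#'   the median of a 2-pixel annulus around the footprint, which on a spot is
#'   the brush top, so h excludes the 2-3 nm brush; `"substrate"`: measured
#'   from the leveled substrate plane (z = 0), so h includes the brush.
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(seed_threshold_nm = NULL,
                             footprint_fraction = 0.1,
                             min_area_px = 4L,
                             spot_margin_nm = 50,
                             background_radius_nm = 60,
                             min_separation_nm = 15,
                             max_footprint_nm = 300,
                             baseline = c("local_annulus", "substrate")) {
  baseline <- match.arg(baseline)
  stopifnot(is.null(seed_threshold_nm) || seed_threshold_nm >= 0,
            footprint_fraction > 0, footprint_fraction < 1,
            min_area_px >= 1, spot_margin_nm >= 0,
            background_radius_nm > 0, min_separation_nm > 0,
            max_footprint_nm > 0)
  structure(list(seed_threshold_nm = seed_threshold_nm,
                 footprint_fraction = footprint_fraction,
                 min_area_px = as.integer(min_area_px),
                 spot_margin_nm = spot_margin_nm,
                 background_radius_nm = background_radius_nm,
                 min_separation_nm = min_separation_nm,
                 max_footprint_nm = max_footprint_nm,
                 baseline = baseline),
            class = "detection_params")
}

# local background by grayscale opening with a flat disc: removes structures
# narrower than ~2 * radius (the particle domes) while preserving the wider
# brush plateaus, so the residual is particle topography referenced to its
# supporting surface (substrate or brush top).
# EBImage grayscale morphology clamps to [0, 1]; run it on a normalised copy
gray_morph <- function(h, fun, brush) {
  lo <- min(h); rng <- max(h) - lo
  if (rng == 0) return(h)
  fun((h - lo) / rng, brush) * rng + lo
}

# Local background from two complementary robust estimators, combined by
# pointwise maximum. Grayscale opening (flat disc wider than any particle,
# narrower than a brush spot) is exact on noise-free plateaus but undershoots
# a noisy one by the minimum statistics of the structuring element; the
# local median has no noise undershoot but dips where the window majority
# leaves a curved plateau rim, exactly where opening is reliable. Both
# remove particle domes, so their max tracks the supporting surface.
local_background <- function(h, pixel_size_nm, radius_nm) {
  r <- max(1L, round(radius_nm / pixel_size_nm))
  brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
  bg_open <- gray_morph(box_smooth(h), EBImage::opening, brush)
  # flat opening also undercuts the rim of digitized discs by a pixel or
  # two; re-dilating by a small disc and clamping to the surface heals that
  bg_open <- pmin(h, gray_morph(bg_open, EBImage::dilate,
                                EBImage::makeBrush(7L, shape = "disc")))
  lo <- min(h); rng <- max(h) - lo
  if (rng == 0) return(h)
  k <- max(2L, round(1.25 * r))
  bg_med <- EBImage::medianFilter((h - lo) / rng, k) * rng + lo
  pmax(bg_open, bg_med)
}

box_smooth <- function(h, times = 2L) {
  k <- matrix(1 / 9, 3, 3)
  for (i in seq_len(times)) h <- EBImage::filter2(h, k, boundary = "replicate")
  h
}

# drop mask pixels with fewer than min_neighbors 4-neighbours in the mask:
# removes straggling noise pixels chained onto a footprint contour while
# leaving solid regions (and 2x2 blocks) intact
prune_mask <- function(m, min_neighbors = 2L, passes = 2L) {
  for (p in seq_len(passes)) {
    nn <- matrix(0L, nrow(m), ncol(m))
    nn[-1, ] <- nn[-1, ] + m[-nrow(m), ]
    nn[-nrow(m), ] <- nn[-nrow(m), ] + m[-1, ]
    nn[, -1] <- nn[, -1] + m[, -ncol(m)]
    nn[, -ncol(m)] <- nn[, -ncol(m)] + m[, -1]
    m <- m & nn >= min_neighbors
  }
  m
}

#' Detect dome-like particles on a leveled height map
#'
#' The local background is estimated by grayscale opening (flat disc of
#' radius `background_radius_nm`) and subtracted; detection seeds are local
#' maxima of the box-smoothed residual with prominence at least
#' `seed_threshold_nm`, de-duplicated to `min_separation_nm`. Each seed's
#' footprint is the connected region of residual above
#' `footprint_fraction * apex`; pixels claimed by several seeds are split by
#' nearest seed, and footprints below `min_area_px` are discarded.
#'
#' @param map a leveled [height_map()].
#' @param params a [detection_params()].
#' @return A list of candidate regions (class `particle_regions`), each a
#'   list with `pixels` (linear indices into the height matrix), `seed`
#'   (row, col) and `h_seed` (residual apex prominence in nm). The resolved
#'   seed threshold is attached as attribute `"threshold_nm"`.
#' @export
detect_particles <- function(map, params = detection_params()) {
  stopifnot(inherits(map, "height_map"), inherits(params, "detection_params"))
  h <- map$heights
  px <- map$pixel_size_nm
  nr <- nrow(h); nc <- ncol(h)
  thr <- params$seed_threshold_nm %||% max(1.0, 3 * estimate_noise(map))
  if (mean(h == max(h)) > 0.001)
    warning("height map looks saturated/clipped at its maximum value")

  resid <- h - local_background(h, px, params$background_radius_nm)
  # the opening envelope rides below the noise floor, so the raw residual
  # carries a positive offset on background pixels; re-centre it there
  resid <- resid - median(resid)
  sm <- box_smooth(resid)

  w <- 2L * max(1L, round(params$min_separation_nm / px)) + 1L
  mx <- gray_morph(sm, EBImage::dilate, EBImage::makeBrush(w, shape = "box"))
  cand <- which(sm >= thr & sm >= mx - 1e-12)
  regions <- list()
  if (length(cand)) {
    cand <- cand[order(sm[cand], decreasing = TRUE)]
    cr <- (cand - 1L) %% nr + 1L
    cc <- (cand - 1L) %/% nr + 1L
    min_sep_px <- max(2, params$min_separation_nm / px)
    keep <- logical(length(cand))
    for (i in seq_along(cand)) {
      if (!any(keep)) { keep[i] <- TRUE; next }
      dmin <- min(sqrt((cr[i] - cr[keep])^2 + (cc[i] - cc[keep])^2))
      keep[i] <- dmin >= min_sep_px
    }
    seeds <- cbind(cr[keep], cc[keep])

    K <- max(3L, ceiling(params$max_footprint_nm / 2 / px))
    claims <- vector("list", nrow(seeds))
    for (i in seq_len(nrow(seeds))) {
      sr <- seeds[i, 1]; sc <- seeds[i, 2]
      h_seed <- resid[sr, sc]
      rs <- max(1L, sr - K):min(nr, sr + K)
      cs <- max(1L, sc - K):min(nc, sc + K)
      m <- resid[rs, cs, drop = FALSE] >= params$footprint_fraction * h_seed
      m <- prune_mask(m)
      m[match(sr, rs), match(sc, cs)] <- TRUE
      lab <- EBImage::bwlabel(m)
      id <- lab[match(sr, rs), match(sc, cs)]
      if (id == 0) { claims[[i]] <- integer(0); next }
      loc <- which(lab == id)
      lr <- (loc - 1L) %% length(rs) + 1L
      lc <- (loc - 1L) %/% length(rs) + 1L
      claims[[i]] <- (cs[lc] - 1L) * nr + rs[lr]
    }

    # split pixels claimed by several seeds: nearest seed wins
    all_px <- unlist(claims)
    dup <- unique(all_px[duplicated(all_px)])
    if (length(dup)) {
      dr <- (dup - 1L) %% nr + 1L
      dc <- (dup - 1L) %/% nr + 1L
      owner <- vapply(seq_along(dup), function(j) {
        holders <- which(vapply(claims, function(p) dup[j] %in% p, logical(1)))
        holders[which.min((seeds[holders, 1] - dr[j])^2 +
                            (seeds[holders, 2] - dc[j])^2)]
      }, integer(1))
      for (i in seq_along(claims)) {
        lose <- dup[owner != i]
        claims[[i]] <- setdiff(claims[[i]], lose)
      }
    }

    for (i in seq_along(claims)) {
      if (length(claims[[i]]) < params$min_area_px) next
      regions[[length(regions) + 1L]] <-
        list(pixels = claims[[i]], seed = seeds[i, ],
             h_seed = resid[seeds[i, 1], seeds[i, 2]])
    }
  }
  structure(regions, threshold_nm = thr, class = "particle_regions")
}

#' @export
print.particle_regions <- function(x, ...) {
  cat(sprintf("%d candidate particle region(s), seed threshold %.3g nm\n",
              length(x), attr(x, "threshold_nm")))
  invisible(x)
}

#' An empty particle table with the canonical columns
#'
#' @return Zero-row data.frame with the particle-table schema.
#' @export
empty_particle_table <- function() {
  data.frame(particle_id = integer(0), x_nm = numeric(0), y_nm = numeric(0),
             major_nm = numeric(0), minor_nm = numeric(0), d_nm = numeric(0),
             h_nm = numeric(0), ar = numeric(0), D_nm = numeric(0),
             klass = character(0), spot_id = integer(0),
             border_flag = logical(0), stringsAsFactors = FALSE)
}

#' Measure morphometry of one detected region
#'
#' The local baseline is the median height on a 2-pixel-wide annulus around
#' the footprint (or 0 under the `"substrate"` convention); apex height h is
#' the region maximum minus baseline. Major/minor footprint axes are the
#' equivalent-ellipse axis lengths from the mask's second central moments
#' (`4 * sqrt(eigenvalue)`, plus a pixel-area term), corrected by
#' `1 / sqrt(1 - f^2)` for the fractional-height contour; the footprint
#' diameter is their mean, AR = h/d, and D = (d^2 h)^(1/3). Regions whose
#' annulus would leave the image are flagged `border_flag` and should be
#' excluded from population statistics.
#'
#' @param region one element of [detect_particles()] output.
#' @param map the [height_map()] the regions were detected on.
#' @param params a [detection_params()].
#' @return One-row particle data.frame (see [empty_particle_table()] columns).
#' @export
measure_particle <- function(region, map, params = detection_params()) {
  stopifnot(length(region$pixels) > 0)
  h <- map$heights
  px <- map$pixel_size_nm
  nr <- nrow(h); nc <- ncol(h)
  idx <- region$pixels
  pr <- (idx - 1L) %% nr + 1L
  pc <- (idx - 1L) %/% nr + 1L

  border <- min(pr) <= 2L || min(pc) <= 2L || max(pr) >= nr - 1L ||
    max(pc) >= nc - 1L

  # 2-pixel-wide annulus around the footprint (chebyshev dilation minus mask)
  r0 <- max(1L, min(pr) - 3L); r1 <- min(nr, max(pr) + 3L)
  c0 <- max(1L, min(pc) - 3L); c1 <- min(nc, max(pc) + 3L)
  crop <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
  crop[cbind(pr - r0 + 1L, pc - c0 + 1L)] <- TRUE
  ring <- EBImage::dilate(crop, EBImage::makeBrush(5L, "box")) & !crop
  ring_idx <- which(ring)
  rr <- (ring_idx - 1L) %% nrow(ring) + r0
  rc <- (ring_idx - 1L) %/% nrow(ring) + c0
  baseline <- if (params$baseline == "substrate") 0 else
    if (length(ring_idx)) median(h[cbind(rr, rc)]) else NA_real_

  h_nm <- max(h[idx]) - baseline

  x <- (pc - 0.5) * px
  y <- (pr - 0.5) * px
  wts <- pmax(h[idx] - baseline, 0)
  if (sum(wts) <= 0) wts <- rep(1, length(idx))
  cx <- sum(wts * x) / sum(wts)
  cy <- sum(wts * y) / sum(wts)

  mx <- mean(x); my <- mean(y)
  cxx <- mean((x - mx)^2) + px^2 / 12
  cyy <- mean((y - my)^2) + px^2 / 12
  cxy <- mean((x - mx) * (y - my))
  ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2), symmetric = TRUE)$values
  corr <- 1 / sqrt(1 - params$footprint_fraction^2)
  major <- 4 * sqrt(max(ev[1], 0)) * corr
  minor <- 4 * sqrt(max(ev[2], 0)) * corr
  d_nm <- (major + minor) / 2

  data.frame(particle_id = NA_integer_, x_nm = cx, y_nm = cy,
             major_nm = major, minor_nm = minor, d_nm = d_nm, h_nm = h_nm,
             ar = if (d_nm > 0) h_nm / d_nm else NA_real_,
             D_nm = if (d_nm > 0 && h_nm > 0) (d_nm^2 * h_nm)^(1 / 3)
                    else NA_real_,
             klass = "unclassified", spot_id = NA_integer_,
             border_flag = border, stringsAsFactors = FALSE)
}

#' Measure all detected regions
#'
#' @param regions output of [detect_particles()].
#' @inheritParams measure_particle
#' @return Particle data.frame, one row per region, `particle_id` assigned
#'   in detection order.
#' @export
measure_particles <- function(regions, map, params = detection_params()) {
  if (!length(regions)) return(empty_particle_table())
  out <- do.call(rbind, lapply(regions, measure_particle, map = map,
                               params = params))
  out$particle_id <- seq_len(nrow(out))
  out
}

#' Assign particles to nanospots and derive the occupancy map
#'
#' A particle is assigned to its nearest spot centre when the distance is at
#' most the spot radius plus `spot_margin_nm`; otherwise it stays
#' unassigned. A spot is occupied when at least one EV-classified particle
#' is assigned to it, so classification should precede assignment.
#'
#' @param particles particle data.frame.
#' @param layout a `nanospot_layout`.
#' @param params a [detection_params()] (for `spot_margin_nm`).
#' @return A list with `particles` (spot_id filled in) and `occupancy`
#'   (data.frame `spot_id`, `occupied`).
#' @export
assign_to_spots <- function(particles, layout, params = detection_params()) {
  stopifnot(inherits(layout, "nanospot_layout") || is.data.frame(layout))
  if (nrow(particles)) {
    for (i in seq_len(nrow(particles))) {
      d <- sqrt((layout$x_nm - particles$x_nm[i])^2 +
                  (layout$y_nm - particles$y_nm[i])^2)
      j <- which.min(d)
      particles$spot_id[i] <-
        if (d[j] <= layout$diameter_nm[j] / 2 + params$spot_margin_nm)
          layout$spot_id[j] else NA_integer_
    }
  }
  ev_spots <- unique(particles$spot_id[particles$klass == "EV" &
                                         !is.na(particles$spot_id)])
  list(particles = particles,
       occupancy = data.frame(spot_id = layout$spot_id,
                              occupied = layout$spot_id %in% ev_spots))
}

#' Write / read a particle table CSV
#'
#' Columns: `particle_id, x_nm, y_nm, major_nm, minor_nm, d_nm, h_nm, ar,
#' D_nm, klass, spot_id, border_flag`.
#'
#' @param particles particle data.frame.
#' @param path file path.
#' @export
write_particles <- function(particles, path) {
  write.csv(particles[, names(empty_particle_table())], path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_particles
#' @export
read_particles <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(names(empty_particle_table()), names(df))
  if (length(miss)) stop("particle CSV missing columns: ",
                         paste(miss, collapse = ", "))
  df
}
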
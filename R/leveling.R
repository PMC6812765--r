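#' Plane (polynomial background) leveling of a height map
#'
#' Fits a least-squares polynomial surface of total degree `order` to the
#' background and subtracts it from every pixel. Pixels belonging to
#' particles or spots are excluded by an iterative mask: after each fit,
#' pixels more than `mask_sigma` robust sigmas above the fitted surface are
#' dropped and the surface refitted (`passes` rounds). Measured from the
#' leveled map, bare substrate sits near 0 and feature heights are
#' preserved.
#'
#' @param map a [height_map()].
#' @param order polynomial order, 1 (plane) or 2.
#' @param mask_sigma masking threshold in robust sigmas above the fit.
#' @param passes masking iterations.
#' @return A list with `map` (the leveled [height_map()]) and `report` (a
#'   `level_report`: fitted coefficients and residual background roughness
#'   `sigma_nm`).
#' @export
plane_level <- function(map, order = 1L, mask_sigma = 3, passes = 2L) {
  stopifnot(inherits(map, "height_map"))
  if (!order %in% c(1L, 2L))
    stop("order must be 1 or 2")
  h <- map$heights
  n <- length(h)
  if (n < (order + 1)^2)
    stop("grid too small for order-", order, " background fit")
  nr <- nrow(h); nc <- ncol(h)
  x <- rep((seq_len(nc) - 0.5) * map$pixel_size_nm, each = nr)
  y <- rep((seq_len(nr) - 0.5) * map$pixel_size_nm, times = nc)
  X <- cbind(1, x, y)
  if (order == 2L) X <- cbind(X, x^2, x * y, y^2)
  z <- as.vector(h)

  keep <- rep(TRUE, n)
  fit <- NULL
  for (pass in 0:passes) {
    fit <- lm.fit(X[keep, , drop = FALSE], z[keep])
    bg <- as.vector(X %*% fit$coefficients)
    res <- z - bg
    if (pass == passes) break
    s <- max(mad(res[keep]), 1e-9)
    new_keep <- res <= mask_sigma * s
    if (sum(new_keep) < 0.1 * n) {
      warning("background mask would leave <10% of pixels; fitting on all")
      keep <- rep(TRUE, n)
      fit <- lm.fit(X, z)
      bg <- as.vector(X %*% fit$coefficients)
      res <- z - bg
      break
    }
    keep <- new_keep
  }
  leveled <- map
  leveled$heights <- matrix(res, nr, nc)
  report <- structure(list(order = order,
                           coefficients = unname(fit$coefficients),
                           sigma_nm = mad(res[keep]),
                           background_fraction = mean(keep)),
                      class = "level_report")
  list(map = leveled, report = report)
}

#' @export
print.level_report <- function(x, ...) {
  cat(sprintf("Background level fit (order %d): sigma = %.4g nm, %0.1f%% background pixels\n",
              x$order, x$sigma_nm, 100 * x$background_fraction))
  cat("  coefficients:", format(x$coefficients, digits = 4), "\n")
  invisible(x)
}

#' Scan-line (per-row offset) leveling
#'
#' Subtracts from each scan row the median of its background pixels.
#' Background pixels are those within `mask_sigma` robust sigmas of the
#' global median, so particles and spots do not bias the row medians; rows
#' whose pixels are all masked fall back to the full row median.
#'
#' @param map a [height_map()] (typically already plane-leveled).
#' @param mask_sigma background masking threshold in robust sigmas.
#' @return A leveled [height_map()].
#' @export
line_level <- function(map, mask_sigma = 3) {
  stopifnot(inherits(map, "height_map"))
  h <- map$heights
  med <- median(h)
  s <- max(mad(h), 1e-12)
  bg <- h <= med + mask_sigma * s
  offsets <- vapply(seq_len(nrow(h)), function(r) {
    v <- h[r, bg[r, ]]
    if (!length(v)) median(h[r, ]) else median(v)
  }, numeric(1))
  out <- map
  out$heights <- h - offsets
  out
}

#' Robust background-noise estimate of a leveled height map
#'
#' Two-pass median-absolute-deviation estimator: an initial MAD-based mask
#' removes pixels far above the background (particles, spots), then sigma is
#' re-estimated as `1.4826 * MAD` of the remaining pixels. Robust to feature
#' coverage of a few tens of percent.
#'
#' @param map a leveled [height_map()].
#' @param mask_sigma masking threshold for the first pass.
#' @return Estimated background sigma in nm (0 for a constant map).
#' @export
estimate_noise <- function(map, mask_sigma = 3) {
  stopifnot(inherits(map, "height_map"))
  h <- as.vector(map$heights)
  m0 <- median(h)
  s0 <- mad(h)
  if (s0 == 0) return(0)
  keep <- h <= m0 + mask_sigma * s0
  mad(h[keep])
}
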
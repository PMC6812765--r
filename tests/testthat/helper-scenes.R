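# shared fixtures: analytic dome maps, rendered benchmark scenes, oracles

# height map with analytic ellipsoidal domes on a flat substrate:
# domes is a data.frame with x, y, a (major axis), b (minor axis), h
analytic_dome_map <- function(domes, size_nm, px = 2, noise_sd = 0,
                              seed = 1) {
  n <- round(size_nm / px)
  xc <- (seq_len(n) - 0.5) * px
  h <- matrix(0, n, n)
  for (i in seq_len(nrow(domes))) {
    d <- domes[i, ]
    u2 <- outer((xc - d$y)^2 / (d$b / 2)^2, (xc - d$x)^2 / (d$a / 2)^2, `+`)
    z <- d$h * sqrt(pmax(0, 1 - u2))
    h <- pmax(h, z)
  }
  if (noise_sd > 0) {
    set.seed(seed)
    h <- h + matrix(rnorm(n * n, 0, noise_sd), n, n)
  }
  height_map(h, px)
}

circular_dome_map <- function(d, h, size_nm = 3 * d, px = 2, noise_sd = 0,
                              seed = 1) {
  analytic_dome_map(data.frame(x = size_nm / 2, y = size_nm / 2,
                               a = d, b = d, h = h),
                    size_nm, px, noise_sd, seed)
}

# benchmark scene: n EVs with footprint d ~ U(35, 85), AR ~ U(0.15, 0.30),
# one per spot on a 300 nm-pitch lattice, rendered at 5 nm/px
benchmark_scene <- function(n = 100, seed = 1, noise_sd = 0.3,
                            pitch = 300, spot_diameter = 200, px = 5) {
  side <- ceiling(sqrt(n)) * pitch
  spec <- layout_spec(side, side, pitch, spot_diameter)
  l <- make_layout(spec, seed = seed)
  stopifnot(nrow(l) >= n)
  set.seed(derive_seed(seed, "benchmark_truth"))
  d <- runif(n, 35, 85)
  ar <- runif(n, 0.15, 0.30)
  tp <- true_particles_from_footprint(d, h_nm = ar * d,
                                      x_nm = l$x_nm[seq_len(n)],
                                      y_nm = l$y_nm[seq_len(n)])
  sc <- render_scene(l, tp, render_config(pixel_size_nm = px,
                                          noise_sd_nm = noise_sd,
                                          seed = derive_seed(seed, "render")))
  sc
}

# match measured particles to ground truth by nearest centre
match_truth <- function(measured, truth, max_dist_nm = 30) {
  idx <- vapply(seq_len(nrow(measured)), function(i) {
    d2 <- (truth$x_nm - measured$x_nm[i])^2 +
      (truth$y_nm - measured$y_nm[i])^2
    j <- which.min(d2)
    if (sqrt(d2[j]) <= max_dist_nm) j else NA_integer_
  }, integer(1))
  idx
}

# independent pooled two-sample t oracle (closed form)
pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = tt, df = df, p = 2 * pt(-abs(tt), df))
}

# brute-force least-squares oracle for AR = c * d^-3 through the origin:
# iterative grid refinement over c, independent of the closed form
grid_fit_oracle <- function(d, ar, rounds = 4, width = 0.5, n_grid = 501) {
  x <- d^-3
  centre <- mean(ar) / mean(x)  # crude starting scale
  lo <- centre * (1 - width); hi <- centre * (1 + width)
  for (r in seq_len(rounds)) {
    cs <- seq(lo, hi, length.out = n_grid)
    sse <- vapply(cs, function(cc) sum((ar - cc * x)^2), numeric(1))
    i <- which.min(sse)
    step <- cs[2] - cs[1]
    lo <- cs[i] - 2 * step; hi <- cs[i] + 2 * step
  }
  cs[i]
}
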
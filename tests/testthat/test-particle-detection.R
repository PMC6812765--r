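test_that("isolated and paired domes are detected without merge or junk", {
  m <- circular_dome_map(60, 12, size_nm = 400, px = 5)
  regs <- detect_particles(m, detection_params())
  expect_length(regs, 1)

  two <- analytic_dome_map(data.frame(x = c(150, 450), y = c(300, 300),
                                      a = 60, b = 60, h = 12),
                           size_nm = 600, px = 5)
  expect_length(detect_particles(two, detection_params()), 2)

  blank <- height_map(matrix(0, 64, 64), 5)
  expect_length(detect_particles(blank, detection_params()), 0)
})

test_that("false-positive rate on noise-only maps is below 1 per 256^2", {
  fp <- vapply(1:3, function(s) {
    set.seed(s)
    m <- height_map(matrix(rnorm(256^2, 0, 0.3), 256), 5)
    length(detect_particles(m, detection_params(seed_threshold_nm = 0.9)))
  }, numeric(1))
  expect_true(all(fp <= 1))
})

test_that("morphometry recovers analytic dome geometry", {
  p <- detection_params()
  m <- circular_dome_map(60, 12, size_nm = 400, px = 2)
  meas <- measure_particles(detect_particles(m, p), m, p)
  expect_equal(nrow(meas), 1)
  expect_lt(abs(meas$d_nm - 60), 4)       # 2 pixels at 2 nm/px
  expect_lt(abs(meas$h_nm - 12), 0.1)
  expect_lt(abs(meas$major_nm / meas$minor_nm - 1), 0.05)
  expect_equal(meas$ar, meas$h_nm / meas$d_nm)

  ell <- analytic_dome_map(data.frame(x = 200, y = 200, a = 80, b = 40,
                                      h = 12), size_nm = 400, px = 2)
  me <- measure_particles(detect_particles(ell, p), ell, p)
  expect_equal(nrow(me), 1)
  expect_lt(abs(me$major_nm - 80), 4)
  expect_lt(abs(me$minor_nm - 40), 4)
  expect_lt(abs(me$d_nm - 60), 4)
})

test_that("baseline convention decides whether the brush is included", {
  spec <- layout_spec(600, 600, 600, 200, 2.5, 2.5)
  l <- make_layout(spec)
  tp <- true_particles_from_footprint(60, 12, x_nm = 300, y_nm = 300)
  sc <- render_scene(l, tp, render_config(pixel_size_nm = 2, noise_sd_nm = 0))
  pa <- detection_params(baseline = "local_annulus")
  ps <- detection_params(baseline = "substrate")
  regs <- detect_particles(sc$map, pa)
  h_annulus <- measure_particles(regs, sc$map, pa)$h_nm
  h_substrate <- measure_particles(regs, sc$map, ps)$h_nm
  expect_lt(abs(h_annulus - 12), 0.15)          # brush excluded
  expect_lt(abs(h_substrate - 14.5), 0.15)      # brush included
})

test_that("particles assign to spots by distance and drive occupancy", {
  spec <- layout_spec(4242, 4242, 1414, 200)
  l <- make_layout(spec)
  p <- empty_particle_table()
  p[1, ] <- list(1L, l$x_nm[1], l$y_nm[1], 50, 50, 50, 10, 0.2, 29.2,
                 "EV", NA_integer_, FALSE)
  p[2, ] <- list(2L, (l$x_nm[1] + l$x_nm[2]) / 2, l$y_nm[1], 50, 50, 50,
                 10, 0.2, 29.2, "EV", NA_integer_, FALSE)
  asg <- assign_to_spots(p, l, detection_params(spot_margin_nm = 50))
  expect_equal(asg$particles$spot_id[1], l$spot_id[1])
  expect_true(is.na(asg$particles$spot_id[2]))
  expect_equal(occupancy_fraction(asg$occupancy), 1 / nrow(l))
})

test_that("pipeline occupancy matches the generated occupancy exactly", {
  spec <- layout_spec(3000, 3000, 300, 200)
  # fixed geometry keeps every EV above the classification thresholds
  sc <- simulate_scene(spec, render_config(pixel_size_nm = 5, seed = 2),
                       occupancy = 0.20,
                       D_dist = dist_spec("fixed", value = 30),
                       ar_dist = dist_spec("fixed", value = 0.2,
                                           min = 0, max = 1),
                       ldl_rate = 0, seed = 21)
  expect_equal(mean(sc$truth$spots$occupied), 0.20)
  res <- process_height_map(sc$map, layout = sc$layout)
  expect_equal(occupancy_fraction(res$occupancy), 0.20)
})

test_that("rendered EV populations are recovered within tolerance", {
  # 200 EVs, d ~ U(35, 85), AR ~ U(0.15, 0.30), sigma = 0.3 nm, 5 nm pixels
  errs_d <- c(); errs_h <- c(); rel_d <- c(); rel_h <- c()
  n_true_detectable <- 0; n_found <- 0
  for (s in 1:2) {
    sc <- benchmark_scene(n = 100, seed = s)
    truth <- sc$truth$particles
    res <- process_height_map(sc$map, layout = sc$layout)
    meas <- res$particles[!res$particles$border_flag &
                            res$particles$h_nm > 2, ]
    mi <- match_truth(meas, truth)
    ok <- !is.na(mi)
    errs_d <- c(errs_d, meas$d_nm[ok] - truth$d_true_nm[mi[ok]])
    errs_h <- c(errs_h, meas$h_nm[ok] - truth$h_true_nm[mi[ok]])
    rel_d <- c(rel_d, (meas$d_nm[ok] - truth$d_true_nm[mi[ok]]) /
                 truth$d_true_nm[mi[ok]])
    rel_h <- c(rel_h, (meas$h_nm[ok] - truth$h_true_nm[mi[ok]]) /
                 truth$h_true_nm[mi[ok]])
    # completeness: every truth EV with h > 7 nm has a detection
    det <- truth$h_true_nm > 7
    found <- vapply(which(det), function(j)
      any(sqrt((meas$x_nm - truth$x_nm[j])^2 +
                 (meas$y_nm - truth$y_nm[j])^2) <= 30), logical(1))
    n_true_detectable <- n_true_detectable + sum(det)
    n_found <- n_found + sum(found)
  }
  expect_gte(length(errs_d), 150)
  expect_lt(abs(mean(rel_d)), 0.05)
  expect_lt(abs(mean(rel_h)), 0.05)
  expect_lt(max(abs(errs_d)), 2 * 5)  # 2 pixels
  expect_equal(n_found, n_true_detectable)
})

test_that("tip broadening widens measured footprints but not heights", {
  spec <- layout_spec(400, 400, 400, 200, 2, 2)
  l <- make_layout(spec)
  tp <- true_particles_from_footprint(60, 12, x_nm = 200, y_nm = 200)
  d_meas <- vapply(c(0, 5, 10), function(r) {
    sc <- render_scene(l, tp, render_config(pixel_size_nm = 2,
                                            noise_sd_nm = 0,
                                            tip_radius_nm = r))
    p <- detection_params()
    m <- measure_particles(detect_particles(sc$map, p), sc$map, p)
    c(m$d_nm, m$h_nm)
  }, numeric(2))
  expect_true(all(diff(d_meas[1, ]) >= 0))
  expect_lt(max(abs(d_meas[2, ] - 12)), 0.2)
})

test_that("particle tables round-trip through CSV", {
  sc <- benchmark_scene(n = 9, seed = 5)
  res <- process_height_map(sc$map, layout = sc$layout)
  f <- tempfile(fileext = ".csv")
  write_particles(res$particles, f)
  back <- read_particles(f)
  expect_equal(back$d_nm, res$particles$d_nm, tolerance = 1e-12)
  expect_equal(back$klass, res$particles$klass)
  expect_error(read_particles({
    f2 <- tempfile(fileext = ".csv")
    write.csv(data.frame(a = 1), f2, row.names = FALSE)
    f2
  }), "missing columns")
})
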
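ev_rows <- function(ar, d = 50) {
  n <- length(ar)
  d <- rep_len(d, n)
  data.frame(particle_id = seq_len(n), x_nm = rep(0, n), y_nm = rep(0, n),
             major_nm = d, minor_nm = d, d_nm = d, h_nm = ar * d, ar = ar,
             D_nm = (d^2 * ar * d)^(1 / 3), klass = rep("EV", n),
             spot_id = rep(NA_integer_, n), border_flag = rep(FALSE, n))
}

test_that("population summaries use mean and sample sd", {
  s <- summarize_population(ev_rows(c(0.2, 0.2, 0.2)), label = "x")
  expect_equal(unname(s$ar["mean"]), 0.2)
  expect_equal(unname(s$ar["sd"]), 0)

  s2 <- summarize_population(ev_rows(c(0.1, 0.2, 0.3), d = c(1, 2, 3) * 50))
  expect_equal(unname(s2$d_nm["mean"]), 100)
  expect_equal(unname(s2$d_nm["sd"]), 50)

  # a drawn population recovers its configured mean within sampling error
  pop <- sample_population(200, ar_dist = dist_spec("normal", mean = 0.20,
                                                    sd = 0.04, min = 1e-3,
                                                    max = 1), seed = 6)
  pop2 <- data.frame(d_nm = pop$d_true_nm, h_nm = pop$h_true_nm,
                     ar = pop$ar_true, D_nm = pop$D_true_nm)
  s3 <- summarize_population(pop2, label = "drawn")
  expect_lt(abs(s3$ar["mean"] - 0.20), 2 * 0.04 / sqrt(200))

  expect_error(summarize_population(ev_rows(numeric(0))), "no EV-class")
  # non-EV and border rows are excluded
  mixed <- rbind(ev_rows(c(0.2, 0.25)),
                 transform(ev_rows(0.9), klass = "LDL_like"),
                 transform(ev_rows(0.5), border_flag = TRUE))
  expect_equal(summarize_population(mixed)$n, 2)
})

test_that("pooled t-test matches the closed form and handles degeneracy", {
  a <- c(0.1, 0.2, 0.3); b <- c(0.4, 0.5, 0.6)
  tt <- student_t_test(a, b)
  expect_equal(tt$t_statistic, -3.674, tolerance = 1e-3)
  expect_equal(tt$degrees_of_freedom, 4)
  expect_equal(tt$p_two_sided, 0.0213, tolerance = 1e-2)
  expect_true(tt$significant)

  # closed-form equivalence on random samples
  set.seed(7)
  for (i in 1:10) {
    x <- rnorm(sample(3:20, 1)); y <- rnorm(sample(3:20, 1), 0.3)
    got <- student_t_test(x, y)
    ora <- pooled_t_oracle(x, y)
    expect_equal(got$t_statistic, ora$t, tolerance = 1e-9)
    expect_equal(got$p_two_sided, ora$p, tolerance = 1e-9)
    expect_equal(got$degrees_of_freedom, ora$df)
  }

  same <- student_t_test(a, a)
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_two_sided, 1)

  swapped <- student_t_test(b, a)
  expect_equal(swapped$t_statistic, -tt$t_statistic)
  expect_equal(swapped$p_two_sided, tt$p_two_sided)

  z <- student_t_test(c(1, 1), c(1, 1))
  expect_equal(z$p_two_sided, 1)
  expect_warning(zz <- student_t_test(c(1, 1), c(2, 2)), "zero pooled")
  expect_equal(zz$p_two_sided, 0)

  expect_error(student_t_test(1, c(1, 2)), "at least 2")
})

test_that("capture model: drag scales as D^2 and D* follows its closed form", {
  m <- capture_model(drag_coefficient = 1, resistance_force = 1600,
                     flow_velocity = 1)
  expect_equal(m$critical_diameter_nm, 40)
  drag <- function(D, mod) mod$drag_coefficient * mod$flow_velocity * D^2
  expect_equal(drag(60, m) / drag(30, m), 4)  # doubling D quadruples drag

  expect_true(capture_predicate(39.9, m))
  expect_false(capture_predicate(40.1, m))

  m_half <- capture_model(1, 1600, flow_velocity = 0.5)
  expect_equal(m_half$critical_diameter_nm, 40 * sqrt(2), tolerance = 1e-12)
})

test_that("capture filter truncates the suspension size distribution", {
  set.seed(8)
  # DLS-like suspension distribution (mean 133 nm, sd 60 nm)
  D <- draw_dist(2000, dist_spec("lognormal", mean = 133, sd = 60, min = 1))
  m40 <- capture_model(1, 1600, 1)
  cs <- apply_capture_filter(D, m40)
  expect_lt(cs$mean_after, 40)
  expect_lt(cs$mean_after, cs$mean_before)

  # identity above the support, empty below it
  all_in <- apply_capture_filter(D, capture_model(1, 1e9, 1))
  expect_equal(all_in$n_captured, length(D))
  expect_equal(all_in$mean_after, all_in$mean_before)
  none <- apply_capture_filter(D, capture_model(1, 1, 1))
  expect_equal(none$n_captured, 0)
  expect_true(is.na(none$mean_after))

  # mean captured D is non-increasing in flow velocity
  vs <- c(0.25, 0.5, 1, 2, 4)
  means <- vapply(vs, function(v) {
    r <- apply_capture_filter(D, capture_model(1, 1600, v))
    if (r$n_captured) r$mean_after else 0
  }, numeric(1))
  expect_true(all(diff(means) <= 1e-9))

  expect_error(apply_capture_filter(numeric(0)), "empty")
})

test_that("two cell-line scenes with AR 0.20 vs 0.18 separate significantly", {
  run_line <- function(ar_mean, seed) {
    spec <- layout_spec(4200, 4200, 300, 200)
    sc <- simulate_scene(spec, render_config(pixel_size_nm = 5,
                                             noise_sd_nm = 0.3, seed = seed),
                         occupancy = 150 / 196,
                         ar_dist = dist_spec("normal", mean = ar_mean,
                                             sd = 0.04, min = 1e-3, max = 1),
                         ldl_rate = 0.3, seed = seed) |> suppressWarnings()
    res <- process_height_map(sc$map, layout = sc$layout)
    res$particles[res$particles$klass == "EV" &
                    !res$particles$border_flag, ]
  }
  a <- run_line(0.20, seed = 101)
  b <- run_line(0.18, seed = 202)
  expect_gte(nrow(a), 100)
  expect_gte(nrow(b), 100)
  tt <- student_t_test(a$ar, b$ar)
  expect_lt(tt$p_two_sided, 0.05)
  expect_gt(tt$t_statistic, 0)  # first line less deformed on average? no: higher AR
})

test_that("reports are schema-stable, deterministic and null-explicit", {
  s1 <- summarize_population(ev_rows(c(0.18, 0.22, 0.2)), 0.2, "lineA")
  s2 <- summarize_population(ev_rows(c(0.15, 0.19, 0.17)), 0.25, "lineB")
  f1 <- fit_ar_model(ev_rows(c(0.18, 0.22, 0.2)))
  tt <- student_t_test(c(0.18, 0.22, 0.2), c(0.15, 0.19, 0.17))
  j1 <- tempfile(fileext = ".json"); j2 <- tempfile(fileext = ".json")
  tab <- tempfile(fileext = ".txt")
  make_report(list(s1, s2), fits = list(f1, f1), test = tt,
              config = list(x = 1), seed = 5, out_json = j1,
              out_table = tab)
  make_report(list(s1, s2), fits = list(f1, f1), test = tt,
              config = list(x = 1), seed = 5, out_json = j2)
  expect_identical(readLines(j1), readLines(j2))
  expect_true(file.exists(tab))

  parsed <- jsonlite::read_json(j1)
  expect_length(parsed$populations, 2)
  expect_false(is.null(parsed$t_test$p_two_sided))
  expect_equal(parsed$provenance$seed, 5)

  # absent sections serialise as null, not as missing keys
  make_report(list(s1), out_json = j1)
  raw <- paste(readLines(j1), collapse = "")
  expect_match(raw, "\"ar_fits\":\\s*null")
  expect_match(raw, "\"t_test\":\\s*null")
})
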
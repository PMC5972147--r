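# closed forms for the feedback-free (v = 0) linear limit
linear_x <- function(t, p, x_init) {
  p$b / p$d + (x_init - p$b / p$d) * exp(-p$d * t)
}
linear_tR <- function(p, x_init) {
  -(1 / p$d) * log((p$xR - p$b / p$d) / (x_init - p$b / p$d))
}

test_that("the feedback-free limit matches its closed-form solution", {
  draws <- snailwave:::sw_with_seed(1, {
    tibble::tibble(
      d = runif(100, 0.1, 2),
      x0 = runif(100, 0.01, 0.5),
      xR = runif(100, 0.6, 1.5)
    )
  })
  for (i in seq_len(nrow(draws))) {
    # choose b so the linear system's ceiling b/d lies above xR
    p <- motif_params(
      b = draws$xR[i] * draws$d[i] * 1.5, v = 1e-12, K = 0.5, n = 4,
      d = draws$d[i], x0 = draws$x0[i], xR = draws$xR[i]
    )
    res <- response_time(p)
    expect_true(res$reached)
    expect_lt(abs(res$t_R - linear_tR(p, p$x0)), 1e-6)
  }
})

test_that("response time is zero at threshold and the field vanishes at rest", {
  p <- motif_params(x0 = 1.19999, xR = 1.2)
  p$x0 <- p$xR
  expect_identical(response_time(p)$t_R, 0)

  demo <- motif_params()
  fp <- motif_fixed_points(demo)
  expect_identical(nrow(fp), 3L)
  expect_identical(sum(fp$stable), 2L)
  x_hi <- max(fp$x[fp$stable])
  expect_lt(abs(motif_rhs(x_hi, demo)), 1e-10)
})

test_that("response time decreases strictly with the initial concentration", {
  demo <- motif_params()
  fp <- motif_fixed_points(demo)
  x_un <- fp$x[!fp$stable][1]
  grid <- seq(x_un * 1.15, 0.9, length.out = 20)
  tR <- vapply(grid, function(x0) {
    p <- demo
    p$x0 <- x0
    response_time(p)$t_R
  }, numeric(1))
  expect_true(all(diff(tR) < 0))
})

test_that("the boost acceleration is positive and fades at higher basal levels", {
  demo <- motif_params()
  curve <- boost_acceleration(demo, seq(0.4, 0.75, length.out = 12),
                              dx0 = 0.05)
  expect_true(all(curve$reached))
  expect_true(all(curve$dt_R > 0))
  expect_true(all(diff(curve$dt_R) < 0))
  none <- boost_acceleration(demo, c(0.4, 0.6), dx0 = 0)
  expect_equal(none$dt_R, c(0, 0), tolerance = 1e-9)
})

test_that("the feedback-free boost acceleration matches the closed form", {
  p <- motif_params(b = 1.2, v = 1e-12, K = 0.5, n = 4, d = 1,
                    x0 = 0.1, xR = 1.0)
  curve <- boost_acceleration(p, c(0.1, 0.3, 0.5), dx0 = 0.05)
  expected <- vapply(c(0.1, 0.3, 0.5), function(x0) {
    linear_tR(p, x0) - linear_tR(p, x0 + 0.05)
  }, numeric(1))
  expect_equal(curve$dt_R, expected, tolerance = 1e-6)
})

test_that("the switch filters weak or short pulses, with or without boost", {
  demo <- motif_params()
  expect_false(noise_filtering(demo, pulse_amplitude = 0,
                               pulse_duration = 10))
  expect_false(noise_filtering(demo, pulse_amplitude = 0.5,
                               pulse_duration = 0.1))
  expect_true(noise_filtering(demo, pulse_amplitude = 0.5,
                              pulse_duration = 40))
  b0 <- switching_boundary(demo, pulse_amplitude = 0.5, boost = FALSE)
  b1 <- switching_boundary(demo, pulse_amplitude = 0.5, boost = TRUE)
  expect_gt(b1, 0)
  expect_lt(abs(b1 - b0), 0.5 * b0)
})
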
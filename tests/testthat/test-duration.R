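# synthetic trajectory builder: piecewise-linear SNAIL1 protein shape
fake_traj <- function(t, snail, psmad = NULL, gli = NULL) {
  structure(
    tibble::tibble(
      time_h = t,
      SNAIL1_prot = snail,
      pSMAD_nuc = psmad %||% rep(1, length(t)),
      GLI1_nuc = gli %||% rep(1, length(t))
    ),
    class = c("sw_trajectory", class(tibble::tibble()))
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("wave classification handles flat, single and double bumps", {
  t <- seq(0, 72, 0.5)
  expect_identical(classify_waves(fake_traj(t, rep(1, length(t))))$label,
                   "none")
  one <- 1 + 2 * exp(-((t - 14) / 6)^2)
  expect_identical(classify_waves(fake_traj(t, one))$label, "one_wave")
  two <- 1 + 2 * exp(-((t - 14) / 5)^2) + 3 / (1 + exp(-(t - 48) / 5))
  expect_identical(classify_waves(fake_traj(t, two))$label, "two_wave")
  # a dip that never recovers is still one wave
  fading <- 1 + 2 * exp(-((t - 14) / 6)^2) + 0.2 / (1 + exp(-(t - 48) / 4))
  expect_identical(classify_waves(fake_traj(t, fading))$label, "one_wave")
  expect_error(
    classify_waves(fake_traj(seq(0, 48, 0.5), rep(1, 97))),
    "72 h"
  )
})

test_that("TOSS encoding discretises exactly at 12 and 48 hours", {
  t <- seq(0, 72, 0.5)
  ps <- 1 + 3 * exp(-((t - 12) / 8)^2)    # H at 12 h, M-ish at 24 h
  gl <- 1 + 2 / (1 + exp(-(t - 40) / 4))  # L at 12 h, H at 48 h
  sn <- 1 + 1 * (t >= 6)                  # H from 6 h on
  enc <- encode_toss(fake_traj(t, sn, ps, gl))
  expect_identical(enc$psmad[[1]], "H")
  expect_identical(enc$gli1, c("L", "H"))
  expect_identical(enc$snail_state, "(H, H)")
  expect_error(encode_toss(fake_traj(seq(0, 24, 0.5), rep(1, 49))), "48 h")
})

test_that("duration scan and threshold bisection validate their inputs", {
  expect_error(duration_scan(full_model, full_params, c(8, 2)),
               "sorted")
  expect_error(duration_threshold(full_model, full_params, lo = 4, hi = 4),
               "lo < hi")
})

test_that("zero-duration stimulus yields no wave", {
  sc <- duration_scan(full_model, full_params, durations = 0,
                      t_grid = seq(0, 72, 0.5))
  expect_identical(sc$label, "none")
})
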
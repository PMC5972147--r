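flat_mean <- function(level) function(t) rep(level, length(t))

test_that("vanishing cell-to-cell variation collapses onto the mean", {
  spec <- population_spec(flat_mean(2), cv = 1e-8, n_cells = 50, seed = 1)
  cells <- sample_population(spec, c(0, 12))
  expect_lt(max(abs(cells$value - 2)), 1e-6)
})

test_that("the sample mean honours the CLT at n = 2000", {
  spec <- population_spec(flat_mean(3), cv = 0.4, n_cells = 2000, seed = 7)
  cells <- sample_population(spec, 12)
  se <- stats::sd(cells$value) / sqrt(nrow(cells))
  expect_lt(abs(mean(cells$value) - 3), 3 * se)
})

test_that("a non-responder subpopulation makes log-values bimodal", {
  skip_if_not_installed("mclust")
  spec <- population_spec(flat_mean(8), cv = 0.3, n_cells = 2000,
                          nonresponder_frac = 0.3, seed = 3)
  cells <- sample_population(spec, 48)
  lx <- log(cells$value)
  bic <- mclust::mclustBIC(lx, G = 1:2, modelNames = "V", verbose = FALSE)
  expect_gt(bic["2", "V"], bic["1", "V"])
  # and the sampled responder fraction matches the spec
  expect_equal(mean(cells$responder), 0.7, tolerance = 0.05)
})

test_that("qPCR replicates are seeded and collapse onto truth as noise -> 0", {
  truth <- tibble::tibble(time_h = c(12, 72), fold = c(3, 10))
  tiny <- sample_qpcr(qpcr_spec(truth, noise_sd = 1e-9, seed = 1))
  expect_equal(tiny$fold, rep(truth$fold, each = 3), tolerance = 1e-6)
  a <- sample_qpcr(qpcr_spec(truth, noise_sd = 0.2, seed = 5))
  b <- sample_qpcr(qpcr_spec(truth, noise_sd = 0.2, seed = 5))
  expect_identical(a, b)
  d <- sample_qpcr(qpcr_spec(truth, noise_sd = 0.2, seed = 6))
  expect_false(isTRUE(all.equal(a$fold, d$fold)))
})

test_that("the geometric-mean estimator is nearly unbiased for triplicates", {
  truth <- tibble::tibble(time_h = 12, fold = 4)
  est <- vapply(seq_len(1000), function(s) {
    reps <- sample_qpcr(qpcr_spec(truth, noise_sd = 0.2, seed = s))
    exp(mean(log(reps$fold)))
  }, numeric(1))
  expect_lt(abs(mean(est) / 4 - 1), 0.05)
})

test_that("recovery fixtures are exact at zero noise and vary by seed only", {
  fx0 <- make_recovery_fixture(full_params, "a_snm_s", seed = 1,
                               noise_sd = 0)
  expect_lt(target_cost(full_params, full_model, fx0$targets), 1e-12)
  fx1 <- make_recovery_fixture(full_params, "a_snm_s", seed = 1,
                               noise_sd = 0.2)
  fx2 <- make_recovery_fixture(full_params, "a_snm_s", seed = 2,
                               noise_sd = 0.2)
  expect_false(isTRUE(all.equal(fx1$targets$target, fx2$targets$target)))
  expect_identical(fx1$truth, fx2$truth)
})
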
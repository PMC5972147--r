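test_that("cost is zero on self-generated targets and for empty tables", {
  fx <- make_recovery_fixture(full_params, free_names = "a_snm_s",
                              seed = 1, noise_sd = 0)
  expect_lt(target_cost(full_params, full_model, fx$targets), 1e-12)
  empty <- fx$targets[0, ]
  expect_identical(target_cost(full_params, full_model, empty), 0)
})

test_that("cost is invariant under reordering of the target list", {
  fx <- make_recovery_fixture(full_params, free_names = "a_snm_s",
                              seed = 2, noise_sd = 0.2)
  c1 <- target_cost(jitter_params(full_params, 7), full_model, fx$targets)
  shuffled <- fx$targets[rev(seq_len(nrow(fx$targets))), ]
  c2 <- target_cost(jitter_params(full_params, 7), full_model, shuffled)
  expect_equal(c1, c2, tolerance = 1e-12)
})

test_that("perturbing one rate away from the generating set raises the cost", {
  # self-targets give zero cost; a 10x change in one rate must not
  tg_small <- dplyr::bind_rows(
    fit_target("SNAIL1_mRNA", 24, "const", 1, tol = 0.2),
    fit_target("SNAIL1_mRNA", 72, "const", 1, tol = 0.2),
    fit_target("pSMAD_nuc", 12, "const", 1, tol = 0.2)
  )
  rates <- c("d_snm", "a_snm_s", "k_smad", "d_smad", "b_snm")
  for (i in seq_len(50)) {
    p <- jitter_params(full_params, 100 + i, sd = 0.04)
    ev <- snailwave:::sw_eval_targets(full_model, p, tg_small)
    tg <- tg_small
    tg$target <- ev$sim
    expect_lt(target_cost(p, full_model, tg), 1e-12)
    p2 <- p
    r <- rates[(i %% length(rates)) + 1]
    p2[r] <- 10 * p2[r]
    expect_gt(target_cost(p2, full_model, tg), 1e-6)
  }
})

test_that("searches are reproducible given the seed", {
  tg <- dplyr::bind_rows(
    fit_target("pSMAD_nuc", 12, "const", 3.5, tol = 0.2),
    fit_target("pSMAD_nuc", 24, "const", 2.2, tol = 0.3)
  )
  cfg <- search_config(starts = 2, iters = 30, seed = 5)
  f1 <- mc_search(full_model, tg, cfg, free = c("k_smad", "d_smad"))
  f2 <- mc_search(full_model, tg, cfg, free = c("k_smad", "d_smad"))
  expect_identical(f1$best_params, f2$best_params)
  expect_identical(f1$trace$cost, f2$trace$cost)
  expect_equal(f1$best_cost, min(tidy(f1)$cost))
})

test_that("acceptance behaves like Metropolis at temperature extremes", {
  tg <- fit_target("pSMAD_nuc", 12, "const", 3.5, tol = 0.2)
  hot <- mc_search(
    full_model, tg,
    search_config(starts = 1, iters = 100, seed = 3, temperature = 1e9),
    free = c("k_smad", "d_smad")
  )
  expect_gt(tidy(hot)$acceptance[1], 0.95)
  cold <- mc_search(
    full_model, tg,
    search_config(starts = 1, iters = 100, seed = 3, temperature = 1e-9),
    free = c("k_smad", "d_smad")
  )
  expect_true(all(diff(cold$trace$cost) <= 1e-12))
})

test_that("a short search recovers free parameters from synthetic targets", {
  free <- c("a_snm_s", "d_snm", "a_snm_g")
  fx <- make_recovery_fixture(full_params, free, seed = 11, noise_sd = 0.05)
  bounds <- param_bounds(full_model, half_decades = 1)
  fit <- mc_search(
    full_model, fx$targets,
    search_config(starts = 3, iters = 250, seed = 11),
    bounds = bounds, free = free
  )
  expect_lt(fit$best_cost, 0.5)
  ratio <- fit$best_params[free] / full_params[free]
  expect_true(all(ratio <= 2 & ratio >= 0.5))
})

test_that("under-budget falsification runs are flagged inconclusive", {
  rep <- falsify_two_wave(search_config(starts = 1, iters = 10, seed = 1))
  expect_false(rep$conclusive)
})
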
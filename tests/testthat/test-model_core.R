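test_that("variant rosters and parameter ownership are nested", {
  smad <- build_model("SMAD_ONLY")
  expect_length(smad$species, 4)
  expect_false(any(grepl("gl|gsk|aa|rel|imp", smad$param_names,
                         ignore.case = TRUE)))
  gli <- build_model("SMAD_GLI")
  full <- build_model("FULL")
  expect_true(all(smad$species %in% gli$species))
  expect_true(all(gli$species %in% full$species))
  expect_true(all(smad$param_names %in% gli$param_names))
  expect_true(all(gli$param_names %in% full$param_names))
  expect_error(build_model("WNT_ONLY"), "unknown model variant")
})

test_that("FULL with relay edges switched off reduces to SMAD_ONLY", {
  full <- build_model("FULL")
  smad <- build_model("SMAD_ONLY")
  pf <- full_params
  pf[c("a_snm_g", "kg_snp", "kg_glc", "kg_gln", "k_aa_u", "k_d_u")] <- 0
  ps <- pf[smad$param_names]
  state <- snailwave:::sw_initial_guess(
    snailwave:::sw_expand_params(full, pf)
  )
  state[1:11] <- abs(state[1:11]) + 0.1
  for (u in c(0, 1)) {
    r_full <- model_rhs(full, pf, state, stimulus = u)
    r_smad <- model_rhs(smad, ps, state, stimulus = u)
    expect_lt(max(abs(r_full[smad$species] - r_smad[smad$species])), 1e-12)
  }
})

test_that("basal state is a fixed point and zero stimulus stays there", {
  b <- basal_state(full_model, full_params)
  expect_true(b$converged)
  expect_lt(b$rhs_norm, 1e-8)
  tr <- simulate_network(full_model, full_params, stimulus("zero"),
                         basal = b)
  fold <- as.matrix(tr[, full_model$species])
  expect_lt(max(abs(fold - 1)), 1e-4)
})

test_that("doubling basal SNAIL1 mRNA synthesis raises basal SNAIL1 mRNA", {
  skip_if_not_installed("lhs")
  n <- 100
  free <- c("b_snm", "d_snm", "a_snm_s", "b_smad", "d_smad", "b_glm")
  grid <- snailwave:::sw_with_seed(42, lhs::randomLHS(n, length(free)))
  informative <- 0
  for (i in seq_len(n)) {
    p <- full_params
    p[free] <- p[free] * 10^(0.6 * (grid[i, ] - 0.5))
    b1 <- basal_state(full_model, p)
    p2 <- p
    p2["b_snm"] <- 2 * p2["b_snm"]
    b2 <- basal_state(full_model, p2)
    # draws without a stationary basal state carry no information here
    if (!(b1$converged && b2$converged)) next
    informative <- informative + 1
    expect_gt(b2$state[["SNAIL1_mRNA"]], b1$state[["SNAIL1_mRNA"]])
  }
  expect_gte(informative, 80)
})

test_that("trajectories are normalised fold changes with conserved GSK3", {
  tr <- simulate_network(full_model, full_params, stimulus("constant"))
  expect_equal(unname(unlist(tr[1, full_model$species])),
               rep(1, length(full_model$species)), tolerance = 1e-6)
  basal <- attr(tr, "basal")
  total <- tr$GSK3_A * basal[["GSK3_A"]] +
    tr$GSK3_AA * basal[["GSK3_AA"]] +
    tr$GSK3_D * basal[["GSK3_D"]]
  expect_lt(max(abs(total - 1)), 1e-9)
})

test_that("an inhibitor with zero efficacy leaves the trajectory unchanged", {
  tr0 <- simulate_network(full_model, full_params, stimulus("constant"))
  tr1 <- simulate_network(
    full_model, full_params, stimulus("constant"),
    inhibitors = list(inhibitor("GSK3_ACT", start = 0, eps = 0))
  )
  expect_lt(
    max(abs(as.matrix(tr1[, full_model$species]) -
              as.matrix(tr0[, full_model$species]))),
    1e-10
  )
})

test_that("complete SMAD-phosphorylation block keeps pSMAD at or below basal", {
  tr <- simulate_network(
    full_model, full_params, stimulus("constant"),
    inhibitors = list(inhibitor("SMAD_PHOS", start = 0, eps = 1))
  )
  expect_lte(max(tr$pSMAD_nuc), 1 + 1e-6)
})

test_that("peak pSMAD response is monotone in stimulus amplitude", {
  peaks <- vapply(c(0.25, 0.5, 1, 2), function(a) {
    tr <- simulate_network(full_model, full_params,
                           stimulus("constant", amplitude = a))
    max(tr$pSMAD_nuc)
  }, numeric(1))
  expect_true(all(diff(peaks) >= 0))
})

test_that("invalid simulation inputs are rejected with clear messages", {
  expect_error(
    simulate_network(full_model, full_params, stimulus("constant"),
                     t_grid = c(0, 0, 1)),
    "strictly increasing"
  )
  expect_error(
    simulate_network(full_model, full_params, stimulus("constant"),
                     t_grid = seq(0, 250, 1)),
    "within"
  )
  expect_error(stimulus("pulse", duration = 0), "duration")
  expect_error(inhibitor("SMAD_PHOS", start = 10, end = 5), "start < end")
  expect_error(inhibitor("SMAD_PHOS", eps = 1.2), "efficacy")
})
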
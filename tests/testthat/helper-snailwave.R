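# shared fixtures: calibrated defaults and a cheap deterministic
# perturbation helper used across test files

full_model <- build_model("FULL")
full_params <- default_params(full_model)

# small deterministic jitter of the calibrated set, staying well inside
# the prior bounds
jitter_params <- function(params, seed, sd = 0.05) {
  free <- setdiff(names(params), snailwave:::sw_fixed_params())
  snailwave:::sw_with_seed(seed, {
    params[free] <- params[free] * 10^rnorm(length(free), 0, sd)
  })
  params
}

expect_no_error <- function(expr) expect_error(expr, NA)
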
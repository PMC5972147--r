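#' Specification of an immunofluorescence-like single-cell population
#'
#' Single-cell fold changes are drawn from a lognormal mixture around a
#' mean trajectory: with probability `1 - nonresponder_frac` a cell
#' follows the population mean with cell-to-cell coefficient of variation
#' `cv`; otherwise it sits at the non-responder level (basal, fold change
#' 1, by default). The lognormal is parameterised so that the arithmetic
#' mean of responders equals the mean trajectory.
#'
#' @param mean_fn function of time returning the population-mean fold
#'   change, or a data frame with columns `time_h` and `value`
#'   (interpolated linearly).
#' @param cv lognormal cell-to-cell coefficient of variation (> 0).
#' @param n_cells cells per time point.
#' @param nonresponder_frac fraction of non-responding cells in `[0, 1]`.
#' @param nonresponder_level mean fold change of non-responders.
#' @param seed integer seed.
#' @return an `sw_population_spec` object.
#' @export
population_spec <- function(mean_fn, cv = 0.4, n_cells = 500,
                            nonresponder_frac = 0,
                            nonresponder_level = 1, seed = 1) {
  if (is.data.frame(mean_fn)) {
    df <- mean_fn
    mean_fn <- function(t) stats::approx(df$time_h, df$value, xout = t)$y
  }
  stopifnot(is.function(mean_fn))
  if (cv <= 0) abort("cv must be > 0")
  if (n_cells < 1) abort("n_cells must be >= 1")
  if (nonresponder_frac < 0 || nonresponder_frac > 1) {
    abort("nonresponder_frac must be in [0, 1]")
  }
  structure(
    list(
      mean_fn = mean_fn, cv = cv, n_cells = as.integer(n_cells),
      nonresponder_frac = nonresponder_frac,
      nonresponder_level = nonresponder_level, seed = as.integer(seed)
    ),
    class = "sw_population_spec"
  )
}

#' Sample a single-cell population
#'
#' @param spec an [population_spec()].
#' @param times time points (h) at which to sample.
#' @return tibble with `time_h`, `cell`, `value`, `responder`.
#' @export
sample_population <- function(spec, times) {
  stopifnot(inherits(spec, "sw_population_spec"))
  mu <- spec$mean_fn(times)
  if (any(!is.finite(mu))) {
    abort("mean trajectory is undefined at some requested times")
  }
  sdlog <- sqrt(log(1 + spec$cv^2))
  sw_with_seed(spec$seed, {
    purrr::map_dfr(seq_along(times), function(i) {
      resp <- stats::runif(spec$n_cells) >= spec$nonresponder_frac
      m <- ifelse(resp, mu[i], spec$nonresponder_level)
      meanlog <- log(m) - sdlog^2 / 2
      tibble(
        time_h = times[i],
        cell = seq_len(spec$n_cells),
        value = stats::rlnorm(spec$n_cells, meanlog, sdlog),
        responder = resp
      )
    })
  })
}

#' Specification of qPCR-like replicate fold changes
#'
#' Replicates carry multiplicative noise on the log2 scale around the
#' true fold change, mimicking triplicate qPCR measurements.
#'
#' @param true_fold data frame with columns `time_h` and `fold` (true
#'   fold changes), or a named numeric vector keyed by time.
#' @param noise_sd replicate standard deviation on the log2 scale (> 0).
#' @param replicates number of replicates (>= 2).
#' @param seed integer seed.
#' @return an `sw_qpcr_spec` object.
#' @export
qpcr_spec <- function(true_fold, noise_sd = 0.2, replicates = 3, seed = 1) {
  if (!is.data.frame(true_fold)) {
    true_fold <- tibble(
      time_h = as.numeric(names(true_fold)),
      fold = as.numeric(true_fold)
    )
  }
  if (noise_sd <= 0) abort("noise_sd must be > 0")
  if (replicates < 2) abort("replicates must be >= 2")
  structure(
    list(
      true_fold = true_fold, noise_sd = noise_sd,
      replicates = as.integer(replicates), seed = as.integer(seed)
    ),
    class = "sw_qpcr_spec"
  )
}

#' Sample qPCR-like replicate fold changes
#'
#' @param spec an [qpcr_spec()].
#' @return tibble with `time_h`, `replicate`, `fold`; the geometric mean
#'   of replicates is an asymptotically unbiased estimate of the true
#'   fold change as the noise vanishes.
#' @export
sample_qpcr <- function(spec) {
  stopifnot(inherits(spec, "sw_qpcr_spec"))
  sw_with_seed(spec$seed, {
    purrr::map_dfr(seq_len(nrow(spec$true_fold)), function(i) {
      tibble(
        time_h = spec$true_fold$time_h[i],
        replicate = seq_len(spec$replicates),
        fold = spec$true_fold$fold[i] *
          2^stats::rnorm(spec$replicates, 0, spec$noise_sd)
      )
    })
  })
}

#' Ground-truth fixture for parameter-recovery experiments
#'
#' Simulates the FULL model with a known parameter set, samples
#' qPCR-like noisy SNAIL1 fold changes at 12, 24, 48 and 72 h under the
#' control and the early/late GLI1-inhibition contexts, and packages them
#' as a fit-target table consumable by [mc_search()]. With zero noise the
#' generating parameter set has exactly zero cost.
#'
#' @param true_params named FULL-variant parameter vector.
#' @param free_names parameters intended to be searched over (recorded in
#'   the fixture for bookkeeping).
#' @param seed integer seed for the replicate noise.
#' @param noise_sd log2-scale noise of the sampled targets (0 for exact).
#' @param times measurement times (h).
#' @param contexts context ids to measure under.
#' @return list with `targets` (tibble), `truth`, `free_names`, `seed`.
#' @export
make_recovery_fixture <- function(true_params, free_names, seed = 1,
                                  noise_sd = 0.1,
                                  times = c(12, 24, 48, 72),
                                  contexts = c("const", "gli_i_early",
                                               "gli_i_late")) {
  model <- build_model("FULL")
  skeleton <- dplyr::bind_rows(lapply(contexts, function(cx) {
    dplyr::bind_rows(lapply(times, function(t) {
      fit_target("SNAIL1_mRNA", t, cx, target = 1, tol = 0.3)
    }))
  }))
  ev <- sw_eval_targets(model, true_params, skeleton)
  if (is.null(ev)) abort("true_params failed to simulate")
  noise <- sw_with_seed(seed, {
    2^stats::rnorm(nrow(ev), 0, noise_sd)
  })
  targets <- ev
  targets$target <- targets$sim * noise
  targets$sim <- NULL
  list(
    targets = targets, truth = true_params,
    free_names = free_names, seed = seed
  )
}
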
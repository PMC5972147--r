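#' Configuration for the multi-start Metropolis search
#'
#' @param starts number of independent configurations (random restarts).
#' @param iters Metropolis iterations per start.
#' @param step proposal standard deviation in log10-parameter units; one
#'   randomly chosen free parameter is perturbed per iteration and
#'   reflected at the prior bounds.
#' @param temperature Metropolis acceptance temperature (no annealing).
#' @param seed integer seed; every random draw of the search flows from it.
#' @return an `sw_search_config` list.
#' @export
search_config <- function(starts = 20, iters = 2000, step = 0.15,
                          temperature = 1, seed = 1) {
  if (starts < 1 || iters < 1) abort("starts and iters must be >= 1")
  if (step <= 0) abort("proposal step must be > 0")
  structure(
    list(
      starts = as.integer(starts), iters = as.integer(iters),
      step = step, temperature = temperature, seed = as.integer(seed)
    ),
    class = "sw_search_config"
  )
}

# run body under a deterministic, restored RNG state
sw_with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Multi-configuration Monte Carlo parameter search
#'
#' Calibrates a model variant against a fold-change constraint table by a
#' multi-start Metropolis walk in log10-parameter space: each start draws
#' a log-uniform initial point inside the prior bounds, then proposes
#' Gaussian single-parameter moves (sd = `step`), accepting with
#' probability `exp(-delta_cost / temperature)`. The best parameter set
#' ever visited is recorded per start; results are deterministic given the
#' seed in `config`.
#'
#' @inheritParams target_cost
#' @param config an [search_config()].
#' @param bounds prior bounds tibble as from [param_bounds()]; parameters
#'   marked `fixed` (and any with `lower == upper`) are pinned.
#' @param free optional character vector restricting the search to a
#'   subset of parameters (all others pinned at `init`).
#' @param init named parameter vector used for pinned values (defaults to
#'   the calibrated defaults of the variant).
#' @return an `sw_fit` object; see [tidy.sw_fit()] and [glance.sw_fit()].
#' @export
mc_search <- function(model, targets, config = search_config(),
                      bounds = param_bounds(model), free = NULL,
                      init = default_params(model)) {
  stopifnot(inherits(model, "sw_model"), inherits(config, "sw_search_config"))
  sw_check_targets(targets)
  bounds <- bounds[match(names(init), bounds$name), ]
  if (any(is.na(bounds$name))) abort("bounds must cover every parameter")
  if (any(bounds$lower > bounds$upper)) abort("bounds must have lower <= upper")
  is_free <- !bounds$fixed & bounds$lower < bounds$upper
  if (!is.null(free)) {
    bad <- setdiff(free, bounds$name)
    if (length(bad) > 0) {
      abort(paste0("unknown free parameter(s): ", paste(bad, collapse = ", ")))
    }
    is_free <- is_free & bounds$name %in% free
  }
  free_names <- bounds$name[is_free]
  if (length(free_names) == 0) abort("no free parameters to search over")
  llb <- log10(bounds$lower[is_free])
  lub <- log10(bounds$upper[is_free])
  nf <- length(free_names)

  cost_fn <- function(p) target_cost(p, model, targets)

  reflect <- function(x, lo, hi) {
    span <- hi - lo
    y <- (x - lo) %% (2 * span)
    lo + ifelse(y > span, 2 * span - y, y)
  }

  starts_out <- vector("list", config$starts)
  traces <- vector("list", config$starts)
  for (s in seq_len(config$starts)) {
    res <- sw_with_seed(config$seed + 1009L * s, {
      lp <- stats::runif(nf, llb, lub)
      p <- init
      p[free_names] <- 10^lp
      cc <- cost_fn(p)
      best_lp <- lp
      best_cost <- cc
      trace <- numeric(config$iters)
      acc <- 0L
      for (it in seq_len(config$iters)) {
        j <- sample.int(nf, 1)
        lp2 <- lp
        lp2[j] <- reflect(lp[j] + stats::rnorm(1, 0, config$step),
                          llb[j], lub[j])
        p[free_names] <- 10^lp2
        c2 <- cost_fn(p)
        if (stats::runif(1) < exp(-(c2 - cc) / config$temperature)) {
          lp <- lp2
          cc <- c2
          acc <- acc + 1L
          if (cc < best_cost) {
            best_cost <- cc
            best_lp <- lp
          }
        }
        trace[it] <- cc
      }
      pbest <- init
      pbest[free_names] <- 10^best_lp
      list(
        best = pbest, cost = best_cost, trace = trace,
        acc_rate = acc / config$iters
      )
    })
    starts_out[[s]] <- res
    traces[[s]] <- tibble(
      start = s, iter = seq_len(config$iters), cost = res$trace
    )
  }
  costs <- vapply(starts_out, function(r) r$cost, numeric(1))
  ibest <- which.min(costs)
  structure(
    list(
      variant = model$variant,
      free = free_names,
      best_params = starts_out[[ibest]]$best,
      best_cost = costs[ibest],
      best_start = ibest,
      starts = starts_out,
      trace = dplyr::bind_rows(traces),
      config = config,
      targets = targets
    ),
    class = "sw_fit"
  )
}

#' @export
print.sw_fit <- function(x, ...) {
  cat(
    "<sw_fit>", x$variant, "|", length(x$starts), "starts x",
    x$config$iters, "iters | best cost",
    signif(x$best_cost, 4), "(start", paste0(x$best_start, ")"), "\n"
  )
  invisible(x)
}

#' Tidy per-start search results
#'
#' @param x an `sw_fit` from [mc_search()].
#' @param ... unused.
#' @return tibble with one row per start: best cost, acceptance rate, and
#'   the best parameter set as a list column.
#' @export
tidy.sw_fit <- function(x, ...) {
  tibble(
    start = seq_along(x$starts),
    cost = vapply(x$starts, function(r) r$cost, numeric(1)),
    acceptance = vapply(x$starts, function(r) r$acc_rate, numeric(1)),
    params = lapply(x$starts, function(r) r$best)
  )
}

#' One-row summary of a search
#'
#' @inheritParams tidy.sw_fit
#' @return tibble with the global best cost, the maximum normalised
#'   residual of the best fit, and the search budget.
#' @export
glance.sw_fit <- function(x, ...) {
  ev <- sw_eval_targets(build_model(x$variant), x$best_params, x$targets)
  max_resid <- if (is.null(ev)) Inf else max(abs(sw_residuals(ev)))
  tibble(
    variant = x$variant,
    best_cost = x$best_cost,
    max_abs_residual = max_resid,
    fit_pass = max_resid <= 1,
    starts = length(x$starts),
    iters = x$config$iters,
    seed = x$config$seed
  )
}

#' @export
autoplot.sw_fit <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(
    x = .data$iter, y = .data$cost,
    group = .data$start, colour = factor(.data$start)
  )) +
    ggplot2::geom_line(alpha = 0.6, show.legend = FALSE) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "cost") +
    ggplot2::theme_minimal()
}

#' Can the canonical SMAD-only pathway explain the two SNAIL1 waves?
#'
#' Runs the Monte Carlo calibration of a variant against the transient
#' pSMAD constraint set together with the two-wave SNAIL1 shape
#' constraints, and reports whether each constraint group can be
#' satisfied (every target within its stated tolerance, i.e. maximum
#' normalised residual at most 1). For `SMAD_ONLY` the pSMAD dynamics are
#' fittable but the two-wave shape is not; the `FULL` variant satisfies
#' both. Runs below 20 starts x 2000 iterations are flagged as
#' inconclusive rather than interpreted.
#'
#' @param config an [search_config()].
#' @param variant model variant to test.
#' @return list with `psmad_fit_pass`, `two_wave_fit_pass`, `conclusive`,
#'   the `sw_fit`, and a residual table of the best fit.
#' @export
falsify_two_wave <- function(config = search_config(),
                             variant = c("SMAD_ONLY", "FULL", "SMAD_GLI")) {
  variant <- match.arg(variant)
  model <- build_model(variant)
  targets <- dplyr::bind_rows(
    read_fit_targets(packaged_targets("targets_psmad_transient.json")),
    read_fit_targets(packaged_targets("targets_snail_twowave.json"))
  )
  fit <- mc_search(model, targets, config)
  ev <- sw_eval_targets(model, fit$best_params, targets)
  conclusive <- config$starts >= 20 && config$iters >= 2000
  if (is.null(ev)) {
    return(list(
      psmad_fit_pass = FALSE, two_wave_fit_pass = FALSE,
      conclusive = conclusive, fit = fit, residuals = NULL
    ))
  }
  ev$residual <- sw_residuals(ev)
  is_psmad <- ev$species == "pSMAD_nuc"
  list(
    psmad_fit_pass = max(abs(ev$residual[is_psmad])) <= 1,
    two_wave_fit_pass = max(abs(ev$residual[!is_psmad])) <= 1,
    conclusive = conclusive,
    fit = fit,
    residuals = as_tibble(ev)
  )
}
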
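sw_ode_segment <- function(cparms, y0, times) {
  out <- deSolve::ode(
    y = y0, times = times, func = "sw_derivs", parms = cparms,
    dllname = "snailwave", initfunc = "sw_init",
    method = "lsoda", rtol = 1e-8, atol = 1e-10, maxsteps = 50000
  )
  if (attr(out, "istate")[1] < 0) {
    abort("ODE integration failed (lsoda istate < 0)")
  }
  out
}

sw_initial_guess <- function(pfull) {
  aa0 <- pfull[["frac_aa0"]]
  d0 <- pfull[["frac_d0"]]
  y <- c(
    pSMAD_nuc = 0.1, ISMAD = 0.1, SNAIL1_mRNA = 0.05, SNAIL1_prot = 0.05,
    GLI1_mRNA = 0.05, GLI1_bound = 0.05, GLI1_free = 0.05, GLI1_nuc = 0.05,
    GSK3_A = 1 - aa0 - d0, GSK3_AA = aa0, GSK3_D = d0,
    TGFR_fast = 0, TGFR_slow = 0
  )
  y[sw_species_all()]
}

#' Basal fixed point of a model
#'
#' Finds the zero-stimulus steady state by long integration (500 h)
#' followed by Newton polishing with a finite-difference Jacobian. The
#' receptor pools are excluded from the Newton step (they are exactly zero
#' without stimulus) and the GSK3 simplex is preserved.
#'
#' @inheritParams model_rhs
#' @param polish_iter maximum Newton iterations.
#' @return a list with `state` (named 13-vector), `converged` (logical:
#'   sup-norm of the right-hand side < 1e-8) and `rhs_norm`. A
#'   non-stationary parameter set yields `converged = FALSE` rather than
#'   an error, so that parameter searches can penalise it.
#' @export
basal_state <- function(model, params, polish_iter = 25) {
  stopifnot(inherits(model, "sw_model"))
  pfull <- sw_expand_params(model, params)
  cp <- c(unname(pfull), 0, 1, 1, 1)
  y <- sw_initial_guess(pfull)
  out <- try(sw_ode_segment(cp, y, c(0, 250, 500)), silent = TRUE)
  if (inherits(out, "try-error")) {
    return(list(state = y, converged = FALSE, rhs_norm = Inf))
  }
  y <- setNames(as.numeric(out[nrow(out), -1]), sw_species_all())
  rhs <- function(z) .Call(sw_rhs_call, 0.0, as.double(z), as.double(cp))
  # Newton polish on the 11 network species; receptors stay 0 and the
  # GSK3 total is conserved by construction of the field.
  idx <- 1:11
  for (it in seq_len(polish_iter)) {
    f <- rhs(y)
    if (max(abs(f)) < 1e-10) break
    J <- matrix(0, 11, 11)
    h <- pmax(abs(y[idx]), 1e-6) * 1e-7
    for (j in idx) {
      yp <- y
      yp[j] <- yp[j] + h[j]
      J[, j] <- (rhs(yp)[idx] - f[idx]) / h[j]
    }
    step <- try(solve(J, -f[idx]), silent = TRUE)
    if (inherits(step, "try-error")) break
    # damp steps that would leave the positive orthant
    lam <- 1
    repeat {
      ynew <- y
      ynew[idx] <- y[idx] + lam * step
      if (all(ynew[idx] > 0) || lam < 1e-4) break
      lam <- lam / 2
    }
    if (any(ynew[idx] <= 0)) break
    y <- ynew
  }
  nrm <- max(abs(rhs(y)))
  list(state = y, converged = is.finite(nrm) && nrm < 1e-8, rhs_norm = nrm)
}

#' Simulate a model variant
#'
#' Stiff-safe integration of a model under a stimulus profile and optional
#' inhibitor interventions. The stimulus and inhibitor windows are
#' piecewise constant, so the trajectory is integrated segment by segment
#' between the change points with `deSolve::lsoda` (rtol 1e-8, atol
#' 1e-10). Output is normalised to the basal fixed point: every reported
#' species column is a fold change that equals 1 at `t = 0`. The two
#' receptor pools (zero basal level) are reported on their raw 0-1 scale.
#'
#' @inheritParams basal_state
#' @param stim an [stimulus()] profile.
#' @param inhibitors list of [inhibitor()] specs.
#' @param t_grid strictly increasing time grid in hours starting at 0
#'   (default 0-72 h in 0.25 h steps; must stay within 0-200 h).
#' @param basal optional precomputed result of [basal_state()] (to avoid
#'   recomputation inside parameter searches).
#' @param params_id identifier recorded in the result, used in diagnostics.
#' @return an `sw_trajectory`: a tibble with `time_h`, one fold-change
#'   column per roster species, and the receptor columns; attributes
#'   `variant`, `basal`, `stimulus`, `inhibitors`, `params_id`.
#' @export
simulate_network <- function(model, params, stim = stimulus("constant"),
                             inhibitors = list(),
                             t_grid = seq(0, 72, by = 0.25),
                             basal = NULL, params_id = "params") {
  stopifnot(inherits(model, "sw_model"), inherits(stim, "sw_stimulus"))
  if (inherits(inhibitors, "sw_inhibitor")) inhibitors <- list(inhibitors)
  if (is.unsorted(t_grid, strictly = TRUE)) {
    abort("t_grid must be strictly increasing")
  }
  if (min(t_grid) < 0 || max(t_grid) > 200) {
    abort("t_grid must lie within [0, 200] hours")
  }
  pfull <- sw_expand_params(model, params)
  if (is.null(basal)) basal <- basal_state(model, params)
  if (!basal$converged) {
    abort(paste0(
      "no stationary basal state for parameter set '", params_id,
      "' (|rhs| = ", signif(basal$rhs_norm, 3), ")"
    ))
  }
  t0 <- min(t_grid)
  tmax <- max(t_grid)
  breaks <- sort(unique(c(
    t0, tmax,
    sw_stim_breaks(stim), sw_inhib_breaks(inhibitors)
  )))
  breaks <- breaks[breaks >= t0 & breaks <= tmax]

  y <- basal$state
  rows <- matrix(NA_real_, nrow = length(t_grid), ncol = 13)
  rows[1, ] <- y
  filled <- 1
  for (k in seq_len(length(breaks) - 1)) {
    a <- breaks[k]
    b <- breaks[k + 1]
    mid <- (a + b) / 2
    u <- sw_stim_level(stim, mid)
    f <- sw_inhib_factors(inhibitors, mid)
    cp <- c(unname(pfull), u, f[["SMAD_PHOS"]], f[["GLI1_ACT"]],
            f[["GSK3_ACT"]])
    inner <- t_grid[t_grid > a & t_grid < b]
    times <- unique(c(a, inner, b))
    out <- sw_ode_segment(cp, y, times)
    y <- setNames(as.numeric(out[nrow(out), -1]), sw_species_all())
    keep <- times %in% t_grid & times > a
    if (any(keep)) {
      m <- out[-1, -1, drop = FALSE][keep[-1], , drop = FALSE]
      rows[filled + seq_len(nrow(m)), ] <- m
      filled <- filled + nrow(m)
    }
  }
  colnames(rows) <- sw_species_all()
  if (min(rows) < -1e-9) {
    abort(paste0(
      "negative concentration in simulation of '", params_id,
      "' (min = ", signif(min(rows), 3), ")"
    ))
  }
  species <- model$species
  fold <- rows[, species, drop = FALSE]
  fold <- sweep(fold, 2, basal$state[species], "/")
  res <- as_tibble(as.data.frame(fold))
  res <- tibble::add_column(res, time_h = t_grid, .before = 1)
  res$TGFR_fast <- rows[, "TGFR_fast"]
  res$TGFR_slow <- rows[, "TGFR_slow"]
  structure(
    res,
    class = c("sw_trajectory", class(res)),
    variant = model$variant,
    basal = basal$state,
    stimulus = stim,
    inhibitors = inhibitors,
    params_id = params_id
  )
}

#' @export
print.sw_trajectory <- function(x, ...) {
  cat(
    "<sw_trajectory> variant", attr(x, "variant"), "|",
    attr(x, "stimulus")$kind, "stimulus |",
    nrow(x), "time points over", max(x$time_h), "h\n"
  )
  NextMethod()
}

#' Plot a simulated trajectory
#'
#' @param object an `sw_trajectory`.
#' @param species character vector of species to show (default: the
#'   classic readouts).
#' @param ... unused.
#' @return a ggplot object of fold change versus time.
#' @export
autoplot.sw_trajectory <- function(object,
                                   species = intersect(
                                     c("pSMAD_nuc", "SNAIL1_mRNA",
                                       "SNAIL1_prot", "GLI1_nuc"),
                                     names(object)
                                   ), ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(as_tibble(object), "time_h", dplyr::all_of(species)),
    -"time_h", names_to = "species", values_to = "fold_change"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$time_h, y = .data$fold_change, colour = .data$species
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "time (h)", y = "fold change over basal", colour = NULL
    ) +
    ggplot2::theme_minimal()
}
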
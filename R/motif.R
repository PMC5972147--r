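#' Parameters of the boosted positive-feedback motif
#'
#' The generic motif is a single species X under autocatalytic Hill
#' feedback, `dx/dt = b + v x^n / (K^n + x^n) - d x`, optionally preceded
#' by the rapid conversion of an inactive reservoir that lifts the
#' initial condition from `x0` to `x0 + dx0` at stimulus onset. The
#' response time `t_R` is the time taken to rise from the initial
#' condition to the response threshold `xR`.
#'
#' @param b basal production rate (conc/h).
#' @param v maximal feedback production rate (conc/h).
#' @param K feedback Hill constant (conc).
#' @param n feedback Hill coefficient.
#' @param d first-order degradation rate (1/h).
#' @param x0 initial active concentration.
#' @param dx0 reservoir boost added to `x0` at time zero.
#' @param xR response threshold concentration.
#' @param tT target response time (h); used only for reporting.
#' @return an `sw_motif` parameter object.
#' @export
motif_params <- function(b = 0.02, v = 1, K = 0.5, n = 4, d = 0.5,
                         x0 = 0.05, dx0 = 0.05, xR = 1.2, tT = 10) {
  vals <- c(b = b, v = v, K = K, n = n, d = d, x0 = x0, xR = xR, tT = tT)
  if (any(vals <= 0)) abort("motif parameters must be positive")
  if (dx0 < 0) abort("dx0 must be >= 0")
  if (!(x0 < xR)) abort("x0 must lie below the response threshold xR")
  structure(
    list(b = b, v = v, K = K, n = n, d = d, x0 = x0, dx0 = dx0,
         xR = xR, tT = tT),
    class = "sw_motif"
  )
}

#' Motif rate field
#'
#' @param x concentration (vectorised).
#' @param p an [motif_params()] object.
#' @return dx/dt at `x`.
#' @export
motif_rhs <- function(x, p) {
  stopifnot(inherits(p, "sw_motif"))
  p$b + p$v * x^p$n / (p$K^p$n + x^p$n) - p$d * x
}

#' Fixed points of the motif
#'
#' Brackets sign changes of the rate field on a fine grid and polishes
#' each root with `uniroot`; stability from the sign of the derivative.
#'
#' @param p an [motif_params()] object.
#' @param upper upper end of the search interval (defaults to well above
#'   the maximal production level `(b + v) / d`).
#' @return tibble with columns `x` and `stable`.
#' @export
motif_fixed_points <- function(p, upper = NULL) {
  stopifnot(inherits(p, "sw_motif"))
  if (is.null(upper)) upper <- 1.5 * (p$b + p$v) / p$d
  grid <- seq(0, upper, length.out = 4001)
  f <- motif_rhs(grid, p)
  sgn <- sign(f)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  roots <- vapply(flips, function(i) {
    stats::uniroot(function(x) motif_rhs(x, p),
      c(grid[i], grid[i + 1]),
      tol = 1e-12
    )$root
  }, numeric(1))
  eps <- 1e-7
  stable <- vapply(roots, function(r) {
    (motif_rhs(r + eps, p) - motif_rhs(r - eps, p)) < 0
  }, logical(1))
  tibble(x = roots, stable = stable)
}

sw_motif_integrate <- function(p, x_init, t_end, input = NULL,
                               xR_event = NA_real_) {
  rhs <- function(t, y, parms) {
    s <- if (is.null(input)) 0 else input(t)
    list(motif_rhs(y, p) + s)
  }
  times <- seq(0, t_end, length.out = 2001)
  if (!is.na(xR_event)) {
    root <- function(t, y, parms) y - xR_event
    out <- deSolve::lsodar(
      y = x_init, times = times, func = rhs,
      rootfunc = root, rtol = 1e-10, atol = 1e-12
    )
  } else {
    out <- deSolve::lsoda(
      y = x_init, times = times, func = rhs,
      rtol = 1e-10, atol = 1e-12
    )
  }
  out
}

#' Response time of the motif
#'
#' Integrates the motif from `x0 + dx0` (set `boost = FALSE` to start at
#' `x0`) and returns the time at which the trajectory crosses `xR`,
#' located by the integrator's root finder.
#'
#' @param p an [motif_params()] object.
#' @param boost apply the reservoir boost at time zero?
#' @param horizon integration horizon (h).
#' @return a list with `t_R` (NA when not reached), `reached`, and the
#'   trajectory as a tibble.
#' @export
response_time <- function(p, boost = FALSE, horizon = 200) {
  stopifnot(inherits(p, "sw_motif"))
  x_init <- p$x0 + if (boost) p$dx0 else 0
  if (x_init >= p$xR) {
    return(list(
      t_R = 0, reached = TRUE,
      trajectory = tibble(time_h = 0, x = x_init)
    ))
  }
  out <- sw_motif_integrate(p, x_init, horizon, xR_event = p$xR)
  troot <- attr(out, "troot")
  reached <- length(troot) > 0
  list(
    t_R = if (reached) troot[1] else NA_real_,
    reached = reached,
    trajectory = tibble(time_h = out[, 1], x = out[, 2])
  )
}

#' Response-time acceleration from the reservoir boost
#'
#' Computes `dt_R(x0) = t_R(x0) - t_R(x0 + dx0)` along a grid of initial
#' concentrations with the boost size fixed. In the accelerating phase of
#' the sigmoidal rise (initial levels above the unstable point but below
#' the point of maximal net velocity) the acceleration is positive and
#' decreases with the initial concentration: cells starting lower gain
#' the most.
#'
#' @param p an [motif_params()] object (its `x0`/`dx0` are overridden).
#' @param x0_grid vector of initial concentrations.
#' @param dx0 fixed boost.
#' @param horizon integration horizon (h).
#' @return tibble with `x0`, `t_R`, `t_R_boosted`, `dt_R`, `reached`;
#'   grid points whose threshold is unreachable are flagged, not dropped.
#' @export
boost_acceleration <- function(p, x0_grid, dx0 = p$dx0, horizon = 200) {
  stopifnot(inherits(p, "sw_motif"))
  if (dx0 < 0) abort("dx0 must be >= 0")
  res <- purrr::map_dfr(x0_grid, function(x0) {
    p1 <- p
    p1$x0 <- x0
    p1$dx0 <- dx0
    base <- response_time(p1, boost = FALSE, horizon = horizon)
    boosted <- response_time(p1, boost = TRUE, horizon = horizon)
    tibble(
      x0 = x0,
      t_R = base$t_R,
      t_R_boosted = boosted$t_R,
      dt_R = base$t_R - boosted$t_R,
      reached = base$reached && boosted$reached
    )
  })
  if (any(!res$reached)) {
    warn(paste0(
      "threshold unreachable within horizon at x0 = ",
      paste(signif(res$x0[!res$reached], 3), collapse = ", ")
    ))
  }
  class(res) <- c("sw_boost_curve", class(res))
  res
}

#' @export
autoplot.sw_boost_curve <- function(object, ...) {
  ggplot2::ggplot(
    dplyr::filter(object, .data$reached),
    ggplot2::aes(x = .data$x0, y = .data$dt_R)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "initial concentration (X)0",
      y = expression(Delta * t[R] ~ "(h)")
    ) +
    ggplot2::theme_minimal()
}

#' Does a transient input pulse switch the motif on?
#'
#' Drives the motif with an additive input of given amplitude and
#' duration, then integrates the relaxation and reports whether the state
#' commits to the high fixed point (ends above the unstable threshold of
#' the bistable field). Short or weak pulses are filtered out, with or
#' without the reservoir boost.
#'
#' @param p an [motif_params()] object.
#' @param pulse_amplitude additive input rate during the pulse.
#' @param pulse_duration pulse length (h).
#' @param boost apply the reservoir boost at pulse onset?
#' @param settle_time relaxation time simulated after the pulse (h).
#' @return logical: committed to the high state?
#' @export
noise_filtering <- function(p, pulse_amplitude, pulse_duration,
                            boost = FALSE, settle_time = 100) {
  stopifnot(inherits(p, "sw_motif"))
  fp <- motif_fixed_points(p)
  if (nrow(fp) < 3) {
    abort("motif is not bistable for these parameters")
  }
  x_unstable <- fp$x[!fp$stable][1]
  x_init <- p$x0 + if (boost) p$dx0 else 0
  if (pulse_duration > 0 && pulse_amplitude > 0) {
    on_phase <- sw_motif_integrate(
      p, x_init, pulse_duration,
      input = function(t) pulse_amplitude
    )
    x_init <- on_phase[nrow(on_phase), 2]
  }
  off_phase <- sw_motif_integrate(p, x_init, settle_time)
  x_end <- off_phase[nrow(off_phase), 2]
  x_end > x_unstable
}

#' Minimal switching duration of an input pulse
#'
#' Bisects the pulse duration at the commit/no-commit boundary for a
#' fixed pulse amplitude (resolution 0.01 h by default).
#'
#' @inheritParams noise_filtering
#' @param lo,hi initial bracket in hours; `lo` must not switch and `hi`
#'   must switch.
#' @param resolution bisection resolution (h).
#' @return boundary duration in hours.
#' @export
switching_boundary <- function(p, pulse_amplitude, lo = 0, hi = 50,
                               boost = FALSE, resolution = 0.01) {
  f_lo <- noise_filtering(p, pulse_amplitude, lo, boost = boost)
  f_hi <- noise_filtering(p, pulse_amplitude, hi, boost = boost)
  if (f_lo || !f_hi) {
    abort("invalid bracket: lo must not switch and hi must switch")
  }
  while (hi - lo > resolution) {
    mid <- (lo + hi) / 2
    if (noise_filtering(p, pulse_amplitude, mid, boost = boost)) {
      hi <- mid
    } else {
      lo <- mid
    }
  }
  (lo + hi) / 2
}
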
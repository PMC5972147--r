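# peak detection with topographic prominence; the right boundary is
# eligible as a peak so that a still-rising sustained wave at the end of
# the horizon counts
sw_find_peaks <- function(x, t) {
  n <- length(x)
  cand <- integer(0)
  for (i in 2:(n - 1)) {
    if (x[i] > x[i - 1] && x[i] >= x[i + 1]) cand <- c(cand, i)
  }
  if (x[n] > x[n - 1]) cand <- c(cand, n)
  if (length(cand) == 0) {
    return(tibble(
      idx = integer(0), time_h = numeric(0), height = numeric(0),
      prominence = numeric(0)
    ))
  }
  prom <- vapply(cand, function(i) {
    h <- x[i]
    # key-saddle height towards the nearest strictly higher terrain on
    # each side; a side with no higher terrain does not constrain, and
    # the global maximum gets its height over the global minimum
    left <- if (any(x[seq_len(i - 1)] > h)) {
      j <- max(which(x[seq_len(i - 1)] > h))
      h - min(x[j:i])
    } else {
      NA_real_
    }
    right <- if (i < n && any(x[(i + 1):n] > h)) {
      j <- i + min(which(x[(i + 1):n] > h))
      h - min(x[i:j])
    } else {
      NA_real_
    }
    if (is.na(left) && is.na(right)) h - min(x)
    else min(left, right, na.rm = TRUE)
  }, numeric(1))
  tibble(idx = cand, time_h = t[cand], height = x[cand], prominence = prom)
}

#' Classify SNAIL1 wave dynamics
#'
#' Labels a trajectory `none`, `one_wave` or `two_wave` from peak
#' detection on the SNAIL1 protein fold change. A "wave" is a local
#' maximum of height at least `min_height` (fold units) with topographic
#' prominence at least `min_prominence` times its height; the end of the
#' horizon may act as the second peak (a sustained rising wave).
#' `one_wave` is a transient response (a wave that has decayed below
#' `min_height` by 72 h); `two_wave` is the sustained response — a wave
#' plus a 72 h level of at least `min_height`, whether the SMAD- and
#' GLI1-driven phases are separated by the characteristic dip or fused
#' into one prolonged wave (as happens under strong drives).
#'
#' @param traj an `sw_trajectory` covering at least 72 h.
#' @param species readout column (default SNAIL1 protein).
#' @param min_height minimal wave height in fold-change units.
#' @param min_prominence minimal relative prominence of a wave.
#' @return an `sw_waves` list: `label`, `peaks` (tibble), `level_72h`.
#' @export
classify_waves <- function(traj, species = "SNAIL1_prot",
                           min_height = 1.5, min_prominence = 0.1) {
  if (!inherits(traj, "sw_trajectory") && !is.data.frame(traj)) {
    abort("classify_waves expects a trajectory")
  }
  if (max(traj$time_h) < 72) {
    abort("trajectory must cover at least 72 h")
  }
  x <- traj[[species]]
  t <- traj$time_h
  lvl72 <- stats::approx(t, x, xout = 72)$y
  pk <- sw_find_peaks(x, t)
  waves <- pk[pk$height >= min_height &
                pk$prominence >= min_prominence * pk$height, ]
  # one_wave = transient (decays back below min_height by 72 h);
  # two_wave = the sustained response: either two waves separated by a
  # dip, or a single merged wave that stays high (strong drives fuse the
  # SMAD- and GLI1-driven phases without an intervening dip)
  label <- "none"
  if (nrow(waves) >= 1) label <- "one_wave"
  if (nrow(waves) >= 1 && lvl72 >= min_height) label <- "two_wave"
  structure(
    list(label = label, peaks = waves, level_72h = lvl72),
    class = "sw_waves"
  )
}

#' @export
print.sw_waves <- function(x, ...) {
  cat("<sw_waves>", x$label, "| 72 h level", signif(x$level_72h, 3), "\n")
  if (nrow(x$peaks) > 0) print(x$peaks)
  invisible(x)
}

#' Pulse-duration scan
#'
#' Simulates one TGF-beta pulse per requested duration and classifies the
#' SNAIL1 response. For a calibrated parameter set the labels are
#' monotone in duration (`none`/`one_wave` below the duration threshold,
#' `two_wave` above); a non-monotone labelling triggers a warning naming
#' the offending durations.
#'
#' @inheritParams basal_state
#' @param durations pulse durations in hours, sorted ascending
#'   (0 is allowed and means no stimulus).
#' @param t_grid simulation grid (h), covering at least 72 h.
#' @return an `sw_duration_scan` tibble: one row per duration with the
#'   label and SNAIL1 summaries; the per-duration SNAIL1 time courses are
#'   kept in the `snail_matrix` attribute (durations x time).
#' @export
duration_scan <- function(model, params, durations = c(0, 1, 2, 4, 6, 8, 12, 24),
                          t_grid = seq(0, 72, by = 0.25)) {
  if (is.unsorted(durations)) abort("durations must be sorted ascending")
  basal <- basal_state(model, params)
  rows <- list()
  snail <- matrix(NA_real_, length(durations), length(t_grid))
  for (i in seq_along(durations)) {
    d <- durations[i]
    stim <- if (d <= 0) stimulus("zero") else stimulus("pulse", duration = d)
    tr <- simulate_network(model, params, stim, t_grid = t_grid,
                           basal = basal)
    cl <- classify_waves(tr)
    snail[i, ] <- tr$SNAIL1_prot
    rows[[i]] <- tibble(
      duration_h = d,
      label = cl$label,
      n_waves = nrow(cl$peaks),
      snail_72h = cl$level_72h,
      first_peak_h = if (nrow(cl$peaks) > 0) cl$peaks$time_h[1] else NA_real_
    )
  }
  out <- dplyr::bind_rows(rows)
  ord <- c(none = 0, one_wave = 1, two_wave = 2)[out$label]
  if (is.unsorted(ord)) {
    bad <- out$duration_h[which(diff(ord) < 0) + 1]
    warn(paste0(
      "wave labels are not monotone in duration (check calibration); ",
      "offending durations: ", paste(bad, collapse = ", "), " h"
    ))
  }
  structure(
    out,
    class = c("sw_duration_scan", class(out)),
    snail_matrix = snail, t_grid = t_grid
  )
}

#' @export
autoplot.sw_duration_scan <- function(object, ...) {
  m <- attr(object, "snail_matrix")
  long <- tibble(
    duration_h = rep(object$duration_h, times = ncol(m)),
    time_h = rep(attr(object, "t_grid"), each = nrow(m)),
    snail = as.vector(m)
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$time_h, y = factor(.data$duration_h), fill = .data$snail
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "SNAIL1 fold") +
    ggplot2::labs(x = "time (h)", y = "TGF-beta pulse duration (h)") +
    ggplot2::theme_minimal()
}

#' Duration threshold for the second SNAIL1 wave
#'
#' Bisects the pulse duration separating `one_wave` from `two_wave`
#' responses.
#'
#' @inheritParams duration_scan
#' @param lo,hi bracket in hours: `lo` must not classify `two_wave`,
#'   `hi` must.
#' @param resolution bisection resolution in hours.
#' @return threshold duration (h).
#' @export
duration_threshold <- function(model, params, lo = 2, hi = 8,
                               resolution = 0.1) {
  if (!(lo < hi)) abort("duration bracket requires lo < hi")
  basal <- basal_state(model, params)
  two_wave_at <- function(d) {
    stim <- if (d <= 0) stimulus("zero") else stimulus("pulse", duration = d)
    tr <- simulate_network(model, params, stim, basal = basal)
    classify_waves(tr)$label == "two_wave"
  }
  if (two_wave_at(lo)) abort("invalid bracket: lo already yields two waves")
  if (!two_wave_at(hi)) abort("invalid bracket: hi does not yield two waves")
  while (hi - lo > resolution) {
    mid <- (lo + hi) / 2
    if (two_wave_at(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Predicted threshold shifts under parameter modulation
#'
#' Recomputes the duration threshold under the four modulations the
#' model predicts to tune the temporal checkpoint: increased nuclear GSK3
#' activity (raises the threshold), increased cytosolic GSK3 activity
#' (lowers it), GLI1 synthesis up-regulation and I-SMAD down-regulation
#' (both lower it).
#'
#' @inheritParams duration_threshold
#' @param modulations named list of parameter multipliers; the default
#'   set is nuclear GSK3 x1.5, cytosolic GSK3 x1.5, GLI1 synthesis x2,
#'   I-SMAD synthesis x0.5.
#' @return tibble with baseline and modulated thresholds, shifts and
#'   directions.
#' @export
modulation_report <- function(model, params, lo = 0.25, hi = 24,
                              resolution = 0.1,
                              modulations = list(
                                nuclear_GSK3 = c(m_nuc = 1.5),
                                cytosolic_GSK3 = c(m_cyt = 1.5),
                                GLI1_synthesis = c(glm_scale = 2),
                                ISMAD_synthesis = c(ismad_scale = 0.5)
                              )) {
  base <- duration_threshold(model, params, lo, hi, resolution)
  rows <- purrr::imap(modulations, function(mult, label) {
    p2 <- params
    p2[names(mult)] <- p2[names(mult)] * mult
    th <- tryCatch(
      duration_threshold(model, p2, lo, hi, resolution),
      error = function(e) NA_real_
    )
    tibble(
      modulation = label,
      parameter = names(mult),
      multiplier = unname(mult),
      threshold_h = th,
      baseline_h = base,
      shift_h = th - base,
      direction = dplyr::case_when(
        is.na(th) ~ "unresolved",
        abs(th - base) <= resolution ~ "none",
        th > base ~ "increase",
        TRUE ~ "decrease"
      )
    )
  })
  dplyr::bind_rows(rows)
}

#' Default coarse-graining thresholds for TOSS encoding
#'
#' pSMAD has three bins (L below `psmad[1]`, M between, H at or above
#' `psmad[2]`); GLI1 and SNAIL1 have two bins split at their single
#' threshold. All thresholds are in fold-change units relative to basal.
#'
#' @return list with elements `psmad`, `gli1`, `snail1`.
#' @export
toss_thresholds <- function() {
  list(psmad = c(L = 1.5, H = 3), gli1 = 1.5, snail1 = 1.5)
}

#' Encode a trajectory into the temporally ordered state space (TOSS)
#'
#' Discretises nuclear pSMAD2/3 and nuclear GLI1 at 12 h and 48 h into a
#' 4-element state, and SNAIL1 protein at the same times into a 2-element
#' state. Without TGF-beta the code reads `(L, L; L, L)`; a 2 h pulse
#' gives `(H, L; L, L)` and an 8 h pulse `(H, M; L, H)`, with SNAIL1
#' `(L, L)`, `(H, L)` and `(H, H)` respectively.
#'
#' @param traj trajectory covering at least 48 h.
#' @param thresholds see [toss_thresholds()].
#' @return an `sw_toss` object.
#' @export
encode_toss <- function(traj, thresholds = toss_thresholds()) {
  if (max(traj$time_h) < 48) {
    abort("trajectory must cover at least 48 h for TOSS encoding")
  }
  val <- function(species, t) stats::approx(
    traj$time_h, traj[[species]], xout = t
  )$y
  bin3 <- function(x) {
    if (x >= thresholds$psmad[["H"]]) "H"
    else if (x >= thresholds$psmad[["L"]]) "M"
    else "L"
  }
  bin2 <- function(x, thr) if (x >= thr) "H" else "L"
  ps <- vapply(c(12, 48), function(t) bin3(val("pSMAD_nuc", t)), "")
  gl <- vapply(
    c(12, 48), function(t) bin2(val("GLI1_nuc", t), thresholds$gli1), ""
  )
  sn <- vapply(
    c(12, 48), function(t) bin2(val("SNAIL1_prot", t), thresholds$snail1), ""
  )
  structure(
    list(
      psmad = ps, gli1 = gl, snail1 = sn,
      state = sprintf("(%s, %s; %s, %s)", ps[1], ps[2], gl[1], gl[2]),
      snail_state = sprintf("(%s, %s)", sn[1], sn[2]),
      thresholds = thresholds
    ),
    class = "sw_toss"
  )
}

#' @export
print.sw_toss <- function(x, ...) {
  cat("<sw_toss> pSMAD/GLI1:", x$state, " SNAIL1:", x$snail_state, "\n")
  invisible(x)
}
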
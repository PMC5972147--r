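#' Build a nested network model variant
#'
#' The three variants form a nested family: `SMAD_ONLY` (canonical
#' TGF-beta/SMAD/SNAIL1 pathway with the I-SMAD negative feedback),
#' `SMAD_GLI` (adds the GLI1 branch with its transcriptional positive
#' feedback, GSK3 pools frozen at their basal fractions), and `FULL`
#' (adds the TGF-beta-driven interconversion of the three GSK3
#' phosphorylation forms and their catalytic action on GLI1 release and
#' protein degradation). Shared edges have identical functional forms and
#' parameter names, so the larger variants reduce exactly to the smaller
#' ones when the extra edges are switched off.
#'
#' @param variant one of `"SMAD_ONLY"`, `"SMAD_GLI"`, `"FULL"`.
#' @return an object of class `sw_model` with elements `variant`,
#'   `species` (reported roster) and `param_names`.
#' @examples
#' m <- build_model("SMAD_ONLY")
#' m$species
#' @export
build_model <- function(variant = c("FULL", "SMAD_GLI", "SMAD_ONLY")) {
  if (length(variant) == 1 && !variant %in% c("FULL", "SMAD_GLI", "SMAD_ONLY")) {
    abort(paste0(
      "unknown model variant '", variant,
      "'; expected one of FULL, SMAD_GLI, SMAD_ONLY"
    ))
  }
  variant <- match.arg(variant)
  structure(
    list(
      variant = variant,
      species = sw_roster(variant),
      param_names = sw_param_names(variant)
    ),
    class = "sw_model"
  )
}

#' @export
print.sw_model <- function(x, ...) {
  cat("<sw_model> variant:", x$variant, "\n")
  cat("  species:", paste(x$species, collapse = ", "), "\n")
  cat("  parameters:", length(x$param_names), "\n")
  invisible(x)
}

#' Stimulus profiles
#'
#' TGF-beta input as a function of time. Amplitude is dimensionless with
#' 1 corresponding to 4 ng/ml TGF-beta1.
#'
#' @param kind `"constant"`, `"pulse"` or `"zero"`.
#' @param amplitude non-negative stimulus amplitude.
#' @param duration pulse duration in hours (pulse only, must be > 0).
#' @param onset onset time in hours.
#' @return an `sw_stimulus` object.
#' @export
stimulus <- function(kind = c("constant", "pulse", "zero"),
                     amplitude = 1, duration = NULL, onset = 0) {
  kind <- match.arg(kind)
  if (amplitude < 0) abort("stimulus amplitude must be >= 0")
  if (kind == "pulse") {
    if (is.null(duration) || duration <= 0) {
      abort("pulse stimulus requires duration > 0")
    }
  } else {
    duration <- Inf
  }
  if (kind == "zero") amplitude <- 0
  structure(
    list(kind = kind, amplitude = amplitude, duration = duration,
         onset = onset),
    class = "sw_stimulus"
  )
}

# stimulus level on each half-open interval [t1, t2)
sw_stim_level <- function(stim, t) {
  if (stim$kind == "zero" || stim$amplitude == 0) return(0)
  on <- t >= stim$onset & t < stim$onset + stim$duration
  ifelse(on, stim$amplitude, 0)
}

sw_stim_breaks <- function(stim) {
  b <- numeric(0)
  if (stim$kind != "zero" && stim$amplitude > 0) {
    b <- c(stim$onset, stim$onset + stim$duration)
  }
  b[is.finite(b)]
}

#' Inhibitor interventions
#'
#' An inhibitor multiplies its targeted rate by `1 - eps` inside
#' `[start, end)`:
#' * `SMAD_PHOS` — the receptor-driven SMAD phosphorylation flux
#'   (LY2109761-like);
#' * `GLI1_ACT` — the transcriptional output of nuclear GLI1
#'   (GANT61-like);
#' * `GSK3_ACT` — the catalytic activity of the active GSK3 forms, i.e.
#'   GSK3-dependent degradation and the GSK3-AA-driven release of
#'   SUFU-bound GLI1 (SB216763-like). Interconversion between the
#'   phosphorylation forms is unaffected.
#'
#' @param target `"SMAD_PHOS"`, `"GLI1_ACT"` or `"GSK3_ACT"`.
#' @param start,end treatment window in hours (`end` may be `Inf`).
#' @param eps fractional efficacy in `[0, 1]`; defaults are 0.95 for
#'   `SMAD_PHOS` and `GLI1_ACT` and 0.9 for `GSK3_ACT`.
#' @return an `sw_inhibitor` object.
#' @export
inhibitor <- function(target = c("SMAD_PHOS", "GLI1_ACT", "GSK3_ACT"),
                      start = 0, end = Inf, eps = NULL) {
  target <- match.arg(target)
  if (is.null(eps)) {
    eps <- if (target == "GSK3_ACT") 0.9 else 0.95
  }
  if (eps < 0 || eps > 1) abort("inhibitor efficacy eps must be in [0, 1]")
  if (!(start < end)) abort("inhibitor window requires start < end")
  structure(
    list(target = target, start = start, end = end, eps = eps),
    class = "sw_inhibitor"
  )
}

sw_inhib_factors <- function(inhibitors, t) {
  f <- c(SMAD_PHOS = 1, GLI1_ACT = 1, GSK3_ACT = 1)
  for (sp in inhibitors) {
    if (t >= sp$start && t < sp$end) {
      f[sp$target] <- f[sp$target] * (1 - sp$eps)
    }
  }
  f
}

sw_inhib_breaks <- function(inhibitors) {
  b <- unlist(lapply(inhibitors, function(sp) c(sp$start, sp$end)))
  if (is.null(b)) return(numeric(0))
  b[is.finite(b)]
}
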
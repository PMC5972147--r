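#' Built-in simulation contexts
#'
#' A context names a (stimulus, inhibitors) experiment used by calibration
#' targets: `none` (no TGF-beta), `const` (continuous stimulus, amplitude
#' 1), `pulse2`/`pulse8` (pulses of 2 and 8 h), `smad_i_early`/
#' `smad_i_late` (continuous stimulus plus SMAD-phosphorylation inhibition
#' from 0 or 48 h, eps 0.95), `gli_i_early`/`gli_i_late` (GLI1-activity
#' inhibition from 0 or 48 h, eps 0.95) and `gsk_i` (GSK3-activity
#' inhibition, eps 0.9, without TGF-beta).
#'
#' @param id context identifier.
#' @return list with elements `stim` and `inhibitors`.
#' @export
fit_context <- function(id) {
  ctx <- switch(id,
    none = list(stim = stimulus("zero"), inhibitors = list()),
    const = list(stim = stimulus("constant"), inhibitors = list()),
    pulse2 = list(stim = stimulus("pulse", duration = 2), inhibitors = list()),
    pulse8 = list(stim = stimulus("pulse", duration = 8), inhibitors = list()),
    smad_i_early = list(
      stim = stimulus("constant"),
      inhibitors = list(inhibitor("SMAD_PHOS", start = 0))
    ),
    smad_i_late = list(
      stim = stimulus("constant"),
      inhibitors = list(inhibitor("SMAD_PHOS", start = 48))
    ),
    gli_i_early = list(
      stim = stimulus("constant"),
      inhibitors = list(inhibitor("GLI1_ACT", start = 0))
    ),
    gli_i_late = list(
      stim = stimulus("constant"),
      inhibitors = list(inhibitor("GLI1_ACT", start = 48))
    ),
    gsk_i = list(
      stim = stimulus("zero"),
      inhibitors = list(inhibitor("GSK3_ACT", start = 0))
    ),
    NULL
  )
  if (is.null(ctx)) abort(paste0("unknown fit context '", id, "'"))
  ctx
}

#' Calibration constraints (fit targets)
#'
#' A fit target pins the simulated fold change of one species at one time
#' in one context, either directly (`type = "fold"`) or as a ratio to the
#' same species/time in a reference context (`type = "ratio"`, e.g.
#' "SNAIL1 mRNA under early inhibition relative to control").
#' `cmp` selects a two-sided constraint (`"eq"`) or a one-sided bound
#' (`"ge"`/`"le"`, penalised only when violated).
#'
#' @param species species name.
#' @param time_h measurement time in hours.
#' @param context context id, see [fit_context()].
#' @param target positive target value (fold change or ratio).
#' @param tol relative tolerance (> 0) used to normalise the residual.
#' @param weight non-negative weight.
#' @param type `"fold"` or `"ratio"`.
#' @param ref_context reference context for ratios (may equal `context`
#'   for within-context shape constraints).
#' @param ref_time_h reference time for ratios (defaults to `time_h`).
#' @param cmp `"eq"`, `"ge"` or `"le"`.
#' @return one-row tibble; rows can be combined with `dplyr::bind_rows()`.
#' @export
fit_target <- function(species, time_h, context, target, tol = 0.2,
                       weight = 1, type = c("fold", "ratio"),
                       ref_context = NA_character_,
                       ref_time_h = NA_real_,
                       cmp = c("eq", "ge", "le")) {
  type <- match.arg(type)
  cmp <- match.arg(cmp)
  if (target <= 0) abort("fit target value must be > 0")
  if (tol <= 0) abort("fit target tolerance must be > 0")
  if (type == "ratio" && is.na(ref_context)) {
    abort("ratio targets need a ref_context")
  }
  if (type == "ratio" && is.na(ref_time_h)) ref_time_h <- time_h
  tibble(
    species = species, time_h = time_h, context = context,
    type = type, ref_context = ref_context, ref_time_h = ref_time_h,
    target = target, tol = tol, weight = weight, cmp = cmp
  )
}

sw_check_targets <- function(targets) {
  need <- c(
    "species", "time_h", "context", "type", "ref_context", "ref_time_h",
    "target", "tol", "weight", "cmp"
  )
  miss <- setdiff(need, names(targets))
  if (length(miss) > 0) {
    abort(paste0(
      "fit target table is missing column(s): ",
      paste(miss, collapse = ", ")
    ))
  }
  if (any(targets$target <= 0)) abort("fit target values must be > 0")
  if (any(targets$tol <= 0)) abort("fit target tolerances must be > 0")
  invisible(targets)
}

#' Read / write fit-target tables as JSON
#'
#' The on-disk document carries a `schema_version` field and a `targets`
#' array whose records mirror the columns of [fit_target()].
#'
#' @param path file path.
#' @return for `read_fit_targets`, a tibble of targets.
#' @export
read_fit_targets <- function(path) {
  doc <- jsonlite::fromJSON(path)
  if (is.null(doc$schema_version)) {
    abort(paste0("'", path, "': missing field 'schema_version'"))
  }
  if (is.null(doc$targets)) {
    abort(paste0("'", path, "': missing field 'targets'"))
  }
  tg <- as_tibble(doc$targets)
  if (!"ref_context" %in% names(tg)) tg$ref_context <- NA_character_
  if (!"ref_time_h" %in% names(tg)) tg$ref_time_h <- NA_real_
  tg$ref_time_h <- ifelse(
    tg$type == "ratio" & is.na(tg$ref_time_h), tg$time_h, tg$ref_time_h
  )
  if (!"cmp" %in% names(tg)) tg$cmp <- "eq"
  if (!"weight" %in% names(tg)) tg$weight <- 1
  sw_check_targets(tg)
}

#' @rdname read_fit_targets
#' @param targets tibble of fit targets.
#' @export
write_fit_targets <- function(targets, path) {
  sw_check_targets(targets)
  jsonlite::write_json(
    list(schema_version = 1L, targets = targets),
    path,
    auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE
  )
  invisible(path)
}

#' Packaged constraint files
#'
#' Lists (or resolves) the fold-change constraint tables shipped with the
#' package, one per experiment-derived constraint set.
#'
#' @param name optional file name (without directory); if missing, all
#'   available names are returned.
#' @return file path(s) or names.
#' @export
packaged_targets <- function(name = NULL) {
  dir <- system.file("extdata", "targets", package = "snailwave")
  if (is.null(name)) {
    return(list.files(dir, pattern = "[.]json$"))
  }
  path <- file.path(dir, name)
  if (!file.exists(path)) {
    abort(paste0("no packaged target file '", name, "'"))
  }
  path
}

#' All packaged calibration constraints, combined
#'
#' Binds every packaged constraint table into one target
#' tibble; this is the constraint set used to calibrate the FULL model.
#'
#' @return tibble of fit targets.
#' @export
calibration_targets <- function() {
  dplyr::bind_rows(lapply(packaged_targets(), function(f) {
    read_fit_targets(packaged_targets(f))
  }))
}

# Evaluate the simulated values for every target row.
# Returns the targets tibble with a `sim` column, or NULL on simulation
# failure. Context trajectories are computed once per parameter set.
sw_eval_targets <- function(model, params, targets, basal = NULL) {
  ctx_ids <- unique(c(targets$context, stats::na.omit(targets$ref_context)))
  if (is.null(basal)) basal <- basal_state(model, params)
  if (!basal$converged) return(NULL)
  times <- sort(unique(c(
    0, targets$time_h, stats::na.omit(targets$ref_time_h)
  )))
  sims <- list()
  for (id in ctx_ids) {
    ctx <- fit_context(id)
    tr <- try(
      simulate_network(model, params, ctx$stim, ctx$inhibitors,
        t_grid = times, basal = basal
      ),
      silent = TRUE
    )
    if (inherits(tr, "try-error")) return(NULL)
    sims[[id]] <- tr
  }
  v <- numeric(nrow(targets))
  for (id in ctx_ids) {
    sel <- which(targets$context == id)
    if (length(sel) > 0) {
      tr <- sims[[id]]
      idx <- match(targets$time_h[sel], tr$time_h)
      v[sel] <- vapply(
        seq_along(sel),
        function(k) tr[[targets$species[sel[k]]]][idx[k]],
        numeric(1)
      )
    }
  }
  ratio <- which(targets$type == "ratio")
  if (length(ratio) > 0) {
    for (k in ratio) {
      tr <- sims[[targets$ref_context[k]]]
      i <- match(targets$ref_time_h[k], tr$time_h)
      v[k] <- v[k] / tr[[targets$species[k]]][i]
    }
  }
  out <- targets
  out$sim <- v
  out
}

# normalised residuals (one-sided for ge/le)
sw_residuals <- function(evaluated) {
  r <- (evaluated$sim - evaluated$target) / (evaluated$tol * evaluated$target)
  r[evaluated$cmp == "ge"] <- pmin(0, r[evaluated$cmp == "ge"])
  r[evaluated$cmp == "le"] <- pmax(0, r[evaluated$cmp == "le"])
  r
}

#' Weighted calibration cost
#'
#' Sum over targets of `weight * ((sim - target) / (tol * target))^2`,
#' with one-sided targets contributing only when violated. A parameter set
#' whose basal state does not converge or whose simulation fails receives
#' a large finite penalty (1e6) rather than an error, so searches can move
#' on.
#'
#' @inheritParams basal_state
#' @param targets tibble of fit targets (see [fit_target()]).
#' @return non-negative scalar cost.
#' @examples
#' m <- build_model("SMAD_ONLY")
#' target_cost(default_params(m), m, fit_target("pSMAD_nuc", 12, "const", 3))
#' @export
target_cost <- function(params, model, targets) {
  sw_check_targets(targets)
  if (nrow(targets) == 0) return(0)
  ev <- sw_eval_targets(model, params, targets)
  if (is.null(ev)) return(1e6)
  r <- sw_residuals(ev)
  sum(ev$weight * r^2)
}
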
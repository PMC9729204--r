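# Run configuration and task presets.  A preset fixes the orientation and the
# distance/position models from four-number ranges in the order
# (MinO, MaxO, Min, Max) = (optimal range, permitted range); the limiting
# bounds MinL/MaxL are extended beyond the permitted range by the same margin
# the built-in defaults use (20 for the primer distance, 0 for Pos).

.PRESETS <- list(
  generic           = list(task = "generic", orientation = "face-to-face",
                           dis = c(120, 160, 80, 200), pos = NULL),
  sanger_genotyping = list(task = "genotyping", orientation = "face-to-face",
                           dis = c(530, 570, 500, 600), pos = c(100, 150, 70, 300)),
  arms              = list(task = "arms", orientation = "face-to-face",
                           dis = c(120, 160, 80, 200), pos = c(0, 0, 0, 0)),
  inverse           = list(task = "inverse", orientation = "back-to-back",
                           dis = c(5, 10, 0, 15), pos = c(10, 20, 5, 45)),
  anchored          = list(task = "anchored", orientation = "unidirectional",
                           dis = c(-15, -10, -30, -5), pos = c(10, 20, 5, 45))
)
.DIS_MARGIN <- 20
.POS_MARGIN <- 0

#' Expand a four-number range into six model parameters
#'
#' Accepts the compact comma-separated form used in task tables —
#' `"MinO,MaxO,Min,Max"` (optimal range then permitted range) — or six
#' numbers, and returns full [model_params()].  With four numbers the
#' limiting bounds are set to `Min - margin` / `Max + margin`.
#'
#' @param x numeric vector of length 4 or 6, or a comma-separated string.
#' @param margin extension applied to the permitted range for the limits.
#' @return a [model_params()] object.
#' @export
parse_params <- function(x, margin = 0) {
  if (is.character(x)) x <- as.numeric(strsplit(gsub(" ", "", x), ",")[[1]])
  if (length(x) == 6L) return(model_params(x))
  if (length(x) != 4L) stop("expected 4 or 6 comma-separated numbers")
  model_params(c(x[1], x[2], x[3], x[4], x[3] - margin, x[4] + margin))
}

#' Build a run configuration
#'
#' Collects every knob of a design run: the task and orientation, the
#' distance and position models, optimal Tm, candidate walking grid,
#' efficiency/seed parameters, thermodynamic conditions and weight tables.
#' [apply_preset()] is the usual entry point; `run_config()` gives the
#' generic defaults.
#'
#' @param task one of `generic`, `genotyping`, `arms`, `inverse`, `anchored`,
#'   `full_covered`, `evaluate`.
#' @param orientation `face-to-face`, `back-to-back` or `unidirectional`.
#' @param dis_params,pos_params [model_params()] (or 4/6-number inputs for
#'   [parse_params()]).
#' @param opt_tm optimal primer Tm, degrees C.
#' @param n_return ranked pairs returned per target/region (default 3).
#' @param min_len,max_len,pos_step,len_step candidate walking grid.
#' @param word seed word size for the specificity search.
#' @param efficiency_cutoff minimum retained binding/product efficiency.
#' @param dimer_tm cross-dimer reporting threshold, degrees C.
#' @param poly_min minimum homopolymer run length reported.
#' @param thermo [thermo_conditions()].
#' @param weights weight tables as in [default_weights()].
#' @param model_overrides named list of [model_params()] overriding registry
#'   entries (see [feature_models()]).
#' @param tiling_count,tiling_spacing full-coverage tiling: number of windows
#'   or window spacing in bases.
#' @return list of class `run_config`.
#' @export
run_config <- function(task = "generic", orientation = "face-to-face",
                       dis_params = c(120, 160, 100, 180, 80, 200),
                       pos_params = c(10, 20, 5, 45, 5, 45),
                       opt_tm = 60, n_return = 3L,
                       min_len = 18L, max_len = 30L,
                       pos_step = 1L, len_step = 2L,
                       word = 7L, efficiency_cutoff = 1e-4,
                       dimer_tm = 45, poly_min = 4L,
                       thermo = thermo_conditions(),
                       weights = default_weights(),
                       model_overrides = list(),
                       tiling_count = NULL, tiling_spacing = NULL) {
  task <- match.arg(task, c("generic", "genotyping", "arms", "inverse",
                            "anchored", "full_covered", "evaluate"))
  orientation <- match.arg(orientation, c("face-to-face", "back-to-back",
                                          "unidirectional"))
  cfg <- list(task = task, orientation = orientation,
              dis_params = parse_params(dis_params, .DIS_MARGIN),
              pos_params = parse_params(pos_params, .POS_MARGIN),
              opt_tm = opt_tm, n_return = as.integer(n_return),
              min_len = as.integer(min_len), max_len = as.integer(max_len),
              pos_step = as.integer(pos_step), len_step = as.integer(len_step),
              word = as.integer(word), efficiency_cutoff = efficiency_cutoff,
              dimer_tm = dimer_tm, poly_min = as.integer(poly_min),
              thermo = thermo, weights = weights,
              model_overrides = model_overrides,
              tiling_count = tiling_count, tiling_spacing = tiling_spacing)
  lapply(weights, .validate_weights)
  structure(cfg, class = "run_config")
}

#' Expand a design-task preset
#'
#' Fills the orientation and the distance/position models of a named task
#' preset (`generic`, `sanger_genotyping`, `arms`, `inverse`, `anchored`,
#' plus `full_covered` and `evaluate` which reuse the generic geometry).
#' User overrides win over preset values.  Expansion is pure: the same preset
#' and overrides always give the same configuration.
#'
#' @param preset preset name.
#' @param ... overrides passed to [run_config()] (e.g. `opt_tm`,
#'   `dis_params = "530,570,500,600"`).
#' @return a `run_config` object.
#' @export
apply_preset <- function(preset, ...) {
  extra <- c("full_covered", "evaluate")
  if (!preset %in% c(names(.PRESETS), extra))
    stop("unknown preset '", preset, "'; valid: ",
         paste(c(names(.PRESETS), extra), collapse = ", "))
  p <- if (preset %in% extra)
    utils::modifyList(.PRESETS$generic, list(task = preset))
  else .PRESETS[[preset]]
  args <- list(task = p$task, orientation = p$orientation,
               dis_params = parse_params(p$dis, .DIS_MARGIN))
  if (!is.null(p$pos)) args$pos_params <- parse_params(p$pos, .POS_MARGIN)
  user <- list(...)
  if (!is.null(user$dis_params)) user$dis_params <- parse_params(user$dis_params, .DIS_MARGIN)
  if (!is.null(user$pos_params)) user$pos_params <- parse_params(user$pos_params, .POS_MARGIN)
  do.call(run_config, utils::modifyList(args, user))
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config> task=", x$task, " orientation=", x$orientation,
      " opt_tm=", x$opt_tm, "\n  dis=(",
      paste(signif(unclass(x$dis_params), 6), collapse = ", "), ")  pos=(",
      paste(signif(unclass(x$pos_params), 6), collapse = ", "), ")\n",
      "  lengths ", x$min_len, "-", x$max_len, " step ", x$pos_step, "/",
      x$len_step, ", n_return ", x$n_return, "\n", sep = "")
  invisible(x)
}
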
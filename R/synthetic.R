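#' Synthetic plate-reader dataset configuration
#'
#' Describes a simulated kinetic ECA plate: the cell-line preset that drives
#' the latent lactate kinetics, the modulator dose applied in each plate
#' condition, the affine lactate-to-RFU map of the virtual sensor, a
#' multiplicative noise level, a linear instrument drift shared by every
#' well of the plate (including the cell-free controls, so that cell-free
#' normalization cancels it exactly), the replicate count and the
#' acquisition grid.
#'
#' @param cell_line preset name passed to [eca_preset()].
#' @param params optional [eca_params()] object driving the latent kinetics;
#'   overrides the preset looked up from `cell_line` when given.
#' @param doses named list of [eca_dose()] per condition; default control
#'   (0, 0), oligo (5, 0) and dg2 (0, 5) — mid-range of the 0-10 model-unit
#'   sweep domain, since the wet-lab doses have no defined model-unit image.
#' @param a,b affine map from Lac_ex (um) to RFU: `rfu = a * Lac_ex + b`.
#' @param sigma multiplicative noise standard deviation (fraction of the
#'   instantaneous signal).
#' @param drift_slope,drift_intercept shared linear drift profile
#'   `drift(t) = drift_intercept + drift_slope * t`, applied multiplicatively.
#' @param replicates wells per condition (the assay ran triplicates).
#' @param grid an [eca_grid()]; default 400 samples at 0.35 min.
#' @param seed integer seed; mandatory.
#' @return An object of class `eca_generator_config`.
#' @export
generator_config <- function(cell_line = "A549", params = NULL,
                             doses = list(control = eca_dose(0, 0),
                                          oligo = eca_dose(oligo = 5),
                                          dg2 = eca_dose(dg2 = 5)),
                             a = 0.004, b = 10, sigma = 0.01,
                             drift_slope = 0.002, drift_intercept = 1,
                             replicates = 3L, grid = eca_grid(), seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (a <= 0) stop("affine scale `a` must be positive", call. = FALSE)
  if (sigma < 0) stop("`sigma` must be nonnegative", call. = FALSE)
  if (replicates < 1L) stop("need at least one replicate", call. = FALSE)
  stopifnot(inherits(grid, "eca_grid"))
  if (!length(doses) || is.null(names(doses)) ||
      !all(names(doses) %in% c("control", "oligo", "dg2"))) {
    stop("`doses` must be a named list with names among control/oligo/dg2",
         call. = FALSE)
  }
  if (is.null(params)) params <- eca_preset(cell_line) else validate_params(params)
  structure(list(cell_line = cell_line, params = params, doses = doses, a = a, b = b,
                 sigma = sigma, drift_slope = drift_slope,
                 drift_intercept = drift_intercept,
                 replicates = as.integer(replicates), grid = grid,
                 seed = as.integer(seed)),
            class = "eca_generator_config")
}

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Generate a synthetic kinetic ECA plate
#'
#' Simulates the latent extracellular lactate course for each condition with
#' the configured preset and dose, maps it through the virtual sensor and
#' emits one [eca_curve()] per well:
#' `RFU(t) = drift(t) * (a * Lac_ex(t) + b) * (1 + eps)` for sample wells and
#' `RFU(t) = drift(t) * b * (1 + eps)` for cell-free wells, with
#' `eps ~ N(0, sigma^2)` independent per well and time point. One cell-free
#' well is produced per replicate index. Output is reproducible from the
#' seed. The pre-starvation initial ECA spike seen in unstarved cells is not
#' emulated: the model targets the starved regime.
#'
#' @param config an [generator_config()].
#' @return An object of class `eca_dataset`: `curves` (list of
#'   [eca_curve()]), `latent` (per-condition drift-free noiseless signal
#'   `a * Lac_ex + b`), and the `config`.
#' @export
generate_eca_dataset <- function(config) {
  stopifnot(inherits(config, "eca_generator_config"))
  params <- config$params
  t <- config$grid$points
  drift <- config$drift_intercept + config$drift_slope * t
  latent <- lapply(config$doses, function(d) {
    traj <- simulate_eca(params, d, config$grid)
    config$a * traj$states[, "Lac_ex"] + config$b
  })
  curves <- with_local_seed(config$seed, {
    out <- list()
    for (cond in names(config$doses)) {
      for (r in seq_len(config$replicates)) {
        eps <- stats::rnorm(length(t), 0, config$sigma)
        out[[length(out) + 1L]] <- eca_curve(
          times = t,
          rfu = drift * latent[[cond]] * (1 + eps),
          cell_line = config$cell_line, condition = cond, replicate = r,
          is_cell_free = FALSE,
          well = sprintf("%s_r%d", cond, r))
      }
    }
    for (r in seq_len(config$replicates)) {
      eps <- stats::rnorm(length(t), 0, config$sigma)
      out[[length(out) + 1L]] <- eca_curve(
        times = t,
        rfu = drift * config$b * (1 + eps),
        cell_line = config$cell_line, condition = "control", replicate = r,
        is_cell_free = TRUE,
        well = sprintf("cellfree_r%d", r))
    }
    out
  })
  structure(list(curves = curves, latent = latent, config = config),
            class = "eca_dataset")
}

#' @export
print.eca_dataset <- function(x, ...) {
  cat(sprintf("<eca_dataset> %d wells x %d time points (%s, seed %d)\n",
              length(x$curves), length(x$config$grid$points),
              x$config$cell_line, x$config$seed))
  invisible(x)
}

#' Generate a parameter-recovery bundle
#'
#' A harness for calibration testing: generates a control-condition dataset
#' from a preset and returns it together with the sealed true values of the
#' declared free parameters, for post-fit comparison.
#'
#' @param cell_line preset name.
#' @param free_names free-parameter names whose true values are recorded.
#' @param sigma multiplicative noise level.
#' @param seed integer seed.
#' @param params optional custom [eca_params()] truth; defaults to the preset.
#' @param ... further arguments passed to [generator_config()].
#' @return List with `dataset` (an `eca_dataset`) and `truth` (named list of
#'   true values of `free_names`).
#' @export
generate_recovery_bundle <- function(cell_line, free_names, sigma, seed,
                                     params = NULL, ...) {
  bad <- setdiff(free_names, param_names())
  if (length(bad)) stop("unknown free parameter(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (is.null(params)) params <- eca_preset(cell_line)
  config <- generator_config(cell_line = cell_line, params = params,
                             doses = list(control = eca_dose(0, 0)),
                             sigma = sigma, seed = seed, ...)
  list(dataset = generate_eca_dataset(config),
       truth = stats::setNames(lapply(free_names, function(nm) params[[nm]]),
                               free_names))
}

#' Normalize and average a generated (or read) plate
#'
#' Convenience preprocessing pipeline matching the declared convention:
#' normalize each sample well by the cell-free control of the same replicate
#' index (falling back to the first cell-free well), then average replicates
#' within each condition.
#'
#' @param curves list of [eca_curve()] objects (an `eca_dataset` is accepted).
#' @return Named list of [eca_norm_curve()], one per condition present.
#' @export
preprocess_plate <- function(curves) {
  if (inherits(curves, "eca_dataset")) curves <- curves$curves
  cf <- Filter(function(c) c$is_cell_free, curves)
  if (!length(cf)) stop("no cell-free control wells present", call. = FALSE)
  cf_by_rep <- stats::setNames(cf, vapply(cf, function(c)
    as.character(c$replicate), character(1)))
  samples <- Filter(function(c) !c$is_cell_free, curves)
  conds <- unique(vapply(samples, `[[`, character(1), "condition"))
  out <- lapply(stats::setNames(conds, conds), function(cond) {
    reps <- Filter(function(c) c$condition == cond, samples)
    normed <- lapply(reps, function(s) {
      ctrl <- cf_by_rep[[as.character(s$replicate)]]
      if (is.null(ctrl)) ctrl <- cf[[1]]
      normalize_by_cell_free(s, ctrl)
    })
    average_replicates(normed)
  })
  out
}
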
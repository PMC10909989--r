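#' One-at-a-time sensitivity sweep
#'
#' Scales a single parameter by multiplicative factors 0.50, 0.60, ..., 1.50
#' (the baseline 1.00 included: five decrements, five increments, eleven
#' simulations in all) while holding every other parameter fixed, and
#' simulates each variant.
#'
#' @param params an [eca_params()] base set.
#' @param name parameter to sweep: any rate constant, capacity or `glu_ex0`.
#' @param dose an [eca_dose()] applied to every run.
#' @param grid an [eca_grid()].
#' @param step step between factors (default 0.1; 0 collapses all runs onto
#'   the baseline).
#' @return An object of class `eca_oat_sweep`: `parameter`, `factors`
#'   (length 11), `trajectories`, `metrics` (per-factor [summarize_eca()]).
#' @export
oat_sweep <- function(params, name, dose = eca_dose(), grid = eca_grid(),
                      step = 0.1) {
  validate_params(params)
  if (!name %in% param_names()) {
    stop("unknown parameter `", name, "`; sweepable: ",
         paste(param_names(), collapse = ", "), call. = FALSE)
  }
  factors <- 1 + step * (-5:5)
  runs <- lapply(factors, function(f) {
    args <- params[param_names()]
    args[[name]] <- args[[name]] * f
    simulate_eca(do.call(eca_params, args), dose, grid)
  })
  structure(list(parameter = name, factors = factors,
                 trajectories = runs,
                 metrics = lapply(runs, summarize_eca)),
            class = "eca_oat_sweep")
}

#' Modulator dose-response sweep
#'
#' Simulates the model over a grid of doses of one modulator (integer doses
#' 0-10 by default, the published sweep domain), holding the other modulator
#' at zero.
#'
#' @param params an [eca_params()] object.
#' @param modulator `"oligo"` or `"dg2"`.
#' @param doses nonnegative increasing dose vector.
#' @param grid an [eca_grid()].
#' @return An object of class `eca_dose_sweep`: `modulator`, `doses`,
#'   `trajectories`, `metrics`.
#' @export
dose_sweep <- function(params, modulator = c("oligo", "dg2"),
                       doses = 0:10, grid = eca_grid()) {
  modulator <- match.arg(modulator)
  validate_params(params)
  doses <- as.numeric(doses)
  if (any(doses < 0) || any(!is.finite(doses)) || is.unsorted(doses, strictly = TRUE)) {
    stop("doses must be nonnegative, finite and strictly increasing", call. = FALSE)
  }
  runs <- lapply(doses, function(d) {
    dd <- if (modulator == "oligo") eca_dose(oligo = d) else eca_dose(dg2 = d)
    simulate_eca(params, dd, grid)
  })
  structure(list(modulator = modulator, doses = doses,
                 trajectories = runs,
                 metrics = lapply(runs, summarize_eca)),
            class = "eca_dose_sweep")
}

#' Ranked sensitivity table
#'
#' Summarizes one or more one-at-a-time sweeps into a table of maximal
#' relative changes (versus the baseline factor 1.0 run) in the lactate peak,
#' its time, and the glucose exhaustion time. Rows are sorted by peak
#' sensitivity, descending, ties broken alphabetically by parameter name.
#'
#' @param sweeps list of `eca_oat_sweep` objects (at least one).
#' @return A data.frame with columns `parameter`, `max_rel_dpeak`,
#'   `max_rel_dpeak_time`, `max_rel_dexhaustion_time`.
#' @export
sensitivity_report <- function(sweeps) {
  if (inherits(sweeps, "eca_oat_sweep")) sweeps <- list(sweeps)
  if (!length(sweeps)) stop("need at least one sweep", call. = FALSE)
  rel_change <- function(vals, base) {
    if (!is.finite(base)) {
      # baseline never reaches the threshold: report 0 if no variant does either
      if (all(!is.finite(vals))) return(0)
      return(Inf)
    }
    if (base == 0) return(max(abs(vals)))
    max(abs(vals - base) / abs(base))
  }
  rows <- lapply(sweeps, function(sw) {
    stopifnot(inherits(sw, "eca_oat_sweep"))
    i0 <- which.min(abs(sw$factors - 1))
    get <- function(field) vapply(sw$metrics, `[[`, numeric(1), field)
    peaks <- get("lac_ex_peak")
    ptimes <- get("lac_ex_peak_time")
    etimes <- get("glucose_exhaustion_time")
    data.frame(parameter = sw$parameter,
               max_rel_dpeak = rel_change(peaks, peaks[i0]),
               max_rel_dpeak_time = rel_change(ptimes, ptimes[i0]),
               max_rel_dexhaustion_time = rel_change(etimes, etimes[i0]))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$max_rel_dpeak, out$parameter), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export sweep results as tidy CSV
#'
#' One row per run per metric: columns `parameter`/`modulator`, `factor` or
#' `dose`, `metric`, `value`.
#'
#' @param sweep an `eca_oat_sweep` or `eca_dose_sweep`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  if (inherits(sweep, "eca_oat_sweep")) {
    key <- "factor"; keyvals <- sweep$factors; label <- sweep$parameter
    labname <- "parameter"
  } else if (inherits(sweep, "eca_dose_sweep")) {
    key <- "dose"; keyvals <- sweep$doses; label <- sweep$modulator
    labname <- "modulator"
  } else stop("not a sweep object", call. = FALSE)
  rows <- do.call(rbind, lapply(seq_along(keyvals), function(i) {
    m <- sweep$metrics[[i]]
    data.frame(label = label, key = keyvals[i],
               metric = names(m), value = unlist(m, use.names = FALSE))
  }))
  names(rows) <- c(labname, key, "metric", "value")
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
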